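# Annotation triage filters and alignment conservation.

annot_fixture <- function() {
  data.frame(
    gene = c("IDH1", "OGDHL", "BIGGENE", "WILD", "GOFG"),
    ec_number = c("1.1.1.42", "1.2.4.2", "2.7.11.1", "1.1.-.-", "2.1.1.43"),
    protein_length = c(414L, 1010L, 1500L, 1400L, NA),
    known_gof = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

test_that("missense filter subsets by class", {
  rec <- make_records(rep("G1", 5), sprintf("P%d", 1:5),
                      c("p.A1T", "p.A2T", "p.A3T", "p.R4*", "p.R5*"),
                      class = c(rep("missense", 3), rep("nonsense", 2)))
  out <- filter_missense(rec)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_removed"), 2)
  expect_equal(nrow(filter_missense(rec[rec$mutation_class == "nonsense", ])), 0)
  expect_equal(nrow(filter_missense(rec[0, ])), 0)
})

test_that("germline removal is strict in MAF and keys on gene+change", {
  v <- make_records(c("G1", "G1", "G2"), c("P1", "P2", "P3"),
                    c("p.A1T", "p.A2T", "p.A3T"))
  gl <- data.frame(gene = c("G1", "G1"),
                   protein_change = c("p.A1T", "p.A2T"),
                   maf = c(0.02, 0.01), stringsAsFactors = FALSE)
  out <- filter_germline(v, gl)
  expect_equal(out$protein_change, c("p.A2T", "p.A3T"))  # 0.01 retained
  expect_equal(attr(out, "removed")$reason, "germline")
  expect_error(filter_germline(v, transform(gl, maf = c(0.7, 0.01))),
               "0, 0.5")
})

test_that("enzyme filter needs an EC number; wildcards count", {
  v <- make_records(c("IDH1", "NOEC", "WILD", "UNKNOWN"),
                    c("P1", "P2", "P3", "P4"),
                    c("p.R132H", "p.A1T", "p.A2T", "p.A3T"))
  ann <- annot_fixture()
  ann <- rbind(ann, data.frame(gene = "NOEC", ec_number = NA,
                               protein_length = 100L, known_gof = FALSE))
  out <- filter_enzyme(v, ann)
  expect_equal(sort(out$gene), c("IDH1", "WILD"))
  rm <- attr(out, "removed")
  expect_equal(rm$reason[rm$gene == "NOEC"], "no_ec")
  expect_equal(rm$reason[rm$gene == "UNKNOWN"], "no_annotation")
})

test_that("known gain-of-function genes are excluded", {
  v <- make_records(c("IDH1", "OGDHL"), c("P1", "P2"),
                    c("p.R132H", "p.A400T"))
  out <- filter_known_gof(v, annot_fixture())
  expect_equal(out$gene, "OGDHL")
  # empty exclusion list is the identity
  expect_equal(nrow(filter_known_gof(v, character(0))), 2)
  # shipped curated list covers the canonical drivers
  expect_true(all(c("IDH1", "IDH2", "EZH2", "PIK3CA", "BRAF") %in%
                    known_gof_genes()))
})

test_that("length filter is strict at the bound and flags missing", {
  v <- make_records(c("WILD", "BIGGENE", "GOFG"), c("P1", "P2", "P3"),
                    c("p.A1T", "p.A2T", "p.A3T"))
  out <- filter_length(v, annot_fixture())
  expect_equal(sort(out$gene), c("GOFG", "WILD"))  # 1400 kept, 1500 removed
  expect_equal(out$flag_length_missing[out$gene == "GOFG"], TRUE)
  expect_equal(attr(out, "removed")$reason, "too_long")
})

test_that("sequence filters commute and reconstruct the input", {
  v <- make_records(c("IDH1", "NOANN", "G1", "G1", "WILD"),
                    sprintf("P%d", 1:5),
                    c("p.R132H", "p.A1T", "p.A2T", "p.A3T", "p.A4T"),
                    class = c(rep("missense", 4), "synonymous"))
  gl <- data.frame(gene = "G1", protein_change = "p.A2T", maf = 0.2)
  ann <- annot_fixture()
  apply_all <- function(ord) {
    funs <- list(m = filter_missense,
                 g = function(x) filter_germline(x, gl),
                 e = function(x) filter_enzyme(x, ann))
    out <- v
    for (f in ord) out <- funs[[f]](out)
    sort(out$source_row)
  }
  ords <- list(c("m", "g", "e"), c("e", "g", "m"), c("g", "e", "m"))
  results <- lapply(ords, apply_all)
  expect_equal(results[[1]], results[[2]])
  expect_equal(results[[1]], results[[3]])
  # removed + kept reconstructs the input exactly
  out <- filter_germline(v, gl)
  expect_setequal(c(out$source_row, attr(out, "removed")$source_row),
                  v$source_row)
  # idempotence
  out2 <- filter_germline(out, gl)
  expect_equal(nrow(out2), nrow(out))
})

test_that("conservation maps ungapped positions through gapped columns", {
  # reference has a gap before position 3, so ungapped pos 3 = column 4
  # column 4 residues: ref D, h1 D, h2 N, h3 gap -> 2 of 3 non-gap match
  seqs <- c(ref = "AC-DE", h1 = "ACGDE", h2 = "AC-ND", h3 = "AC--E")
  path <- write_fixture_alignment(seqs)
  r <- conservation_at(path, "ref", 3)
  expect_equal(r$column, 4L)
  expect_equal(r$reference_residue, "D")
  expect_equal(r$n_homologs, 3L)
  expect_equal(r$fraction_identical, 2 / 3)
})

test_that("conservation fractions with and without gaps", {
  mk <- function(col_residues) {
    seqs <- paste0("AA", col_residues, "AA")
    names(seqs) <- c("ref", sprintf("h%d", seq_along(seqs)[-1]))
    write_fixture_alignment(seqs)
  }
  # 10 sequences all A at the column
  r <- conservation_at(mk(rep("A", 10)), "ref", 3)
  expect_equal(r$fraction_identical, 1.0)
  # 9 A, one T
  r <- conservation_at(mk(c(rep("A", 9), "T")), "ref", 3)
  expect_equal(r$fraction_identical, 0.9)
  # 8 A, 1 T, 1 gap: hand count with gap exclusion -> 8/9
  r <- conservation_at(mk(c(rep("A", 8), "T", "-")), "ref", 3)
  expect_equal(r$fraction_identical, 8 / 9)
  expect_equal(r$n_homologs, 9L)
})

test_that("conservation agrees with a brute-force column scan", {
  aln <- gen_alignment(n_sequences = 20, length = 200,
                       conserved = c(5, 50, 117), divergence_rate = 0.3,
                       gap_rate = 0.05, seed = 9)
  mat <- do.call(rbind, strsplit(unname(aln), ""))
  for (pos in c(1, 5, 50, 117, 200)) {
    r <- conservation_at(aln, "ref", pos)
    col <- mat[, r$column]
    keep <- col != "-"
    expect_equal(r$fraction_identical,
                 sum(col[keep] == mat[1, r$column]) / sum(keep),
                 label = sprintf("pos %d", pos))
  }
  expect_equal(conservation_at(aln, "ref", 5)$fraction_identical, 1.0)
})

test_that("conservation errors on bad reference or position", {
  path <- write_fixture_alignment(c(ref = "ACDE", h1 = "ACDE"))
  expect_error(conservation_at(path, "nope", 1), "not in alignment")
  expect_error(conservation_at(path, "ref", 5), "outside")
  expect_error(conservation_at(path, "ref", 0), "outside")
})

test_that("conserved-residue filter is non-strict at the threshold", {
  v <- make_records(c("G1", "G1", "G1"), c("P1", "P2", "P3"),
                    c("p.A1T", "p.A2T", "p.A3T"))
  cons <- data.frame(gene = "G1", position = 1:3,
                     fraction_identical = c(1.0, 0.5, 0.9))
  out <- filter_conserved(v, cons)
  expect_equal(sort(out$position), c(1L, 3L))  # 0.9 retained (non-strict)
  expect_equal(attr(out, "removed")$position, 2L)
})
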