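# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing is read from disk except files these helpers
# write into tempdir().

write_fixture_catalog <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "Gene name\tSample name\tID_tumour\tMutation AA\tMutation Description"
  writeLines(c(header, rows), path)
  path
}

# Six-row catalog covering dedup triples enumerated by hand:
#   IDH1 p.R132H in tumours T1 (twice, two samples), T2  -> 2 unique rows
#   IDH1 p.R100Q in tumour T1                            -> kept (new change)
#   TP53 p.R175H in tumour T1                            -> kept (new gene)
#   BRAF p.V600E in tumour T9                            -> kept
# Expected after deduplicate: 5 records.
six_row_catalog <- function() {
  write_fixture_catalog(c(
    "IDH1\tS1\tT1\tp.R132H\tSubstitution - Missense",
    "IDH1\tS2\tT1\tp.R132H\tSubstitution - Missense",
    "IDH1\tS3\tT2\tp.R132H\tSubstitution - Missense",
    "IDH1\tS1\tT1\tp.R100Q\tSubstitution - Missense",
    "TP53\tS1\tT1\tp.R175H\tSubstitution - Missense",
    "BRAF\tS9\tT9\tp.V600E\tSubstitution - Missense"
  ))
}

# Records data.frame built directly (skipping file round-trip) for filter
# tests.
make_records <- function(gene, patient, change, class = "missense",
                         fathmm = NA_real_) {
  n <- max(length(gene), length(patient), length(change))
  gene <- rep_len(gene, n); patient <- rep_len(patient, n)
  change <- rep_len(change, n); class <- rep_len(class, n)
  fathmm <- rep_len(fathmm, n)
  parsed <- lapply(change, function(x) {
    p <- tryCatch(parse_protein_change(x), error = function(e) NULL)
    if (is.null(p)) list(ref_aa = NA, position = NA, alt_aa = NA) else p
  })
  data.frame(
    gene = toupper(gene), transcript = NA_character_,
    sample_id = paste0("S_", patient), patient_id = patient,
    mutation_class = class,
    protein_change = ifelse(is.na(sapply(parsed, `[[`, "position")),
                            NA_character_, change),
    ref_aa = sapply(parsed, `[[`, "ref_aa"),
    position = as.integer(sapply(parsed, `[[`, "position")),
    alt_aa = sapply(parsed, `[[`, "alt_aa"),
    fathmm_score = fathmm, source_row = seq_len(n),
    stringsAsFactors = FALSE)
}

# n_patients copies of one variant, patients P1..Pk
variant_block <- function(gene, change, k, fathmm = NA_real_) {
  make_records(gene, sprintf("%s_%s_P%d", gene, change, seq_len(k)),
               change, fathmm = fathmm)
}

write_fixture_alignment <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

# Minimal fixed-width PDB writer for hand-placed atoms.
write_fixture_pdb <- function(atoms, path = tempfile(fileext = ".pdb"),
                              extra_lines = NULL) {
  fmt <- "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf(fmt, a$rec, i, sprintf(" %-3s", a$name),
            if (is.null(a$alt)) " " else a$alt, a$resn, a$chain, a$resno,
            " ", a$x, a$y, a$z,
            if (is.null(a$occ)) 1 else a$occ, 0, substr(a$name, 1, 1))
  }, character(1))
  writeLines(c(lines, extra_lines, "END"), path)
  path
}

pdb_atom <- function(rec = "ATOM", name = "CA", resn = "ALA", chain = "A",
                     resno = 1L, x = 0, y = 0, z = 0, occ = 1, alt = " ") {
  data.frame(rec = rec, name = name, resn = resn, chain = chain,
             resno = resno, x = x, y = y, z = z, occ = occ, alt = alt,
             stringsAsFactors = FALSE)
}

# Independent all-pairs minimum-distance oracle (plain loops, no shared
# code with the implementation).
oracle_min_distance <- function(res_xyz, site_xyz) {
  best <- Inf
  for (i in seq_len(nrow(res_xyz))) {
    for (j in seq_len(nrow(site_xyz))) {
      d <- sqrt(sum((res_xyz[i, ] - site_xyz[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Independent binomial upper-tail oracle: direct pmf summation in log
# space, no pbinom.
oracle_binom_tail <- function(n, p, k) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Independent two-tailed Welch p oracle: t statistic from first principles
# and the tail of the t density by adaptive quadrature (no pt()).
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi) -
          (df + 1) / 2 * log1p(x^2 / df))
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}
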