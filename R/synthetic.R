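# Seeded generators for every input the screen consumes, so the whole
# pipeline is testable without external downloads: mutation catalogs with a
# binomial background plus planted hotspots, homolog alignments with
# designated conserved columns, toy PDB structures with a ligand at a known
# distance, and log-normal metabolite matrices with planted fold-change
# effects. Each generator runs on its own RNG stream seeded explicitly and
# restores the caller's random state on exit.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulate a somatic mutation catalog
#'
#' Background: each site of each gene is mutated independently in
#' Binomial(n_samples, background_rate) samples — the same null the
#' recurrence model assumes. Hotspots are planted on top with exact
#' unique-patient counts. One catalog row per (site, sample) event; sample
#' and patient identifiers coincide (one tumour per patient).
#'
#' @param n_samples number of tumours.
#' @param n_genes,sites_per_gene catalog dimensions; genes are named
#'   `GENE1..GENEn` with residues `1..sites_per_gene`.
#' @param background_rate per-sample per-site mutation probability, in
#'   (0, 1).
#' @param hotspots data.frame with columns `gene`, `position`, `ref_aa`,
#'   `alt_aa`, `n_patients`, optional `fathmm_score`.
#' @param seed RNG seed.
#' @param path optional output path; when given the catalog is written as
#'   canonical TSV.
#' @return the catalog record data.frame (canonical columns); attribute
#'   `truth` holds the planted hotspot table.
#' @export
gen_catalog <- function(n_samples = 1000L, n_genes = 20L,
                        sites_per_gene = 500L, background_rate = 1e-4,
                        hotspots = NULL, seed = 1L, path = NULL) {
  stopifnot(background_rate >= 0, background_rate < 1)
  if (!is.null(hotspots)) {
    if (any(hotspots$n_patients > n_samples)) {
      stop("planted hotspot count exceeds n_samples")
    }
    hkey <- paste(hotspots$gene, hotspots$position)
    if (anyDuplicated(hkey)) stop("hotspots collide at the same site")
  }
  with_local_seed(seed, {
    genes <- character(0); pos <- integer(0); samp <- integer(0)
    ref <- character(0); alt <- character(0); fathmm <- numeric(0)
    if (background_rate > 0) {
      for (g in seq_len(n_genes)) {
        k <- stats::rbinom(sites_per_gene, n_samples, background_rate)
        sites <- which(k > 0)
        for (s in sites) {
          who <- sample.int(n_samples, k[s])
          aa <- sample(AA20, 2L)
          genes <- c(genes, rep(sprintf("GENE%d", g), k[s]))
          pos <- c(pos, rep(s, k[s]))
          samp <- c(samp, who)
          ref <- c(ref, rep(aa[1], k[s]))
          alt <- c(alt, rep(aa[2], k[s]))
          fathmm <- c(fathmm, rep(round(stats::runif(1, -8, 2), 2), k[s]))
        }
      }
    }
    if (!is.null(hotspots)) {
      for (i in seq_len(nrow(hotspots))) {
        h <- hotspots[i, ]
        who <- sample.int(n_samples, h$n_patients)
        genes <- c(genes, rep(toupper(h$gene), h$n_patients))
        pos <- c(pos, rep(h$position, h$n_patients))
        samp <- c(samp, who)
        ref <- c(ref, rep(h$ref_aa, h$n_patients))
        alt <- c(alt, rep(h$alt_aa, h$n_patients))
        fs <- if ("fathmm_score" %in% names(h) && !is.na(h$fathmm_score)) {
          h$fathmm_score
        } else -5
        fathmm <- c(fathmm, rep(fs, h$n_patients))
      }
    }
    cat_df <- data.frame(
      gene = genes,
      transcript = NA_character_,
      sample_id = sprintf("S%05d", samp),
      patient_id = sprintf("P%05d", samp),
      mutation_class = "missense",
      protein_change = sprintf("p.%s%d%s", ref, pos, alt),
      ref_aa = ref, position = pos, alt_aa = alt,
      fathmm_score = fathmm,
      stringsAsFactors = FALSE
    )
    o <- order(cat_df$gene, cat_df$position, cat_df$sample_id)
    cat_df <- cat_df[o, , drop = FALSE]
    cat_df$source_row <- seq_len(nrow(cat_df))
    rownames(cat_df) <- NULL
    attr(cat_df, "truth") <- hotspots
    if (!is.null(path)) write_catalog(cat_df, path)
    cat_df
  })
}

#' Simulate a homolog multiple sequence alignment
#'
#' A reference sequence plus homologs derived from it: listed conserved
#' positions are identical across all sequences; every other position is
#' substituted independently per homolog with probability
#' `divergence_rate`. Optional gaps are injected into homologs at
#' non-conserved positions.
#'
#' @param n_sequences total sequences (first is the reference, named
#'   `ref`).
#' @param length sequence length (no gaps in the reference, so alignment
#'   columns equal reference positions).
#' @param conserved integer positions held identical in all sequences.
#' @param divergence_rate substitution probability per homolog per
#'   non-conserved position.
#' @param gap_rate probability of a gap in a homolog at a non-conserved
#'   position.
#' @param seed RNG seed.
#' @param path optional aligned-FASTA output path.
#' @return named character vector of aligned sequences.
#' @export
gen_alignment <- function(n_sequences = 10L, length = 100L,
                          conserved = integer(0), divergence_rate = 0.2,
                          gap_rate = 0, seed = 1L, path = NULL) {
  stopifnot(all(conserved >= 1L), all(conserved <= length))
  with_local_seed(seed, {
    ref <- sample(AA20, length, replace = TRUE)
    seqs <- vector("list", n_sequences)
    seqs[[1]] <- ref
    for (i in seq_len(n_sequences - 1L)) {
      s <- ref
      mutable <- setdiff(seq_len(length), conserved)
      flip <- mutable[stats::runif(base::length(mutable)) < divergence_rate]
      for (j in flip) s[j] <- sample(setdiff(AA20, s[j]), 1L)
      if (gap_rate > 0) {
        gap <- mutable[stats::runif(base::length(mutable)) < gap_rate]
        s[gap] <- "-"
      }
      seqs[[i + 1L]] <- s
    }
    out <- vapply(seqs, paste, character(1), collapse = "")
    names(out) <- c("ref", sprintf("homolog%d", seq_len(n_sequences - 1L)))
    if (!is.null(path)) {
      writeLines(paste0(">", names(out), "\n", out), path)
    }
    out
  })
}

#' Simulate a toy structure with a ligand at a known distance
#'
#' A single chain of C-alpha atoms spaced along the x axis plus one hetero
#' ligand atom placed perpendicular to a designated residue, so that
#' residue's minimum distance to the ligand is exactly `ligand_distance`
#' (and it is the closest residue). Written as fixed-width PDB ATOM/HETATM
#' records readable by standard parsers.
#'
#' @param n_residues chain length; residues numbered 1..n, spaced
#'   `spacing` A apart.
#' @param target_residue residue the ligand is placed next to.
#' @param ligand_distance exact distance (A) from the target residue's atom
#'   to the ligand atom.
#' @param spacing inter-residue spacing along x, default 4 A.
#' @param jitter_sd Gaussian coordinate noise (A) applied to non-target
#'   residues only, default 0.
#' @param seed RNG seed (only used when `jitter_sd > 0`).
#' @param path output PDB path (required).
#' @return invisibly, a list with the ground truth: `target_residue`,
#'   `distance`, `chain`.
#' @export
gen_structure <- function(n_residues = 50L, target_residue = 25L,
                          ligand_distance = 5, spacing = 4, jitter_sd = 0,
                          seed = 1L, path) {
  stopifnot(target_residue >= 1L, target_residue <= n_residues)
  with_local_seed(seed, {
    x <- spacing * seq_len(n_residues)
    y <- rep(0, n_residues)
    z <- rep(0, n_residues)
    if (jitter_sd > 0) {
      idx <- setdiff(seq_len(n_residues), target_residue)
      y[idx] <- stats::rnorm(length(idx), 0, jitter_sd)
      z[idx] <- stats::rnorm(length(idx), 0, jitter_sd)
    }
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n_residues), seq_len(n_residues), x, y, z)
    lig <- sprintf(
      "HETATM%5d  C1  LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      n_residues + 1L, n_residues + 1L,
      spacing * target_residue, ligand_distance, 0)
    writeLines(c(lines, lig, "END"), path)
    invisible(list(target_residue = target_residue,
                   distance = ligand_distance, chain = "A", path = path))
  })
}

#' Simulate a normalized-ion-count metabolite matrix
#'
#' Log-normal baseline per metabolite (location drawn per metabolite, scale
#' set from the replicate coefficient of variation), planted multiplicative
#' group effects, and optional left-censoring-style missingness.
#'
#' @param n_metabolites number of metabolites (named `MET1..`, with a
#'   fraction renamed `X-<i>` to mimic unidentified biochemicals when
#'   `unknown_fraction > 0`).
#' @param groups named integer vector: replicates per group label
#'   (e.g. `c(MUT = 3, WT = 3, EV = 3)`).
#' @param cv replicate coefficient of variation on the natural scale,
#'   default 0.10.
#' @param effects data.frame with `metabolite`, `group`, `fold_change`
#'   (> 0) planted multiplicatively.
#' @param missing_rate probability a cell is masked missing, default 0.
#' @param unknown_fraction fraction of metabolites labelled as unknown
#'   composition, default 0.
#' @param seed RNG seed.
#' @return a [metabolite_matrix()]; attribute `truth` holds `effects`.
#' @export
gen_metabolite_matrix <- function(n_metabolites = 50L,
                                  groups = c(A = 3L, B = 3L, C = 3L),
                                  cv = 0.10, effects = NULL,
                                  missing_rate = 0, unknown_fraction = 0,
                                  seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1, cv > 0)
  if (!is.null(effects) && any(effects$fold_change <= 0)) {
    stop("planted fold changes must be positive")
  }
  with_local_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- stats::runif(n_metabolites, log(1e3), log(1e6))
    glabels <- rep(names(groups), groups)
    n_samp <- length(glabels)
    v <- matrix(stats::rlnorm(n_metabolites * n_samp,
                              rep(meanlog, n_samp), sdlog),
                nrow = n_metabolites)
    met_names <- sprintf("MET%d", seq_len(n_metabolites))
    if (unknown_fraction > 0) {
      n_unk <- round(unknown_fraction * n_metabolites)
      if (n_unk > 0) {
        unk <- seq(n_metabolites - n_unk + 1L, n_metabolites)
        met_names[unk] <- sprintf("X-%d", seq_along(unk))
      }
    }
    rownames(v) <- met_names
    colnames(v) <- sprintf("%s_%d", glabels,
                           stats::ave(seq_len(n_samp), glabels,
                                      FUN = seq_along))
    if (!is.null(effects)) {
      for (i in seq_len(nrow(effects))) {
        r <- match(effects$metabolite[i], met_names)
        if (is.na(r)) stop(sprintf("unknown metabolite '%s' in effects",
                                   effects$metabolite[i]))
        cols <- glabels == effects$group[i]
        if (!any(cols)) stop(sprintf("unknown group '%s' in effects",
                                     effects$group[i]))
        v[r, cols] <- v[r, cols] * effects$fold_change[i]
      }
    }
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(v)) < missing_rate, nrow = nrow(v))
      # never blank an entire metabolite
      full <- rowSums(!mask) == 0L
      mask[full, 1L] <- FALSE
      v[mask] <- NA_real_
    }
    mm <- metabolite_matrix(v, glabels)
    attr(mm, "truth") <- effects
    mm
  })
}

#' Write a metabolite matrix to CSV
#' @param mat a [metabolite_matrix()].
#' @param path output CSV path (wide layout: BIOCHEMICAL, SUPER.PATHWAY,
#'   one column per sample).
#' @return `path`, invisibly.
#' @export
write_metabolite_matrix <- function(mat, path) {
  d <- data.frame(BIOCHEMICAL = rownames(mat$values),
                  SUPER.PATHWAY = mat$metabolites$super_pathway,
                  mat$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
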