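# Recurrence/fraction hotspot filters (first- and second-generation screens)
# and the exact binomial null model behind the recurrence cutoffs.

#' Recurrence filter configuration
#'
#' Thresholds for the hotspot filter. The first-generation screen keeps
#' variants seen in at least 3 unique patients that also account for more
#' than 5% of all mutations in the gene; the second generation raises this
#' to 9+ patients, more than 25% of the gene's recurrent (9+) mutations, and
#' adds a pathogenicity cutoff (FATHMM score at or below -3; more negative
#' means more damaging).
#'
#' @param min_patients minimum unique-patient count (non-strict, ">=").
#' @param min_fraction minimum fraction of the gene's mutations (strict ">").
#' @param fraction_basis denominator for the fraction:
#'   `"all_gene_mutations"` (every deduplicated observation in the gene) or
#'   `"recurrent_gene_mutations"` (observations of variants that themselves
#'   meet `min_patients`).
#' @param fathmm_max keep only variants with FATHMM score <= this value;
#'   `NA` disables the cutoff.
#' @param fathmm_missing what to do with variants lacking a FATHMM score when
#'   the cutoff is active: `"keep"` (retained, flagged `fathmm_missing`) or
#'   `"drop"`.
#' @return a `recurrence_config` list.
#' @export
recurrence_config <- function(min_patients = 3L, min_fraction = 0.05,
                              fraction_basis = c("all_gene_mutations",
                                                 "recurrent_gene_mutations"),
                              fathmm_max = NA_real_,
                              fathmm_missing = c("keep", "drop")) {
  fraction_basis <- match.arg(fraction_basis)
  fathmm_missing <- match.arg(fathmm_missing)
  stopifnot(min_patients >= 2L, min_fraction > 0, min_fraction < 1)
  structure(list(min_patients = as.integer(min_patients),
                 min_fraction = min_fraction,
                 fraction_basis = fraction_basis,
                 fathmm_max = fathmm_max,
                 fathmm_missing = fathmm_missing),
            class = "recurrence_config")
}

#' @rdname recurrence_config
#' @export
metis1_config <- function() recurrence_config(3L, 0.05, "all_gene_mutations")

#' @rdname recurrence_config
#' @export
metis2_config <- function() {
  recurrence_config(9L, 0.25, "recurrent_gene_mutations", fathmm_max = -3)
}

#' Summarize unique-patient counts per protein-level variant
#'
#' Builds one summary row per distinct (gene, protein change) among the
#' missense records. The fraction denominators come from the full input:
#' `gene_total` counts every deduplicated observation in the gene (any
#' class), and `gene_recurrent_total` counts only observations of variants
#' that themselves reach `config$min_patients` unique patients.
#'
#' @param records deduplicated mutation records ([deduplicate()]); missense
#'   rows yield the summaries, all rows feed the gene denominators.
#' @param config a [recurrence_config()]; only `min_patients` is used here
#'   (for the recurrent denominator).
#' @return a data.frame with one row per variant: `gene`, `protein_change`,
#'   `ref_aa`, `position`, `alt_aa`, `n_patients`, `gene_total`,
#'   `gene_recurrent_total`, `fraction_all`, `fraction_recurrent`,
#'   `fathmm_score` (per-variant median of available scores).
#' @export
summarize_variants <- function(records, config = metis1_config()) {
  empty <- data.frame(gene = character(), protein_change = character(),
                      ref_aa = character(), position = integer(),
                      alt_aa = character(), n_patients = integer(),
                      gene_total = integer(), gene_recurrent_total = integer(),
                      fraction_all = numeric(), fraction_recurrent = numeric(),
                      fathmm_score = numeric(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)

  mis <- records[records$mutation_class == "missense" &
                   !is.na(records$protein_change), , drop = FALSE]
  if (nrow(mis) == 0L) return(empty)

  key <- paste(mis$gene, mis$protein_change, sep = "\r")
  n_patients <- tapply(mis$patient_id, key, function(x) length(unique(x)))
  first <- mis[!duplicated(key), , drop = FALSE]
  first_key <- paste(first$gene, first$protein_change, sep = "\r")
  fathmm <- tapply(mis$fathmm_score, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) stats::median(x) else NA_real_
  })

  out <- data.frame(
    gene = first$gene,
    protein_change = first$protein_change,
    ref_aa = first$ref_aa,
    position = first$position,
    alt_aa = first$alt_aa,
    n_patients = as.integer(n_patients[first_key]),
    fathmm_score = as.numeric(fathmm[first_key]),
    stringsAsFactors = FALSE
  )

  gene_total_tab <- table(records$gene)
  out$gene_total <- as.integer(gene_total_tab[out$gene])

  rec <- out$n_patients >= config$min_patients
  grt <- tapply(out$n_patients * rec, out$gene, sum)
  out$gene_recurrent_total <- as.integer(grt[out$gene])

  out$fraction_all <- out$n_patients / out$gene_total
  out$fraction_recurrent <- ifelse(out$gene_recurrent_total > 0,
                                   out$n_patients / out$gene_recurrent_total,
                                   NA_real_)
  rownames(out) <- NULL
  out[order(out$gene, out$position, out$alt_aa),
      c("gene", "protein_change", "ref_aa", "position", "alt_aa",
        "n_patients", "gene_total", "gene_recurrent_total",
        "fraction_all", "fraction_recurrent", "fathmm_score")]
}

#' Apply the recurrence/fraction/pathogenicity filter
#'
#' A variant passes iff its unique-patient count reaches
#' `config$min_patients` (non-strict), the selected fraction strictly
#' exceeds `config$min_fraction`, and (when a FATHMM cutoff is set) its
#' score is at or below `config$fathmm_max`. Failures carry a reason code
#' (`min_patients`, `fraction`, `fathmm`); reason codes are assigned in that
#' priority order so they partition the failures.
#'
#' @param summaries output of [summarize_variants()] computed under the same
#'   config.
#' @param config a [recurrence_config()].
#' @return `summaries` with added columns `pass` (logical), `reason`
#'   (`""` for passes) and `flag` (e.g. `fathmm_missing`).
#' @export
apply_recurrence_filter <- function(summaries, config = metis1_config()) {
  s <- summaries
  frac <- switch(config$fraction_basis,
                 all_gene_mutations = s$fraction_all,
                 recurrent_gene_mutations = s$fraction_recurrent)
  n <- nrow(s)
  reason <- character(n)
  flag <- character(n)

  ok_pat <- s$n_patients >= config$min_patients
  ok_frac <- !is.na(frac) & frac > config$min_fraction
  ok_fathmm <- rep(TRUE, n)
  if (!is.na(config$fathmm_max)) {
    miss <- is.na(s$fathmm_score)
    ok_fathmm <- !miss & s$fathmm_score <= config$fathmm_max
    if (config$fathmm_missing == "keep") {
      ok_fathmm[miss] <- TRUE
      flag[miss & ok_pat & ok_frac] <- "fathmm_missing"
    }
  }

  reason[!ok_fathmm] <- "fathmm"
  reason[!ok_frac] <- "fraction"
  reason[!ok_pat] <- "min_patients"

  s$pass <- ok_pat & ok_frac & ok_fathmm
  s$reason <- ifelse(s$pass, "", reason)
  s$flag <- flag
  s
}

#' Most frequent recurrent variant per gene
#'
#' The screen focuses on the most frequent recurrent mutation in each gene:
#' per gene, the variant with the maximal unique-patient count. Ties are
#' broken deterministically by smallest residue position, then alphabetical
#' alternate residue.
#'
#' @param summaries passing variant summaries (rows with `pass == TRUE` are
#'   used if a `pass` column is present).
#' @return one summary row per gene.
#' @export
top_variant_per_gene <- function(summaries) {
  s <- summaries
  if ("pass" %in% names(s)) s <- s[s$pass, , drop = FALSE]
  if (nrow(s) == 0L) return(s)
  o <- order(s$gene, -s$n_patients, s$position, s$alt_aa)
  s <- s[o, , drop = FALSE]
  out <- s[!duplicated(s$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact binomial null probability of site recurrence
#'
#' Probability that a fixed protein site is mutated in at least `k` of
#' `n_samples` tumours when each tumour independently mutates the site with
#' probability `per_sample_site_rate`: the upper tail of
#' Binomial(n_samples, rate). This is the null model used to argue that the
#' recurrence cutoffs (3+ patients in a small catalog, 9+ in a large one)
#' are very unlikely by chance.
#'
#' @param n_samples number of tumours screened.
#' @param per_sample_site_rate per-sample, per-site mutation probability,
#'   in (0, 1).
#' @param k recurrence count of interest.
#' @return P(X >= k); 1 when `k <= 0`, 0 when `k > n_samples`.
#' @examples
#' recurrence_null_pvalue(11000, 1e-6, 3)
#' @export
recurrence_null_pvalue <- function(n_samples, per_sample_site_rate, k) {
  stopifnot(n_samples >= 0, k >= 0)
  if (per_sample_site_rate <= 0 || per_sample_site_rate >= 1) {
    stop("per_sample_site_rate must be in (0, 1)")
  }
  if (k <= 0) return(1)
  if (k > n_samples) return(0)
  stats::pbinom(k - 1, n_samples, per_sample_site_rate, lower.tail = FALSE)
}
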