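# Metabolomic validation screen statistics.
#
# The validation arm profiles cells expressing each candidate mutant, its
# wild-type control, and vector controls (typically 10 groups x 3
# replicates over ~277 semi-quantified metabolites as normalized ion
# counts). Each metabolite is tested with Welch's unequal-variances t-test
# in two kinds of contrasts — one group against all remaining samples
# pooled, and mutant against its own wild-type — with Bonferroni adjustment
# over the metabolite family for the group-vs-rest screen.

#' Construct a metabolite matrix object
#'
#' @param values numeric matrix, metabolites x samples (rownames =
#'   metabolite names, colnames = sample ids); non-negative normalized ion
#'   counts, `NA` for missing.
#' @param groups character vector of group labels, one per sample column.
#' @param metabolite_info optional data.frame with `name`,
#'   `known_composition` (logical), `super_pathway`.
#' @return a `metabolite_matrix` object.
#' @export
metabolite_matrix <- function(values, groups, metabolite_info = NULL) {
  stopifnot(is.matrix(values), length(groups) == ncol(values))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique metabolite rownames")
  }
  if (any(values < 0, na.rm = TRUE)) stop("negative ion counts")
  if (is.null(metabolite_info)) {
    metabolite_info <- data.frame(
      name = rownames(values),
      # the platform labels unidentified biochemicals "X-<number>"
      known_composition = !grepl("^X-", rownames(values)),
      super_pathway = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  structure(list(values = values,
                 samples = data.frame(sample_id = colnames(values),
                                      group = as.character(groups),
                                      stringsAsFactors = FALSE),
                 metabolites = metabolite_info),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix: %d metabolites (%d known, %d unknown) x %d samples in %d groups\n",
              nrow(x$values), sum(x$metabolites$known_composition),
              sum(!x$metabolites$known_composition), ncol(x$values),
              length(unique(x$samples$group))))
  invisible(x)
}

#' Read a metabolite matrix from a delimited file
#'
#' Ingests a wide layout: one row per metabolite, annotation columns named
#' by `name_col`/`pathway_col`, and one numeric column per sample. Sample-
#' to-group assignment comes either from a two-column table
#' (`sample_id`, `group`) or, when `group_map` is `NULL`, by stripping a
#' trailing replicate suffix (`_1`, `-2`, `.3`, ...) from sample names.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param group_map data.frame (`sample_id`, `group`), path to such a TSV,
#'   or `NULL`.
#' @param name_col metabolite-name column, default `"BIOCHEMICAL"`.
#' @param pathway_col super-pathway column, default `"SUPER.PATHWAY"`
#'   (optional in the file).
#' @return a [metabolite_matrix()].
#' @export
read_metabolite_matrix <- function(path, group_map = NULL,
                                   name_col = "BIOCHEMICAL",
                                   pathway_col = "SUPER.PATHWAY") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, sep = sep, header = TRUE, check.names = TRUE,
                         stringsAsFactors = FALSE, quote = "\"",
                         comment.char = "")
  name_col <- make.names(name_col)
  pathway_col <- make.names(pathway_col)
  if (!name_col %in% names(d)) {
    stop(sprintf("metabolite name column '%s' not found", name_col))
  }
  ann_cols <- intersect(c(name_col, pathway_col), names(d))
  sample_cols <- setdiff(names(d), ann_cols)
  vals <- as.matrix(d[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- d[[name_col]]
  if (is.character(group_map) && length(group_map) == 1L) {
    group_map <- utils::read.delim(group_map, stringsAsFactors = FALSE)
  }
  groups <- if (is.null(group_map)) {
    sub("[._-][0-9]+$", "", sample_cols)
  } else {
    g <- group_map$group[match(sample_cols, make.names(group_map$sample_id))]
    g2 <- group_map$group[match(sample_cols, group_map$sample_id)]
    g[is.na(g)] <- g2[is.na(g)]
    if (any(is.na(g))) {
      stop(sprintf("samples missing from group map: %s",
                   paste(sample_cols[is.na(g)], collapse = ", ")))
    }
    g
  }
  info <- data.frame(
    name = d[[name_col]],
    known_composition = !grepl("^X-", d[[name_col]]),
    super_pathway = if (pathway_col %in% names(d)) d[[pathway_col]]
                    else NA_character_,
    stringsAsFactors = FALSE
  )
  metabolite_matrix(vals, groups, info)
}

#' Impute missing ion counts by the per-metabolite minimum
#'
#' Missing values on this kind of platform are left-censored (below
#' detection), so each metabolite's missing entries are filled with its
#' minimum observed value across all samples. The imputation mask is kept
#' as an attribute.
#'
#' @param mat a [metabolite_matrix()].
#' @return the matrix with no missing values; attribute `imputed` is the
#'   logical mask of filled cells.
#' @export
impute_missing <- function(mat) {
  v <- mat$values
  mask <- is.na(v)
  if (any(rowSums(!mask) == 0L)) {
    stop(sprintf("metabolite(s) with no observed values: %s",
                 paste(rownames(v)[rowSums(!mask) == 0L], collapse = ", ")))
  }
  if (any(mask)) {
    mins <- apply(v, 1L, min, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    v[mask] <- mins[idx[, 1L]]
  }
  mat$values <- v
  attr(mat, "imputed") <- mask
  mat
}

#' Welch's unequal-variances t-test
#'
#' Two-sample t with Welch-Satterthwaite degrees of freedom and a two-tailed
#' p-value. Degenerate inputs follow a fixed convention: two constant equal
#' groups give t = 0, p = 1; two constant unequal groups give p = 0 with a
#' `degenerate` flag (the difference is real but the t statistic is
#' undefined).
#'
#' @param group_a,group_b numeric vectors of length >= 2.
#' @return list `(t, df, p, degenerate)`.
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = NA_real_, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m family size (here: the number of metabolites tested in the
#'   contrast).
#' @return q = min(1, p * m).
#' @examples
#' bonferroni(1.2e-9, 277)   # ~3.3e-7
#' bonferroni(1.2e-5, 277)   # ~0.003
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(1, p * m)
}

run_contrast <- function(mat, in_cols, out_cols, contrast_label,
                         adjust = TRUE) {
  v <- impute_missing(mat)$values
  m <- nrow(v)
  res <- data.frame(metabolite = rownames(v),
                    contrast = contrast_label,
                    fold_change = NA_real_, t_statistic = NA_real_,
                    df = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    n_in = length(in_cols), n_out = length(out_cols),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- v[i, in_cols]
    b <- v[i, out_cols]
    w <- welch_t(a, b)
    res$fold_change[i] <- mean(a) / mean(b)
    res$t_statistic[i] <- w$t
    res$df[i] <- w$df
    res$p_value[i] <- w$p
    res$degenerate[i] <- w$degenerate
  }
  res$q_value <- if (adjust) bonferroni(res$p_value, m) else NA_real_
  if (!is.null(mat$metabolites$super_pathway)) {
    res$super_pathway <-
      mat$metabolites$super_pathway[match(res$metabolite,
                                          mat$metabolites$name)]
  }
  res
}

#' One group versus all other samples
#'
#' For each metabolite: in-group = the named group's replicates, out-group =
#' every remaining sample pooled. Fold change is the in-group mean over the
#' out-group mean of imputed normalized counts; q-values are Bonferroni over
#' the metabolite family (m = number of metabolites).
#'
#' @param mat a [metabolite_matrix()].
#' @param group group label to test.
#' @return a data.frame, one row per metabolite: `metabolite`, `contrast`,
#'   `fold_change`, `t_statistic`, `df`, `p_value`, `q_value`, `n_in`,
#'   `n_out` (+ `super_pathway` when annotated).
#' @export
group_vs_rest <- function(mat, group) {
  g <- mat$samples$group
  if (!group %in% g) stop(sprintf("unknown group '%s'", group))
  in_cols <- which(g == group)
  out_cols <- which(g != group)
  if (length(in_cols) < 2L || length(out_cols) < 2L) {
    stop("each side of the contrast needs >= 2 samples")
  }
  run_contrast(mat, in_cols, out_cols,
               sprintf("%s_vs_rest", group), adjust = TRUE)
}

#' Mutant versus wild-type control
#'
#' Same machinery as [group_vs_rest()] but the out-group is a single named
#' control group, and p-values are reported without multiplicity correction
#' (the volcano view of these pairwise comparisons uses raw p < 0.05).
#'
#' @param mat a [metabolite_matrix()].
#' @param mut_group,wt_group group labels; must be distinct.
#' @return a data.frame as in [group_vs_rest()], `q_value` set `NA`.
#' @export
pairwise_mut_vs_wt <- function(mat, mut_group, wt_group) {
  g <- mat$samples$group
  if (!mut_group %in% g) stop(sprintf("unknown group '%s'", mut_group))
  if (!wt_group %in% g) stop(sprintf("unknown group '%s'", wt_group))
  if (mut_group == wt_group) stop("mutant and wild-type groups overlap")
  run_contrast(mat, which(g == mut_group), which(g == wt_group),
               sprintf("%s_vs_%s", mut_group, wt_group), adjust = FALSE)
}

#' Metabolites significant at a q cutoff
#' @param results a contrast result data.frame.
#' @param q_cutoff strict cutoff, default 0.05 (q < cutoff).
#' @return character vector of metabolite names.
#' @export
significant_set <- function(results, q_cutoff = 0.05) {
  if (nrow(results) == 0L) return(character())
  results$metabolite[!is.na(results$q_value) & results$q_value < q_cutoff]
}

#' Volcano-ready table
#' @param results a contrast result data.frame.
#' @return data.frame with `metabolite`, `log2_fold_change`,
#'   `neg_log10_p`.
#' @export
volcano_table <- function(results) {
  data.frame(metabolite = results$metabolite,
             log2_fold_change = log2(results$fold_change),
             neg_log10_p = -log10(results$p_value),
             stringsAsFactors = FALSE)
}
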