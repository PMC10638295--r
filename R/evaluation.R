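# Gold-standard evaluation: fixed-universe confusion matrix.
#
# The screen's operating point is scored against a curated panel of known
# change-of-metabolic-function mutations inside an a-priori universe of
# enzymes plausibly involved in cancer-related metabolic pathways
# (historically: a 42-entry panel inside a 300-enzyme universe).

#' Evaluation configuration
#'
#' @param gold_standard data.frame with `gene` and optionally
#'   `protein_change` (`NA` for gene-level entries), or a character vector
#'   of keys.
#' @param universe_size size of the conceptual candidate universe; default
#'   300.
#' @return an `evaluation_config` list.
#' @export
evaluation_config <- function(gold_standard, universe_size = 300L) {
  gold <- gold_keys(gold_standard)
  if (length(gold$keys) > universe_size) {
    stop("gold standard larger than the universe")
  }
  structure(list(universe_size = as.integer(universe_size),
                 gold = gold), class = "evaluation_config")
}

# Normalizes gold entries into match keys. Mutation-level entries match at
# (gene, protein_change); gene-level entries (no residue given) match any
# prediction in that gene.
gold_keys <- function(gold_standard) {
  if (is.character(gold_standard)) {
    gold_standard <- data.frame(
      gene = toupper(sub(":.*$", "", gold_standard)),
      protein_change = ifelse(grepl(":", gold_standard),
                              sub("^[^:]*:", "", gold_standard), NA),
      stringsAsFactors = FALSE)
  }
  g <- toupper(gold_standard$gene)
  pc <- if ("protein_change" %in% names(gold_standard)) {
    gold_standard$protein_change
  } else {
    rep(NA_character_, length(g))
  }
  keys <- ifelse(is.na(pc) | !nzchar(pc), g, paste0(g, ":", pc))
  list(keys = unique(keys), gene_level = unique(g[is.na(pc) | !nzchar(pc)]))
}

#' Read a gold-standard panel from TSV
#' @param path two-column TSV (`gene`, `protein_change`; the second may be
#'   empty for gene-level entries).
#' @return data.frame.
#' @export
read_gold_standard <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  stopifnot("gene" %in% names(g))
  g$gene <- toupper(g$gene)
  g
}

predicted_keys <- function(predicted) {
  if (is.character(predicted)) return(unique(predicted))
  pc <- predicted$protein_change
  unique(ifelse(is.na(pc), toupper(predicted$gene),
                paste0(toupper(predicted$gene), ":", pc)))
}

#' Build the fixed-universe confusion matrix
#'
#' A prediction is a true positive when it matches a gold entry — at
#' (gene, protein change) granularity, or at gene level for gold entries
#' that carry no residue. tn = universe - gold - fp.
#'
#' @param predicted predicted candidate set: data.frame with `gene` and
#'   `protein_change`, or a character vector of `GENE:p.X123Y` / `GENE`
#'   keys.
#' @param config an [evaluation_config()].
#' @return a `confusion_matrix` list `(tp, fp, tn, fn, universe_size,
#'   n_gold, n_predicted)`.
#' @export
build_confusion <- function(predicted, config) {
  pk <- predicted_keys(predicted)
  gold <- config$gold
  matched <- pk %in% gold$keys |
    sub(":.*$", "", pk) %in% gold$gene_level
  # a gold entry can only be detected once
  hit_gold <- unique(c(
    pk[pk %in% gold$keys],
    intersect(sub(":.*$", "", pk), gold$gene_level)))
  tp <- length(intersect(hit_gold, gold$keys))
  fp <- sum(!matched)
  fn <- length(gold$keys) - tp
  tn <- config$universe_size - length(gold$keys) - fp
  if (tn < 0) {
    stop("predicted set exceeds the non-gold universe (tn < 0); ",
         "increase universe_size")
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 universe_size = config$universe_size,
                 n_gold = length(gold$keys), n_predicted = length(pk)),
            class = "confusion_matrix")
}

#' Direct confusion matrix from counts
#' @param tp,fp,tn,fn non-negative counts.
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 universe_size = tp + fp + tn + fn,
                 n_gold = tp + fn, n_predicted = tp + fp),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (universe %d): tp=%d fp=%d tn=%d fn=%d\n",
              x$universe_size, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity, specificity, accuracy
#'
#' Reported both as exact fractions and as percentages (nearest integer).
#' A zero denominator yields `NaN` for that metric, flagged in `undefined`,
#' rather than an error.
#'
#' @param cm a confusion matrix ([build_confusion()] or
#'   [confusion_matrix()]).
#' @return list with `sensitivity`, `specificity`, `accuracy` (percent,
#'   full precision), `*_pct` rounded integers, the exact fraction strings,
#'   and `undefined`.
#' @export
metrics <- function(cm) {
  frac <- function(num, den) if (den > 0) 100 * num / den else NaN
  sens <- frac(cm$tp, cm$tp + cm$fn)
  spec <- frac(cm$tn, cm$tn + cm$fp)
  acc <- frac(cm$tp + cm$tn, cm$universe_size)
  list(
    sensitivity = sens, specificity = spec, accuracy = acc,
    sensitivity_pct = round(sens), specificity_pct = round(spec),
    accuracy_pct = round(acc),
    sensitivity_fraction = sprintf("%d/%d", cm$tp, cm$tp + cm$fn),
    specificity_fraction = sprintf("%d/%d", cm$tn, cm$tn + cm$fp),
    accuracy_fraction = sprintf("%d/%d", cm$tp + cm$tn, cm$universe_size),
    undefined = c(sensitivity = is.nan(sens), specificity = is.nan(spec),
                  accuracy = is.nan(acc))
  )
}
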