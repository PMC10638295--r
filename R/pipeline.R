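# End-to-end orchestration of the screen, with a stage-by-stage funnel
# report mirroring the counts annotated on the pipeline schematic. Stage
# order: parse -> dedup -> missense -> recurrence -> germline -> enzyme ->
# known-GOF -> top-per-gene -> length -> conservation -> structure
# proximity. The sequence-level subset filters commute, so order only
# affects which stage a removal is attributed to.

#' Pipeline configuration
#'
#' @param mode `"metis1"` (3+ patients, >5% of all gene mutations) or
#'   `"metis2"` (9+ patients, >25% of recurrent gene mutations, FATHMM
#'   <= -3).
#' @param recurrence optional [recurrence_config()] overriding the mode
#'   default.
#' @param annotations gene annotation table ([read_gene_annotation()]) or
#'   path; `NULL` skips the enzyme/length stages.
#' @param germline germline MAF table or path; `NULL` skips the stage.
#' @param gof_genes character vector of known gain-of-function genes;
#'   `NULL` uses the shipped curated list; `NA` skips the stage.
#' @param conservation conservation table (`gene`, `position`,
#'   `fraction_identical`) or `NULL` to skip.
#' @param min_conservation conservation retention threshold, default 0.9.
#' @param structure_map per-gene structure map (see [classify_proximity()])
#'   or `NULL` to skip the structure stage.
#' @param max_length protein length bound, default 1500.
#' @param maf_cutoff germline MAF cutoff, default 0.01.
#' @param proximity_bins bins that count as structural hits, default
#'   `"hit_le10"` (add `"marginal_10_15"` for the relaxed band).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("metis1", "metis2"), recurrence = NULL,
                            annotations = NULL, germline = NULL,
                            gof_genes = NULL, conservation = NULL,
                            min_conservation = 0.9, structure_map = NULL,
                            max_length = 1500L, maf_cutoff = 0.01,
                            proximity_bins = "hit_le10") {
  mode <- match.arg(mode)
  if (is.null(recurrence)) {
    recurrence <- if (mode == "metis1") metis1_config() else metis2_config()
  }
  if (is.character(annotations)) annotations <- read_gene_annotation(annotations)
  if (is.character(germline) && length(germline) == 1L &&
      file.exists(germline)) {
    germline <- utils::read.delim(germline, stringsAsFactors = FALSE)
  }
  structure(list(mode = mode, recurrence = recurrence,
                 annotations = annotations, germline = germline,
                 gof_genes = gof_genes, conservation = conservation,
                 min_conservation = min_conservation,
                 structure_map = structure_map, max_length = max_length,
                 maf_cutoff = maf_cutoff, proximity_bins = proximity_bins),
            class = "pipeline_config")
}

#' Run the candidate screen end to end
#'
#' @param catalog mutation records ([parse_catalog()] output) or a path to
#'   a canonical catalog TSV.
#' @param config a [pipeline_config()].
#' @param dialect dialect for reading `catalog` when it is a path.
#' @return list with `candidates` (final variant table with proximity
#'   columns when a structure map is configured) and `funnel` (data.frame:
#'   `stage`, `n_in`, `n_out`, `n_removed`).
#' @export
run_comf_screen <- function(catalog, config = pipeline_config(),
                            dialect = canonical_dialect()) {
  if (is.character(catalog)) catalog <- parse_catalog(catalog, dialect)

  funnel <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer(), n_removed = integer(),
                       stringsAsFactors = FALSE)
  log_stage <- function(stage, n_in, n_out) {
    funnel <<- rbind(funnel, data.frame(
      stage = stage, n_in = n_in, n_out = n_out, n_removed = n_in - n_out,
      stringsAsFactors = FALSE))
  }

  dd <- deduplicate(catalog)
  log_stage("deduplicate", nrow(catalog), nrow(dd))

  mis <- filter_missense(dd)
  log_stage("missense", nrow(dd), nrow(mis))

  # unit conversion: missense records collapse into protein-level variants
  # (gene denominators still see the full deduplicated catalog)
  summaries <- summarize_variants(dd, config$recurrence)
  log_stage("summarize_variants", nrow(mis), nrow(summaries))

  filtered <- apply_recurrence_filter(summaries, config$recurrence)
  v <- filtered[filtered$pass, , drop = FALSE]
  log_stage("recurrence", nrow(summaries), nrow(v))

  if (!is.null(config$germline)) {
    v2 <- filter_germline(v, config$germline, config$maf_cutoff)
    log_stage("germline", nrow(v), nrow(v2)); v <- v2
  }
  if (!is.null(config$annotations)) {
    v2 <- filter_enzyme(v, config$annotations)
    log_stage("enzyme", nrow(v), nrow(v2)); v <- v2
  }
  gof <- config$gof_genes
  if (is.null(gof)) gof <- tryCatch(known_gof_genes(), error = function(e) NA)
  if (!identical(gof, NA) && !all(is.na(gof))) {
    v2 <- filter_known_gof(v, gof)
    log_stage("known_gof", nrow(v), nrow(v2)); v <- v2
  }

  v2 <- top_variant_per_gene(v)
  log_stage("top_per_gene", nrow(v), nrow(v2)); v <- v2

  if (!is.null(config$annotations)) {
    v2 <- filter_length(v, config$annotations, config$max_length)
    log_stage("length", nrow(v), nrow(v2)); v <- v2
  }
  if (!is.null(config$conservation)) {
    v2 <- filter_conserved(v, config$conservation, config$min_conservation)
    log_stage("conservation", nrow(v), nrow(v2)); v <- v2
  }
  if (!is.null(config$structure_map)) {
    v <- classify_proximity(v, config$structure_map)
    keep <- !is.na(v$bin) & v$bin %in% config$proximity_bins
    v2 <- v[keep, , drop = FALSE]
    log_stage("structure_proximity", nrow(v), nrow(v2)); v <- v2
  }
  rownames(v) <- NULL
  list(candidates = v, funnel = funnel)
}

#' Write the funnel report as JSON
#' @param result a [run_comf_screen()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_funnel <- function(result, path) {
  jsonlite::write_json(list(funnel = result$funnel,
                            n_candidates = nrow(result$candidates)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the metabolomic validation screen
#'
#' Executes the group-vs-rest contrast for every group and the pairwise
#' mutant-vs-wild-type contrast for each configured pair, returning one
#' combined results table.
#'
#' @param mat a [metabolite_matrix()] or a path readable by
#'   [read_metabolite_matrix()].
#' @param pairs optional data.frame with `mut` and `wt` group columns.
#' @param group_map passed to [read_metabolite_matrix()] when `mat` is a
#'   path.
#' @return data.frame of stacked [group_vs_rest()] and
#'   [pairwise_mut_vs_wt()] results.
#' @export
run_metabolomics <- function(mat, pairs = NULL, group_map = NULL) {
  if (is.character(mat)) mat <- read_metabolite_matrix(mat, group_map)
  res <- lapply(unique(mat$samples$group),
                function(g) group_vs_rest(mat, g))
  if (!is.null(pairs)) {
    if (!all(c("mut", "wt") %in% names(pairs))) {
      stop("pairs must have 'mut' and 'wt' columns")
    }
    res <- c(res, lapply(seq_len(nrow(pairs)), function(i) {
      pairwise_mut_vs_wt(mat, pairs$mut[i], pairs$wt[i])
    }))
  }
  do.call(rbind, res)
}
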