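# Post-recurrence candidate triage: mutation class, germline exclusion,
# enzyme (EC) status, known gain-of-function exclusion, protein length, and
# alignment-column conservation at the mutated residue.
#
# Every filter here is a subset operation; removed rows are tallied by a
# machine-readable reason code so the pipeline funnel reconstructs the input
# exactly.

subset_with_reason <- function(x, keep, reason) {
  out <- x[keep, , drop = FALSE]
  removed <- x[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason
  attr(out, "removed") <- removed
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep only missense records
#' @param records mutation records ([parse_catalog()]).
#' @return the missense subset; attribute `n_removed` counts drops.
#' @export
filter_missense <- function(records) {
  subset_with_reason(records, records$mutation_class == "missense",
                     "not_missense")
}

#' Remove likely germline polymorphisms
#'
#' Variants matching a germline record with minor allele frequency strictly
#' above `maf_cutoff` are removed; a variant absent from the table, or at
#' exactly the cutoff, is retained. Matching is by (gene, protein change).
#'
#' @param variants a data.frame with `gene` and `protein_change` columns
#'   (records or variant summaries).
#' @param germline_table data.frame with columns `gene`, `protein_change`,
#'   `maf` (in \[0, 0.5\]).
#' @param maf_cutoff remove when maf > cutoff (strict); default 0.01.
#' @return the retained subset.
#' @export
filter_germline <- function(variants, germline_table, maf_cutoff = 0.01) {
  stopifnot(all(c("gene", "protein_change", "maf") %in% names(germline_table)))
  if (any(germline_table$maf < 0 | germline_table$maf > 0.5)) {
    stop("germline MAF values must lie in [0, 0.5]")
  }
  gkey <- paste(toupper(germline_table$gene), germline_table$protein_change)
  vkey <- paste(variants$gene, variants$protein_change)
  maf <- germline_table$maf[match(vkey, gkey)]
  drop <- !is.na(maf) & maf > maf_cutoff
  subset_with_reason(variants, !drop, "germline")
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene`, `ec_number` (empty when the product
#'   is not an enzyme), `protein_length`, and optional `known_gof`
#'   (TRUE/FALSE).
#' @return data.frame with upper-cased gene symbols.
#' @export
read_gene_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  stopifnot(all(c("gene", "ec_number", "protein_length") %in% names(a)))
  a$gene <- toupper(a$gene)
  if (is.null(a$known_gof)) a$known_gof <- FALSE
  a$known_gof[is.na(a$known_gof)] <- FALSE
  bad <- !is.na(a$ec_number) &
    !grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9n]+|-)$", a$ec_number)
  if (any(bad)) {
    stop(sprintf("malformed EC numbers: %s",
                 paste(unique(a$ec_number[bad]), collapse = ", ")))
  }
  a
}

annotation_lookup <- function(variants, annotations, field) {
  annotations[[field]][match(variants$gene, annotations$gene)]
}

#' Keep only genes whose product has an EC number
#'
#' Enzyme status is taken from the annotation table's `ec_number` column
#' (wildcard classes such as "1.1.-.-" count). Genes absent from the table
#' are removed with reason `no_annotation`.
#'
#' @param variants data.frame with a `gene` column.
#' @param annotations [read_gene_annotation()] table.
#' @return the enzyme-gene subset.
#' @export
filter_enzyme <- function(variants, annotations) {
  known <- variants$gene %in% annotations$gene
  ec <- annotation_lookup(variants, annotations, "ec_number")
  out <- subset_with_reason(variants, known & !is.na(ec), "no_ec")
  rm <- attr(out, "removed")
  if (!is.null(rm) && nrow(rm)) {
    rm$reason[!rm$gene %in% annotations$gene] <- "no_annotation"
    attr(out, "removed") <- rm
  }
  out
}

#' Exclude genes on the curated known gain-of-function list
#'
#' The screen looks for novel change-of-function candidates, so genes whose
#' recurrent mutations are already established gain-of-function drivers
#' (IDH1, IDH2, EZH2, PIK3CA, BRAF, ...) are set aside. The curated list
#' ships as a plain-text data file and is user-editable.
#'
#' @param variants data.frame with a `gene` column.
#' @param annotations annotation table with a logical `known_gof` column, or
#'   a character vector of gene symbols.
#' @return the subset excluding known gain-of-function genes.
#' @export
filter_known_gof <- function(variants, annotations) {
  gof_genes <- if (is.character(annotations)) {
    toupper(annotations)
  } else {
    annotations$gene[isTRUE_vec(annotations$known_gof)]
  }
  subset_with_reason(variants, !variants$gene %in% gof_genes, "known_gof")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read the shipped curated gain-of-function gene list
#' @return character vector of gene symbols.
#' @export
known_gof_genes <- function() {
  path <- system.file("extdata", "known_gof_genes.txt", package = "comfscreen")
  x <- readLines(path)
  toupper(trimws(x[!grepl("^#", x) & nzchar(trimws(x))]))
}

#' Keep proteins short enough for downstream biochemistry
#'
#' Candidates must be feasible to manipulate experimentally, which the
#' screen operationalizes as a protein length strictly below `max_length`
#' residues. Genes with no recorded length are retained with flag
#' `length_missing`.
#'
#' @param variants data.frame with a `gene` column.
#' @param annotations annotation table with `protein_length`.
#' @param max_length strict upper bound, default 1500.
#' @return the subset.
#' @export
filter_length <- function(variants, annotations, max_length = 1500L) {
  len <- annotation_lookup(variants, annotations, "protein_length")
  keep <- is.na(len) | len < max_length
  out <- subset_with_reason(variants, keep, "too_long")
  out$flag_length_missing <- is.na(len[keep])
  out
}

#' Read an aligned-FASTA multiple sequence alignment
#' @param path aligned FASTA (all sequences the same length; `-` or `.` gaps).
#' @return a named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  x <- as.character(aln)
  names(x) <- sub("\\s.*$", "", names(aln))
  if (length(unique(nchar(x))) != 1L) {
    stop("sequences are not aligned (unequal lengths)")
  }
  x
}

#' Conservation of a reference residue across a homolog alignment
#'
#' Maps a 1-based ungapped residue index on the reference sequence to its
#' alignment column, then computes the fraction of sequences carrying the
#' reference residue there. Gap characters are excluded from both numerator
#' and denominator, so the fraction is over sequences that actually have a
#' residue at that column.
#'
#' @param alignment named character vector from [read_alignment()], or a
#'   path to an aligned FASTA.
#' @param reference_id name of the reference sequence in the alignment.
#' @param position 1-based residue index on the ungapped reference.
#' @return list with `gene` (the reference id), `position`, `column`,
#'   `reference_residue`, `n_homologs` (non-gap sequences at the column) and
#'   `fraction_identical`.
#' @export
conservation_at <- function(alignment, reference_id, position) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- read_alignment(alignment)
  }
  if (!reference_id %in% names(alignment)) {
    stop(sprintf("reference sequence '%s' not in alignment", reference_id))
  }
  ref <- strsplit(alignment[[reference_id]], "")[[1]]
  is_res <- !ref %in% c("-", ".")
  ungapped_len <- sum(is_res)
  if (position < 1L || position > ungapped_len) {
    stop(sprintf("position %d outside ungapped reference length %d",
                 position, ungapped_len))
  }
  column <- which(cumsum(is_res) == position & is_res)[1]
  col_res <- toupper(vapply(alignment, function(s) substr(s, column, column),
                            character(1)))
  non_gap <- !col_res %in% c("-", ".")
  ref_res <- toupper(ref[column])
  list(gene = reference_id, position = as.integer(position),
       column = as.integer(column), reference_residue = ref_res,
       n_homologs = sum(non_gap),
       fraction_identical = sum(col_res[non_gap] == ref_res) / sum(non_gap))
}

#' Keep variants at conserved residues
#'
#' "Highly conserved" is quantified as a fraction of identical residues at
#' the alignment column of at least `min_fraction` (non-strict); the
#' threshold is a tunable with default 0.9.
#'
#' @param variants data.frame with `gene` and `position` columns.
#' @param conservation a data.frame with `gene`, `position`,
#'   `fraction_identical` (e.g. rows built from [conservation_at()]).
#' @param min_fraction retention threshold, default 0.9.
#' @param missing what to do when no conservation value is available:
#'   `"keep"` (default, flagged) or `"drop"`.
#' @return the conserved subset.
#' @export
filter_conserved <- function(variants, conservation, min_fraction = 0.9,
                             missing = c("keep", "drop")) {
  missing <- match.arg(missing)
  ckey <- paste(conservation$gene, conservation$position)
  vkey <- paste(variants$gene, variants$position)
  frac <- conservation$fraction_identical[match(vkey, ckey)]
  keep <- ifelse(is.na(frac), missing == "keep", frac >= min_fraction)
  out <- subset_with_reason(variants, keep, "not_conserved")
  out$flag_conservation_missing <- is.na(frac[keep])
  out
}
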