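# Reading and normalizing COSMIC-export-style somatic mutation catalogs.
#
# The unit record throughout the screen is one somatic mutation observation:
# gene symbol, sample and patient identifiers, mutation class, and (for
# substitutions) the protein-level change. Catalogs arrive as tab-separated
# exports whose header names vary between database versions, so every column
# is resolved through an explicit dialect (column-mapping) object.

AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*", Sec = "U"
)

AA_ALPHABET <- c(unname(AA3TO1), "*")

#' Define a catalog column mapping (dialect)
#'
#' Maps the canonical fields the screen needs onto the header names of a
#' particular catalog export. Nothing is hard-coded: a COSMIC v59-like and a
#' v96-like export differ in header names but both can be described here.
#'
#' @param gene header name of the gene-symbol column.
#' @param sample_id header name of the sample identifier column.
#' @param patient_id header name of the tumour/patient-level identifier used
#'   for unique-patient counting; if `NULL`, `sample_id` stands in for it and
#'   a warning is emitted once per file (samples are then assumed to be one
#'   per patient).
#' @param protein_change header name of the HGVS-p-like protein change column.
#' @param mutation_class header name of a mutation description column (e.g.
#'   "Substitution - Missense"); if `NULL` the class is inferred from the
#'   protein change string.
#' @param transcript,fathmm_score optional header names.
#' @return a `catalog_dialect` list used by [parse_catalog()].
#' @export
catalog_dialect <- function(gene = "Gene name",
                            sample_id = "Sample name",
                            patient_id = "ID_tumour",
                            protein_change = "Mutation AA",
                            mutation_class = "Mutation Description",
                            transcript = NULL,
                            fathmm_score = NULL) {
  structure(list(gene = gene, sample_id = sample_id, patient_id = patient_id,
                 protein_change = protein_change,
                 mutation_class = mutation_class,
                 transcript = transcript, fathmm_score = fathmm_score),
            class = "catalog_dialect")
}

#' Canonical dialect for catalogs written by this package
#' @return a `catalog_dialect` for the canonical TSV emitted by
#'   [write_catalog()] and the synthetic generator.
#' @export
canonical_dialect <- function() {
  catalog_dialect(gene = "gene", sample_id = "sample_id",
                  patient_id = "patient_id", protein_change = "protein_change",
                  mutation_class = "mutation_class",
                  transcript = "transcript", fathmm_score = "fathmm_score")
}

classify_description <- function(x) {
  x <- tolower(x)
  cls <- rep("other", length(x))
  cls[grepl("missense", x)] <- "missense"
  cls[grepl("nonsense", x)] <- "nonsense"
  cls[grepl("silent|synonymous|coding silent", x)] <- "synonymous"
  cls[grepl("frameshift", x)] <- "frameshift"
  cls[grepl("inframe|in frame|in-frame", x)] <- "inframe_indel"
  cls
}

MUTATION_CLASSES <- c("missense", "nonsense", "synonymous", "frameshift",
                      "inframe_indel", "other")

#' Parse one HGVS-p-like protein change
#'
#' Accepts `"p.R132H"` and `"R132H"` forms as well as three-letter codes
#' (`"p.Arg132His"`), normalized to one-letter. Deletion/insertion/frameshift
#' strings are classified as non-substitutions, not parse failures.
#'
#' @param text a single protein change string.
#' @return a list with class `protein_change`: `ref_aa`, `position`,
#'   `alt_aa`, or `NULL` for a recognized non-substitution.
#' @examples
#' parse_protein_change("p.A400T")
#' parse_protein_change("p.Arg132His")
#' @export
parse_protein_change <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty protein change string")
  p <- parse_protein_change_vec(text)
  if (p$kind == "non_substitution") return(NULL)
  if (p$kind == "error") {
    stop(sprintf("cannot parse protein change: '%s'", text))
  }
  structure(list(ref_aa = p$ref_aa, position = p$position, alt_aa = p$alt_aa),
            class = "protein_change")
}

#' @export
format.protein_change <- function(x, ...) {
  sprintf("p.%s%d%s", x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.protein_change <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Vectorized worker: returns a data.frame with kind, ref_aa, position, alt_aa.
# kind is one of "substitution", "non_substitution", "error".
parse_protein_change_vec <- function(text) {
  text <- trimws(text)
  core <- sub("^p\\.", "", text)
  n <- length(core)
  out <- data.frame(kind = rep("error", n), ref_aa = NA_character_,
                    position = NA_integer_, alt_aa = NA_character_,
                    stringsAsFactors = FALSE)

  # obvious non-substitutions: del/ins/dup/fs/splice/extension/?
  nonsub <- grepl("(del|ins|dup|fs|ext)", core, ignore.case = TRUE) |
    core %in% c("?", "") | grepl("^\\*", core)
  out$kind[nonsub] <- "non_substitution"

  one <- regmatches(core, regexec("^([A-Z])([0-9]+)([A-Z*])$", core))
  three <- regmatches(core,
    regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|\\*)$", core))

  for (i in seq_len(n)) {
    if (nonsub[i]) next
    m <- one[[i]]
    if (length(m) == 4L && m[2] %in% AA_ALPHABET && m[4] %in% AA_ALPHABET) {
      out$kind[i] <- "substitution"
      out$ref_aa[i] <- m[2]
      out$position[i] <- as.integer(m[3])
      out$alt_aa[i] <- m[4]
      next
    }
    m <- three[[i]]
    if (length(m) == 4L && m[2] %in% names(AA3TO1) &&
        (m[4] %in% names(AA3TO1) || m[4] == "*")) {
      out$kind[i] <- "substitution"
      out$ref_aa[i] <- unname(AA3TO1[m[2]])
      out$position[i] <- as.integer(m[3])
      out$alt_aa[i] <- if (m[4] == "*") "*" else unname(AA3TO1[m[4]])
    }
  }
  # a "substitution" to the same residue is synonymous, still a valid parse
  out
}

#' Read and normalize a mutation catalog
#'
#' Reads a tab-separated catalog export, resolves columns through `dialect`,
#' parses protein changes, assigns mutation classes, and returns one record
#' per data row. Substitution-class rows whose protein change cannot be
#' parsed are retained with class `other` (and counted in the returned
#' attributes); nothing is silently dropped at this stage.
#'
#' @param path path to a tab-separated catalog file with a header row.
#' @param dialect a [catalog_dialect()] describing the file's columns; the
#'   default matches a COSMIC-style export, [canonical_dialect()] reads the
#'   normalized TSV this package writes.
#' @return a data.frame of mutation records with canonical columns `gene`,
#'   `transcript`, `sample_id`, `patient_id`, `mutation_class`,
#'   `protein_change` (canonical `p.X123Y` form or `NA`), `ref_aa`,
#'   `position`, `alt_aa`, `fathmm_score`, `source_row`. Attributes
#'   `n_rows` (data rows read) and `n_unparseable` are attached.
#' @export
parse_catalog <- function(path, dialect = catalog_dialect()) {
  if (!file.exists(path)) stop(sprintf("catalog file not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (nrow(raw) == 0L) stop(sprintf("empty catalog (header only): %s", path))

  need <- c("gene", "sample_id", "protein_change")
  for (f in need) {
    col <- dialect[[f]]
    if (is.null(col) || !col %in% names(raw)) {
      stop(sprintf("catalog is missing mapped column '%s' (field %s)",
                   if (is.null(col)) "<unset>" else col, f))
    }
  }
  opt_col <- function(f) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }

  gene <- toupper(trimws(raw[[dialect$gene]]))
  sample_id <- trimws(raw[[dialect$sample_id]])
  patient <- opt_col("patient_id")
  if (is.null(patient)) {
    warning("no patient/tumour ID column mapped or present; ",
            "using sample_id as patient identity")
    patient <- sample_id
  } else {
    patient <- trimws(patient)
  }
  if (any(!nzchar(patient) | is.na(patient))) {
    stop("empty patient identifiers in catalog")
  }

  pc_raw <- raw[[dialect$protein_change]]
  pc_raw[is.na(pc_raw)] <- ""
  parsed <- parse_protein_change_vec(pc_raw)

  desc <- opt_col("mutation_class")
  if (!is.null(desc)) {
    cls <- classify_description(desc)
    cls[cls %in% MUTATION_CLASSES[1:5] == FALSE] <- "other"
  } else {
    cls <- rep("other", nrow(raw))
    cls[parsed$kind == "substitution" & parsed$alt_aa == "*"] <- "nonsense"
    cls[parsed$kind == "substitution" & parsed$alt_aa != "*" &
          parsed$ref_aa == parsed$alt_aa] <- "synonymous"
    cls[parsed$kind == "substitution" & parsed$alt_aa != "*" &
          parsed$ref_aa != parsed$alt_aa] <- "missense"
    cls[parsed$kind == "non_substitution" & grepl("fs", pc_raw)] <- "frameshift"
  }

  # substitution classes with an unparseable change fall back to "other"
  unparseable <- cls %in% c("missense", "nonsense", "synonymous") &
    parsed$kind != "substitution"
  cls[unparseable] <- "other"

  fathmm <- opt_col("fathmm_score")
  fathmm <- if (is.null(fathmm)) rep(NA_real_, nrow(raw)) else
    suppressWarnings(as.numeric(fathmm))
  if (any(is.infinite(fathmm), na.rm = TRUE)) {
    stop("non-finite FATHMM scores in catalog")
  }

  transcript <- opt_col("transcript")
  if (is.null(transcript)) transcript <- rep(NA_character_, nrow(raw))

  has_pc <- parsed$kind == "substitution" & cls %in%
    c("missense", "nonsense", "synonymous")
  records <- data.frame(
    gene = gene,
    transcript = transcript,
    sample_id = sample_id,
    patient_id = patient,
    mutation_class = cls,
    protein_change = ifelse(has_pc,
      sprintf("p.%s%d%s", parsed$ref_aa, parsed$position, parsed$alt_aa),
      NA_character_),
    ref_aa = ifelse(has_pc, parsed$ref_aa, NA_character_),
    position = ifelse(has_pc, parsed$position, NA_integer_),
    alt_aa = ifelse(has_pc, parsed$alt_aa, NA_character_),
    fathmm_score = fathmm,
    source_row = seq_len(nrow(raw)),
    stringsAsFactors = FALSE
  )
  attr(records, "n_rows") <- nrow(raw)
  attr(records, "n_unparseable") <- sum(unparseable)
  if (any(unparseable)) {
    message(sprintf("%d substitution rows with unparseable protein change %s",
                    sum(unparseable), "retained as class 'other'"))
  }
  records
}

#' Write a catalog in the canonical TSV form
#' @param records a record data.frame as returned by [parse_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(records, path) {
  cols <- c("gene", "transcript", "sample_id", "patient_id", "mutation_class",
            "protein_change", "fathmm_score")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Remove duplicate mutation entries
#'
#' Keeps at most one record per (gene, protein change, patient) triple so
#' that multiple tumour samples from the same patient count once. Records
#' without a protein change are keyed by (gene, class, patient).
#'
#' @param records a record data.frame.
#' @return the deduplicated subset (first occurrence wins); attribute
#'   `n_removed` gives the number of dropped rows.
#' @export
deduplicate <- function(records) {
  change_key <- ifelse(is.na(records$protein_change),
                       paste0("class:", records$mutation_class),
                       records$protein_change)
  key <- paste(records$gene, change_key, records$patient_id, sep = "\r")
  keep <- !duplicated(key)
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
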