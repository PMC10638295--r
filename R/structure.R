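# Active-site proximity classification on protein structures.
#
# Candidates surviving the sequence-level filters are classified by the
# minimum Euclidean distance between any atom of the mutated residue and any
# atom of the enzyme's active/ligand-binding site, on an experimental PDB
# entry or a predicted (e.g. AlphaFold) model exported in PDB format.
# "Within 10 A" is the hit criterion (inclusive); 10-15 A is a marginal
# band; beyond 15 A the mutation is considered distant from the site.

# Hetero residue names that never define a site in ligand-auto mode:
# waters, common ions, and cryo/buffer additives.
DEFAULT_LIGAND_EXCLUSIONS <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG",
                               "CA", "ZN", "SO4", "PO4", "GOL")

#' Parse a PDB-format structure
#'
#' Loads ATOM/HETATM records into a flat atom table. For multi-model files
#' only model 1 is kept; alternate locations are resolved to the highest-
#' occupancy conformer per atom.
#'
#' @param path a PDB-format file (experimental entry or a predicted model's
#'   PDB export).
#' @return a `structure_model`: list with `id` (file stem), `source`
#'   (`"pdb_file"`), and `atoms`, a data.frame with columns `kind`
#'   (`polymer`/`hetero`), `chain`, `resno`, `insert`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @export
parse_structure <- function(path) {
  if (!file.exists(path)) stop(sprintf("structure file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) {
    stop(sprintf("no ATOM/HETATM records in %s", path))
  }
  atoms <- data.frame(
    kind = ifelse(a$type == "ATOM", "polymer", "hetero"),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), " ", a$insert),
    resid = a$resid,
    elety = a$elety,
    alt = ifelse(is.na(a$alt), " ", a$alt),
    occ = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in structure")
  }
  # altloc: keep the highest-occupancy conformer of each atom
  akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
                atoms$elety, sep = "\r")
  if (anyDuplicated(akey)) {
    o <- order(akey, -atoms$occ)
    atoms <- atoms[o, , drop = FALSE]
    atoms <- atoms[!duplicated(akey[o]), , drop = FALSE]
  }
  atoms$alt <- NULL
  atoms$occ <- NULL
  rownames(atoms) <- NULL
  structure(list(id = sub("\\.[^.]*$", "", basename(path)),
                 source = "pdb_file", atoms = atoms),
            class = "structure_model")
}

#' Define the active/ligand-binding site
#'
#' In `ligand_auto` mode the site is every hetero atom except waters, ions
#' and buffer components — appropriate for holo experimental structures. An
#' apo model (e.g. most predicted models) has no ligand, so the site must be
#' given explicitly as a residue list.
#'
#' @param mode `"ligand_auto"` or `"residue_list"`.
#' @param residues for `residue_list` mode: data.frame with `chain` and
#'   `resno` columns naming the catalytic/site residues.
#' @param ligand_exclusions hetero residue names never treated as ligands.
#' @return a `site_definition` list.
#' @export
site_definition <- function(mode = c("ligand_auto", "residue_list"),
                            residues = NULL,
                            ligand_exclusions = DEFAULT_LIGAND_EXCLUSIONS) {
  mode <- match.arg(mode)
  if (mode == "residue_list" &&
      (is.null(residues) || nrow(residues) == 0L)) {
    stop("residue_list mode requires a non-empty residues data.frame")
  }
  structure(list(mode = mode, residues = residues,
                 ligand_exclusions = toupper(ligand_exclusions)),
            class = "site_definition")
}

#' Select the atoms that define the site
#'
#' @param model a [parse_structure()] model.
#' @param site a [site_definition()].
#' @return the subset of `model$atoms` forming the site.
#' @export
select_site_atoms <- function(model, site = site_definition()) {
  a <- model$atoms
  if (site$mode == "ligand_auto") {
    sel <- a$kind == "hetero" &
      !toupper(a$resid) %in% site$ligand_exclusions
  } else {
    rkey <- paste(site$residues$chain, site$residues$resno)
    sel <- a$kind == "polymer" & paste(a$chain, a$resno) %in% rkey
  }
  out <- a[sel, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no site atoms found: the model appears to be apo (no ligand ",
         "hetero groups); supply a residue_list site definition naming the ",
         "active-site residues")
  }
  out
}

bin_distance <- function(d) {
  if (d <= 10) "hit_le10" else if (d <= 15) "marginal_10_15" else "distant_gt15"
}

#' Minimum distance from a residue to the site
#'
#' All atoms of the target residue are used by default (the hit criterion is
#' a residue-level statement and side-chain atoms matter); `calpha_only`
#' restricts to the C-alpha atom. The distance is the minimum over all
#' residue-atom x site-atom pairs; bins: \[0, 10\] A hit, (10, 15\] A
#' marginal, beyond 15 A distant.
#'
#' @param model a [parse_structure()] model.
#' @param site_atoms atom subset from [select_site_atoms()].
#' @param chain chain identifier of the target residue.
#' @param residue_number residue number (structure numbering).
#' @param insert insertion code, default `" "`.
#' @param calpha_only use only the C-alpha atom of the residue.
#' @return list `proximity_result`: `min_distance` (A), `bin`,
#'   `residue_found`, `n_site_atoms`, `n_residue_atoms`. A residue absent
#'   from the model yields `residue_found = FALSE` and `NA` distance/bin,
#'   not an error.
#' @export
min_distance_to_site <- function(model, site_atoms, chain, residue_number,
                                 insert = " ", calpha_only = FALSE) {
  a <- model$atoms
  sel <- a$kind == "polymer" & a$chain == chain &
    a$resno == residue_number & a$insert == insert
  if (calpha_only) sel <- sel & a$elety == "CA"
  res <- a[sel, , drop = FALSE]
  if (nrow(res) == 0L) {
    return(structure(list(min_distance = NA_real_, bin = NA_character_,
                          residue_found = FALSE,
                          n_site_atoms = nrow(site_atoms),
                          n_residue_atoms = 0L),
                     class = "proximity_result"))
  }
  rx <- as.matrix(res[, c("x", "y", "z")])
  sx <- as.matrix(site_atoms[, c("x", "y", "z")])
  # all-pairs squared distances via the cross-term expansion
  d2 <- outer(rowSums(rx^2), rowSums(sx^2), "+") - 2 * rx %*% t(sx)
  d <- sqrt(max(0, min(d2)))
  structure(list(min_distance = d, bin = bin_distance(d),
                 residue_found = TRUE, n_site_atoms = nrow(site_atoms),
                 n_residue_atoms = nrow(res)),
            class = "proximity_result")
}

#' Map protein residue numbering onto structure numbering
#'
#' Structures (crystallized constructs, short transcript variants) often
#' number residues differently from the full-length protein; the
#' reconciliation is a constant per-structure offset supplied in config.
#' For example an offset of -209 maps protein residue 400 onto construct
#' residue 191.
#'
#' @param protein_position 1-based residue index in the protein.
#' @param offset structure numbering minus protein numbering.
#' @return the structure residue number.
#' @export
map_residue_numbering <- function(protein_position, offset = 0L) {
  out <- as.integer(protein_position + offset)
  if (any(out < 1L)) {
    stop("residue mapping yields a non-positive structure residue number")
  }
  out
}

#' Classify candidate variants by site proximity
#'
#' Convenience wrapper running [min_distance_to_site()] for each candidate
#' through a per-gene structure map.
#'
#' @param variants data.frame with `gene` and `position` columns.
#' @param structure_map named list (by gene symbol) of entries
#'   `list(path=, chain=, offset=, site=)`; `site` defaults to ligand-auto.
#' @return `variants` with `structure_id`, `structure_resno`,
#'   `min_distance`, `bin`, `residue_found` columns (NA where the gene has
#'   no mapped structure).
#' @export
classify_proximity <- function(variants, structure_map) {
  n <- nrow(variants)
  variants$structure_id <- NA_character_
  variants$structure_resno <- NA_integer_
  variants$min_distance <- NA_real_
  variants$bin <- NA_character_
  variants$residue_found <- NA
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    g <- variants$gene[i]
    sm <- structure_map[[g]]
    if (is.null(sm)) next
    key <- sm$path
    if (is.null(cache[[key]])) {
      model <- parse_structure(sm$path)
      site <- if (is.null(sm$site)) site_definition() else sm$site
      cache[[key]] <- list(model = model,
                           site_atoms = select_site_atoms(model, site))
    }
    cm <- cache[[key]]
    resno <- map_residue_numbering(variants$position[i],
                                   if (is.null(sm$offset)) 0L else sm$offset)
    chain <- if (is.null(sm$chain)) cm$model$atoms$chain[1] else sm$chain
    pr <- min_distance_to_site(cm$model, cm$site_atoms, chain, resno)
    variants$structure_id[i] <- cm$model$id
    variants$structure_resno[i] <- resno
    variants$min_distance[i] <- pr$min_distance
    variants$bin[i] <- pr$bin
    variants$residue_found[i] <- pr$residue_found
  }
  variants
}
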