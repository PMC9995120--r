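#' Protein structure container
#'
#' A light container for one conformation: an atom table plus an N x 3
#' coordinate matrix in Angstrom. Built by [read_structure()] or directly from
#' components (used heavily by the synthetic generators).
#'
#' @param atoms data.frame with columns `elety` (atom name), `elesy` (element
#'   symbol), `resno` (residue number), `resid` (residue name), `chain`
#'   (chain id). Missing `elesy` entries are inferred from `elety`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `pe_structure`.
#' @export
pe_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(atoms) < 1L) stop("structure must contain at least one atom")
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3L)
    stop("coordinate matrix must be N x 3 with N matching the atom table")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("elety", "resno", "resid")) {
    if (is.null(atoms[[col]])) stop("atom table lacks column ", col)
  }
  atoms$chain <- as.character(atoms$chain %||% rep("A", nrow(atoms)))
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  if (is.null(atoms$elesy) || all(is.na(atoms$elesy) | atoms$elesy == "")) {
    atoms$elesy <- infer_element(atoms$elety)
  } else {
    blank <- is.na(atoms$elesy) | trimws(atoms$elesy) == ""
    atoms$elesy[blank] <- infer_element(atoms$elety[blank])
    atoms$elesy <- toupper(trimws(atoms$elesy))
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "pe_structure")
}

#' @export
print.pe_structure <- function(x, ...) {
  cat(sprintf(
    "<pe_structure> %d atoms, %d residues, chains: %s\n",
    nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
    paste(unique(x$atoms$chain), collapse = ",")
  ))
  invisible(x)
}

n_atoms <- function(x) nrow(x$atoms)

#' Read a structure from a PDB file
#'
#' Wraps [bio3d::read.pdb()]. For multi-model files the requested model
#' (0-based) is returned. When an atom carries alternate locations, the
#' highest-occupancy altloc is kept (ties broken by altloc letter).
#' Hydrogens are retained if present.
#'
#' @param path Path to a PDB file.
#' @param model 0-based model index (default 0, the first model).
#' @return A [pe_structure()].
#' @export
read_structure <- function(path, model = 0L) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  n_models <- max(1L, nrow(pdb$xyz))
  if (model < 0L || model >= n_models)
    stop("model index ", model, " out of range (file has ", n_models,
         " model(s))")
  at <- pdb$atom
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  xyz <- matrix(pdb$xyz[model + 1L, ], ncol = 3L, byrow = TRUE)[keep, ,
                                                                drop = FALSE]
  pe_structure(
    atoms = data.frame(
      elety = at$elety, elesy = at$elesy, resno = at$resno,
      resid = at$resid, chain = at$chain, stringsAsFactors = FALSE
    ),
    xyz = xyz
  )
}

## Keep, per (chain, resno, insert, atom name) group, the altloc row with the
## highest occupancy; blank altloc rows are untouched.
resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert %||% "", at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  dup_keys <- unique(key[alt != ""])
  for (k in dup_keys) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      ord <- order(-occ[idx], alt[idx])
      keep[idx[-ord[1L]]] <- FALSE
    }
  }
  keep
}

#' Write a structure to a PDB file
#'
#' @param structure A [pe_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(structure$xyz)),
    resno = at$resno, resid = at$resid, chain = at$chain,
    elety = at$elety, elesy = at$elesy
  )
  invisible(path)
}

#' Select atoms by simple criteria
#'
#' Returns a strictly increasing 0-based atom index vector. Criteria combine
#' with AND; `NULL` criteria are ignored.
#'
#' @param structure A [pe_structure()].
#' @param chain Chain id(s).
#' @param resno Residue numbers.
#' @param resid Residue names.
#' @param elety Atom names.
#' @param protein_only Drop waters/ions and any residue named in `blacklist`.
#' @param heavy_only Drop hydrogens.
#' @param blacklist Residue names treated as non-protein solvent/ions.
#' @return Integer vector of 0-based atom indices (class `pe_selection`).
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL, resid = NULL,
                         elety = NULL, protein_only = FALSE,
                         heavy_only = FALSE, blacklist = SOLVENT_RESNAMES) {
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(elety)) keep <- keep & trimws(at$elety) %in% trimws(elety)
  if (protein_only) keep <- keep & !(at$resid %in% blacklist)
  if (heavy_only) keep <- keep & at$elesy != "H"
  sel <- which(keep) - 1L
  class(sel) <- "pe_selection"
  sel
}

sel_idx <- function(selection, n) {
  idx <- as.integer(unclass(selection)) + 1L
  if (anyDuplicated(idx) || any(idx < 1L) || any(idx > n))
    stop("invalid atom selection: indices must be unique and within bounds")
  idx
}

#' Ligand coordinates container
#'
#' @param xyz M x 3 coordinate matrix (Angstrom).
#' @param elements Element symbols, length M.
#' @return An object of class `pe_ligand`.
#' @export
pe_ligand <- function(xyz, elements = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 1L || ncol(xyz) != 3L) stop("ligand must be M x 3, M >= 1")
  if (!all(is.finite(xyz))) stop("non-finite ligand coordinates")
  elements <- elements %||% rep("C", nrow(xyz))
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, elements = toupper(elements)),
            class = "pe_ligand")
}

#' Extract a ligand from a structure by residue name
#'
#' @param structure A [pe_structure()] (typically a holo complex).
#' @param resname Ligand residue name, e.g. `"BIT"` for blebbistatin.
#' @param heavy_only Keep heavy atoms only (default TRUE).
#' @return A [pe_ligand()].
#' @export
extract_ligand <- function(structure, resname, heavy_only = TRUE) {
  sel <- select_atoms(structure, resid = resname, heavy_only = heavy_only)
  idx <- sel_idx(sel, n_atoms(structure))
  if (length(idx) == 0L) stop("no atoms with residue name ", resname)
  pe_ligand(structure$xyz[idx, , drop = FALSE],
            structure$atoms$elesy[idx])
}

#' Residues in contact with a ligand
#'
#' Identifies binding-site residues: those with at least one heavy atom whose
#' minimum distance to any ligand heavy atom is within `cutoff`. Hydrogens are
#' excluded by default because they are usually absent from crystal
#' structures; set `heavy_only = FALSE` to include them.
#'
#' @param structure A [pe_structure()].
#' @param ligand A [pe_ligand()].
#' @param cutoff Contact distance cutoff in Angstrom (default 5).
#' @param heavy_only Use heavy atoms only (default TRUE).
#' @param protein_only Restrict to non-solvent residues (default TRUE).
#' @return data.frame with columns `chain`, `resno`, `resid`, `min_dist`,
#'   sorted by (chain, resno).
#' @export
select_contact_residues <- function(structure, ligand, cutoff = 5,
                                    heavy_only = TRUE, protein_only = TRUE) {
  stopifnot(cutoff > 0)
  if (n_atoms(structure) == 0L) stop("empty structure")
  sel <- select_atoms(structure, protein_only = protein_only,
                      heavy_only = heavy_only)
  idx <- sel_idx(sel, n_atoms(structure))
  if (length(idx) == 0L) stop("no protein atoms in structure")
  lig_xyz <- ligand$xyz
  if (heavy_only && any(ligand$elements == "H"))
    lig_xyz <- lig_xyz[ligand$elements != "H", , drop = FALSE]
  d <- min_dist_to_set(structure$xyz[idx, , drop = FALSE], lig_xyz)
  at <- structure$atoms[idx, , drop = FALSE]
  key <- paste(at$chain, at$resno, sep = "\r")
  min_by_res <- tapply(d, key, min)
  hit <- names(min_by_res)[min_by_res <= cutoff]
  if (length(hit) == 0L) {
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), min_dist = numeric()))
  }
  first <- match(hit, key)
  out <- data.frame(
    chain = at$chain[first], resno = at$resno[first], resid = at$resid[first],
    min_dist = as.numeric(min_by_res[hit]), stringsAsFactors = FALSE
  )
  out[order(out$chain, out$resno), , drop = FALSE]
}

## Minimum Euclidean distance from each row of `points` to the set `ref`.
min_dist_to_set <- function(points, ref) {
  pp <- rowSums(points^2)
  rr <- rowSums(ref^2)
  d2 <- outer(pp, rr, "+") - 2 * points %*% t(ref)
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1L, min))
}
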