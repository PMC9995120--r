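## Side-chain chi-angle atom quadruplets (standard definitions, chi1-chi4).
CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

## Dihedral angles (radians) for one atom quadruplet across all frames.
## frames: F x N x 3. Standard atan2 formulation; vectorised over frames.
frames_dihedral <- function(frames, quad) {
  a <- frames[, quad[1], , drop = TRUE]
  b <- frames[, quad[2], , drop = TRUE]
  c_ <- frames[, quad[3], , drop = TRUE]
  d <- frames[, quad[4], , drop = TRUE]
  if (is.null(dim(a))) {           # single frame
    a <- rbind(a); b <- rbind(b); c_ <- rbind(c_); d <- rbind(d)
  }
  b1 <- b - a; b2 <- c_ - b; b3 <- d - c_
  cross <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  ## IUPAC sign convention (matches the standard torsion routines)
  -atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

## Enumerate resolvable dihedral quadruplets (atom indices) for a set of
## residues. Backbone phi/psi use the chain-adjacent residues; chi angles use
## CHI_ATOMS. Returns a data.frame: label, i1..i4 (1-based atom indices).
enumerate_dihedrals <- function(topology, site) {
  at <- topology$atoms
  at$elety <- trimws(at$elety)
  res_key <- paste(at$chain, at$resno, sep = "\r")
  find_atom <- function(chain, resno, name) {
    hit <- which(at$chain == chain & at$resno == resno & at$elety == name)
    if (length(hit) >= 1L) hit[1L] else NA_integer_
  }
  rows <- list()
  add <- function(label, idx) {
    if (!anyNA(idx)) rows[[length(rows) + 1L]] <<-
        data.frame(label = label, i1 = idx[1], i2 = idx[2], i3 = idx[3],
                   i4 = idx[4], stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(site))) {
    ch <- site$chain[r]; rn <- site$resno[r]
    resname <- at$resid[match(paste(ch, rn, sep = "\r"), res_key)]
    if (is.na(resname)) stop("site residue ", ch, ":", rn,
                             " not found in topology")
    n_i <- find_atom(ch, rn, "N"); ca_i <- find_atom(ch, rn, "CA")
    c_i <- find_atom(ch, rn, "C")
    if (anyNA(c(n_i, ca_i, c_i)))
      stop("unresolvable backbone atoms for residue ", ch, ":", rn)
    cp <- find_atom(ch, rn - 1L, "C")
    nn <- find_atom(ch, rn + 1L, "N")
    add(sprintf("%s:%d:phi", ch, rn), c(cp, n_i, ca_i, c_i))
    add(sprintf("%s:%d:psi", ch, rn), c(n_i, ca_i, c_i, nn))
    chis <- CHI_ATOMS[[resname]]
    if (!is.null(chis)) {
      for (ci in seq_along(chis)) {
        idx <- vapply(chis[[ci]], function(nm) find_atom(ch, rn, nm), 1L)
        add(sprintf("%s:%d:chi%d", ch, rn, ci), idx)
      }
    }
  }
  if (length(rows) == 0L)
    stop("no resolvable dihedrals for the given residues")
  do.call(rbind, rows)
}

#' Dihedral features of binding-site residues
#'
#' For each site residue, emits the backbone phi and psi angles (where the
#' flanking atoms exist) and all defined side-chain chi angles (chi1-chi4),
#' each encoded as a (sin, cos) pair so that angle periodicity introduces no
#' artificial discontinuities.
#'
#' @param traj A [pe_trajectory()].
#' @param site_residues data.frame with columns `chain` and `resno` (as
#'   returned by [select_contact_residues()]), or a numeric vector of residue
#'   numbers (chain "A" assumed).
#' @return F x (2 * n_angles) matrix; columns alternate sin/cos, named
#'   `<chain>:<resno>:<angle>:sin|cos`. Attribute `labels` stores the angle
#'   labels.
#' @export
dihedral_features <- function(traj, site_residues) {
  if (is.numeric(site_residues))
    site_residues <- data.frame(chain = "A", resno = site_residues)
  quads <- enumerate_dihedrals(traj$topology, site_residues)
  f <- n_frames(traj)
  out <- matrix(0, f, 2L * nrow(quads))
  cn <- character(2L * nrow(quads))
  for (q in seq_len(nrow(quads))) {
    ang <- frames_dihedral(traj$frames,
                           c(quads$i1[q], quads$i2[q], quads$i3[q],
                             quads$i4[q]))
    out[, 2L * q - 1L] <- sin(ang)
    out[, 2L * q] <- cos(ang)
    cn[2L * q - 1L] <- paste0(quads$label[q], ":sin")
    cn[2L * q] <- paste0(quads$label[q], ":cos")
  }
  colnames(out) <- cn
  attr(out, "labels") <- quads$label
  out
}
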