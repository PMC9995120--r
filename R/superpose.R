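#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired point sets, via SVD of the cross-covariance with the usual sign
#' correction guaranteeing det(R) = +1.
#'
#' @param mobile n x 3 coordinates to move.
#' @param reference n x 3 target coordinates, paired row-wise with `mobile`.
#' @return List of class `pe_alignment`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom, after transform). The transform maps a
#'   point x to `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be n x 3 with equal n")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2L, cm); b <- sweep(reference, 2L, cr)
  h <- t(a) %*% b
  s <- svd(h)
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2L)
    stop("degenerate point set: points are collinear or coincident")
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - as.vector(cm %*% rot)
  moved <- sweep(mobile %*% rot, 2L, trans, "+")
  structure(
    list(rotation = rot, translation = trans,
         rmsd = sqrt(mean(rowSums((moved - reference)^2))), iterations = 1L),
    class = "pe_alignment"
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 coordinates.
#' @param alignment A `pe_alignment` from [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, alignment) {
  sweep(as.matrix(xyz) %*% alignment$rotation, 2L, alignment$translation, "+")
}

#' RMSD between paired coordinate sets
#' @param a,b n x 3 matrices.
#' @return Root-mean-square deviation in Angstrom.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Iterative alignment of an ensemble to its mean
#'
#' Aligns every frame to the running mean of a selection, recomputes the
#' mean, and repeats until the mean moves less than `tol` (RMSD over the
#' selection) or `max_iter` is reached. This is the standard procedure for
#' defining a common frame over an ensemble, used here to centre the docking
#' box on a binding site.
#'
#' @param traj A [pe_trajectory()].
#' @param selection 0-based atom indices (from [select_atoms()]) used both to
#'   fit the alignment and to measure convergence; the transform is applied
#'   to all atoms.
#' @param tol Convergence tolerance on the mean shift, Angstrom (default
#'   1e-6). `tol = Inf` performs exactly one iteration.
#' @param max_iter Maximum number of iterations (default 100).
#' @return List: `trajectory` (aligned [pe_trajectory()]), `mean` (converged
#'   mean coordinates of the selection, m x 3), `iterations`, `final_shift`,
#'   `converged`.
#' @export
iterative_ensemble_align <- function(traj, selection, tol = 1e-6,
                                     max_iter = 100L) {
  idx <- sel_idx(selection, dim(traj$frames)[2])
  if (length(idx) < 3L) stop("selection must contain at least 3 atoms")
  frames <- traj$frames
  f <- dim(frames)[1]
  if (f == 1L) {
    return(list(trajectory = traj, mean = frames[1L, idx, , drop = TRUE],
                iterations = 0L, final_shift = 0, converged = TRUE))
  }
  ## start from the ensemble mean so a pre-aligned ensemble converges in one
  ## pass; fall back to the first frame if the raw mean is degenerate. The
  ## reference is re-centred at the origin each iteration, so the converged
  ## selection centroid is (0,0,0) in the aligned coordinate system and a
  ## global translation of the input ensemble drops out.
  centre <- function(x) sweep(x, 2L, colMeans(x))
  ref <- centre(apply(frames[, idx, , drop = FALSE], c(2L, 3L), mean))
  if (inherits(try(kabsch_superpose(frames[1L, idx, , drop = TRUE], ref),
                   silent = TRUE), "try-error")) {
    ref <- centre(frames[1L, idx, , drop = TRUE])
  }
  shift <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(f)) {
      al <- kabsch_superpose(frames[i, idx, , drop = TRUE], ref)
      frames[i, , ] <- apply_transform(frames[i, , , drop = TRUE], al)
    }
    new_ref <- centre(apply(frames[, idx, , drop = FALSE], c(2L, 3L), mean))
    shift <- coord_rmsd(new_ref, ref)
    ref <- new_ref
    if (shift < tol) break
  }
  if (shift >= tol && is.finite(tol))
    warning(sprintf(
      "ensemble alignment did not converge in %d iterations (final shift %.3g A)",
      max_iter, shift))
  list(trajectory = pe_trajectory(traj$topology, frames,
                                  traj$frame_interval),
       mean = ref, iterations = it, final_shift = shift,
       converged = shift < tol)
}

#' Read a residue mapping file
#'
#' Two-column CSV `ref_resid,target_resid` pairing residue numbers in the
#' reference (holo) structure with homologous residue numbers in a target.
#'
#' @param path CSV path.
#' @return data.frame with integer columns `ref_resid`, `target_resid`.
#' @export
read_residue_mapping <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ref_resid", "target_resid") %in% names(m)))
    stop("mapping file must have columns ref_resid,target_resid")
  if (anyDuplicated(m$ref_resid) || anyDuplicated(m$target_resid))
    stop("residue mapping must be one-to-one")
  m[c("ref_resid", "target_resid")]
}

#' Transfer a reference ligand into a target structure's frame
#'
#' Superposes the holo structure onto the target using backbone heavy atoms
#' (N, CA, C, O) of mapped binding-site residues — a local alignment of the
#' site, robust to rearrangements elsewhere — then applies that transform to
#' the ligand.
#'
#' @param holo Holo reference [pe_structure()].
#' @param holo_ligand The ligand [pe_ligand()] in the holo frame.
#' @param target Target [pe_structure()].
#' @param mapping data.frame `ref_resid`/`target_resid` (see
#'   [read_residue_mapping()]); site residues are its subset within
#'   `site_cutoff` of the ligand in the holo structure.
#' @param site_cutoff Site definition cutoff, Angstrom (default 5).
#' @param backbone_atoms Atom names used for the fit.
#' @return The ligand as a [pe_ligand()] in the target frame; attributes
#'   `alignment` (the `pe_alignment`) and `n_site_residues`.
#' @export
place_reference_ligand <- function(holo, holo_ligand, target, mapping,
                                   site_cutoff = 5,
                                   backbone_atoms = c("N", "CA", "C", "O")) {
  site <- select_contact_residues(holo, holo_ligand, cutoff = site_cutoff)
  m <- mapping[mapping$ref_resid %in% site$resno, , drop = FALSE]
  if (nrow(m) < 3L)
    stop("fewer than 3 mappable site residues within ", site_cutoff, " A")
  pick <- function(struct, resnos) {
    at <- struct$atoms
    keep <- at$resno %in% resnos & trimws(at$elety) %in% backbone_atoms
    key <- paste(at$resno[keep], trimws(at$elety)[keep])
    list(xyz = struct$xyz[keep, , drop = FALSE],
         key = key, resno = at$resno[keep])
  }
  h <- pick(holo, m$ref_resid)
  t2 <- pick(target, m$target_resid)
  ## pair atoms through the residue mapping + atom name
  hkey <- paste(m$target_resid[match(h$resno, m$ref_resid)],
                sub("^\\S+ ", "", h$key))
  j <- match(hkey, t2$key)
  ok <- !is.na(j)
  if (sum(ok) < 9L) stop("too few matched backbone atoms for site alignment")
  al <- kabsch_superpose(h$xyz[ok, , drop = FALSE],
                         t2$xyz[j[ok], , drop = FALSE])
  out <- pe_ligand(apply_transform(holo_ligand$xyz, al),
                   holo_ligand$elements)
  attr(out, "alignment") <- al
  attr(out, "n_site_residues") <- nrow(m)
  out
}
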