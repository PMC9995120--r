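#' Trajectory container
#'
#' Frames are stored as an F x N x 3 array in Angstrom together with the
#' topology (atom table) and the time between stored frames in picoseconds.
#'
#' @param topology A [pe_structure()] providing the atom table; its own
#'   coordinates are ignored.
#' @param frames F x N x 3 numeric array (Angstrom).
#' @param frame_interval Time between frames, ps (> 0).
#' @return An object of class `pe_trajectory`.
#' @export
pe_trajectory <- function(topology, frames, frame_interval = 20) {
  if (length(dim(frames)) != 3L || dim(frames)[3] != 3L)
    stop("frames must be an F x N x 3 array")
  if (dim(frames)[1] < 1L) stop("trajectory must contain at least one frame")
  if (dim(frames)[2] != n_atoms(topology))
    stop("atom count mismatch: trajectory has ", dim(frames)[2],
         " atoms, topology has ", n_atoms(topology))
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be positive (ps)")
  storage.mode(frames) <- "double"
  structure(list(topology = topology, frames = frames,
                 frame_interval = as.numeric(frame_interval)),
            class = "pe_trajectory")
}

#' @export
print.pe_trajectory <- function(x, ...) {
  cat(sprintf("<pe_trajectory> %d frames x %d atoms, %.3g ps/frame\n",
              n_frames(x), dim(x$frames)[2], x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [pe_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as a structure
#' @param traj A [pe_trajectory()].
#' @param frame 0-based frame index.
#' @return A [pe_structure()].
#' @export
trajectory_frame <- function(traj, frame) {
  if (frame < 0L || frame >= n_frames(traj)) stop("frame index out of range")
  pe_structure(traj$topology$atoms, traj$frames[frame + 1L, , ])
}

#' Read a trajectory file
#'
#' Supports DCD (via [bio3d::read.dcd()]) and multi-model PDB. Coordinates
#' are returned in Angstrom. XTC is not supported; convert to DCD or
#' multi-model PDB upstream.
#'
#' @param path Trajectory file (.dcd, .pdb).
#' @param topology A [pe_structure()] with a matching atom count.
#' @param stride Keep every `stride`-th frame, starting at the first
#'   (default 1). `frame_interval` is scaled by `stride`.
#' @param frame_interval Time between stored frames in the file, ps
#'   (default 20, one frame per 20 ps).
#' @return A [pe_trajectory()].
#' @export
read_trajectory <- function(path, topology, stride = 1L,
                            frame_interval = 20) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  stopifnot(stride >= 1L)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)     # frames x 3N, Angstrom
    frames <- xyz_mat_to_frames(m)
  } else if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                           verbose = FALSE)
    frames <- xyz_mat_to_frames(pdb$xyz)
  } else {
    stop("unsupported trajectory format: .", ext,
         " (supported: dcd, multi-model pdb)")
  }
  if (dim(frames)[2] != n_atoms(topology))
    stop("atom count mismatch: trajectory has ", dim(frames)[2],
         " atoms, topology has ", n_atoms(topology))
  idx <- seq(1L, dim(frames)[1], by = stride)
  pe_trajectory(topology, frames[idx, , , drop = FALSE],
                frame_interval = frame_interval * stride)
}

## (frames x 3N) matrix -> F x N x 3 array
xyz_mat_to_frames <- function(m) {
  m <- rbind(m)
  f <- nrow(m)
  n <- ncol(m) / 3L
  out <- array(0, dim = c(f, n, 3L))
  for (k in 1:3) out[, , k] <- m[, seq(k, ncol(m), by = 3L), drop = FALSE]
  out
}

## F x N x 3 -> (frames x 3N), bio3d xyz ordering
frames_to_xyz_mat <- function(frames) {
  f <- dim(frames)[1]; n <- dim(frames)[2]
  m <- matrix(0, f, 3L * n)
  for (k in 1:3) m[, seq(k, 3L * n, by = 3L)] <- frames[, , k]
  m
}
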