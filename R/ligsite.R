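#' Parameters for grid-based pocket detection
#'
#' Defaults follow the published parameterisation of the pocket detector:
#' minimum rank 6 of 7 scan directions, probe radius 1.4 A (0.14 nm, chosen
#' large so that only ligand-relevant concavities are detected), minimum
#' cluster size 3 grid points, a 2.5 A ligand-proximity filter and a 1.5 A
#' single-linkage cutoff for pocket continuity. Grid spacing defaults to
#' 1.0 A, which keeps 26-neighbourhood adjacency compatible with the 1.5 A
#' linkage cutoff at face/edge neighbours.
#'
#' @param grid_spacing Grid spacing, Angstrom.
#' @param probe_radius Solvent probe radius added to atomic vdW radii,
#'   Angstrom.
#' @param min_rank Minimum number (0-7) of protein-solvent-protein scan
#'   directions for a grid point to count as pocket.
#' @param min_cluster_size Minimum connected-component size (grid points).
#' @param ligand_proximity Keep pocket points within this distance of any
#'   ligand heavy atom, Angstrom.
#' @param linkage_cutoff Single-linkage distance cutoff defining a continuous
#'   pocket, Angstrom.
#' @param padding Padding added around the structure bounding box, Angstrom.
#' @param vdw_table Named vector of van der Waals radii by element.
#' @param vdw_default Radius for elements missing from `vdw_table`.
#' @return List of class `ligsite_params`.
#' @export
ligsite_params <- function(grid_spacing = 1.0, probe_radius = 1.4,
                           min_rank = 6L, min_cluster_size = 3L,
                           ligand_proximity = 2.5, linkage_cutoff = 1.5,
                           padding = 2.0, vdw_table = VDW_RADII,
                           vdw_default = VDW_DEFAULT) {
  stopifnot(grid_spacing > 0, probe_radius >= 0,
            min_rank >= 0L, min_rank <= 7L, min_cluster_size >= 1L,
            ligand_proximity > 0, linkage_cutoff > 0, padding >= 0)
  structure(list(grid_spacing = grid_spacing, probe_radius = probe_radius,
                 min_rank = as.integer(min_rank),
                 min_cluster_size = as.integer(min_cluster_size),
                 ligand_proximity = ligand_proximity,
                 linkage_cutoff = linkage_cutoff, padding = padding,
                 vdw_table = vdw_table, vdw_default = vdw_default),
            class = "ligsite_params")
}

## The 7 scan lines: the 3 grid axes plus the 4 cube diagonals.
SCAN_DIRECTIONS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1)
)

#' Protein-solvent-protein rank grid
#'
#' Classifies every grid point as protein-excluded or solvent and counts, for
#' each solvent point, on how many of 7 scan lines (3 axes + 4 cube
#' diagonals) protein-excluded points occur on both sides — the
#' protein-solvent-protein (PSP) events of the LIGSITE algorithm. A point is
#' protein-excluded iff its distance to some atom is less than that atom's
#' van der Waals radius plus the probe radius. Scan lines clip at the box
#' boundary: a direction with no protein on one side is not a PSP event.
#'
#' @param structure A [pe_structure()].
#' @param params A [ligsite_params()].
#' @param box Optional list with numeric `lower` and `upper` (length-3, A);
#'   default is the structure bounding box plus `params$padding`.
#' @return List of class `pocket_grid`: `origin`, `spacing`, `dims`,
#'   `protein` (logical array), `rank` (integer array, `NA` on protein
#'   points).
#' @export
ligsite_rank_grid <- function(structure, params = ligsite_params(),
                              box = NULL) {
  xyz <- structure$xyz
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(box)) {
    box <- list(lower = apply(xyz, 2L, min) - params$padding,
                upper = apply(xyz, 2L, max) + params$padding)
  }
  if (any(box$upper <= box$lower)) stop("empty grid box")
  h <- params$grid_spacing
  dims <- pmax(1L, as.integer(floor((box$upper - box$lower) / h)) + 1L)
  origin <- box$lower
  protein <- occupancy_grid(xyz, structure$atoms$elesy, origin, h, dims,
                            params)
  rank <- psp_rank(protein)
  rank[protein] <- NA_integer_
  structure(list(origin = origin, spacing = h, dims = dims,
                 protein = protein, rank = rank),
            class = "pocket_grid")
}

## Mark grid points lying within (vdW + probe) of any atom, visiting only the
## local sub-box around each atom.
occupancy_grid <- function(xyz, elements, origin, h, dims, params) {
  occ <- array(FALSE, dim = dims)
  radii <- vdw_radius(elements, params$vdw_table, params$vdw_default) +
    params$probe_radius
  ax <- (xyz[, 1] - origin[1]) / h
  ay <- (xyz[, 2] - origin[2]) / h
  az <- (xyz[, 3] - origin[3]) / h
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a] / h
    i0 <- max(1L, ceiling(ax[a] - r) + 1L); i1 <- min(dims[1], floor(ax[a] + r) + 1L)
    j0 <- max(1L, ceiling(ay[a] - r) + 1L); j1 <- min(dims[2], floor(ay[a] + r) + 1L)
    k0 <- max(1L, ceiling(az[a] - r) + 1L); k1 <- min(dims[3], floor(az[a] + r) + 1L)
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    ii <- i0:i1; jj <- j0:j1; kk <- k0:k1
    dx2 <- (ii - 1 - ax[a])^2
    dy2 <- (jj - 1 - ay[a])^2
    dz2 <- (kk - 1 - az[a])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    occ[ii, jj, kk] <- occ[ii, jj, kk] | (d2 < r * r)
  }
  occ
}

## Shift a logical 3D array by one grid cell along direction d (content moves
## in +d; vacated cells become FALSE).
shift_grid <- function(a, d) {
  dm <- dim(a)
  out <- array(FALSE, dim = dm)
  rng <- function(n, s) {
    if (s == 0L) list(dst = 1:n, src = 1:n)
    else if (s > 0L) list(dst = 2:n, src = 1:(n - 1))
    else list(dst = 1:(n - 1), src = 2:n)
  }
  r1 <- rng(dm[1], d[1]); r2 <- rng(dm[2], d[2]); r3 <- rng(dm[3], d[3])
  if (any(dm[abs(d) > 0] < 2L)) return(out)
  out[r1$dst, r2$dst, r3$dst] <- a[r1$src, r2$src, r3$src]
  out
}

## "Protein somewhere strictly before this point along -d" via iterated
## shifted OR; one pass per direction sign.
reachable_protein <- function(protein, d) {
  b <- array(FALSE, dim = dim(protein))
  steps <- max(dim(protein))
  for (s in seq_len(steps)) {
    nb <- shift_grid(protein | b, d)
    if (identical(nb, b)) break
    b <- nb
  }
  b
}

## Integer PSP rank per grid point (0-7), counting directions with protein on
## both sides.
psp_rank <- function(protein) {
  rank <- array(0L, dim = dim(protein))
  for (r in seq_len(nrow(SCAN_DIRECTIONS))) {
    d <- SCAN_DIRECTIONS[r, ]
    hit <- reachable_protein(protein, d) & reachable_protein(protein, -d)
    rank <- rank + (hit & !protein)
  }
  rank
}

## Cartesian coordinates of grid points given array indices (n x 3, 1-based).
grid_coords <- function(grid, idx) {
  sweep((idx - 1) * grid$spacing, 2L, grid$origin, "+")
}

## Array indices (1-based, n x 3) of grid points satisfying a logical array.
which_grid <- function(mask) {
  which(mask, arr.ind = TRUE, useNames = FALSE)
}

## Connected components of a set of grid points under 26-neighbourhood.
## `idx` is n x 3 integer array indices; returns integer component labels.
grid_components <- function(idx, dims) {
  n <- nrow(idx)
  if (n == 0L) return(integer())
  id <- idx[, 1] + (dims[1] + 2) * (idx[, 2] + (dims[2] + 2) * idx[, 3])
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ## only need half the offsets; each edge found once
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  el <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nid <- id + offs[o, 1] + (dims[1] + 2) * (offs[o, 2] +
                                                (dims[2] + 2) * offs[o, 3])
    j <- match(nid, id)
    ok <- !is.na(j)
    if (any(ok)) el[[o]] <- cbind(which(ok), j[ok])
  }
  edges <- do.call(rbind, el)
  if (is.null(edges) || nrow(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

#' Ligand-site pocket volume of one structure
#'
#' Full site-volume pipeline: (1) pocket points are solvent grid points with
#' PSP rank at least `min_rank`; (2) connected components (26-neighbourhood)
#' smaller than `min_cluster_size` are dropped; (3) surviving points are
#' filtered to those within `ligand_proximity` of any ligand heavy atom;
#' (4) the remainder is single-linkage clustered at `linkage_cutoff` and the
#' largest cluster kept (ties broken by centroid distance to the ligand
#' centroid); (5) volume = point count x spacing^3.
#'
#' @param structure A [pe_structure()].
#' @param ligand A [pe_ligand()] already placed in the structure's frame (see
#'   [place_reference_ligand()]).
#' @param params A [ligsite_params()].
#' @param grid Optionally a precomputed `pocket_grid` for this structure.
#' @return List of class `pocket_result`: `volume` (A^3), `n_grid_points`,
#'   `points` (n x 3 coordinates of the selected cluster).
#' @export
ligand_site_pocket_volume <- function(structure, ligand,
                                      params = ligsite_params(),
                                      grid = NULL) {
  if (is.null(grid)) grid <- ligsite_rank_grid(structure, params)
  empty <- list(volume = 0, n_grid_points = 0L,
                points = matrix(numeric(), 0L, 3L))
  class(empty) <- "pocket_result"
  mask <- !is.na(grid$rank) & grid$rank >= params$min_rank
  if (!any(mask)) return(empty)
  idx <- which_grid(mask)
  ## (2) prune small connected components
  comp <- grid_components(idx, grid$dims)
  sizes <- tabulate(comp)
  idx <- idx[sizes[comp] >= params$min_cluster_size, , drop = FALSE]
  if (nrow(idx) == 0L) return(empty)
  pts <- grid_coords(grid, idx)
  ## (3) ligand proximity filter (heavy atoms)
  lig <- ligand$xyz[ligand$elements != "H", , drop = FALSE]
  if (nrow(lig) == 0L) lig <- ligand$xyz
  near <- min_dist_to_set(pts, lig) <= params$ligand_proximity
  pts <- pts[near, , drop = FALSE]
  if (nrow(pts) == 0L) return(empty)
  ## (4) continuity: single-linkage, keep largest cluster
  if (nrow(pts) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(pts), method = "single")
    cl <- stats::cutree(hc, h = params$linkage_cutoff)
  }
  sizes <- tabulate(cl)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    lig_cen <- colMeans(lig)
    d <- vapply(best, function(b) {
      sqrt(sum((colMeans(pts[cl == b, , drop = FALSE]) - lig_cen)^2))
    }, numeric(1))
    best <- best[which.min(d)]
  }
  keep <- pts[cl == best[1L], , drop = FALSE]
  out <- list(volume = nrow(keep) * grid$spacing^3,
              n_grid_points = nrow(keep), points = keep)
  class(out) <- "pocket_result"
  out
}

#' @export
print.pocket_result <- function(x, ...) {
  cat(sprintf("<pocket_result> volume %.1f A^3 (%d grid points)\n",
              x$volume, x$n_grid_points))
  invisible(x)
}

#' Pocket volumes along a trajectory
#'
#' Computes the ligand-site pocket volume for every frame. The ligand is
#' placed once per frame by local site alignment when `holo`/`mapping` are
#' given, or taken as fixed coordinates when `ligand` is supplied (useful
#' when frames are pre-aligned).
#'
#' @param traj A [pe_trajectory()].
#' @param ligand Fixed [pe_ligand()] in the trajectory frame, or `NULL`.
#' @param holo,holo_ligand,mapping Alternative: holo complex, its ligand and
#'   a residue mapping; the ligand is re-placed per frame via
#'   [place_reference_ligand()].
#' @param params A [ligsite_params()].
#' @param traj_id Identifier recorded in the output.
#' @return data.frame of class `pocket_volume_series`: `traj_id`, `frame`
#'   (0-based), `time_ps`, `volume_A3`, `n_points`.
#' @export
trajectory_pocket_volumes <- function(traj, ligand = NULL, holo = NULL,
                                      holo_ligand = NULL, mapping = NULL,
                                      params = ligsite_params(),
                                      traj_id = "traj") {
  f <- n_frames(traj)
  vol <- numeric(f); npt <- integer(f)
  for (i in seq_len(f)) {
    st <- trajectory_frame(traj, i - 1L)
    lig <- if (!is.null(ligand)) ligand
    else place_reference_ligand(holo, holo_ligand, st, mapping)
    res <- ligand_site_pocket_volume(st, lig, params)
    vol[i] <- res$volume; npt[i] <- res$n_grid_points
  }
  out <- data.frame(
    traj_id = traj_id, frame = seq_len(f) - 1L,
    time_ps = (seq_len(f) - 1L) * traj$frame_interval,
    volume_A3 = vol, n_points = npt, stringsAsFactors = FALSE
  )
  class(out) <- c("pocket_volume_series", "data.frame")
  out
}
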