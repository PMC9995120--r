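## Shared fixtures and independent oracles for the test suite.

## ---- PDB text fixtures -----------------------------------------------------

pdb_atom_line <- function(serial, name, resn, chain, resno, xyz, occ = 1,
                          alt = "", elem = NULL) {
  elem <- elem %||% substr(gsub("[0-9]", "", name), 1, 1)
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, alt, resn, chain, resno, xyz[1], xyz[2], xyz[3],
          occ, 0, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

## A fake folded peptide: per-residue backbone (N, CA, C, O) plus CB for
## non-GLY, with a fixed non-planar local geometry, offset per residue.
make_fake_protein <- function(resnames, chain = "A", offset0 = c(0, 0, 0)) {
  local_geom <- list(
    N = c(0, 0, 0), CA = c(1.458, 0, 0), C = c(2.009, 1.42, 0),
    O = c(1.40, 2.44, 0.25), CB = c(1.99, -0.77, 1.21),
    OG = c(1.52, -2.15, 1.25), CG = c(3.49, -0.90, 1.35),
    CD = c(4.05, -2.31, 1.42)
  )
  side_atoms <- list(GLY = character(), ALA = "CB", SER = c("CB", "OG"),
                     LEU = c("CB", "CG"), LYS = c("CB", "CG", "CD"))
  atoms <- list(); coords <- list()
  for (i in seq_along(resnames)) {
    rn <- resnames[i]
    nm <- c("N", "CA", "C", "O", side_atoms[[rn]] %||% "CB")
    off <- offset0 + c(3.3 * (i - 1), 0.9 * (i %% 2), 0.5 * ((i %% 3) - 1))
    for (a in nm) {
      atoms[[length(atoms) + 1L]] <- data.frame(
        elety = a, elesy = substr(a, 1, 1), resno = i, resid = rn,
        chain = chain, stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- local_geom[[a]] + off
    }
  }
  pe_structure(do.call(rbind, atoms), do.call(rbind, coords))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  rbind(
    c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_)),
    c(2 * (b * c_ + a * d), a^2 - b^2 + c_^2 - d^2, 2 * (c_ * d - a * b)),
    c(2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 - b^2 - c_^2 + d^2)
  )
}

## ---- LIGSITE oracles -------------------------------------------------------

## Exhaustive per-point line-scan PSP rank on an occupancy array: for every
## solvent point march step-by-step along each of the 7 directions in both
## senses and count directions with protein on both sides. Independent of the
## package's shifted-OR implementation.
oracle_psp_rank <- function(protein) {
  dims <- dim(protein)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  hits <- function(p, d) {
    q <- p + d
    while (all(q >= 1) && all(q <= dims)) {
      if (protein[q[1], q[2], q[3]]) return(TRUE)
      q <- q + d
    }
    FALSE
  }
  rank <- array(NA_integer_, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (protein[i, j, k]) next
      p <- c(i, j, k)
      r <- 0L
      for (dd in seq_len(7)) {
        d <- dirs[dd, ]
        if (hits(p, d) && hits(p, -d)) r <- r + 1L
      }
      rank[i, j, k] <- r
    }
  rank
}

## Brute-force interior count for a cavity fixture: direct all-atom distance
## occupancy, oracle rank, minimum rank 6, ligand proximity 2.5 A. No
## component pruning or linkage clustering (the cavity is one component), so
## this is an independent estimate of the same interior.
oracle_cavity_count <- function(structure, ligand, params = ligsite_params()) {
  xyz <- structure$xyz
  lower <- apply(xyz, 2, min) - params$padding
  upper <- apply(xyz, 2, max) + params$padding
  h <- params$grid_spacing
  dims <- pmax(1L, as.integer(floor((upper - lower) / h)) + 1L)
  radius <- vdw_radius(structure$atoms$elesy) + params$probe_radius
  protein <- array(FALSE, dims)
  count <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- lower + (c(i, j, k) - 1) * h
      d <- sqrt(colSums((t(xyz) - p)^2))
      protein[i, j, k] <- any(d < radius)
    }
  rank <- oracle_psp_rank(protein)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      if (protein[i, j, k]) next
      if (rank[i, j, k] < params$min_rank) next
      p <- lower + (c(i, j, k) - 1) * h
      dl <- sqrt(colSums((t(ligand$xyz) - p)^2))
      if (min(dl) <= params$ligand_proximity) count <- count + 1L
    }
  count
}

## ---- shared synthetic reference ensemble -----------------------------------

## One 3-state, 2e5-frame ensemble shared by the heavier tests (memoised).
.fixture_env <- new.env(parent = emptyenv())

reference_spec <- function(seed = 42L) {
  ensemble_spec(
    transition = rbind(c(0.97, 0.02, 0.01),
                       c(0.04, 0.94, 0.02),
                       c(0.02, 0.04, 0.94)),
    dihedral_means = rbind(c(-2.0, 1.0, 0.5),
                           c(0.5, -1.5, 2.5),
                           c(2.5, 0.3, -2.0)),
    dihedral_kappa = 8,
    volume_mean = c(40, 160, 260), volume_sd = c(25, 30, 35),
    score_mean = c(-3, -6.5, -8), score_sd = c(0.3, 0.3, 0.3),
    n_traj = 10L, n_frames = 20000L, seed = seed
  )
}

reference_ensemble <- function() {
  if (is.null(.fixture_env$ens))
    .fixture_env$ens <- simulate_reference_ensemble(reference_spec())
  .fixture_env$ens
}
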