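#' Stationary distribution of a transition matrix
#'
#' Leading left eigenvector of a row-stochastic matrix, normalised to sum
#' to 1.
#'
#' @param transition Row-stochastic matrix.
#' @return Numeric stationary distribution.
#' @export
stationary_distribution <- function(transition) {
  if (any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  e <- eigen(t(transition))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  abs(v) / sum(abs(v))
}

## Sample a Markov chain of length n from a row-stochastic matrix (1-based
## states internally, returned 0-based).
sample_markov_chain <- function(transition, n, init = NULL) {
  k <- nrow(transition)
  p <- stationary_distribution(transition)
  s <- init %||% sample.int(k, 1L, prob = p)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- s
    s <- sample.int(k, 1L, prob = transition[s, ])
  }
  out - 1L
}

## von Mises sampler (Best & Fisher 1979 rejection scheme).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

## Truncated-at-zero normal sampling by inverse CDF (exact).
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

## P(V >= thr) for a normal truncated at zero.
ptrunc0_upper <- function(thr, mean, sd) {
  if (sd == 0) return(as.numeric(max(mean, 0) >= thr))
  thr <- max(thr, 0)
  stats::pnorm(thr, mean, sd, lower.tail = FALSE) /
    stats::pnorm(0, mean, sd, lower.tail = FALSE)
}

#' Specification of a synthetic reference ensemble
#'
#' Defines a hidden metastable Markov chain with state-coupled emissions:
#' dihedral-like periodic features (von Mises angles emitted as sin/cos
#' pairs), ligand-site pocket volumes (normal truncated at zero), and
#' per-structure docking scores (normal). All ground truths are closed-form
#' functions of these parameters.
#'
#' @param transition Row-stochastic hidden-state transition matrix (one step
#'   = one saved frame).
#' @param dihedral_means n_states x n_angles matrix of circular means
#'   (radians).
#' @param dihedral_kappa von Mises concentration (default 8, high enough
#'   that states are geometrically separable).
#' @param volume_mean,volume_sd Per-state pocket-volume emission parameters
#'   (A^3), length n_states.
#' @param score_mean,score_sd Per-state docking-score emission parameters
#'   (kcal/mol), length n_states.
#' @param n_traj Number of trajectories.
#' @param n_frames Frames per trajectory.
#' @param frame_interval Frame interval, ps (default 20).
#' @param seed RNG seed.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(transition, dihedral_means, dihedral_kappa = 8,
                          volume_mean, volume_sd, score_mean, score_sd,
                          n_traj = 4L, n_frames = 5000L,
                          frame_interval = 20, seed = 1L) {
  transition <- as.matrix(transition)
  k <- nrow(transition)
  dihedral_means <- as.matrix(dihedral_means)
  stopifnot(ncol(transition) == k,
            all(abs(rowSums(transition) - 1) < 1e-8),
            nrow(dihedral_means) == k, dihedral_kappa > 0,
            length(volume_mean) == k, length(volume_sd) == k,
            all(volume_sd >= 0), length(score_mean) == k,
            length(score_sd) == k, all(score_sd >= 0),
            n_traj >= 1L, n_frames >= 2L, frame_interval > 0)
  structure(list(transition = transition, n_states = k,
                 dihedral_means = dihedral_means,
                 dihedral_kappa = dihedral_kappa,
                 volume_mean = volume_mean, volume_sd = volume_sd,
                 score_mean = score_mean, score_sd = score_sd,
                 n_traj = as.integer(n_traj),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Closed-form ground truths of an ensemble specification
#'
#' Deterministic functions of the spec (no sampling): the stationary
#' distribution of the hidden chain; the opening probability at a volume
#' threshold, `p_open = sum_s pi_s * P(V >= thr | s)` with the zero
#' truncation of the volume emission accounted for; and the aggregate
#' binding free energy
#' `dG = -RT * log( sum_s pi_s * exp(-mu_s/RT + sigma_s^2/(2 RT^2)) )`
#' implied by the Gaussian score emissions.
#'
#' @param spec An [ensemble_spec()].
#' @param threshold Volume threshold for p_open, A^3.
#' @param temperature Temperature in K (default 310).
#' @return List: `pi_true`, `p_open_true`, `dG_true`.
#' @export
ensemble_ground_truth <- function(spec, threshold, temperature = 310) {
  p <- stationary_distribution(spec$transition)
  popen <- sum(p * vapply(seq_len(spec$n_states), function(s) {
    ptrunc0_upper(threshold, spec$volume_mean[s], spec$volume_sd[s])
  }, numeric(1)))
  rt <- rt_kcal(temperature)
  lk <- -spec$score_mean / rt + spec$score_sd^2 / (2 * rt^2)
  amax <- max(lk)
  dg <- -rt * (amax + log(sum(p * exp(lk - amax))))
  list(pi_true = p, p_open_true = popen, dG_true = dg)
}

#' Simulate a synthetic reference ensemble
#'
#' Samples hidden Markov chains from the spec's transition matrix and emits,
#' per frame, dihedral-like sin/cos features and a pocket volume, both
#' conditioned on the hidden state. Identical seeds give bit-identical
#' output.
#'
#' @param spec An [ensemble_spec()].
#' @return List of class `synthetic_ensemble`: `features` (list of frames x
#'   2*n_angles matrices), `volumes` (`pocket_volume_series` data.frame over
#'   all trajectories), `states` (list of hidden 0-based state sequences),
#'   `spec`.
#' @export
simulate_reference_ensemble <- function(spec) {
  set.seed(spec$seed)
  n_ang <- ncol(spec$dihedral_means)
  features <- vector("list", spec$n_traj)
  states <- vector("list", spec$n_traj)
  vols <- vector("list", spec$n_traj)
  for (tr in seq_len(spec$n_traj)) {
    s <- sample_markov_chain(spec$transition, spec$n_frames)
    states[[tr]] <- s
    x <- matrix(0, spec$n_frames, 2L * n_ang)
    for (st in seq_len(spec$n_states)) {
      idx <- which(s == st - 1L)
      if (length(idx) == 0L) next
      for (a in seq_len(n_ang)) {
        ang <- rvonmises(length(idx), spec$dihedral_means[st, a],
                         spec$dihedral_kappa)
        x[idx, 2L * a - 1L] <- sin(ang)
        x[idx, 2L * a] <- cos(ang)
      }
    }
    features[[tr]] <- x
    v <- numeric(spec$n_frames)
    for (st in seq_len(spec$n_states)) {
      idx <- which(s == st - 1L)
      if (length(idx) > 0L)
        v[idx] <- rtruncnorm0(length(idx), spec$volume_mean[st],
                              spec$volume_sd[st])
    }
    vols[[tr]] <- data.frame(
      traj_id = sprintf("traj%02d", tr), frame = seq_len(spec$n_frames) - 1L,
      time_ps = (seq_len(spec$n_frames) - 1L) * spec$frame_interval,
      volume_A3 = v, n_points = NA_integer_, stringsAsFactors = FALSE
    )
  }
  volumes <- do.call(rbind, vols)
  class(volumes) <- c("pocket_volume_series", "data.frame")
  structure(list(features = features, volumes = volumes, states = states,
                 spec = spec),
            class = "synthetic_ensemble")
}

#' Synthetic docking-score table for a sampled structure plan
#'
#' Draws one docking score per sampled frame from its hidden state's score
#' emission (ground truth states, not re-estimated ones) and returns a table
#' in the layout consumed by [ingest_docking_scores()].
#'
#' @param spec An [ensemble_spec()].
#' @param states List of hidden 0-based state sequences (from
#'   [simulate_reference_ensemble()]).
#' @param samples A `state_sample` data.frame (from
#'   [sample_docking_structures()]) with `traj` and `frame` columns.
#' @param seed RNG seed (default `spec$seed + 1`).
#' @param path Optional CSV output path.
#' @return data.frame `traj_id,frame,score_kcal_mol`; attribute `dG_true`
#'   carries the closed-form aggregate free energy at 310 K.
#' @export
make_docking_table <- function(spec, states, samples, seed = NULL,
                               path = NULL) {
  set.seed(seed %||% derive_seed(spec$seed, 17L))
  hidden <- vapply(seq_len(nrow(samples)), function(i) {
    states[[samples$traj[i]]][samples$frame[i] + 1L]
  }, numeric(1))
  score <- stats::rnorm(nrow(samples),
                        spec$score_mean[hidden + 1L],
                        spec$score_sd[hidden + 1L])
  out <- data.frame(traj_id = samples$traj, frame = samples$frame,
                    score_kcal_mol = score)
  attr(out, "dG_true") <- ensemble_ground_truth(spec, threshold = 0)$dG_true
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Synthetic hollow-cage structure with a known cavity
#'
#' Tiles pseudo-atoms on a spherical shell (Fibonacci lattice at roughly
#' `atom_spacing` separation) around an empty interior cavity, mimicking a
#' buried pocket. `lid_fraction` opens an aperture (1 removes the upper
#' hemisphere, emulating a fully solvent-exposed site); `blocker` adds an
#' interior atom cluster emulating a gating side chain that partially fills
#' the cavity. A pseudo-ligand (carbon grid, 2.5 A pitch, covering the
#' cavity) is placed at the centre so the ligand-proximity filter retains
#' the interior. The analytic estimate is the sphere volume of radius
#' `shell_radius - (r_vdW(C) + probe)`, ignoring aperture and blocker.
#'
#' @param shell_radius Shell radius, Angstrom (>= 4).
#' @param atom_spacing Target spacing between shell atoms, Angstrom
#'   (default 1).
#' @param lid_fraction Fraction in [0, 1]: 0 = closed shell, 1 = upper
#'   hemisphere removed.
#' @param blocker Add an interior blocking cluster (default FALSE).
#' @param probe_radius Probe radius used for the analytic estimate
#'   (default 1.4).
#' @return List: `structure` ([pe_structure()]), `ligand` ([pe_ligand()]),
#'   `analytic_volume` (A^3).
#' @export
make_cavity_structure <- function(shell_radius, atom_spacing = 1,
                                  lid_fraction = 0, blocker = FALSE,
                                  probe_radius = 1.4) {
  stopifnot(shell_radius >= 4, atom_spacing > 0,
            lid_fraction >= 0, lid_fraction <= 1)
  n_pts <- max(12L, ceiling(4 * pi * shell_radius^2 / atom_spacing^2))
  ## Fibonacci sphere lattice
  i <- seq_len(n_pts) - 0.5
  z <- 1 - 2 * i / n_pts
  phi <- pi * (1 + sqrt(5)) * i
  r_xy <- sqrt(pmax(0, 1 - z^2))
  pts <- shell_radius * cbind(r_xy * cos(phi), r_xy * sin(phi), z)
  ## aperture: remove the polar cap covering lid_fraction of a hemisphere
  keep <- z <= 1 - lid_fraction
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 12L)
    stop("spacing too coarse to close the shell at this radius")
  if (blocker) {
    b0 <- c(0, 0, shell_radius / 2)
    pts <- rbind(pts, sweep(rbind(c(0, 0, 0), c(1.2, 0, 0), c(-1.2, 0, 0),
                                  c(0, 1.2, 0), c(0, -1.2, 0)),
                            2L, b0, "+"))
  }
  n <- nrow(pts)
  atoms <- data.frame(
    elety = "C", elesy = "C", resno = seq_len(n), resid = "CAG",
    chain = "A", stringsAsFactors = FALSE
  )
  st <- pe_structure(atoms, pts)
  ## pseudo-ligand: carbon grid covering the cavity interior
  r_in <- shell_radius - (VDW_RADII[["C"]] + probe_radius)
  g <- seq(-ceiling(r_in), ceiling(r_in), by = 2.5)
  lig_pts <- as.matrix(expand.grid(g, g, g))
  lig_pts <- lig_pts[sqrt(rowSums(lig_pts^2)) <= max(0.1, r_in - 0.5), ,
                     drop = FALSE]
  if (nrow(lig_pts) == 0L) lig_pts <- matrix(0, 1L, 3L)
  list(structure = st, ligand = pe_ligand(lig_pts),
       analytic_volume = 4 / 3 * pi * max(0, r_in)^3)
}
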