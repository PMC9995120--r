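#' Sample structures per MSM state for docking
#'
#' For each active state s the number of structures docked is
#' `N_s = max(base, round(pi_s * scale))`, capped at the number of frames
#' assigned to s (with a warning when capped). Frames are drawn uniformly
#' without replacement.
#'
#' @param msm An `msm` object.
#' @param dtrajs The discrete trajectories the MSM was fitted on.
#' @param base Minimum structures per state (default 3).
#' @param scale Proportionality constant on pi_s (default 2000).
#' @param seed RNG seed.
#' @return data.frame of class `state_sample`: `state` (0-based), `traj`
#'   (1-based trajectory index), `frame` (0-based), `requested`; attribute
#'   `seed`.
#' @export
sample_docking_structures <- function(msm, dtrajs, base = 3L, scale = 2000L,
                                      seed = 1L) {
  stopifnot(base >= 1L)
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  frame_tab <- do.call(rbind, lapply(seq_along(dtrajs), function(i) {
    data.frame(traj = i, frame = seq_along(dtrajs[[i]]) - 1L,
               state = dtrajs[[i]])
  }))
  out <- vector("list", length(msm$active))
  for (si in seq_along(msm$active)) {
    s <- msm$active[si]
    pool <- frame_tab[frame_tab$state == s, , drop = FALSE]
    n_req <- max(base, round(msm$pi[si] * scale))
    n_take <- min(n_req, nrow(pool))
    if (n_take < n_req)
      warning(sprintf(
        "state %d: requested %d structures but only %d frames available",
        s, n_req, nrow(pool)))
    set.seed(derive_seed(seed, s))
    pick <- pool[sample.int(nrow(pool), n_take), , drop = FALSE]
    pick$requested <- n_req
    out[[si]] <- pick
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  class(res) <- c("state_sample", "data.frame")
  res
}

#' Docking box from an aligned ensemble
#'
#' The box centre is the centroid of the site selection in the converged
#' mean structure of an iteratively aligned ensemble — the origin of the
#' aligned coordinate system when the ensemble was aligned on that
#' selection.
#'
#' @param aligned_traj A [pe_trajectory()] already aligned with
#'   [iterative_ensemble_align()] on `site_selection`.
#' @param site_selection 0-based atom indices of the site.
#' @param edge Cubic box edge length, Angstrom (default 20).
#' @return List of class `docking_box`: `center` (length 3, A), `edge`
#'   (length 3, A).
#' @export
define_docking_box <- function(aligned_traj, site_selection, edge = 20) {
  idx <- sel_idx(site_selection, dim(aligned_traj$frames)[2])
  if (length(idx) == 0L) stop("empty site selection")
  stopifnot(all(edge > 0))
  mean_sel <- apply(aligned_traj$frames[, idx, , drop = FALSE], c(2L, 3L),
                    mean)
  if (is.null(dim(mean_sel))) mean_sel <- rbind(mean_sel)
  structure(list(center = colMeans(mean_sel), edge = rep(edge, 3L)[1:3]),
            class = "docking_box")
}

#' Write a docking box to a plain-text config
#'
#' Six floats: center_x/y/z and size_x/y/z in Angstrom.
#' @param box A `docking_box`.
#' @param path Output path.
#' @export
write_docking_box <- function(box, path) {
  keys <- c("center_x", "center_y", "center_z", "size_x", "size_y", "size_z")
  vals <- c(box$center, box$edge)
  writeLines(sprintf("%s = %.17g", keys, vals), path)
  invisible(path)
}

#' Ingest a docking-score table
#'
#' Reads a CSV with columns `traj_id,frame,score_kcal_mol[,pose_rmsd_A]`
#' (a `score` column is accepted as an alias), keys each row to its MSM
#' state via the frame assignment, and collapses multiple poses per frame to
#' the best (lowest) score. Frames assigned to states outside the MSM active
#' set are dropped with a warning.
#'
#' @param path CSV path (or a data.frame already in that layout).
#' @param dtrajs List of 0-based discrete trajectories; `traj_id` values
#'   must be list names or 1-based indices.
#' @param msm Optional `msm`; when given, inactive-state records are
#'   dropped.
#' @return data.frame of class `docking_records`: `traj_id`, `frame`,
#'   `state`, `score` (kcal/mol), `pose_rmsd` (NA when absent).
#' @export
ingest_docking_scores <- function(path, dtrajs, msm = NULL) {
  d <- if (is.data.frame(path)) path
  else utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("no docking records")
  if (!"score_kcal_mol" %in% names(d) && "score" %in% names(d))
    names(d)[names(d) == "score"] <- "score_kcal_mol"
  if (!all(c("traj_id", "frame", "score_kcal_mol") %in% names(d)))
    stop("docking CSV must have columns traj_id,frame,score_kcal_mol")
  if (!is.numeric(d$score_kcal_mol) || anyNA(d$score_kcal_mol))
    stop("non-numeric docking score")
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  tid <- d$traj_id
  ti <- if (!is.null(names(dtrajs)) && !all(tid %in% seq_along(dtrajs)))
    match(as.character(tid), names(dtrajs)) else as.integer(tid)
  if (anyNA(ti)) stop("unknown traj_id in docking table")
  state <- vapply(seq_len(nrow(d)), function(i) {
    dt <- dtrajs[[ti[i]]]
    f <- d$frame[i]
    if (f < 0L || f >= length(dt))
      stop("frame ", f, " not found in trajectory ", tid[i])
    dt[f + 1L]
  }, numeric(1))
  rec <- data.frame(traj_id = tid, frame = d$frame, state = as.integer(state),
                    score = d$score_kcal_mol,
                    pose_rmsd = d$pose_rmsd_A %||% rep(NA_real_, nrow(d)))
  ## best pose per structure
  key <- paste(rec$traj_id, rec$frame, sep = "\r")
  best <- tapply(seq_len(nrow(rec)), key, function(ii) {
    ii[which.min(rec$score[ii])]
  })
  rec <- rec[sort(as.integer(best)), , drop = FALSE]
  if (!is.null(msm)) {
    drop <- !(rec$state %in% msm$active)
    if (any(drop)) {
      warning(sum(drop), " docking record(s) in inactive states dropped")
      rec <- rec[!drop, , drop = FALSE]
    }
  }
  rownames(rec) <- NULL
  class(rec) <- c("docking_records", "data.frame")
  rec
}

#' Aggregate docking scores over an MSM into a binding free energy
#'
#' Converts each structure's best docking score g to a micro equilibrium
#' constant `K = exp(-g / RT)` and Boltzmann-aggregates over the ensemble:
#' `dG_total = -RT * log( sum_f (pi_s(f) / N_s(f)) * K_f )`, where pi_s is
#' the equilibrium probability of the MSM state of structure f and N_s the
#' number of docked structures from that state. With one structure per state
#' this reduces exactly to `-RT * log( sum_s pi_s * K_s )`. Active states
#' with no docked structures contribute zero (reported via a message).
#'
#' @param records `docking_records` (see [ingest_docking_scores()]), or any
#'   data.frame with `state` and `score` columns.
#' @param msm The `msm` supplying pi.
#' @param samples Optional `state_sample`; when given, N_s is the number of
#'   sampled structures per state, otherwise the number of docked records
#'   per state.
#' @param temperature Temperature in K (default 310).
#' @return Object of class `affinity_estimate`: `dG_total` (kcal/mol),
#'   `K_eq`, `K_d` (molar), `temperature`, `sem` (NULL).
#' @export
aggregate_binding_free_energy <- function(records, msm, samples = NULL,
                                          temperature = 310) {
  rt <- rt_kcal(temperature)
  st <- records$state
  si <- match(st, msm$active)
  if (anyNA(si)) stop("docking record in a state outside the MSM active set")
  n_s <- if (!is.null(samples)) {
    tab <- table(samples$state)
    n <- as.numeric(tab[as.character(st)])
    if (anyNA(n)) stop("record state missing from the docking sample plan")
    n
  } else {
    tab <- table(st)
    as.numeric(tab[as.character(st)])
  }
  w <- msm$pi[si] / n_s
  if (sum(w) <= 0) stop("total weight of represented states is zero")
  missing_states <- setdiff(msm$active, st)
  if (length(missing_states) > 0L)
    message(length(missing_states),
            " active state(s) have no docked structures; they contribute 0")
  ## log-sum-exp for numerical stability
  a <- -records$score / rt + log(w)
  amax <- max(a)
  k_eq <- exp(amax) * sum(exp(a - amax))
  dg <- -rt * (amax + log(sum(exp(a - amax))))
  structure(list(dG_total = dg, K_eq = k_eq, K_d = exp(dg / rt),
                 temperature = temperature, R = GAS_CONSTANT_KCAL,
                 n_records = nrow(records), sem = NULL),
            class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf(
    "<affinity_estimate> dG = %.2f kcal/mol (Kd = %.3g M) at %g K%s\n",
    x$dG_total, x$K_d, x$temperature,
    if (!is.null(x$sem)) sprintf(", SEM %.2f kcal/mol", x$sem) else ""))
  invisible(x)
}

#' Convert a binding free energy to a dissociation constant
#'
#' `K_d = exp(dG / RT)` in molar units (1 M standard state); the inverse of
#' [Kd_to_deltaG()].
#'
#' @param dG Binding free energy, kcal/mol.
#' @param temperature Temperature in K (default 310).
#' @return K_d in molar.
#' @export
deltaG_to_Kd <- function(dG, temperature = 310) {
  if (!all(is.finite(dG))) stop("non-finite free energy")
  exp(dG / rt_kcal(temperature))
}

#' @rdname deltaG_to_Kd
#' @param Kd Dissociation constant, molar.
#' @return `Kd_to_deltaG`: free energy in kcal/mol.
#' @export
Kd_to_deltaG <- function(Kd, temperature = 310) {
  if (!all(is.finite(Kd)) || any(Kd <= 0)) stop("Kd must be positive")
  rt_kcal(temperature) * log(Kd)
}
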