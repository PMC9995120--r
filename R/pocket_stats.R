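## Flatten a pocket_volume_series or numeric vector to volumes.
as_volume_vector <- function(volumes) {
  if (is.data.frame(volumes)) {
    if (!"volume_A3" %in% names(volumes))
      stop("volume series must have a volume_A3 column")
    volumes$volume_A3
  } else {
    as.numeric(volumes)
  }
}

## Flatten frame_weights (or numeric vector) to a weight vector.
as_weight_vector <- function(weights) {
  if (inherits(weights, "frame_weights")) unlist(weights$weights)
  else as.numeric(weights)
}

#' MSM-weighted pocket-volume distribution
#'
#' Histogram of pocket volumes with each frame contributing its equilibrium
#' weight (pi_s / N_s). Zero-weight frames (outside the MSM active set) carry
#' no mass. In `mode = "per_state"` the inputs are instead one representative
#' volume per state weighted by pi_s, the procedure used with very large
#' legacy state decompositions.
#'
#' @param volumes A `pocket_volume_series` data.frame or numeric vector of
#'   volumes (A^3).
#' @param weights A `frame_weights` object or numeric weights aligned with
#'   `volumes`.
#' @param bin_width Histogram bin width, A^3 (default 10).
#' @param mode `"per_frame"` (default) or `"per_state"`; the latter only
#'   changes the expected interpretation of the inputs and requires
#'   `weights` to sum to 1 over states.
#' @return List of class `volume_distribution`: `breaks`, `mids`, `prob`
#'   (sums to 1), `bin_width`, `mode`.
#' @export
weighted_volume_distribution <- function(volumes, weights, bin_width = 10,
                                         mode = c("per_frame", "per_state")) {
  mode <- match.arg(mode)
  v <- as_volume_vector(volumes)
  w <- as_weight_vector(weights)
  if (length(v) != length(w))
    stop("volumes and weights cover different frame sets (",
         length(v), " vs ", length(w), ")")
  keep <- w > 0
  v <- v[keep]; w <- w[keep]
  if (length(v) == 0L) stop("no frames with positive weight")
  w <- w / sum(w)
  breaks <- seq(0, max(v) + bin_width, by = bin_width)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE)
  prob <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(w[bin == b]), numeric(1))
  structure(list(breaks = breaks, mids = utils::head(breaks, -1L) +
                   bin_width / 2, prob = prob, bin_width = bin_width,
                 mode = mode),
            class = "volume_distribution")
}

#' Equilibrium probability of pocket opening
#'
#' p_open is the total equilibrium weight of frames whose ligand-site pocket
#' volume reaches or exceeds the holo (ligand-bound) reference volume; the
#' comparison is inclusive.
#'
#' @param volumes A `pocket_volume_series` or numeric vector (A^3).
#' @param weights A `frame_weights` object or numeric weights.
#' @param holo_volume Threshold volume, A^3 (>= 0). Compute it with
#'   [ligand_site_pocket_volume()] on the holo structure with identical
#'   parameters.
#' @param sem Optional standard error to attach (from [bootstrap_sem()]).
#' @return List of class `opening_probability`: `p_open`, `holo_volume`,
#'   `sem`.
#' @export
p_open <- function(volumes, weights, holo_volume, sem = NULL) {
  stopifnot(holo_volume >= 0)
  v <- as_volume_vector(volumes)
  w <- as_weight_vector(weights)
  if (length(v) != length(w))
    stop("volumes and weights cover different frame sets")
  tot <- sum(w)
  if (tot <= 0) stop("no positive frame weights")
  p <- sum(w[v >= holo_volume]) / tot
  structure(list(p_open = p, holo_volume = holo_volume, sem = sem),
            class = "opening_probability")
}

#' @export
print.opening_probability <- function(x, ...) {
  cat(sprintf("p_open = %.4f (holo volume %.1f A^3)%s\n", x$p_open,
              x$holo_volume,
              if (!is.null(x$sem)) sprintf(" +/- %.4f (SEM)", x$sem) else ""))
  invisible(x)
}

#' Centred rolling average of a volume series
#'
#' Centred moving mean over a time window; at the edges the window shrinks
#' to the available frames. For an even window length the extra frame is
#' taken on the trailing side.
#'
#' @param series A `pocket_volume_series` data.frame (single trajectory) or
#'   numeric vector.
#' @param window Window length in ns (when `series` has `time_ps`) or in
#'   frames (numeric vector input).
#' @return The series with a `volume_smooth` column, or a numeric vector.
#' @export
rolling_average <- function(series, window) {
  if (is.data.frame(series)) {
    if (nrow(series) == 0L) stop("empty series")
    dt_ps <- if (nrow(series) > 1L) diff(series$time_ps[1:2]) else 1
    wf <- max(1L, round(window * 1000 / dt_ps))
    series$volume_smooth <- rolling_mean(series$volume_A3, wf)
    series
  } else {
    if (length(series) == 0L) stop("empty series")
    rolling_mean(as.numeric(series), max(1L, round(window)))
  }
}

rolling_mean <- function(x, wf) {
  n <- length(x)
  lo <- floor((wf - 1) / 2)
  hi <- wf - 1L - lo
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - lo):min(n, i + hi)])
  }, numeric(1))
}

#' Trajectory bootstrap of an MSM-derived statistic
#'
#' Draws N trajectories with replacement from the N supplied discrete
#' trajectories, re-fits the transition matrix on the resample (the cluster
#' definition is kept fixed), recomputes the statistic, and repeats for
#' `n_trials` trials (default 250). The reported uncertainty is the standard
#' deviation of the bootstrap distribution, used as an estimate of the
#' standard error of the mean. Trials whose resample gives a disconnected or
#' degenerate model are skipped and counted; more than 50% skipped is an
#' error.
#'
#' @param dtrajs List of 0-based discrete trajectories.
#' @param statistic `function(msm, idx)` where `msm` is the trial's re-fitted
#'   model and `idx` the drawn trajectory indices; must return one number.
#' @param lag MSM lag in frames.
#' @param n_trials Number of bootstrap trials (default 250).
#' @param seed RNG seed.
#' @param estimator MSM estimator tag (see [fit_msm()]).
#' @return List of class `bootstrap_result`: `n_trials`, `values`, `mean`,
#'   `sem`, `n_skipped`, `seed`.
#' @export
bootstrap_sem <- function(dtrajs, statistic, lag, n_trials = 250L,
                          seed = 1L, estimator = "reversible_mle") {
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  n <- length(dtrajs)
  if (n < 2L) stop("need at least 2 trajectories to bootstrap")
  stopifnot(n_trials >= 2L)
  values <- rep(NA_real_, n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(derive_seed(seed, tr))
    idx <- sample.int(n, n, replace = TRUE)
    val <- try({
      m <- fit_msm(dtrajs[idx], lag, estimator = estimator)
      statistic(m, idx)
    }, silent = TRUE)
    if (!inherits(val, "try-error") && is.finite(val)) values[tr] <- val
  }
  skipped <- sum(is.na(values))
  if (skipped > n_trials / 2)
    stop("more than half of bootstrap trials failed (", skipped, "/",
         n_trials, ")")
  ok <- values[!is.na(values)]
  structure(list(n_trials = n_trials, values = values, mean = mean(ok),
                 sem = stats::sd(ok), n_skipped = skipped, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d trials (%d skipped): mean %.4g, SEM %.3g\n",
              x$n_trials, x$n_skipped, x$mean, x$sem))
  invisible(x)
}

#' Read / write a pocket volume series CSV
#'
#' Columns: `traj_id,frame,time_ps,volume_A3,n_points`.
#' @param path CSV path.
#' @return data.frame of class `pocket_volume_series`.
#' @export
read_volume_series <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("traj_id", "frame", "time_ps", "volume_A3")
  if (!all(need %in% names(v)))
    stop("volume series CSV must have columns ", paste(need, collapse = ","))
  class(v) <- c("pocket_volume_series", "data.frame")
  v
}

#' @rdname read_volume_series
#' @param series A `pocket_volume_series`.
#' @export
write_volume_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
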