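#' Cluster conformations in tICA space
#'
#' k-means clustering (10 restarts, best inertia) on the fit subset, followed
#' by assignment of every frame to the nearest centroid by Euclidean
#' distance. Ties in assignment go to the lowest-index centroid.
#'
#' @param tica_coords Projected coordinates: matrix or list of matrices (one
#'   per trajectory).
#' @param k Number of microstates.
#' @param seed RNG seed for the k-means restarts.
#' @param fit_subset Optional: indices of trajectories used to fit the
#'   centroids (default all); held-out trajectories are assigned only.
#' @param nstart k-means restarts (default 10).
#' @return List of class `cluster_model`: `centroids` (k x d), `k`, `seed`,
#'   `dtrajs` (list of 0-based integer state sequences).
#' @export
cluster_assign <- function(tica_coords, k, seed = 1L, fit_subset = NULL,
                           nstart = 10L) {
  coords <- if (is.list(tica_coords)) tica_coords else list(tica_coords)
  coords <- lapply(coords, as.matrix)
  fit_subset <- fit_subset %||% seq_along(coords)
  fit <- do.call(rbind, coords[fit_subset])
  if (k > nrow(fit)) stop("k exceeds the number of fit frames")
  if (k == 1L) {
    centroids <- matrix(colMeans(fit), 1L)
  } else {
    centroids <- NULL
    for (attempt in 1:3) {
      set.seed(derive_seed(seed, attempt - 1L))
      km <- try(stats::kmeans(fit, centers = k, nstart = nstart,
                              iter.max = 200L, algorithm = "MacQueen"),
                silent = TRUE)
      if (!inherits(km, "try-error")) { centroids <- km$centers; break }
    }
    if (is.null(centroids))
      stop("k-means failed repeatedly (empty cluster); reduce k")
  }
  dimnames(centroids) <- NULL
  dtrajs <- lapply(coords, assign_to_centroids, centroids = centroids)
  structure(list(centroids = centroids, k = as.integer(k),
                 seed = as.integer(seed), dtrajs = dtrajs),
            class = "cluster_model")
}

## Nearest-centroid assignment, 0-based states; exact ties -> lowest index
## (max.col with ties.method "first" on negated distances).
assign_to_centroids <- function(x, centroids) {
  x <- as.matrix(x)
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") -
    2 * x %*% t(centroids)
  max.col(-d2, ties.method = "first") - 1L
}

## Sliding-window transition counts at a lag over a list of 0-based dtrajs.
## Returns a k x k matrix over states 0..(k-1), k = max state + 1.
transition_counts <- function(dtrajs, lag, n_states = NULL) {
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  k <- n_states %||% (max(unlist(dtrajs)) + 1L)
  counts <- matrix(0, k, k)
  for (d in dtrajs) {
    n <- length(d) - lag
    if (n < 1L) next
    from <- d[seq_len(n)] + 1L
    to <- d[seq_len(n) + lag] + 1L
    tab <- table(factor(from, levels = 1:k), factor(to, levels = 1:k))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  counts
}

## Largest strongly connected set of the positive-count graph (0-based ids).
largest_connected_set <- function(counts) {
  pos <- which(counts > 0, arr.ind = TRUE)
  k <- nrow(counts)
  if (length(pos) == 0L) stop("no observed transitions")
  g <- igraph::graph_from_edgelist(pos, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  comp <- igraph::components(g, mode = "strong")
  ## among strongly connected components, keep the one with most frames of
  ## count mass (ties: most states)
  mass <- vapply(seq_len(comp$no), function(cc) {
    s <- which(comp$membership == cc)
    sum(counts[s, s, drop = FALSE])
  }, numeric(1))
  best <- which.max(mass)
  sort(which(comp$membership == best)) - 1L
}

## Reversible maximum-likelihood transition matrix via the standard
## fixed-point iteration on the symmetric flux matrix x:
##   x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j)
## converged when the stationary distribution moves less than tol.
reversible_mle <- function(counts, tol = 1e-10, max_iter = 1e6) {
  cs <- counts + t(counts)
  x <- cs / sum(cs)
  ci <- rowSums(counts)
  pi_old <- rowSums(x) / sum(x)
  it <- 0L; delta <- Inf
  while (it < max_iter) {
    it <- it + 1L
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    x <- cs / denom
    x[cs == 0] <- 0
    pi_new <- rowSums(x) / sum(x)
    delta <- max(abs(pi_new - pi_old))
    pi_old <- pi_new
    if (delta < tol) break
  }
  if (delta >= tol)
    warning(sprintf("reversible MLE did not converge (residual %.3g)", delta))
  xi <- rowSums(x)
  list(transition = x / xi, pi = xi / sum(xi), iterations = it,
       converged = delta < tol, residual = delta)
}

## Legacy estimator: add a 1/k pseudocount to every entry, row-normalise,
## stationary distribution from the leading left eigenvector.
pseudocount_rownorm <- function(counts) {
  k <- nrow(counts)
  c2 <- counts + 1 / k
  t_mat <- c2 / rowSums(c2)
  e <- eigen(t(t_mat))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  p <- abs(v) / sum(abs(v))
  list(transition = t_mat, pi = p, iterations = 1L, converged = TRUE,
       residual = 0)
}

#' Fit a Markov state model
#'
#' Estimates a row-stochastic transition matrix at the given lag from
#' sliding-window transition counts, restricted to the largest strongly
#' connected set of the count graph. Two estimators are available: the
#' reversible maximum-likelihood estimator (detailed balance enforced; the
#' default) and the legacy row-normalisation estimator with a 1/k
#' pseudocount.
#'
#' @param dtrajs List of 0-based integer state sequences (or one vector).
#' @param lag Lag time in frames (>= 1).
#' @param estimator `"reversible_mle"` or `"pseudocount_rownorm"`.
#' @param tol Convergence tolerance on the stationary distribution
#'   (reversible MLE).
#' @param max_iter Iteration cap for the reversible MLE.
#' @param frame_interval Frame interval in ps (recorded; enables ns
#'   reporting).
#' @return Object of class `msm`: `transition` (row-stochastic over active
#'   states), `pi` (stationary distribution), `active` (0-based original
#'   state ids of the active set), `counts` (full count matrix), `lag`
#'   (frames), `estimator`, `converged`, `n_states_total`.
#' @export
fit_msm <- function(dtrajs, lag,
                    estimator = c("reversible_mle", "pseudocount_rownorm"),
                    tol = 1e-10, max_iter = 1e6, frame_interval = NULL) {
  estimator <- match.arg(estimator)
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  stopifnot(lag >= 1L)
  counts <- transition_counts(dtrajs, lag)
  active <- largest_connected_set(counts)
  ca <- counts[active + 1L, active + 1L, drop = FALSE]
  est <- if (estimator == "reversible_mle") {
    reversible_mle(ca, tol = tol, max_iter = max_iter)
  } else {
    pseudocount_rownorm(ca)
  }
  structure(
    list(transition = est$transition, pi = est$pi, active = active,
         counts = counts, lag = as.integer(lag), estimator = estimator,
         converged = est$converged, iterations = est$iterations,
         n_states_total = nrow(counts),
         frame_interval = frame_interval),
    class = "msm"
  )
}

#' @export
print.msm <- function(x, ...) {
  cat(sprintf(
    "<msm> %d active / %d total states, lag %d frames, estimator %s\n",
    length(x$active), x$n_states_total, x$lag, x$estimator))
  cat("pi:", paste(sprintf("%.4f", utils::head(x$pi, 8L)), collapse = " "),
      if (length(x$pi) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.msm <- function(object, n_timescales = 5L, ...) {
  ev <- sort(Re(eigen(object$transition)$values), decreasing = TRUE)
  its <- implied_timescales_from_eigen(ev, object$lag, n_timescales)
  out <- list(n_active = length(object$active),
              n_total = object$n_states_total,
              lag = object$lag, estimator = object$estimator,
              pi = object$pi, implied_timescales = its,
              converged = object$converged)
  class(out) <- "summary.msm"
  out
}

#' @export
print.summary.msm <- function(x, ...) {
  cat(sprintf("Markov state model (%s), lag %d frames\n", x$estimator, x$lag))
  cat(sprintf("%d active of %d states; converged: %s\n", x$n_active,
              x$n_total, x$converged))
  cat("implied timescales (frames):",
      paste(sprintf("%.3g", x$implied_timescales), collapse = ", "), "\n")
  invisible(x)
}

implied_timescales_from_eigen <- function(ev, lag, n) {
  ev <- ev[ev < 1 - 1e-12 & ev > 0]
  utils::head(-lag / log(ev), n)
}

#' Simulate a discrete trajectory from a fitted MSM
#'
#' @param object An `msm` object.
#' @param nsim Number of steps.
#' @param seed Optional RNG seed.
#' @param init Initial state (0-based, in the original labelling); default:
#'   drawn from the stationary distribution.
#' @param ... Unused.
#' @return Integer vector of 0-based states (original labelling).
#' @export
simulate.msm <- function(object, nsim = 1000L, seed = NULL, init = NULL,
                         ...) {
  if (!is.null(seed)) set.seed(seed)
  t_mat <- object$transition
  k <- nrow(t_mat)
  s <- if (is.null(init)) sample.int(k, 1L, prob = object$pi)
  else match(init, object$active)
  out <- integer(nsim)
  for (i in seq_len(nsim)) {
    out[i] <- s
    s <- sample.int(k, 1L, prob = t_mat[s, ])
  }
  object$active[out]
}

#' Per-frame equilibrium weights from an MSM
#'
#' Each frame assigned to active state s gets weight pi_s / N_s, where N_s is
#' the number of frames assigned to s; frames outside the active set get
#' weight 0. Weights over active frames sum to 1.
#'
#' @param msm An `msm` object fitted on these `dtrajs`.
#' @param dtrajs List of 0-based state sequences (or one vector).
#' @return List of class `frame_weights`: `weights` (list of numeric vectors
#'   matching `dtrajs`), `states` (the dtrajs), `state_counts` (N_s per
#'   active state).
#' @export
frame_weights <- function(msm, dtrajs) {
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  all_states <- unlist(dtrajs)
  n_s <- vapply(msm$active, function(s) sum(all_states == s), numeric(1))
  if (any(n_s == 0))
    stop("active state with zero assigned frames; MSM/dtrajs mismatch")
  per_state <- msm$pi / n_s
  w <- lapply(dtrajs, function(d) {
    j <- match(d, msm$active)
    out <- ifelse(is.na(j), 0, per_state[j])
    as.numeric(out)
  })
  structure(list(weights = w, states = dtrajs, state_counts = n_s,
                 active = msm$active, pi = msm$pi),
            class = "frame_weights")
}

#' Rank-r VAMP-2 score of transition statistics
#'
#' Sum of the `rank` largest squared singular values of
#' C00^(-1/2) C01 C11^(-1/2), the whitened transition operator built from
#' transition counts of discrete trajectories at a lag.
#'
#' @param dtrajs List of 0-based state sequences (or one vector).
#' @param lag Lag in frames.
#' @param rank Number of singular values retained (default 10).
#' @param n_states Total number of states (default inferred).
#' @return Numeric VAMP-2 score (bounded above by `rank`).
#' @export
vamp2_score <- function(dtrajs, lag, rank = 10L, n_states = NULL) {
  counts <- transition_counts(dtrajs, lag, n_states = n_states)
  c0 <- rowSums(counts); c1 <- colSums(counts)
  keep0 <- c0 > 0; keep1 <- c1 > 0
  if (sum(keep0) < 2L || sum(keep1) < 2L)
    stop("need at least 2 visited states for a VAMP-2 score")
  k <- counts[keep0, keep1, drop = FALSE] / sum(counts)
  p0 <- c0[keep0] / sum(counts); p1 <- c1[keep1] / sum(counts)
  kbar <- diag(1 / sqrt(p0)) %*% k %*% diag(1 / sqrt(p1))
  sv <- svd(kbar, nu = 0, nv = 0)$d
  sum(utils::head(sv, rank)^2)
}

#' Cross-validated microstate-count selection
#'
#' For each candidate k: trajectories are split 50/50 into train and test
#' sets; centroids are fitted on the training trajectories; test trajectories
#' are assigned by Euclidean proximity; the rank-10 VAMP-2 score of the test
#' transition statistics measures model quality. Repeated over `n_splits`
#' random splits. Implied timescales over a lag grid are reported for the
#' best k.
#'
#' @param tica_coords List of projected trajectories (matrices).
#' @param k_grid Candidate microstate counts.
#' @param msm_lag MSM lag in frames for the scoring.
#' @param n_splits Number of random 50/50 trajectory splits (default 5).
#' @param seed RNG seed.
#' @param rank VAMP-2 rank (default 10).
#' @param lag_grid Lags (frames) for the implied-timescale table (default
#'   `msm_lag * c(1, 2, 4)`).
#' @return List of class `msm_validation`: `scores` (data.frame k / mean /
#'   sd), `best_k`, `implied_timescales` (data.frame lag x timescale index).
#' @export
validate_msm <- function(tica_coords, k_grid, msm_lag, n_splits = 5L,
                         seed = 1L, rank = 10L, lag_grid = NULL) {
  coords <- if (is.list(tica_coords)) tica_coords else list(tica_coords)
  n_traj <- length(coords)
  if (n_traj < 2L) stop("need at least 2 trajectories for cross-validation")
  res <- matrix(NA_real_, length(k_grid), n_splits)
  for (s in seq_len(n_splits)) {
    set.seed(derive_seed(seed, 100L + s))
    train <- sample(n_traj, max(1L, floor(n_traj / 2)))
    test <- setdiff(seq_len(n_traj), train)
    for (ki in seq_along(k_grid)) {
      cl <- try(cluster_assign(coords, k_grid[ki],
                               seed = derive_seed(seed, 200L + s),
                               fit_subset = train), silent = TRUE)
      if (inherits(cl, "try-error")) next
      sc <- try(vamp2_score(cl$dtrajs[test], msm_lag, rank = rank,
                            n_states = k_grid[ki]), silent = TRUE)
      if (!inherits(sc, "try-error")) res[ki, s] <- sc
    }
  }
  scores <- data.frame(
    k = k_grid,
    mean = rowMeans(res, na.rm = TRUE),
    sd = apply(res, 1L, stats::sd, na.rm = TRUE)
  )
  best_k <- scores$k[which.max(scores$mean)]
  lag_grid <- lag_grid %||% unique(pmax(1L, msm_lag * c(1L, 2L, 4L)))
  cl <- cluster_assign(coords, best_k, seed = derive_seed(seed, 300L))
  its <- implied_timescales(cl$dtrajs, lag_grid)
  structure(list(scores = scores, best_k = best_k,
                 implied_timescales = its, n_splits = n_splits,
                 rank = rank, seed = seed),
            class = "msm_validation")
}

#' @export
print.msm_validation <- function(x, ...) {
  cat(sprintf("<msm_validation> rank-%d VAMP-2, %d splits; best k = %d\n",
              x$rank, x$n_splits, x$best_k))
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Implied timescales over a lag grid
#'
#' @param dtrajs List of 0-based state sequences.
#' @param lags Lag times in frames.
#' @param n_timescales How many timescales per lag (default 5).
#' @param estimator Passed to [fit_msm()].
#' @return data.frame: `lag` plus `t1..tn` columns, timescales in frames.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 5L,
                               estimator = "reversible_mle") {
  rows <- lapply(lags, function(l) {
    m <- fit_msm(dtrajs, l, estimator = estimator)
    ev <- sort(Re(eigen(m$transition)$values), decreasing = TRUE)
    its <- implied_timescales_from_eigen(ev, l, n_timescales)
    length(its) <- n_timescales
    c(lag = l, stats::setNames(its, paste0("t", seq_len(n_timescales))))
  })
  as.data.frame(do.call(rbind, rows))
}
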