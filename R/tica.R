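#' Time-lagged independent component analysis with commute mapping
#'
#' Solves the time-lagged generalised eigenproblem on symmetrised covariance
#' estimates: with instantaneous covariance C00 and lagged covariance C0t
#' (both symmetrised over time reversal), eigenvectors of
#' C00^-1 C0t identify the slowest linear collective coordinates of the
#' feature process. Components are scaled by sqrt(t_i / 2) (the commute map),
#' where t_i = -lag / log|lambda_i| is the implied timescale, so that
#' Euclidean distances in the projected space approximate kinetic distances.
#' The retained dimension is the smallest n whose cumulative kinetic variance
#' (share of component i proportional to t_i / 2) reaches `var_cutoff`.
#'
#' @param features Feature matrix (frames x features) or a list of such
#'   matrices, one per trajectory.
#' @param lag Lag time in frames (>= 1, shorter than every trajectory).
#' @param var_cutoff Kinetic variance fraction to retain (default 0.9).
#' @param regularization Ridge added to C00's diagonal (default 1e-10)
#'   so duplicated or constant features do not make the problem singular.
#' @return Object of class `tica_model`: `lag`, `mean`, `eigenvalues`,
#'   `eigenvectors` (features x components), `timescales` (frames),
#'   `commute_scales`, `n_retained`, `kinetic_variance_fraction`
#'   (cumulative).
#' @export
fit_tica <- function(features, lag, var_cutoff = 0.9,
                     regularization = 1e-10) {
  feats <- if (is.list(features)) features else list(features)
  stopifnot(lag >= 1L, var_cutoff > 0, var_cutoff <= 1)
  if (any(vapply(feats, nrow, 1L) <= lag))
    stop("lag must be shorter than every trajectory")
  p <- ncol(feats[[1L]])
  ## symmetrised (reversible) covariance accumulation
  sum_x <- numeric(p); n_pairs <- 0
  c00 <- matrix(0, p, p); c0t <- matrix(0, p, p)
  for (x in feats) {
    n <- nrow(x) - lag
    x0 <- x[seq_len(n), , drop = FALSE]
    xt <- x[seq_len(n) + lag, , drop = FALSE]
    sum_x <- sum_x + colSums(x0) + colSums(xt)
    n_pairs <- n_pairs + n
    c00 <- c00 + crossprod(x0) + crossprod(xt)
    cxy <- crossprod(x0, xt)
    c0t <- c0t + cxy + t(cxy)
  }
  mu <- sum_x / (2 * n_pairs)
  c00 <- c00 / (2 * n_pairs) - tcrossprod(mu)
  c0t <- c0t / (2 * n_pairs) - tcrossprod(mu)
  c00 <- c00 + diag(regularization, p)
  ## whiten, then symmetric eigenproblem
  e0 <- eigen(c00, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-12
  w <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  m <- t(w) %*% c0t %*% w
  m <- (m + t(m)) / 2
  em <- eigen(m, symmetric = TRUE)
  lambda <- em$values
  vecs <- w %*% em$vectors
  ## implied timescales; |lambda| clipped away from 0 and 1
  lam_c <- pmin(pmax(abs(lambda), 1e-12), 1 - 1e-6)
  ts <- -lag / log(lam_c)
  scales <- sqrt(ts / 2)
  kv <- ts / 2
  cumfrac <- cumsum(kv) / sum(kv)
  n_ret <- which(cumfrac >= var_cutoff)[1L]
  structure(
    list(lag = lag, mean = mu, eigenvalues = lambda, eigenvectors = vecs,
         timescales = ts, commute_scales = scales, n_retained = n_ret,
         kinetic_variance_fraction = cumfrac, var_cutoff = var_cutoff),
    class = "tica_model"
  )
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf(
    "<tica_model> lag %d frames; %d/%d components retained (%.0f%% kinetic variance)\n",
    x$lag, x$n_retained, length(x$eigenvalues), 100 * x$var_cutoff))
  cat("leading eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 5L)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project features into the commute-mapped tICA space
#'
#' @param model A `tica_model` from [fit_tica()].
#' @param features Matrix or list of matrices with the same feature columns.
#' @param n_components Number of components (default: the retained
#'   dimension).
#' @param commute Apply the commute-map scaling (default TRUE).
#' @return Projected matrix, or list of matrices if `features` was a list.
#' @export
project_tica <- function(model, features, n_components = model$n_retained,
                         commute = TRUE) {
  proj1 <- function(x) {
    z <- sweep(as.matrix(x), 2L, model$mean) %*%
      model$eigenvectors[, seq_len(n_components), drop = FALSE]
    if (commute)
      z <- sweep(z, 2L, model$commute_scales[seq_len(n_components)], "*")
    z
  }
  if (is.list(features)) lapply(features, proj1) else proj1(features)
}
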