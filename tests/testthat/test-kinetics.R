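single_frame_traj <- function(st) {
  pe_trajectory(st, array(st$xyz, c(1, nrow(st$atoms), 3)))
}

test_that("glycine contributes backbone dihedrals only", {
  st <- make_fake_protein(c("ALA", "GLY", "ALA"))
  traj <- single_frame_traj(st)
  feats <- dihedral_features(traj, data.frame(chain = "A", resno = 2))
  labels <- attr(feats, "labels")
  expect_setequal(labels, c("A:2:phi", "A:2:psi"))
  expect_equal(ncol(feats), 4L)
})

test_that("feature count matches a hand enumeration of rotatable quadruplets", {
  ## ALA-GLY-SER: psi1, phi2, psi2, phi3 and SER chi1 -> 5 angles, 10 cols
  st <- make_fake_protein(c("ALA", "GLY", "SER"))
  traj <- single_frame_traj(st)
  feats <- dihedral_features(traj, data.frame(chain = "A", resno = 1:3))
  expect_equal(ncol(feats), 10L)
  expect_setequal(attr(feats, "labels"),
                  c("A:1:psi", "A:2:phi", "A:2:psi", "A:3:phi", "A:3:chi1"))
  ## LYS has chi1-chi4 but our fixture only carries CB/CG/CD -> chi1, chi2
  st2 <- make_fake_protein(c("ALA", "LYS", "ALA"))
  feats2 <- dihedral_features(single_frame_traj(st2),
                              data.frame(chain = "A", resno = 2))
  expect_setequal(attr(feats2, "labels"),
                  c("A:2:phi", "A:2:psi", "A:2:chi1", "A:2:chi2"))
})

test_that("every sin/cos pair lies on the unit circle", {
  st <- make_fake_protein(c("ALA", "SER", "LEU", "GLY"))
  set.seed(31)
  frames <- array(0, c(8, nrow(st$atoms), 3))
  for (i in 1:8) frames[i, , ] <- st$xyz + matrix(rnorm(nrow(st$xyz) * 3,
                                                        sd = 0.3), ncol = 3)
  feats <- dihedral_features(pe_trajectory(st, frames),
                             data.frame(chain = "A", resno = 1:4))
  s2c2 <- feats[, seq(1, ncol(feats), 2)]^2 + feats[, seq(2, ncol(feats), 2)]^2
  expect_equal(as.vector(s2c2), rep(1, length(s2c2)), tolerance = 1e-9)
})

test_that("dihedral values agree with the bio3d torsion oracle", {
  set.seed(32)
  for (i in 1:5) {
    quad <- matrix(rnorm(12, sd = 3), 4)
    frames <- array(quad, c(1, 4, 3))
    ours <- frames_dihedral(frames, 1:4)
    ref <- bio3d::torsion.xyz(as.vector(t(quad)), atm.inc = 4)
    expect_equal(as.numeric(ours) * 180 / pi, as.numeric(ref)[1],
                 tolerance = 1e-6)
  }
})

test_that("tICA on white noise finds no slow components", {
  set.seed(33)
  x <- matrix(rnorm(1e4 * 6), ncol = 6)
  m <- fit_tica(x, lag = 5)
  expect_lt(max(abs(m$eigenvalues)), 0.1)
})

test_that("tICA recovers a planted slow coordinate", {
  set.seed(34)
  n <- 20000
  ## two-state jump process: slow flips
  s <- numeric(n); s[1] <- 1
  for (i in 2:n) s[i] <- if (runif(1) < 0.005) -s[i - 1] else s[i - 1]
  x <- cbind(s + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 10), ncol = 10))
  m <- fit_tica(x, lag = 10)
  proj <- project_tica(m, x, n_components = 1)
  expect_gt(abs(cor(proj[, 1], s)), 0.9)
  expect_gt(m$eigenvalues[1], 0.8)
})

test_that("duplicated feature columns are absorbed by regularisation", {
  set.seed(35)
  x <- matrix(rnorm(2000 * 3), ncol = 3)
  x <- cbind(x, x[, 1])
  m <- fit_tica(x, lag = 2)
  expect_true(all(is.finite(m$eigenvalues)))
  expect_true(all(is.finite(m$eigenvectors)))
})

test_that("tICA projection is invariant (up to sign) under feature rotation", {
  set.seed(36)
  n <- 5000
  s <- cumsum(rnorm(n)) / 10
  x <- cbind(s + rnorm(n, sd = 0.2), rnorm(n), rnorm(n), rnorm(n))
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  m1 <- fit_tica(x, lag = 5)
  m2 <- fit_tica(x %*% q, lag = 5)
  p1 <- project_tica(m1, x, n_components = 1)
  p2 <- project_tica(m2, x %*% q, n_components = 1)
  expect_gt(abs(cor(p1[, 1], p2[, 1])), 1 - 1e-6)
  expect_equal(m1$eigenvalues[1], m2$eigenvalues[1], tolerance = 1e-8)
})

test_that("retained dimension honours the kinetic variance cutoff", {
  set.seed(37)
  x <- matrix(rnorm(5000 * 5), ncol = 5)
  m <- fit_tica(x, lag = 2, var_cutoff = 1)
  expect_equal(m$n_retained, length(m$eigenvalues))
  m2 <- fit_tica(x, lag = 2, var_cutoff = 0.2)
  expect_lte(m2$n_retained, m$n_retained)
  cf <- m$kinetic_variance_fraction
  expect_true(all(diff(cf) >= -1e-12))
  expect_equal(cf[length(cf)], 1, tolerance = 1e-9)
})

test_that("clustering assigns blobs correctly and k=1 is trivial", {
  set.seed(38)
  blobs <- rbind(matrix(rnorm(200, 0, 0.2), ncol = 2),
                 matrix(rnorm(200, 5, 0.2), ncol = 2),
                 matrix(rnorm(200, -5, 0.2), ncol = 2))
  truth <- rep(0:2, each = 100)
  cl <- cluster_assign(blobs, k = 3, seed = 1)
  ## perfect agreement up to label permutation
  tab <- table(cl$dtrajs[[1]], truth)
  expect_equal(sum(apply(tab, 1, max)), 300)

  cl1 <- cluster_assign(blobs, k = 1, seed = 1)
  expect_true(all(cl1$dtrajs[[1]] == 0L))
})

test_that("equidistant frames go to the lowest-index centroid", {
  centroids <- rbind(c(-1, 0), c(1, 0))
  expect_equal(assign_to_centroids(matrix(c(0, 0), 1), centroids), 0L)
})

test_that("held-out trajectories are assigned by proximity to fitted centroids", {
  set.seed(39)
  t1 <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
              matrix(rnorm(100, 4, 0.1), ncol = 2))
  t2 <- matrix(rnorm(60, 4, 0.1), ncol = 2)
  cl <- cluster_assign(list(t1, t2), k = 2, seed = 2, fit_subset = 1L)
  ## all frames of the held-out trajectory fall in the blob-at-4 state
  s4 <- cl$dtrajs[[1]][60]   # a frame known to be in the 4-blob
  expect_true(all(cl$dtrajs[[2]] == s4))
})

test_that("VAMP-2 equals state count for a frozen chain and ~1 for iid jumps", {
  frozen <- lapply(0:4, function(s) rep(s, 50L))
  expect_equal(vamp2_score(frozen, lag = 1), 5, tolerance = 1e-10)
  set.seed(40)
  iid <- list(sample(0:4, 20000, replace = TRUE))
  expect_equal(vamp2_score(iid, lag = 1), 1, tolerance = 0.05)
})

test_that("MSM fitting: constant trajectory gives the trivial model", {
  m <- fit_msm(rep(0L, 100), lag = 1)
  expect_equal(m$transition, matrix(1, 1, 1))
  expect_equal(m$pi, 1)
})

test_that("a two-state chain is recovered within tolerance", {
  t_true <- rbind(c(0.95, 0.05), c(0.10, 0.90))
  set.seed(41)
  d <- pocketensemble:::sample_markov_chain(t_true, 1e5)
  m <- fit_msm(d, lag = 1)
  expect_lt(max(abs(m$transition - t_true)), 0.02)
  expect_lt(max(abs(m$pi - c(2 / 3, 1 / 3))), 0.02)
})

test_that("non-exchanging states are excluded from the active set", {
  d1 <- rep(c(0L, 1L), 50)
  d2 <- rep(2L, 60)
  m <- fit_msm(list(d1, d2), lag = 1)
  expect_equal(m$active, c(0L, 1L))
  expect_equal(dim(m$transition), c(2L, 2L))
})

test_that("the reversible MLE satisfies detailed balance and row-stochasticity", {
  set.seed(42)
  for (trial in 1:5) {
    k <- sample(3:6, 1)
    t_true <- matrix(runif(k * k), k); t_true <- t_true / rowSums(t_true)
    d <- pocketensemble:::sample_markov_chain(t_true, 20000)
    m <- fit_msm(d, lag = 1)
    expect_equal(rowSums(m$transition), rep(1, length(m$pi)),
                 tolerance = 1e-10)
    db <- m$pi * m$transition - t(m$pi * m$transition)
    expect_lt(max(abs(db)), 1e-8)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    ## stationarity: pi T = pi
    expect_lt(max(abs(as.numeric(m$pi %*% m$transition) - m$pi)), 1e-8)
  }
})

test_that("the pseudocount estimator row-normalises counts plus 1/k", {
  d <- c(0L, 0L, 1L, 0L, 1L, 1L, 0L)
  m <- fit_msm(d, lag = 1, estimator = "pseudocount_rownorm")
  counts <- pocketensemble:::transition_counts(list(d), 1L)
  expected <- (counts + 0.5) / rowSums(counts + 0.5)
  expect_equal(m$transition, expected, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(m$pi %*% m$transition) - m$pi)), 1e-8)
})

test_that("frame weights are pi_s / N_s, sum to one, and survive relabeling", {
  ## uniform 2-state chain, 5 frames each -> every weight 0.1
  d <- rep(c(0L, 1L), 5)
  m <- fit_msm(c(d, d), lag = 1)   # symmetric counts -> pi = (0.5, 0.5)
  w <- frame_weights(m, list(d, d))
  expect_equal(sum(unlist(w$weights)), 1, tolerance = 1e-12)
  if (max(abs(m$pi - 0.5)) < 1e-9)
    expect_equal(unique(round(unlist(w$weights), 12)), 0.05)

  ## pi = (0.9, 0.1), N = (9, 1): every frame weighted 0.1
  m2 <- structure(list(pi = c(0.9, 0.1), active = c(0L, 1L)), class = "msm")
  d2 <- c(rep(0L, 9), 1L)
  w2 <- frame_weights(m2, d2)
  expect_equal(unlist(w2$weights), rep(0.1, 10))

  ## relabeling invariance of total mass and per-frame weights
  m3 <- structure(list(pi = c(0.1, 0.9), active = c(1L, 0L)), class = "msm")
  w3 <- frame_weights(m3, d2)
  expect_equal(unlist(w3$weights), unlist(w2$weights))

  ## frames outside the active set carry no weight
  m4 <- structure(list(pi = 1, active = 0L), class = "msm")
  w4 <- frame_weights(m4, c(rep(0L, 4), 5L))
  expect_equal(unlist(w4$weights), c(rep(0.25, 4), 0))
})

test_that("implied timescales are lag-independent for Markovian data", {
  t_true <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  lam2 <- sort(eigen(t_true)$values)[1]
  true_ts <- -1 / log(lam2)
  set.seed(43)
  d <- pocketensemble:::sample_markov_chain(t_true, 2e5)
  its <- implied_timescales(list(d), lags = c(1L, 2L, 4L), n_timescales = 1)
  expect_equal(its$t1, rep(true_ts, 3), tolerance = 0.1)
})

test_that("cross-validated VAMP-2 selection prefers the true state count", {
  set.seed(44)
  t_true <- rbind(c(0.95, 0.05, 0), c(0.05, 0.9, 0.05), c(0, 0.05, 0.95))
  coords <- lapply(1:4, function(i) {
    s <- pocketensemble:::sample_markov_chain(t_true, 3000)
    cbind(s * 3 + rnorm(3000, sd = 0.3), rnorm(3000, sd = 0.3))
  })
  rep <- validate_msm(coords, k_grid = c(2L, 3L, 5L), msm_lag = 1L,
                      n_splits = 3L, seed = 7)
  expect_s3_class(rep, "msm_validation")
  expect_true(all(rep$scores$mean <= 10 + 1e-6))
  ## 3 metastable basins: k >= 3 should beat k = 2
  s2 <- rep$scores$mean[rep$scores$k == 2]
  s3 <- rep$scores$mean[rep$scores$k == 3]
  expect_gt(s3, s2)
  expect_true(all(rep$implied_timescales$t1 > 0, na.rm = TRUE))
})

test_that("simulating from a fitted MSM reproduces its stationary distribution", {
  t_true <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  set.seed(45)
  d <- pocketensemble:::sample_markov_chain(t_true, 5e4)
  m <- fit_msm(d, lag = 1)
  sim <- simulate(m, nsim = 5e4, seed = 46)
  occ <- tabulate(sim + 1L, 2) / 5e4
  expect_lt(max(abs(occ - m$pi)), 0.03)
})
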