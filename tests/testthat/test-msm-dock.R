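fake_msm <- function(pi, active = seq_along(pi) - 1L) {
  structure(list(pi = pi, active = as.integer(active)), class = "msm")
}

test_that("per-state sample sizes follow the max(base, round(pi*scale)) rule", {
  ## state occupancies engineered: pi ~ (0.989, 0.001 -> base 3, 0.01 -> 20)
  set.seed(61)
  d <- c(rep(0L, 96890), rep(1L, 110), rep(2L, 1100),
         rep(c(0L, 1L, 2L), 300))  # tail guarantees connectivity
  m <- fake_msm(c(0.989, 0.001, 0.01))
  s <- sample_docking_structures(m, list(d), base = 3, scale = 2000, seed = 5)
  n_by_state <- table(s$state)
  expect_equal(unname(n_by_state[["1"]]), 3L)     # 0.001*2000 = 2 < 3
  expect_equal(unname(n_by_state[["2"]]), 20L)    # round(0.01*2000)
  expect_equal(unname(n_by_state[["0"]]), round(0.989 * 2000))
  ## frames are unique and belong to their state
  expect_false(any(duplicated(s[c("traj", "frame")])))
  expect_true(all(d[s$frame + 1L] == s$state))
})

test_that("a state with fewer frames than requested is capped with a warning", {
  d <- c(rep(0L, 20), 1L, 0L, 1L)
  m <- fake_msm(c(0.9, 0.1))
  expect_warning(
    s <- sample_docking_structures(m, list(d), base = 3, scale = 10, seed = 1),
    "only")
  expect_equal(sum(s$state == 1L), 2L)
})

test_that("the docking box centres on the aligned-site centroid", {
  st <- make_fake_protein(c("ALA", "LEU", "SER", "GLY"))
  n <- nrow(st$atoms)
  sel <- select_atoms(st, elety = c("N", "CA", "C", "O"))
  idx <- as.integer(unclass(sel)) + 1L

  ## single frame: centroid of that frame's selection
  one <- pe_trajectory(st, array(st$xyz, c(1, n, 3)))
  box1 <- define_docking_box(one, sel, edge = 20)
  expect_equal(box1$center, colMeans(st$xyz[idx, ]))

  ## two frames with selection centroids offset by (2,0,0): centre midway
  f2 <- st$xyz; f2[, 1] <- f2[, 1] + 2
  two <- pe_trajectory(st, array(c(rbind(st$xyz, f2)[c(seq(1, 2 * n, 2),
                                                       seq(2, 2 * n, 2)), ]),
                                 c(2, n, 3)))
  ## build the 2-frame array directly to avoid interleave confusion
  fr <- array(0, c(2, n, 3)); fr[1, , ] <- st$xyz; fr[2, , ] <- f2
  two <- pe_trajectory(st, fr)
  box2 <- define_docking_box(two, sel)
  expect_equal(box2$center, colMeans(st$xyz[idx, ]) + c(1, 0, 0))

  ## rigid pre-alignment translation is removed by iterative alignment
  fr2 <- fr; fr2[2, , ] <- fr2[2, , ] + 100
  al <- iterative_ensemble_align(pe_trajectory(st, fr2), sel)
  box3 <- define_docking_box(al$trajectory, sel)
  al_ref <- iterative_ensemble_align(pe_trajectory(st, fr), sel)
  box_ref <- define_docking_box(al_ref$trajectory, sel)
  expect_equal(box3$center, box_ref$center, tolerance = 1e-6)

  p <- tempfile()
  write_docking_box(box2, p)
  got <- read.table(p, sep = "=", strip.white = TRUE)
  expect_equal(got$V2[1:3], box2$center, tolerance = 1e-12)
})

test_that("docking score ingestion keeps the best pose and flags problems", {
  d <- list(c(0L, 0L, 1L, 1L))
  tab <- data.frame(traj_id = 1, frame = c(0, 0, 0, 2),
                    score_kcal_mol = c(-5.1, -4.2, -3.0, -6.0))
  rec <- ingest_docking_scores(tab, d)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$score[rec$frame == 0], -5.1)
  expect_equal(rec$state, c(0L, 1L))

  m <- fake_msm(1, active = 0L)
  expect_warning(rec2 <- ingest_docking_scores(tab, d, msm = m), "inactive")
  expect_true(all(rec2$state == 0L))

  expect_error(ingest_docking_scores(tab[0, ], d), "no docking records")
  bad <- tab; bad$frame[1] <- 99
  expect_error(ingest_docking_scores(bad, d), "not found")
})

test_that("aggregation reduces to the score itself in the degenerate case", {
  m <- fake_msm(c(0.3, 0.7))
  rec <- data.frame(state = c(0L, 0L, 1L), score = rep(-5.5, 3))
  est <- aggregate_binding_free_energy(rec, m)
  expect_equal(est$dG_total, -5.5, tolerance = 1e-12)
})

test_that("the two-state worked example matches direct arithmetic", {
  m <- fake_msm(c(0.9, 0.1))
  rec <- data.frame(state = c(0L, 1L), score = c(-2, -8))
  est <- aggregate_binding_free_energy(rec, m, temperature = 310)
  rt <- 1.987204e-3 * 310
  oracle <- -rt * log(0.9 * exp(2 / rt) + 0.1 * exp(8 / rt))
  expect_equal(est$dG_total, oracle, tolerance = 1e-10)
  expect_equal(est$K_d, exp(est$dG_total / rt), tolerance = 1e-12)
})

test_that("one structure per state reduces to the single-structure equation", {
  set.seed(62)
  pi <- runif(4); pi <- pi / sum(pi)
  g <- -runif(4, 2, 9)
  m <- fake_msm(pi)
  rec <- data.frame(state = 0:3, score = g)
  est <- aggregate_binding_free_energy(rec, m, temperature = 310)
  rt <- 1.987204e-3 * 310
  expect_equal(est$dG_total, -rt * log(sum(pi * exp(-g / rt))),
               tolerance = 1e-12)
})

test_that("soft-min bounds and monotonicity hold over random instances", {
  set.seed(63)
  rt <- 1.987204e-3 * 310
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    pi <- runif(k); pi <- pi / sum(pi)
    n_per <- sample(1:3, k, replace = TRUE)
    st <- rep(0:(k - 1), n_per)
    g <- -runif(length(st), 0, 10)
    m <- fake_msm(pi)
    rec <- data.frame(state = st, score = g)
    est <- suppressMessages(aggregate_binding_free_energy(rec, m,
                                                          temperature = 310))
    w <- pi[st + 1] / n_per[st + 1]
    ## soft-min bounds
    expect_gte(est$dG_total, min(g) - 1e-9)
    expect_true(all(est$dG_total <= g + rt * log(1 / w) + 1e-9))
    ## monotonicity: improving one score can only improve the aggregate
    j <- sample(length(g), 1)
    rec2 <- rec; rec2$score[j] <- rec2$score[j] - runif(1, 0, 3)
    est2 <- aggregate_binding_free_energy(rec2, m, temperature = 310)
    expect_lte(est2$dG_total, est$dG_total + 1e-12)
  }
})

test_that("aggregation is invariant under record duplication with N rescaled", {
  m <- fake_msm(c(0.6, 0.4))
  rec <- data.frame(state = c(0L, 1L), score = c(-4, -7))
  est1 <- aggregate_binding_free_energy(rec, m)
  rec2 <- rbind(rec, rec[1, ], rec[1, ])   # state 0 now has N = 3 copies
  est2 <- aggregate_binding_free_energy(rec2, m)
  expect_equal(est2$dG_total, est1$dG_total, tolerance = 1e-12)
})

test_that("sampled-plan counts (not record counts) define N when supplied", {
  m <- fake_msm(c(0.5, 0.5))
  samples <- data.frame(state = c(0L, 0L, 1L), traj = 1, frame = 0:2)
  rec <- data.frame(state = c(0L, 1L), score = c(-5, -5))
  est <- aggregate_binding_free_energy(rec, m, samples)
  ## state 0 contributes pi/2 * K, state 1 pi/1 * K: sum = 0.75 K
  rt <- 1.987204e-3 * 310
  expect_equal(est$dG_total, -rt * log(0.75 * exp(5 / rt)),
               tolerance = 1e-12)
})

test_that("free energy / dissociation constant conversions are consistent", {
  expect_equal(deltaG_to_Kd(0), 1)
  kd <- deltaG_to_Kd(-8.8, 310)
  expect_gt(kd * 1e6, 0.57); expect_lt(kd * 1e6, 0.68)
  x <- c(-12, -8.8, -3, 0, 1)
  expect_equal(Kd_to_deltaG(deltaG_to_Kd(x)), x, tolerance = 1e-12)
  expect_error(deltaG_to_Kd(NaN), "non-finite")
  expect_error(Kd_to_deltaG(-1), "positive")
})

test_that("synthetic end-to-end docking recovers the ground-truth free energy", {
  ens <- reference_ensemble()
  spec <- ens$spec
  gt <- ensemble_ground_truth(spec, threshold = 150)
  m <- fit_msm(ens$states, lag = 1)
  samples <- sample_docking_structures(m, ens$states, seed = 11)
  tab <- make_docking_table(spec, ens$states, samples, seed = 13)
  rec <- ingest_docking_scores(tab, ens$states, msm = m)
  est <- aggregate_binding_free_energy(rec, m, samples)
  expect_lt(abs(est$dG_total - gt$dG_true), 0.2)
})
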