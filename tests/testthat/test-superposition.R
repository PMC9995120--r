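test_that("superposing identical sets gives zero RMSD and identity rotation", {
  set.seed(1)
  a <- matrix(rnorm(30), 10)
  al <- kabsch_superpose(a, a)
  expect_equal(al$rmsd, 0, tolerance = 1e-10)
  expect_equal(al$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(al$rotation), 1, tolerance = 1e-8)
})

test_that("a known rigid transform is recovered exactly", {
  set.seed(2)
  a <- matrix(rnorm(36), 12)
  rot <- random_rotation()
  b <- a %*% rot + matrix(c(3, -1, 2), 12, 3, byrow = TRUE)
  al <- kabsch_superpose(a, b)
  expect_lt(al$rmsd, 1e-8)
  expect_equal(al$rotation, rot, tolerance = 1e-8)
  expect_equal(apply_transform(a, al), b, tolerance = 1e-8)
})

test_that("minimal RMSD matches a numeric optimisation oracle", {
  ## 4 points, one displaced by 1 A along x; oracle minimises RMSD over
  ## rotations (Euler angles) + optimal translation, independent of SVD
  a <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  b <- a; b[2, 1] <- b[2, 1] + 1
  euler <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  }
  obj <- function(p) {
    ar <- sweep(a, 2, colMeans(a)) %*% euler(p)
    br <- sweep(b, 2, colMeans(b))
    sqrt(mean(rowSums((ar - br)^2)))
  }
  best <- Inf
  set.seed(3)
  for (i in 1:25) {
    o <- stats::optim(stats::runif(3, -pi, pi), obj,
                      control = list(reltol = 1e-14))
    best <- min(best, o$value)
  }
  al <- kabsch_superpose(a, b)
  expect_equal(al$rmsd, best, tolerance = 1e-5)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("alignment results are invariant under global rigid motion", {
  set.seed(4)
  a <- matrix(rnorm(24), 8)
  b <- a + matrix(rnorm(24, sd = 0.3), 8)
  base <- kabsch_superpose(a, b)$rmsd
  for (i in 1:5) {
    rot <- random_rotation()
    t0 <- rnorm(3, sd = 10)
    rmsd2 <- kabsch_superpose(
      sweep(a %*% rot, 2, t0, "+"), sweep(b %*% rot, 2, t0, "+"))$rmsd
    expect_equal(rmsd2, base, tolerance = 1e-8)
  }
})

test_that("kabsch agrees with the bio3d fitting routine", {
  set.seed(5)
  a <- matrix(rnorm(30), 10)
  b <- a + matrix(rnorm(30, sd = 0.5), 10)
  al <- kabsch_superpose(a, b)
  fitted <- bio3d::fit.xyz(
    fixed = as.vector(t(b)), mobile = as.vector(t(a)),
    fixed.inds = 1:30, mobile.inds = 1:30)
  ref_rmsd <- sqrt(mean(rowSums((matrix(fitted, 10, byrow = TRUE) - b)^2)))
  expect_equal(al$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("iterative ensemble alignment collapses rigid-rotation copies", {
  st <- make_fake_protein(c("ALA", "LEU", "SER", "GLY", "ALA"))
  n <- nrow(st$atoms)
  set.seed(6)
  frames <- array(0, c(6, n, 3))
  for (i in 1:6) {
    frames[i, , ] <- sweep(st$xyz %*% random_rotation(), 2,
                           rnorm(3, sd = 4), "+")
  }
  traj <- pe_trajectory(st, frames)
  sel <- select_atoms(st, elety = c("N", "CA", "C", "O"))
  res <- iterative_ensemble_align(traj, sel)
  expect_true(res$converged)
  idx <- as.integer(unclass(sel)) + 1L
  for (i in 2:6) {
    expect_lt(coord_rmsd(res$trajectory$frames[1, idx, ],
                         res$trajectory$frames[i, idx, ]), 1e-6)
  }
})

test_that("single-frame alignment is the identity and tol=Inf stops after one pass", {
  st <- make_fake_protein(c("ALA", "GLY", "SER"))
  sel <- select_atoms(st)
  one <- pe_trajectory(st, array(st$xyz, c(1, nrow(st$atoms), 3)))
  res1 <- iterative_ensemble_align(one, sel)
  expect_equal(res1$trajectory$frames[1, , ], st$xyz)
  expect_equal(res1$mean, st$xyz)

  set.seed(7)
  frames <- array(0, c(4, nrow(st$atoms), 3))
  for (i in 1:4) frames[i, , ] <- st$xyz + rnorm(1)
  res2 <- iterative_ensemble_align(pe_trajectory(st, frames), sel, tol = Inf)
  expect_equal(res2$iterations, 1L)
})

test_that("iterative alignment is idempotent", {
  st <- make_fake_protein(c("ALA", "LEU", "SER", "GLY"))
  set.seed(8)
  frames <- array(0, c(5, nrow(st$atoms), 3))
  for (i in 1:5) {
    frames[i, , ] <- sweep((st$xyz + matrix(rnorm(nrow(st$xyz) * 3, sd = 0.2),
                                            ncol = 3)) %*% random_rotation(),
                           2, rnorm(3, sd = 2), "+")
  }
  sel <- select_atoms(st, elety = c("N", "CA", "C"))
  r1 <- iterative_ensemble_align(pe_trajectory(st, frames), sel)
  r2 <- iterative_ensemble_align(r1$trajectory, sel)
  expect_lte(r2$iterations, 1L)
  expect_lt(r2$final_shift, 1e-6)
})

test_that("ligand placement follows the site transform", {
  holo <- make_fake_protein(rep(c("ALA", "LEU", "SER"), 3))
  ## ligand near residues 4-6
  lig <- pe_ligand(rbind(c(10, 0, 1), c(11, 1, 1), c(10.5, -1, 2)))
  mapping <- data.frame(ref_resid = 1:9, target_resid = 1:9)

  ## identical target: ligand unchanged
  placed <- place_reference_ligand(holo, lig, holo, mapping)
  expect_equal(placed$xyz, lig$xyz, tolerance = 1e-6)

  ## rigid translation: ligand translated identically
  target <- pe_structure(holo$atoms, holo$xyz + matrix(c(5, 0, 0),
                                                       nrow(holo$xyz), 3,
                                                       byrow = TRUE))
  placed <- place_reference_ligand(holo, lig, target, mapping)
  expect_equal(placed$xyz, lig$xyz + matrix(c(5, 0, 0), 3, 3, byrow = TRUE),
               tolerance = 1e-6)
})

test_that("ligand placement uses the site residues, not distant ones", {
  holo <- make_fake_protein(rep(c("ALA", "LEU", "SER"), 4))
  lig <- pe_ligand(rbind(c(10, 0, 1), c(11, 1, 1), c(10.5, -1, 2), c(9, 1, 0)))
  mapping <- data.frame(ref_resid = 1:12, target_resid = 1:12)
  site <- select_contact_residues(holo, lig, cutoff = 5)$resno
  expect_gte(length(site), 3L)

  ## rotate the site residues as a rigid unit; scramble distant residues
  set.seed(9)
  rot <- random_rotation(); shift <- c(2, -3, 1)
  xyz2 <- holo$xyz
  in_site <- holo$atoms$resno %in% site
  xyz2[in_site, ] <- sweep(holo$xyz[in_site, ] %*% rot, 2, shift, "+")
  xyz2[!in_site, ] <- xyz2[!in_site, ] + matrix(rnorm(sum(!in_site) * 3, sd = 3),
                                                ncol = 3)
  target <- pe_structure(holo$atoms, xyz2)
  placed <- place_reference_ligand(holo, lig, target, mapping)

  ## oracle: manual Kabsch on the site backbone atoms only
  bb <- in_site & trimws(holo$atoms$elety) %in% c("N", "CA", "C", "O")
  al <- kabsch_superpose(holo$xyz[bb, ], xyz2[bb, ])
  expect_equal(placed$xyz, apply_transform(lig$xyz, al), tolerance = 1e-8)
  expect_equal(placed$xyz, sweep(lig$xyz %*% rot, 2, shift, "+"),
               tolerance = 1e-6)
})
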