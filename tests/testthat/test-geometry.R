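rotation_z <- function(th) {
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
}

test_that("Kabsch superposition removes rigid motions exactly", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  sup <- kabsch_superpose(X, X)
  expect_lt(sup$rmsd, 1e-12)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  Y <- X %*% t(rotation_z(pi / 2)) + matrix(rep(c(5, 5, 5), each = 10), 10)
  sup2 <- kabsch_superpose(Y, X)
  expect_lt(sup2$rmsd, 1e-9)
  expect_equal(det(sup2$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(transform_coords(sup2, Y) - X)), 1e-9)
})

test_that("Kabsch RMSD agrees with a numerical-minimisation oracle", {
  set.seed(7)
  for (k in 1:10) {
    X <- matrix(rnorm(12), 4, 3)
    Y <- X + matrix(rnorm(12, sd = 0.3), 4, 3)
    r <- kabsch_superpose(Y, X)$rmsd
    expect_lt(abs(r - oracle_min_rmsd(Y, X)), 1e-6)
  }
})

test_that("rotations are always proper and degenerate input errors", {
  # a reflection-tempting configuration still yields det +1
  X <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  Y <- X; Y[, 3] <- -Y[, 3]
  expect_equal(det(kabsch_superpose(Y, X)$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("RMSD series vanishes for rigid-motion trajectories", {
  base <- make_ideal_helix(10)
  b <- coords(base)
  arr <- array(NA_real_, c(6, nrow(b), 3))
  set.seed(2)
  for (f in 1:6) {
    arr[f, , ] <- b %*% t(rotation_z(runif(1, 0, 2 * pi))) +
      matrix(rnorm(3, sd = 5), nrow(b), 3, byrow = TRUE)
  }
  tr <- md_trajectory(base, arr)
  expect_lt(max(rmsd_series(tr)$values), 1e-9)
})

test_that("RMSD mean matches the Gaussian closed-form expectation", {
  base <- make_ideal_helix(50)
  sigma <- 0.5
  tr <- simulate_trajectory(base, covariance_spec(sigma = sigma, seed = 11), 800)
  m <- rmsd_series(tr, "calpha")$mean
  # frame-to-frame-0 displacement differences are N(0, 2 sigma^2) per
  # coordinate, so E[RMSD] ~ sqrt(6) sigma for many residues
  expect_lt(abs(m - sqrt(6) * sigma) / (sqrt(6) * sigma), 0.1)
})

test_that("RMSF recovers the planted flexible residue and ignores rotation", {
  base <- make_ideal_helix(20)
  sig <- rep(0.1, 20); sig[7] <- 2
  tr <- simulate_trajectory(base, covariance_spec(sigma = sig, seed = 3), 300)
  r <- rmsf_per_residue(tr)
  expect_equal(which.max(r$values), 7)
  expect_error(rmsf_per_residue(md_trajectory(base, tr$coords[1, , , drop = FALSE])),
               "single frame")
  # applying one global rotation to every frame leaves RMSF unchanged
  R <- rotation_z(1.1)
  arr <- tr$coords
  for (f in seq_len(n_frames(tr))) arr[f, , ] <- matrix(arr[f, , ], ncol = 3) %*% t(R)
  r2 <- rmsf_per_residue(md_trajectory(base, arr))
  expect_equal(r$values, r2$values, tolerance = 1e-9)
  # zero-variance trajectory has zero RMSF
  tr0 <- simulate_trajectory(base, covariance_spec(sigma = 0, seed = 1), 5)
  expect_lt(max(rmsf_per_residue(tr0)$values), 1e-12)
})

test_that("radius of gyration matches hand-computed closed forms", {
  one <- atoms_structure(matrix(c(0, 0, 0), 1), radius = 1.7)
  tr1 <- md_trajectory(one, array(coords(one), c(1, 1, 3)))
  expect_equal(radius_of_gyration_series(tr1, "all")$values, 0)

  two <- atoms_structure(matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE), 1.7)
  tr2 <- md_trajectory(two, array(rep(coords(two), each = 1), c(1, 2, 3)))
  expect_equal(radius_of_gyration_series(tr2, "all")$values, 1.0, tolerance = 1e-12)

  s <- 3.2
  tri <- atoms_structure(rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0)), 1.7)
  tr3 <- md_trajectory(tri, array(coords(tri), c(1, 3, 3)))
  expect_equal(radius_of_gyration_series(tr3, "all")$values, s / sqrt(3),
               tolerance = 1e-12)
})

test_that("series summaries convert to nm at the reporting boundary", {
  x <- series_summary(c(3, 4, 5), "angstrom")
  expect_equal(x$mean, 4); expect_equal(x$mean_nm, 0.4)
  expect_equal(x$sd, sd(c(3, 4, 5)))
  y <- series_summary(c(100, 300), "angstrom2")
  expect_equal(y$values_nm, c(1, 3))
})
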