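# one anti-correlated block over the first two thirds, one correlated
# block over the remainder, scaled to n_res
make_block_traj <- function(n_res = 30, n_frames = 2000, seed = 7) {
  t1 <- floor(n_res / 3)
  h <- floor((n_res - 2 * t1) / 2)
  blocks <- list(list(i = 1:t1, j = (t1 + 1):(2 * t1), sign = -1),
                 list(i = (2 * t1 + 1):(2 * t1 + h),
                      j = (2 * t1 + h + 1):(2 * t1 + 2 * h), sign = +1))
  spec <- covariance_spec(blocks = blocks, sigma = 0.5, seed = seed)
  simulate_trajectory(make_ideal_helix(n_res), spec, n_frames)
}

test_that("covariance matches a textbook two-pass oracle", {
  base <- make_ideal_helix(6)
  tr <- simulate_trajectory(base, covariance_spec(sigma = 0.4, seed = 5), 40)
  C <- covariance_matrix(tr, "calpha", superpose = FALSE)
  idx <- select_atoms(tr, "calpha")
  M <- t(vapply(1:40, function(f) as.numeric(t(frame_coords(tr, f)[idx, ])),
                numeric(18)))
  oracle <- stats::cov(M) * (nrow(M) - 1) / nrow(M)
  expect_lt(max(abs(C - oracle)), 1e-10)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-9)  # positive semi-definite
  # frozen trajectory gives the zero matrix
  tr0 <- simulate_trajectory(base, covariance_spec(sigma = 0, seed = 1), 5)
  expect_equal(max(abs(covariance_matrix(tr0, "calpha", superpose = FALSE))), 0)
})

test_that("PCA is internally consistent and finds single-mode motion", {
  one <- atoms_structure(matrix(0, 1, 3), radius = 1.7)
  arr <- array(0, c(50, 1, 3))
  arr[, 1, 1] <- rnorm(50)
  tr <- md_trajectory(one, arr)
  p <- trajectory_pca(tr, "all", superpose = FALSE)
  expect_equal(p$variance_fractions[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-9)
  # projection variance equals the eigenvalue (population convention)
  tr2 <- make_block_traj(n_frames = 300)
  p2 <- trajectory_pca(tr2)
  for (k in 1:2) {
    pv <- mean(p2$projections[, k]^2) - mean(p2$projections[, k])^2
    expect_equal(pv, p2$eigenvalues[k], tolerance = 1e-8)
  }
  expect_error(pca_from_covariance(matrix(1, 2, 3)), "square")
})

test_that("PCA recovers a planted 9:1 two-mode variance ratio", {
  base <- make_ideal_helix(10)
  b <- coords(base)
  n <- 2000
  set.seed(13)
  u <- c(1, 0, 0); v <- c(0, 1, 0)
  arr <- array(NA_real_, c(n, nrow(b), 3))
  z1 <- rnorm(n, sd = 3); z2 <- rnorm(n, sd = 1)
  for (f in seq_len(n)) {
    arr[f, , ] <- b + matrix(z1[f] * u + z2[f] * v, nrow(b), 3, byrow = TRUE)
  }
  p <- trajectory_pca(md_trajectory(base, arr), "calpha", superpose = FALSE)
  ratio <- p$eigenvalues[1] / p$eigenvalues[2]
  expect_lt(abs(ratio - 9) / 9, 0.2)
})

test_that("DCCM reproduces exact limiting cases", {
  base <- make_ideal_helix(6)
  b <- coords(base)
  n <- 100
  set.seed(21)
  shifts <- rnorm(n)
  arr <- array(NA_real_, c(n, nrow(b), 3))
  for (f in seq_len(n)) arr[f, , ] <- b + shifts[f]  # identical motion
  tr <- md_trajectory(base, arr)
  C <- dccm(tr, superpose = FALSE)
  expect_equal(max(abs(unclass(C) - 1)), 0, tolerance = 1e-9)
  # residue pair moving exactly opposite
  arr2 <- array(rep(b, each = n), c(n, nrow(b), 3))
  dx <- rnorm(n)
  a <- base$atoms
  arr2[, which(a$res_index == 1), 1] <- arr2[, which(a$res_index == 1), 1] + dx
  arr2[, which(a$res_index == 2), 1] <- arr2[, which(a$res_index == 2), 1] - dx
  C2 <- suppressWarnings(dccm(md_trajectory(base, arr2), superpose = FALSE))
  expect_equal(C2[1, 2], -1, tolerance = 1e-9)
  # zero-variance residues: warned, zeroed off-diagonal, unit diagonal
  expect_warning(dccm(md_trajectory(base, arr2), superpose = FALSE),
                 "zero displacement")
  expect_equal(C2[3, 4], 0)
  expect_equal(diag(unclass(C2)), rep(1, 6), ignore_attr = TRUE)
})

test_that("DCCM recovers planted correlation blocks and stays bounded", {
  tr <- make_block_traj()
  C <- dccm(tr)
  expect_true(all(abs(unclass(C)) <= 1 + 1e-12))
  expect_equal(unclass(C), t(unclass(C)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(unclass(C)), rep(1, 30), tolerance = 1e-9, ignore_attr = TRUE)
  anti <- C[1:10, 11:20]; pos <- C[21:25, 26:30]
  expect_lt(mean(anti), 0)
  expect_gt(mean(pos), 0)
  expect_gte(mean(anti < 0), 0.95)
  expect_gte(mean(pos > 0), 0.95)
})

test_that("DCCM agrees with the bio3d reference implementation", {
  tr <- make_block_traj(n_res = 12, n_frames = 60)
  idx <- select_atoms(tr, "calpha")
  X <- t(vapply(1:60, function(f) as.numeric(t(frame_coords(tr, f)[idx, ])),
                numeric(36)))
  fit <- bio3d::fit.xyz(fixed = X[1, ], mobile = X,
                        fixed.inds = 1:ncol(X), mobile.inds = 1:ncol(X))
  fit2 <- bio3d::fit.xyz(fixed = colMeans(fit), mobile = fit,
                         fixed.inds = 1:ncol(X), mobile.inds = 1:ncol(X))
  ref <- bio3d::dccm.xyz(fit2)
  ours <- mdhotspot::dccm(tr)
  expect_lt(max(abs(unclass(ours) - unclass(ref))), 1e-9)
})

test_that("DCCM is invariant under frame reordering", {
  tr <- make_block_traj(n_frames = 200)
  set.seed(2)
  perm <- sample(n_frames(tr))
  tr2 <- md_trajectory(tr$topology, tr$coords[perm, , , drop = FALSE])
  # approximate invariance: the superposition reference is frame 1, so
  # reordering perturbs the alignment at a level far below the +/-0.05
  # classification bands
  C1 <- dccm(tr); C2 <- dccm(tr2)
  expect_lt(max(abs(unclass(C1) - unclass(C2))), 5e-3)
})

test_that("DCCM classification follows the strict +/-0.05 rule", {
  Z <- matrix(0, 10, 10)
  expect_equal(unname(classify_dccm(Z)), c(0, 0, 100))
  I10 <- diag(10)
  expect_equal(unname(classify_dccm(I10)), c(10, 0, 90))
  B <- matrix(0, 4, 4); B[1, 2] <- -0.05  # boundary value is neutral
  expect_equal(unname(classify_dccm(B)["pct_anticorrelated"]), 0)
  B[1, 3] <- -0.050001
  expect_equal(unname(classify_dccm(B)["pct_anticorrelated"]), 100 / 16)
  # off-diagonal mode excludes the diagonal from the denominator
  expect_equal(unname(classify_dccm(I10, include_diagonal = FALSE)), c(0, 0, 100))
  p <- classify_dccm(dccm(make_block_traj(n_frames = 100)))
  expect_equal(sum(p), 100, tolerance = 1e-9)
})
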