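# build a minimal donor(N,H)/acceptor(O) structure with a chosen
# D-A distance and D-H...A angle
dha_structure <- function(da, angle_dha) {
  th <- (180 - angle_dha) * pi / 180
  u <- c(cos(th), sin(th), 0)
  tq <- -cos(th) + sqrt(cos(th)^2 - 1 + da^2)
  A <- c(1, 0, 0) + tq * u
  md_structure(data.frame(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    res_name = "GLY", res_id = c(1, 1, 2), chain = "A",
    x = c(0, 1, A[1]), y = c(0, 0, A[2]), z = c(0, 0, A[3]), het = FALSE))
}

test_that("distance and angle cutoffs gate detection as specified", {
  expect_equal(nrow(find_hbonds(dha_structure(2.9, 170))), 1)  # inside both
  expect_equal(nrow(find_hbonds(dha_structure(3.6, 180))), 0)  # distance fails
  expect_equal(nrow(find_hbonds(dha_structure(2.9, 140))), 0)  # 40 deg > 30 deg
  expect_equal(nrow(find_hbonds(dha_structure(2.9, 151))), 1)  # just inside
  # donor-vertex convention: same geometry judged at the donor atom
  crit_d <- hbond_criteria(vertex = "donor")
  expect_equal(nrow(find_hbonds(dha_structure(2.9, 170), criteria = crit_d)), 1)
  expect_error(hbond_criteria(max_angle_deviation = 95), "90")
})

test_that("donor/acceptor typing requires an attached hydrogen", {
  s <- dha_structure(2.9, 170)
  da <- detect_donors_acceptors(s)
  expect_equal(da$donors$donor, 1)
  expect_equal(da$donors$hydrogen, 2)
  expect_equal(da$acceptors, c(1, 3))
  # strip the hydrogen: no donors remain and occupancy warns
  s2 <- md_structure(s$atoms[-2, ])
  expect_equal(nrow(detect_donors_acceptors(s2)$donors), 0)
  tr <- md_trajectory(s2, array(coords(s2), c(1, 2, 3)))
  expect_warning(occupancy_table(tr), "no donors")
})

test_that("count series matches schedule expectations", {
  tr3 <- simulate_hbond_trajectory(hbond_schedule(c(1, 1, 1), seed = 2), 50)
  s3 <- hbond_count_series(tr3)
  expect_equal(unique(s3$values), 3)
  tr0 <- simulate_hbond_trajectory(hbond_schedule(c(0, 0), seed = 2), 50)
  expect_equal(unique(hbond_count_series(tr0)$values), 0)
  trh <- simulate_hbond_trajectory(hbond_schedule(c(0.5, 0.5), seed = 9), 1000)
  sh <- hbond_count_series(trh)
  expect_lt(abs(sh$mean - 1.0), 0.1)
  expect_equal(attr(s3, "min"), 3); expect_equal(attr(s3, "max"), 3)
})

test_that("per-frame counts equal find_hbonds sizes (internal consistency)", {
  tr <- simulate_hbond_trajectory(hbond_schedule(c(0.4, 0.8), seed = 4), 30)
  s <- hbond_count_series(tr)
  per_frame <- vapply(1:30, function(f) {
    nrow(find_hbonds(tr$topology, frame_coords(tr, f)))
  }, integer(1))
  expect_equal(s$values, as.numeric(per_frame))
})

test_that("occupancy is exact for deterministic bond patterns", {
  # start from an always-bonded pair and break it in exactly 750 frames
  tr <- simulate_hbond_trajectory(hbond_schedule(1.0, seed = 1), 1000)
  arr <- tr$coords
  arr[251:1000, 3, 1] <- 6.0; arr[251:1000, 3, 2] <- 0; arr[251:1000, 3, 3] <- 0
  ot <- occupancy_table(md_trajectory(tr$topology, arr))
  expect_equal(ot$atoms$pct, 25.0)
  # occupancy is invariant under frame reordering
  set.seed(8)
  arr2 <- arr[sample(1000), , , drop = FALSE]
  ot2 <- occupancy_table(md_trajectory(tr$topology, arr2))
  expect_equal(ot2$atoms$pct, ot$atoms$pct)
})

test_that("residue-level occupancy sums atom pairs and can exceed 100%", {
  # two independent D-H groups in residue 1 donating to the same O of
  # residue 2, bonded 80% and 78% of 50 frames -> residue level 158%
  th <- (180 - 170) * pi / 180
  u <- c(cos(th), sin(th), 0)
  tq <- -cos(th) + sqrt(cos(th)^2 - 1 + 2.9^2)
  A <- c(1, 0, 0) + tq * u
  at <- data.frame(
    serial = 1:5,
    name = c("N", "H", "ND", "HD", "O"),
    element = c("N", "H", "N", "H", "O"),
    res_name = c("ASN", "ASN", "ASN", "ASN", "GLY"),
    res_id = c(1, 1, 1, 1, 2), chain = "A",
    x = c(0, 1, 0, 1, A[1]), y = c(0, 0, 0, 0, A[2]), z = c(0, 0, 0.02, 0.02, A[3]),
    het = FALSE)
  s <- md_structure(at)
  arr <- array(rep(coords(s), each = 50), c(50, 5, 3))
  # pair 1 (N-H): break in the last 10 frames by moving H away from linearity
  arr[41:50, 2, 3] <- 2.0
  # pair 2 (ND-HD): break in the last 11 frames
  arr[40:50, 4, 3] <- -2.0
  ot <- occupancy_table(md_trajectory(s, arr))
  expect_equal(sort(ot$atoms$pct), c(78, 80))
  expect_equal(ot$residues$pct, 158)
  expect_gte(ot$residues$pct[1], max(ot$atoms$pct))
})

test_that("planted occupancies are recovered within binomial tolerance", {
  sch <- hbond_schedule(c(0.25, 0.5), seed = 31)
  ot <- occupancy_table(simulate_hbond_trajectory(sch, 1000))
  # order atoms by donor residue to match the schedule order
  ord <- order(ot$atoms$donor)
  expect_lt(abs(ot$atoms$pct[ord][1] - 25), 3)
  expect_lt(abs(ot$atoms$pct[ord][2] - 50), 3)
})
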