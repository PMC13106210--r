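# Independent oracles and fixture builders shared across test files.
# Each oracle is a brute-force or closed-form computation kept deliberately
# separate from the package's own code paths.

# Minimum RMSD over rotation space by direct numerical minimisation over
# Euler angles (both point sets centred first; translation optimal at the
# centroid). Multiple starts guard against local minima.
oracle_min_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((X %*% t(rot(ang)) - Y)^2)))
  starts <- rbind(c(0, 0, 0), c(pi / 4, -pi / 4, pi / 4), c(pi, 0, 0),
                  c(0.3, 1.2, -0.7))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
    best <- min(best, o$value)
  }
  best
}

# Reference GROMOS clustering: an independent, naive re-implementation
# using explicit loops (strict < cutoff, ties to the lowest frame index).
oracle_gromos <- function(m, cutoff) {
  n <- nrow(m)
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    best_count <- -1L; best_center <- NA_integer_
    for (i in seq_len(n)) {
      if (!alive[i]) next
      cnt <- 0L
      for (j in seq_len(n)) {
        if (alive[j] && (i == j || m[i, j] < cutoff)) cnt <- cnt + 1L
      }
      if (cnt > best_count) { best_count <- cnt; best_center <- i }
    }
    members <- integer(0)
    for (j in seq_len(n)) {
      if (alive[j] && (j == best_center || m[best_center, j] < cutoff)) {
        members <- c(members, j)
      }
    }
    clusters[[length(clusters) + 1L]] <- list(center = best_center,
                                              members = members)
    alive[members] <- FALSE
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  ord <- order(-sizes, vapply(clusters, function(cl) cl$center, integer(1)))
  clusters[ord]
}

# Closed-form total SASA of two overlapping spheres of extended radii
# R1 = r1 + probe, R2 = r2 + probe at centre distance d: each sphere loses
# a spherical cap of area 2*pi*R*h.
oracle_two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

# Kabsch-Sander H-bond energy computed directly from four atom positions,
# independent of the package's matrix implementation.
oracle_ks_energy <- function(N, H, C, O) {
  d <- function(a, b) max(sqrt(sum((a - b)^2)), 0.5)
  0.084 * 332 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

# Single-atom structure builder for SASA geometry tests.
atoms_structure <- function(xyz, radius, element = "C") {
  n <- nrow(xyz)
  md_structure(data.frame(
    serial = seq_len(n), name = paste0(element, seq_len(n)), element = element,
    res_name = "LIG", res_id = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = TRUE,
    vdw_radius = radius, mass = 12, stringsAsFactors = FALSE))
}

# Trajectory whose frames hop between explicitly constructed conformations
# plus small jitter: planted basin structure for clustering tests.
basin_trajectory <- function(n_basins = 3, n_frames = 30, jitter = 0.05,
                             seed = 4) {
  base <- make_ideal_helix(10)
  b <- coords(base)
  confs <- lapply(seq_len(n_basins) - 1L, function(k) {
    bk <- b; bk[1:12, ] <- bk[1:12, ] + 3 * k; bk
  })
  set.seed(seed)
  arr <- array(NA_real_, c(n_frames, nrow(b), 3))
  for (f in seq_len(n_frames)) {
    arr[f, , ] <- confs[[(f %% n_basins) + 1L]] +
      rnorm(length(b), sd = jitter)
  }
  md_trajectory(base, arr)
}

# A small hand-written PDB fixture (3 residues + a HETATM ligand atom).
write_toy_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.988   2.833   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.504   2.696   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.030   1.585   0.000  1.00  0.00           O",
    "ATOM      9  N   SER B   3       6.189   3.829   0.000  1.00  0.00           N",
    "ATOM     10  CA  SER B   3       7.643   3.840   0.000  1.00  0.00           C",
    "ATOM     11  C   SER B   3       8.212   5.253   0.000  1.00  0.00           C",
    "ATOM     12  O   SER B   3       7.479   6.243   0.000  1.00  0.00           O",
    "HETATM   13  C1  LIG B 900      10.000  10.000  10.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# Interaction-table CSV fixture writer.
write_toy_interactions <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE)
  path
}
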