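#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Accessible area is estimated by sampling points on each atom's
#' probe-expanded sphere (radius r_i + probe) and discarding points that
#' fall inside any neighbour's expanded sphere. Sphere points come from the
#' deterministic golden-spiral construction, so results carry no RNG state.
#'
#' @name sasa
NULL

#' Deterministic near-uniform points on the unit sphere
#' @param n number of points (>= 16 for meaningful SASA estimates).
#' @return n x 3 matrix of unit vectors (golden-spiral construction).
#' @export
golden_sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley SASA of one conformation
#'
#' @param x `md_structure` supplying atoms and vdW radii.
#' @param xyz optional n_atoms x 3 coordinates overriding the structure's
#'   own (used when evaluating trajectory frames).
#' @param probe probe radius, Angstrom (1.4 approximates water).
#' @param n_points sphere sample points per atom (>= 16); accuracy improves
#'   roughly as 1/sqrt(n_points).
#' @param include_hydrogens include H atoms in the calculation; by default
#'   hydrogens are excluded and heavy-atom radii are used as-is.
#' @return List of class `sasa_result`: `per_atom` (Angstrom^2, zero for
#'   excluded atoms), `total` (Angstrom^2), `total_nm2`, `probe_radius`,
#'   `n_points`.
#' @export
shrake_rupley <- function(x, xyz = NULL, probe = 1.4, n_points = 960,
                          include_hydrogens = FALSE) {
  stopifnot(inherits(x, "md_structure"))
  if (n_points < 16L) stop("n_points must be at least 16")
  if (is.null(xyz)) xyz <- coords(x)
  keep <- if (include_hydrogens) rep(TRUE, n_atoms(x)) else x$atoms$element != "H"
  radii <- x$atoms$vdw_radius[keep]
  if (any(!is.finite(radii) | radii <= 0)) {
    bad <- which(!is.finite(radii) | radii <= 0)[1]
    stop("atom ", x$atoms$serial[keep][bad], " (", x$atoms$name[keep][bad],
         ") has no usable vdW radius")
  }
  per <- numeric(n_atoms(x))
  per[keep] <- cpp_sasa(as.matrix(xyz[keep, , drop = FALSE]), radii, probe,
                        golden_sphere_points(n_points))
  structure(list(per_atom = per, total = sum(per), total_nm2 = sum(per) / 100,
                 probe_radius = probe, n_points = n_points),
            class = "sasa_result")
}

#' Per-frame total SASA series
#'
#' @param traj `md_trajectory`.
#' @param probe probe radius, Angstrom.
#' @param n_points sphere points per atom.
#' @param stride evaluate every `stride`-th frame (SASA is the most
#'   expensive per-frame analysis; the sampled series is reported).
#' @param include_hydrogens see [shrake_rupley()].
#' @return `series_summary` in Angstrom^2 (nm^2 fields included), one value
#'   per evaluated frame; attribute `frames` records which frames were used.
#' @export
sasa_series <- function(traj, probe = 1.4, n_points = 960, stride = 1L,
                        include_hydrogens = FALSE) {
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  vals <- vapply(frames, function(f) {
    shrake_rupley(traj$topology, xyz = frame_coords(traj, f), probe = probe,
                  n_points = n_points, include_hydrogens = include_hydrogens)$total
  }, numeric(1))
  out <- series_summary(vals, "angstrom2")
  attr(out, "frames") <- frames
  out
}
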