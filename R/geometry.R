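#' Rigid-body superposition and scalar stability metrics
#'
#' Kabsch least-squares superposition underlies the RMSD, RMSF and
#' clustering analyses. Internally everything is in Angstrom; summaries also
#' carry nm (or nm^2) fields, matching how MD stability metrics are usually
#' reported.
#'
#' @name geometry
NULL

#' Per-frame / per-residue series with mean and standard deviation
#'
#' @param values numeric vector (Angstrom or Angstrom^2 scale).
#' @param unit `"angstrom"` or `"angstrom2"`; controls the nm conversion
#'   (divide by 10 or by 100).
#' @param labels optional element labels (e.g. residue labels).
#' @return Object of class `series_summary` with `values`, `mean`, `sd` and
#'   the nm-scale counterparts `values_nm`, `mean_nm`, `sd_nm`.
#' @export
series_summary <- function(values, unit = c("angstrom", "angstrom2"), labels = NULL) {
  unit <- match.arg(unit)
  div <- if (unit == "angstrom") 10 else 100
  s <- if (length(values) > 1L) stats::sd(values) else 0
  structure(list(values = values, mean = mean(values), sd = s, unit = unit,
                 labels = labels,
                 values_nm = values / div, mean_nm = mean(values) / div,
                 sd_nm = s / div),
            class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  nm_unit <- if (x$unit == "angstrom") "nm" else "nm^2"
  cat(sprintf("series of %d values: (%.4f +/- %.4f) %s\n",
              length(x$values), x$mean_nm, x$sd_nm, nm_unit))
  invisible(x)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired point sets. Reflections are excluded by
#' the usual determinant sign correction, so the rotation always has
#' det = +1.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), n >= 3.
#' @param weights optional non-negative fitting weights, length n.
#' @return List of class `superposition`: `rotation` (3 x 3, applied as
#'   `x %*% t(rotation)`), `translation` (length-3), `rmsd` (Angstrom).
#'   `transform(sup, x)` maps mobile-frame coordinates onto the reference.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be equal-sized n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  mc <- colSums(mobile * w); rc <- colSums(reference * w)
  X <- sweep(mobile, 2, mc); Y <- sweep(reference, 2, rc)
  # collinearity check on the fit set (rank < 2 leaves the rotation underdetermined)
  sx <- svd(X * sqrt(w), nu = 0, nv = 0)$d
  sy <- svd(Y * sqrt(w), nu = 0, nv = 0)$d
  if (sx[2] <= 1e-9 * max(sx[1], 1e-12) || sy[2] <= 1e-9 * max(sy[1], 1e-12)) {
    stop("degenerate geometry: fit points are collinear or coincident")
  }
  H <- crossprod(X * w, Y)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(max(0, sum(w * rowSums((fitted - Y)^2))))
  structure(list(rotation = R, translation = as.numeric(rc - mc %*% t(R)),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup `superposition` from [kabsch_superpose()].
#' @param xyz n x 3 matrix in the mobile frame.
#' @return n x 3 matrix in the reference frame.
#' @export
transform_coords <- function(sup, xyz) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, "+")
}

# Superpose every frame of a trajectory onto reference coordinates, fitting
# on `fit_idx` and returning the whole-atom coordinate array.
#' @noRd
superpose_frames <- function(traj, fit_idx, ref_xyz) {
  arr <- traj$coords
  out <- array(NA_real_, dim = dim(arr))
  for (f in seq_len(dim(arr)[1])) {
    xyz <- matrix(arr[f, , ], ncol = 3L)
    sup <- kabsch_superpose(xyz[fit_idx, , drop = FALSE], ref_xyz)
    out[f, , ] <- transform_coords(sup, xyz)
  }
  out
}

#' Per-frame RMSD series
#'
#' Each frame is superposed (on `selection`, backbone by default) onto the
#' reference frame and the RMSD of the selection is recorded. Lower average
#' RMSD indicates a more conformationally stable system.
#'
#' @param traj `md_trajectory`.
#' @param selection atom selection used both to fit and to measure.
#' @param reference_frame frame index used as the reference (default the
#'   first frame, i.e. deviation from initial positions).
#' @return `series_summary` (Angstrom, with nm fields), one value per frame.
#' @export
rmsd_series <- function(traj, selection = "backbone", reference_frame = 1L) {
  idx <- select_atoms(traj, selection, require_nonempty = TRUE)
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(frame_coords(traj, f)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  series_summary(vals, "angstrom")
}

#' Per-residue RMSF
#'
#' Frames are superposed onto the time-average structure (computed after an
#' initial alignment to the first frame, then refined once), and each
#' selected atom's root-mean-square fluctuation about its mean position is
#' reported. With the default C-alpha selection this is the per-residue
#' flexibility profile.
#'
#' @param traj `md_trajectory`, at least 2 frames.
#' @param selection atom selection (default `"calpha"`).
#' @return `series_summary` over residues/atoms of the selection; `labels`
#'   gives `res_name res_id` per value.
#' @export
rmsf_per_residue <- function(traj, selection = "calpha") {
  if (n_frames(traj) < 2L) stop("RMSF is undefined for a single frame")
  idx <- select_atoms(traj, selection, require_nonempty = TRUE)
  sel <- function(arr, f) matrix(arr[f, , ], ncol = 3L)[idx, , drop = FALSE]
  nf <- n_frames(traj)
  # pass 1: align to frame 1, average; pass 2: align to the average
  ref <- sel(traj$coords, 1L)
  aligned <- array(NA_real_, dim = c(nf, length(idx), 3L))
  for (f in seq_len(nf)) {
    xyz <- sel(traj$coords, f)
    aligned[f, , ] <- transform_coords(kabsch_superpose(xyz, ref), xyz)
  }
  avg <- apply(aligned, c(2, 3), mean)
  for (f in seq_len(nf)) {
    xyz <- matrix(aligned[f, , ], ncol = 3L)
    aligned[f, , ] <- transform_coords(kabsch_superpose(xyz, avg), xyz)
  }
  avg <- apply(aligned, c(2, 3), mean)
  dev2 <- sweep(aligned, c(2, 3), avg)^2
  msf <- apply(dev2, 2, sum) / nf
  at <- traj$topology$atoms[idx, ]
  series_summary(sqrt(msf), "angstrom",
                 labels = paste(at$res_name, at$res_id))
}

#' Radius of gyration series
#'
#' Per-frame (mass-weighted) radius of gyration about the centre of mass,
#' a measure of the compactness of the system.
#'
#' @param traj `md_trajectory`.
#' @param selection atom selection (default all protein atoms).
#' @param mass_weighted weight atoms by mass (default) or uniformly.
#' @return `series_summary` (Angstrom, with nm fields), one value per frame.
#' @export
radius_of_gyration_series <- function(traj, selection = "protein",
                                      mass_weighted = TRUE) {
  idx <- select_atoms(traj, selection, require_nonempty = TRUE)
  m <- if (mass_weighted) traj$topology$atoms$mass[idx] else rep(1, length(idx))
  if (sum(m) <= 0) stop("total mass must be positive")
  w <- m / sum(m)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)[idx, , drop = FALSE]
    com <- colSums(xyz * w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
  }, numeric(1))
  series_summary(vals, "angstrom")
}
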