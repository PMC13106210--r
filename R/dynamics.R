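#' Essential-dynamics PCA and dynamic cross-correlation matrices
#'
#' Collective motions are characterised by (i) eigendecomposition of the
#' positional covariance matrix of the selected atoms (essential dynamics;
#' PC1/PC2 typically capture most of the global motion) and (ii) the DCCM,
#' the matrix of normalised residue-residue displacement correlations in
#' [-1, 1], summarised by the percentage of matrix elements classified as
#' correlated (> +0.05), anti-correlated (< -0.05) or neutral.
#'
#' @name dynamics
NULL

# Selected coordinates of all frames, optionally least-squares superposed
# onto the time-average of the selection (one refinement pass), returned as
# an n_frames x (3 n_sel) matrix (x1 y1 z1 x2 ...).
#' @noRd
selection_frame_matrix <- function(traj, idx, superpose = TRUE) {
  nf <- n_frames(traj)
  sub <- traj$coords[, idx, , drop = FALSE]
  if (superpose) {
    ref <- matrix(sub[1L, , ], ncol = 3L)
    for (f in seq_len(nf)) {
      xyz <- matrix(sub[f, , ], ncol = 3L)
      sub[f, , ] <- transform_coords(kabsch_superpose(xyz, ref), xyz)
    }
    avg <- apply(sub, c(2, 3), mean)
    for (f in seq_len(nf)) {
      xyz <- matrix(sub[f, , ], ncol = 3L)
      sub[f, , ] <- transform_coords(kabsch_superpose(xyz, avg), xyz)
    }
  }
  matrix(aperm(sub, c(1, 3, 2)), nrow = nf)  # columns grouped per atom? see below
}

# NOTE on layout: aperm gives n_frames x (3, n_atoms) flattened with
# coordinate fastest, i.e. columns are x1 y1 z1 x2 y2 z2 ...

#' Positional covariance matrix of a trajectory
#'
#' Frames are superposed onto the average structure of the selection before
#' the covariance of the concatenated coordinates is computed (population
#' covariance, dividing by the number of frames).
#'
#' @param traj `md_trajectory`, at least 2 frames.
#' @param selection atom selection (default `"calpha"`).
#' @param superpose remove global rotation/translation first (default TRUE).
#' @return 3N x 3N positive semi-definite matrix (Angstrom^2), N = number of
#'   selected atoms; coordinate order x1 y1 z1 x2 ...
#' @export
covariance_matrix <- function(traj, selection = "calpha", superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("covariance needs at least 2 frames")
  idx <- select_atoms(traj, selection, require_nonempty = TRUE)
  M <- selection_frame_matrix(traj, idx, superpose = superpose)
  Mc <- sweep(M, 2, colMeans(M))
  crossprod(Mc) / nrow(M)
}

#' Essential-dynamics PCA of a trajectory
#'
#' Diagonalises the positional covariance matrix and projects the centred
#' frames onto the leading eigenvectors.
#'
#' @param traj `md_trajectory`.
#' @param selection atom selection (default `"calpha"`).
#' @param n_components number of projection columns returned (default 2,
#'   i.e. PC1 and PC2).
#' @param superpose remove global motion first (default TRUE).
#' @return List of class `pca_result`: `eigenvalues` (descending,
#'   Angstrom^2, clamped at 0), `variance_fractions` (summing to 1),
#'   `projections` (n_frames x n_components, Angstrom).
#' @export
trajectory_pca <- function(traj, selection = "calpha", n_components = 2L,
                           superpose = TRUE) {
  idx <- select_atoms(traj, selection, require_nonempty = TRUE)
  M <- selection_frame_matrix(traj, idx, superpose = superpose)
  Mc <- sweep(M, 2, colMeans(M))
  C <- crossprod(Mc) / nrow(M)
  pca_from_covariance(C, Mc, n_components = n_components)
}

#' PCA from a precomputed covariance matrix
#'
#' @param cov 3N x 3N covariance matrix from [covariance_matrix()].
#' @param centered_frames optional n_frames x 3N matrix of centred
#'   coordinates to project (same atom/coordinate order as `cov`).
#' @param n_components projection columns (default 2).
#' @return `pca_result` (projections NULL when `centered_frames` is absent).
#' @export
pca_from_covariance <- function(cov, centered_frames = NULL, n_components = 2L) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) stop("covariance matrix must be square")
  e <- eigen(cov, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  proj <- NULL
  if (!is.null(centered_frames)) {
    k <- min(n_components, ncol(cov))
    proj <- as.matrix(centered_frames) %*% e$vectors[, seq_len(k), drop = FALSE]
    colnames(proj) <- paste0("PC", seq_len(k))
  }
  structure(list(eigenvalues = ev,
                 variance_fractions = if (sum(ev) > 0) ev / sum(ev) else ev,
                 projections = proj),
            class = "pca_result")
}

#' Dynamic cross-correlation matrix
#'
#' For each pair of selected atoms (one per residue with the default
#' C-alpha selection), the normalised covariance of their displacement
#' vectors from the time-mean position:
#' C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>).
#' Atoms with zero displacement variance get 0 off-diagonal and 1 on the
#' diagonal, with a warning.
#'
#' @param traj `md_trajectory`, at least 2 frames.
#' @param selection atom selection (default `"calpha"`).
#' @param superpose remove global motion before correlating (default TRUE;
#'   set FALSE to see rigid-body motion as all-positive correlation).
#' @return Object of class `dccm_matrix`: the N x N correlation matrix with
#'   residue labels as dimnames.
#' @export
dccm <- function(traj, selection = "calpha", superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames")
  idx <- select_atoms(traj, selection, require_nonempty = TRUE)
  M <- selection_frame_matrix(traj, idx, superpose = superpose)
  Mc <- sweep(M, 2, colMeans(M))
  n <- length(idx)
  nf <- nrow(Mc)
  # <dr_i . dr_j> summed over the 3 coordinate blocks
  inner <- matrix(0, n, n)
  for (k in 1:3) {
    B <- Mc[, seq(k, 3 * n, by = 3), drop = FALSE]
    inner <- inner + crossprod(B) / nf
  }
  v <- diag(inner)
  zero <- v <= 1e-12
  if (any(zero)) {
    warning(sum(zero), " selected atom(s) have zero displacement variance; ",
            "their correlations are reported as 0", call. = FALSE)
  }
  denom <- sqrt(pmax(v, 1e-300))
  C <- inner / outer(denom, denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  at <- traj$topology$atoms[idx, ]
  dimnames(C) <- list(paste(at$res_name, at$res_id), paste(at$res_name, at$res_id))
  class(C) <- c("dccm_matrix", class(C))
  C
}

#' Classify a DCCM into correlated / anti-correlated / neutral percentages
#'
#' Each matrix element is classified by strict thresholds: correlated when
#' value > +threshold, anti-correlated when value < -threshold, neutral
#' otherwise (boundary values are neutral). Counts are divided by the total
#' number of classified elements and multiplied by 100.
#'
#' @param C correlation matrix (e.g. from [dccm()]).
#' @param threshold classification half-width (default 0.05).
#' @param include_diagonal include the diagonal (all +1) in the
#'   denominators; the default TRUE classifies every matrix element, which
#'   makes the correlated percentage at least N/N^2. Set FALSE to classify
#'   off-diagonal elements only.
#' @return Named numeric vector `pct_correlated`, `pct_anticorrelated`,
#'   `pct_neutral`, summing to 100.
#' @export
classify_dccm <- function(C, threshold = 0.05, include_diagonal = TRUE) {
  C <- unclass(as.matrix(C))
  vals <- if (include_diagonal) as.numeric(C) else C[row(C) != col(C)]
  total <- length(vals)
  pos <- sum(vals > threshold)
  neg <- sum(vals < -threshold)
  c(pct_correlated = 100 * pos / total,
    pct_anticorrelated = 100 * neg / total,
    pct_neutral = 100 * (total - pos - neg) / total)
}
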