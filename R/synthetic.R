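#' Synthetic structures, trajectories and tables with planted ground truth
#'
#' Every analysis stage in the package has a recovery test against data
#' whose answer is known by construction: trajectories with planted
#' residue-residue covariance blocks and flexible regions, H-bond schedules
#' with planted occupancies, interaction tables with planted occurrence
#' counts, and energy tables with planted top contributors. All generators
#' are pure functions of their arguments (including an explicit seed).
#'
#' @name synthetic_data
NULL

# Backbone internal-coordinate templates (lengths in Angstrom, angles deg).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

# Place atom D given positions A, B, C and internal coordinates
# |C-D| = bond, angle(B,C,D) = ang, dihedral(A,B,C,D) = tor (NeRF).
#' @noRd
place_atom <- function(A, B, C, bond, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an N/CA/C/O backbone chain from constant (phi, psi) torsions.
#' @noRd
build_backbone <- function(n_res, phi, psi) {
  g <- .bb_geom
  pos <- list()  # per residue: N, CA, C
  # seed residue placed explicitly
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  a <- g$ang_n_ca_c * pi / 180
  C1 <- CA1 + g$ca_c * c(-cos(a), sin(a), 0)
  pos[[1]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n_res)[-1]) {
    p <- pos[[i - 1]]
    N <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi)
    CA <- place_atom(p$CA, p$C, N, g$n_ca, g$ang_c_n_ca, g$omega)
    C <- place_atom(p$C, N, CA, g$ca_c, g$ang_n_ca_c, phi)
    pos[[i]] <- list(N = N, CA = CA, C = C)
  }
  # carbonyl O: in the peptide plane, anti to the next N (psi + 180 about CA-C)
  rows <- list(); k <- 0L
  for (i in seq_len(n_res)) {
    p <- pos[[i]]
    O <- place_atom(p$N, p$CA, p$C, .bb_geom$c_o, .bb_geom$ang_ca_c_o, psi + 180)
    add <- function(name, xyz, elem) {
      k <<- k + 1L
      rows[[k]] <<- data.frame(serial = k, name = name, element = elem,
                               res_name = "ALA", res_id = i, chain = "A",
                               x = xyz[1], y = xyz[2], z = xyz[3], het = FALSE,
                               stringsAsFactors = FALSE)
    }
    add("N", p$N, "N"); add("CA", p$CA, "C"); add("C", p$C, "C"); add("O", O, "O")
  }
  md_structure(do.call(rbind, rows))
}

#' Ideal alpha-helix backbone fixture
#'
#' Builds an N/CA/C/O poly-alanine backbone with canonical helical torsions
#' (phi = -57, psi = -47 degrees; ~1.5 Angstrom rise and ~100 degree twist
#' per residue), so that interior residues form the i -> i+4
#' carbonyl-amide hydrogen bonds that a DSSP-style assigner labels H.
#' Deterministic: no randomness is involved.
#'
#' @param n_res number of residues, at least 6 (shorter chains cannot form
#'   the i, i+4 pattern).
#' @return `md_structure`.
#' @export
make_ideal_helix <- function(n_res) {
  if (n_res < 6L) stop("an alpha-helix fixture needs n_res >= 6")
  build_backbone(n_res, phi = -57, psi = -47)
}

#' Fully extended backbone fixture
#'
#' Poly-alanine backbone with phi = psi = 180 degrees: a straight chain
#' with no backbone hydrogen bonds, the negative control for
#' secondary-structure assignment.
#'
#' @param n_res number of residues, at least 2.
#' @return `md_structure`.
#' @export
make_extended_chain <- function(n_res) {
  if (n_res < 2L) stop("need n_res >= 2")
  build_backbone(n_res, phi = 180, psi = 180)
}

#' Planted covariance specification for trajectory simulation
#'
#' Each block plants a correlated (+1) or anti-correlated (-1) relationship
#' between two residue ranges: all residues of both ranges share one latent
#' 3-D Gaussian factor per frame, with loading +1 on the first range and
#' `sign` on the second, mixed with independent per-residue noise. A
#' residue may appear in at most one block side.
#'
#' @param blocks list of `list(i = range, j = range, sign = +1 or -1)`.
#' @param sigma per-residue displacement scale (Angstrom per coordinate);
#'   scalar or one value per residue.
#' @param latent_weight fraction of displacement variance carried by the
#'   shared factor (controls how strong the planted correlation is).
#' @param seed integer RNG seed.
#' @return Object of class `covariance_spec`.
#' @export
covariance_spec <- function(blocks = list(), sigma = 0.5, latent_weight = 0.6,
                            seed = 1L) {
  stopifnot(latent_weight >= 0, latent_weight <= 1, all(sigma >= 0))
  for (b in blocks) {
    if (!all(c("i", "j", "sign") %in% names(b)) || !b$sign %in% c(-1, 1)) {
      stop("each block needs residue ranges i, j and sign +1/-1")
    }
  }
  members <- unlist(lapply(blocks, function(b) c(b$i, b$j)))
  if (anyDuplicated(members)) stop("a residue may belong to at most one block side")
  structure(list(blocks = blocks, sigma = sigma, latent_weight = latent_weight,
                 seed = as.integer(seed)),
            class = "covariance_spec")
}

#' Simulate a trajectory with planted residue covariance
#'
#' Frame t is the base structure plus Gaussian displacements applied
#' rigidly per residue (all atoms of a residue move together, so C-alpha
#' correlations equal all-atom correlations by construction). Residues
#' inside a planted block share a latent factor whose sign realises the
#' planted correlation; all other variation is independent noise of scale
#' `sigma`.
#'
#' @param x base `md_structure`.
#' @param spec `covariance_spec`.
#' @param n_frames number of frames, at least 2.
#' @param timestep ps between frames (metadata).
#' @return `md_trajectory`, deterministic given `spec$seed`.
#' @export
simulate_trajectory <- function(x, spec, n_frames, timestep = 10) {
  stopifnot(inherits(x, "md_structure"), inherits(spec, "covariance_spec"))
  if (n_frames < 2L) stop("need n_frames >= 2")
  nres <- n_residues(x)
  members <- unlist(lapply(spec$blocks, function(b) c(b$i, b$j)))
  if (length(members) && (min(members) < 1L || max(members) > nres)) {
    stop("block residue ranges fall outside the protein (1..", nres, ")")
  }
  sigma <- if (length(spec$sigma) == 1L) rep(spec$sigma, nres) else spec$sigma
  if (length(sigma) != nres) stop("sigma must be scalar or one value per residue")
  loading <- rep(0, nres); block_id <- rep(NA_integer_, nres)
  for (k in seq_along(spec$blocks)) {
    b <- spec$blocks[[k]]
    loading[b$i] <- 1; loading[b$j] <- b$sign
    block_id[c(b$i, b$j)] <- k
  }
  w <- spec$latent_weight
  base <- coords(x)
  res_of <- x$atoms$res_index
  arr <- array(NA_real_, dim = c(n_frames, n_atoms(x), 3L))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  nb <- length(spec$blocks)
  for (f in seq_len(n_frames)) {
    latent <- if (nb) matrix(rnorm(3L * nb), nb, 3L) else matrix(0, 0, 3L)
    noise <- matrix(rnorm(3L * nres), nres, 3L)
    disp <- sqrt(1 - ifelse(is.na(block_id), 0, w)) * noise
    if (nb) {
      shared <- latent[ifelse(is.na(block_id), 1L, block_id), , drop = FALSE]
      disp <- disp + ifelse(is.na(block_id), 0, sqrt(w)) * loading * shared
    }
    disp <- disp * sigma
    arr[f, , ] <- base + disp[res_of, , drop = FALSE]
  }
  restore_seed(old)
  md_trajectory(x, arr, timestep = timestep)
}

#' @noRd
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Hydrogen-bond schedule with planted occupancies
#'
#' Describes independent donor-hydrogen-acceptor triples, each of which is
#' bonded (donor-acceptor 2.9 Angstrom, D-H...A angle 170 degrees) in a
#' random `occupancy` fraction of frames and broken (donor-acceptor
#' 6.0 Angstrom) otherwise.
#'
#' @param occupancy numeric vector of target occupancy fractions in [0, 1],
#'   one per scheduled triple.
#' @param seed integer RNG seed.
#' @return Object of class `hbond_schedule`.
#' @export
hbond_schedule <- function(occupancy, seed = 1L) {
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must be in [0, 1]")
  structure(list(occupancy = occupancy, seed = as.integer(seed),
                 bonded_da = 2.9, bonded_angle = 170, broken_da = 6.0),
            class = "hbond_schedule")
}

#' Simulate a trajectory realising an H-bond schedule
#'
#' Builds one donor residue (amide N with explicit H) and one carbonyl-O
#' acceptor residue per scheduled triple, pairs spaced 50 Angstrom apart so
#' they cannot cross-interact, and draws each frame's bonded/broken state
#' independently with the planted probability.
#'
#' @param schedule `hbond_schedule`.
#' @param n_frames number of frames.
#' @return `md_trajectory`, deterministic given `schedule$seed`.
#' @export
simulate_hbond_trajectory <- function(schedule, n_frames) {
  stopifnot(inherits(schedule, "hbond_schedule"))
  np <- length(schedule$occupancy)
  if (np < 1L) stop("schedule is empty")
  # geometry of the bonded state: D at origin, H at (1,0,0), A in the xy
  # plane with angle(D,H,A) = bonded_angle and |D-A| = bonded_da
  th <- (180 - schedule$bonded_angle) * pi / 180
  u <- c(cos(th), sin(th), 0)
  tq <- -cos(th) + sqrt(cos(th)^2 - 1 + schedule$bonded_da^2)
  A_on <- c(1, 0, 0) + tq * u
  A_off <- c(schedule$broken_da, 0, 0)
  rows <- list()
  for (k in seq_len(np)) {
    off <- c(0, 50 * (k - 1), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      serial = 3L * k - 2L + c(0L, 1L, 2L),
      name = c("N", "H", "O"), element = c("N", "H", "O"),
      res_name = c("GLY", "GLY", "GLY"),
      res_id = c(2L * k - 1L, 2L * k - 1L, 2L * k),
      chain = "A",
      x = c(0, 1, A_on[1]) + off[1],
      y = c(0, 0, A_on[2]) + off[2],
      z = c(0, 0, A_on[3]) + off[3],
      het = FALSE, stringsAsFactors = FALSE)
  }
  topo <- md_structure(do.call(rbind, rows))
  base <- coords(topo)
  arr <- array(rep(base, each = n_frames), dim = c(n_frames, n_atoms(topo), 3L))
  old <- .Random.seed_exists()
  set.seed(schedule$seed)
  for (k in seq_len(np)) {
    bonded <- runif(n_frames) < schedule$occupancy[k]
    acc <- 3L * k  # acceptor O atom index
    off_y <- 50 * (k - 1)
    arr[!bonded, acc, 1] <- A_off[1]
    arr[!bonded, acc, 2] <- A_off[2] + off_y
    arr[!bonded, acc, 3] <- A_off[3]
    arr[bonded, acc, 1] <- A_on[1]
    arr[bonded, acc, 2] <- A_on[2] + off_y
    arr[bonded, acc, 3] <- A_on[3]
  }
  restore_seed(old)
  md_trajectory(topo, arr, timestep = 1)
}

#' Specification for planted interaction / energy tables
#'
#' @param n_ligands size of the ligand universe.
#' @param residues data.frame with columns `chain`, `res_id`, `res_name`
#'   (the residue universe).
#' @param occurrence planted occurrence count per residue (number of
#'   distinct ligands interacting with it); each must be `<= n_ligands`.
#' @param energy planted per-residue energy contribution (kcal/mol).
#' @param seed integer RNG seed (controls which ligands are assigned and
#'   which interaction classes decorate each row).
#' @return Object of class `table_spec`.
#' @export
table_spec <- function(n_ligands, residues, occurrence, energy = NULL, seed = 1L) {
  stopifnot(nrow(residues) == length(occurrence))
  if (any(occurrence < 0L) || any(occurrence > n_ligands)) {
    stop("planted occurrence counts must be between 0 and n_ligands")
  }
  if (!is.null(energy) && length(energy) != nrow(residues)) {
    stop("energy must have one value per residue")
  }
  structure(list(n_ligands = as.integer(n_ligands), residues = residues,
                 occurrence = as.integer(occurrence), energy = energy,
                 seed = as.integer(seed)),
            class = "table_spec")
}

#' Interaction table with planted occurrence counts
#'
#' For each residue, `occurrence[r]` distinct ligands are drawn and given
#' one or more interaction rows (a random subset of ligands receives a
#' second interaction class, exercising the distinct-ligand counting rule).
#' Re-counting occurrences from the table recovers the planted values
#' exactly; residues planted at 0 are absent.
#'
#' @param spec `table_spec`.
#' @return `interaction_table` with attribute `n_ligands`.
#' @export
make_interaction_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  ligands <- sprintf("LIG%02d", seq_len(spec$n_ligands))
  out <- list()
  for (r in seq_len(nrow(spec$residues))) {
    cnt <- spec$occurrence[r]
    if (cnt == 0L) next
    chosen <- sort(sample(spec$n_ligands, cnt))
    for (lg in chosen) {
      classes <- sample(.interaction_classes, 1L + (runif(1) < 0.3))
      out[[length(out) + 1L]] <- data.frame(
        ligand_id = ligands[lg],
        chain = spec$residues$chain[r],
        res_id = spec$residues$res_id[r],
        res_name = spec$residues$res_name[r],
        interaction_class = unique(classes),
        stringsAsFactors = FALSE)
    }
  }
  restore_seed(old)
  if (!length(out)) {
    df <- data.frame(ligand_id = character(), chain = character(),
                     res_id = integer(), res_name = character(),
                     interaction_class = character(), stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, out)
  }
  as_interaction_table(df, n_ligands = spec$n_ligands)
}

#' Energy decomposition table with planted contributions
#'
#' One row per residue with the planted energy, so that ranking by most
#' favourable (lowest) energy recovers the planted order exactly.
#'
#' @param spec `table_spec` with non-NULL `energy`.
#' @param complex_id complex label for all rows.
#' @return `energy_table`.
#' @export
make_energy_table <- function(spec, complex_id = "complex1") {
  stopifnot(inherits(spec, "table_spec"))
  if (is.null(spec$energy)) stop("table_spec has no planted energies")
  df <- data.frame(complex_id = complex_id,
                   chain = spec$residues$chain,
                   res_id = spec$residues$res_id,
                   res_name = spec$residues$res_name,
                   energy_kcal_mol = spec$energy,
                   stringsAsFactors = FALSE)
  class(df) <- c("energy_table", "data.frame")
  df
}
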