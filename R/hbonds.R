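#' Geometric hydrogen-bond detection and percentage occupancy
#'
#' A hydrogen bond is recorded when the donor-acceptor distance is within
#' `max_da_distance` (3.5 Angstrom by default) and the D-H...A arrangement
#' deviates from linearity by at most `max_angle_deviation` (30 degrees by
#' default, i.e. angle(D, H, A) >= 150 degrees). The deviation can
#' alternatively be measured at the donor vertex (angle(H, D, A) <= 30
#' degrees) via `vertex = "donor"`.
#'
#' Occupancy is the percentage of frames in which a given bond is present.
#' Atom-level occupancies lie in [0, 100]; residue-level occupancies are
#' the *sum* of the atom-level occupancies between the two residues and may
#' therefore exceed 100% when several distinct atom pairs (or main-chain
#' and side-chain contacts) bond between the same residue pair.
#'
#' @name hbonds
NULL

#' Hydrogen-bond detection criteria
#'
#' @param max_da_distance maximum donor-acceptor distance, Angstrom.
#' @param max_angle_deviation maximum deviation from linearity, degrees
#'   (must be in (0, 90)).
#' @param vertex `"hydrogen"` measures angle(D, H, A) against
#'   180 - deviation; `"donor"` measures angle(H, D, A) against the
#'   deviation itself.
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_angle_deviation = 30,
                           vertex = c("hydrogen", "donor")) {
  stopifnot(max_da_distance > 0,
            max_angle_deviation > 0, max_angle_deviation < 90)
  structure(list(max_da_distance = max_da_distance,
                 max_angle_deviation = max_angle_deviation,
                 vertex = match.arg(vertex)),
            class = "hbond_criteria")
}

#' Detect donors and acceptors of a structure
#'
#' Donors are N/O atoms with at least one hydrogen within the covalent
#' bonding distance (1.2 Angstrom, measured on the topology coordinates);
#' acceptors are all N/O atoms. Donors without any attached hydrogen are
#' skipped (with a warning from the detection functions when requested).
#'
#' @param x `md_structure`.
#' @return List with `donors` (data.frame `donor`, `hydrogen` atom indices;
#'   one row per D-H pair) and `acceptors` (atom indices).
#' @export
detect_donors_acceptors <- function(x) {
  stopifnot(inherits(x, "md_structure"))
  a <- x$atoms
  xyz <- coords(x)
  no <- which(a$element %in% c("N", "O"))
  hyd <- which(a$element == "H")
  pairs <- NULL
  if (length(hyd) && length(no)) {
    for (h in hyd) {
      d2 <- rowSums(sweep(xyz[no, , drop = FALSE], 2, xyz[h, ])^2)
      j <- which.min(d2)
      if (d2[j] <= 1.2^2) pairs <- rbind(pairs, c(no[j], h))
    }
  }
  donors <- if (is.null(pairs)) {
    data.frame(donor = integer(), hydrogen = integer())
  } else {
    data.frame(donor = pairs[, 1], hydrogen = pairs[, 2])
  }
  list(donors = donors[order(donors$donor, donors$hydrogen), , drop = FALSE],
       acceptors = no)
}

# Candidate donor-acceptor pair table (excludes same-residue pairs and the
# donor atom itself as acceptor); reused across frames.
#' @noRd
hbond_candidates <- function(x, donors, acceptors) {
  nd <- nrow(donors)
  na_ <- length(acceptors)
  if (nd == 0L || na_ == 0L) {
    return(data.frame(donor = integer(), hydrogen = integer(), acceptor = integer()))
  }
  g <- expand.grid(d = seq_len(nd), a = seq_len(na_))
  out <- data.frame(donor = donors$donor[g$d], hydrogen = donors$hydrogen[g$d],
                    acceptor = acceptors[g$a])
  res <- x$atoms$res_index
  out[res[out$donor] != res[out$acceptor] & out$donor != out$acceptor, ,
      drop = FALSE]
}

#' @noRd
hbond_frame_mask <- function(cand, xyz, criteria) {
  if (nrow(cand) == 0L) return(logical(0))
  D <- xyz[cand$donor, , drop = FALSE]
  A <- xyz[cand$acceptor, , drop = FALSE]
  Hh <- xyz[cand$hydrogen, , drop = FALSE]
  d2 <- rowSums((D - A)^2)
  ok <- d2 <= criteria$max_da_distance^2
  if (any(ok)) {
    ang <- function(P, Q, R) {  # angle at Q, degrees
      u <- P - Q; v <- R - Q
      cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
      acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    io <- which(ok)
    if (criteria$vertex == "hydrogen") {
      dev <- 180 - ang(D[io, , drop = FALSE], Hh[io, , drop = FALSE],
                       A[io, , drop = FALSE])
    } else {
      dev <- ang(Hh[io, , drop = FALSE], D[io, , drop = FALSE],
                 A[io, , drop = FALSE])
    }
    ok[io] <- dev <= criteria$max_angle_deviation
  }
  ok
}

#' Hydrogen bonds of one conformation
#'
#' @param x `md_structure`.
#' @param xyz optional coordinates overriding the structure's own.
#' @param donors optional data.frame (`donor`, `hydrogen` atom indices);
#'   auto-detected when NULL.
#' @param acceptors optional acceptor atom indices; auto-detected when NULL.
#' @param criteria `hbond_criteria`.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), one row per bond.
#' @export
find_hbonds <- function(x, xyz = NULL, donors = NULL, acceptors = NULL,
                        criteria = hbond_criteria()) {
  stopifnot(inherits(x, "md_structure"), inherits(criteria, "hbond_criteria"))
  if (is.null(xyz)) xyz <- coords(x)
  if (is.null(donors) || is.null(acceptors)) {
    da <- detect_donors_acceptors(x)
    if (is.null(donors)) donors <- da$donors
    if (is.null(acceptors)) acceptors <- da$acceptors
  }
  cand <- hbond_candidates(x, donors, acceptors)
  cand[hbond_frame_mask(cand, xyz, criteria), , drop = FALSE]
}

#' Per-frame hydrogen-bond count series
#'
#' @param traj `md_trajectory`.
#' @inheritParams find_hbonds
#' @return `series_summary` of per-frame counts (unit-less; the nm fields
#'   are not meaningful here) with attributes `min` and `max` giving the
#'   observed range, the conventional "(min-max)" report.
#' @export
hbond_count_series <- function(traj, donors = NULL, acceptors = NULL,
                               criteria = hbond_criteria()) {
  x <- traj$topology
  if (is.null(donors) || is.null(acceptors)) {
    da <- detect_donors_acceptors(x)
    if (is.null(donors)) donors <- da$donors
    if (is.null(acceptors)) acceptors <- da$acceptors
  }
  cand <- hbond_candidates(x, donors, acceptors)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    sum(hbond_frame_mask(cand, frame_coords(traj, f), criteria))
  }, numeric(1))
  out <- series_summary(vals, "angstrom")
  attr(out, "min") <- min(vals)
  attr(out, "max") <- max(vals)
  out
}

#' Hydrogen-bond percentage occupancy over a trajectory
#'
#' @param traj `md_trajectory`.
#' @inheritParams find_hbonds
#' @return List of class `occupancy_table`: `atoms` (data.frame: donor /
#'   acceptor atom indices and labels, `pct` in [0, 100]) and `residues`
#'   (data.frame: donor / acceptor residue labels and `pct` = sum of the
#'   atom-level percentages, which may exceed 100). Both sorted by
#'   decreasing occupancy; zero-occupancy pairs are omitted.
#' @export
occupancy_table <- function(traj, donors = NULL, acceptors = NULL,
                            criteria = hbond_criteria()) {
  x <- traj$topology
  if (is.null(donors) || is.null(acceptors)) {
    da <- detect_donors_acceptors(x)
    if (is.null(donors)) donors <- da$donors
    if (is.null(acceptors)) acceptors <- da$acceptors
  }
  if (nrow(donors) == 0L) warning("no donors with attached hydrogens found",
                                  call. = FALSE)
  cand <- hbond_candidates(x, donors, acceptors)
  nf <- n_frames(traj)
  counts <- numeric(nrow(cand))
  frame_counts <- integer(nf)
  for (f in seq_len(nf)) {
    m <- hbond_frame_mask(cand, frame_coords(traj, f), criteria)
    counts <- counts + m
    frame_counts[f] <- sum(m)
  }
  # collapse multiple hydrogens of one donor onto the donor-acceptor atom pair
  pair_key <- paste(cand$donor, cand$acceptor)
  agg <- rowsum(counts, pair_key)
  first <- !duplicated(pair_key)
  ord0 <- match(rownames(agg), pair_key[first])
  dat <- cand[first, , drop = FALSE][ord0, , drop = FALSE]
  pct <- pmin(100 * as.numeric(agg) / nf, 100)
  a <- x$atoms
  lab <- function(i) sprintf("%s%d@%s", residue_label_vec(a$res_name[i]),
                             a$res_id[i], a$name[i])
  atoms <- data.frame(donor = dat$donor, acceptor = dat$acceptor,
                      donor_label = lab(dat$donor),
                      acceptor_label = lab(dat$acceptor),
                      pct = pct, stringsAsFactors = FALSE)
  atoms <- atoms[atoms$pct > 0, , drop = FALSE]
  atoms <- atoms[order(-atoms$pct, atoms$donor, atoms$acceptor), , drop = FALSE]
  rownames(atoms) <- NULL
  dres <- a$res_index[atoms$donor]; ares <- a$res_index[atoms$acceptor]
  rkey <- paste(dres, ares)
  ragg <- rowsum(atoms$pct, rkey)
  rfirst <- !duplicated(rkey)
  rmap <- match(rownames(ragg), rkey[rfirst])
  rlab <- function(i) sprintf("%s%d", residue_label_vec(x$residues$res_name[i]),
                              x$residues$res_id[i])
  residues <- data.frame(donor_res = rlab(dres[rfirst][rmap]),
                         acceptor_res = rlab(ares[rfirst][rmap]),
                         pct = as.numeric(ragg), stringsAsFactors = FALSE)
  residues <- residues[order(-residues$pct), , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues, n_frames = nf,
                 criteria = criteria),
            frame_counts = frame_counts,
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("H-bond occupancy over", x$n_frames, "frames;",
      nrow(x$atoms), "atom pair(s),", nrow(x$residues), "residue pair(s)\n")
  if (nrow(x$residues)) {
    top <- utils::head(x$residues, 5L)
    for (k in seq_len(nrow(top))) {
      cat(sprintf("  %s -> %s (%.2f%%)\n", top$donor_res[k],
                  top$acceptor_res[k], top$pct[k]))
    }
  }
  invisible(x)
}

#' @noRd
residue_label_vec <- function(res_name) {
  paste0(toupper(substr(res_name, 1, 1)), tolower(substring(res_name, 2)))
}

#' Add constructed amide hydrogens to a backbone trajectory
#'
#' Most deposited structures and all backbone-only fixtures lack amide
#' hydrogens, which geometric H-bond detection needs. This appends one H
#' atom per eligible residue (not the first of a segment, not proline,
#' complete N/CA/C backbone), positioned per frame 1.0 Angstrom from N
#' along the bisector of the N-C(prev) and N-CA directions -- the same
#' construction the secondary-structure module uses. Original atom indices
#' are unchanged; hydrogens are appended after the existing atoms.
#'
#' @param traj `md_trajectory`.
#' @return `md_trajectory` with explicit amide hydrogens. Returns the
#'   input unchanged if every eligible donor already has a hydrogen.
#' @export
protonate_backbone <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  x <- traj$topology
  a <- x$atoms
  ctx <- ss_context(x, frame_coords(traj, 1L))
  elig <- which(ctx$constructible)
  if (!length(elig)) return(traj)
  nf <- n_frames(traj)
  newH <- array(NA_real_, dim = c(nf, length(elig), 3L))
  for (f in seq_len(nf)) {
    H <- amide_h_coords(ctx, frame_coords(traj, f))
    newH[f, , ] <- H[elig, , drop = FALSE]
  }
  hrows <- data.frame(serial = max(a$serial) + seq_along(elig),
                      name = "H", element = "H",
                      res_name = x$residues$res_name[elig],
                      res_id = x$residues$res_id[elig],
                      chain = x$residues$chain[elig],
                      x = newH[1, , 1], y = newH[1, , 2], z = newH[1, , 3],
                      het = FALSE, stringsAsFactors = FALSE)
  topo <- md_structure(rbind(a[, names(hrows)], hrows))
  arr <- array(NA_real_, dim = c(nf, n_atoms(topo), 3L))
  arr[, seq_len(nrow(a)), ] <- traj$coords
  arr[, nrow(a) + seq_along(elig), ] <- newH
  md_trajectory(topo, arr, timestep = traj$timestep)
}
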