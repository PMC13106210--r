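#' DSSP-style secondary-structure assignment and structured-residue summary
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
#' energy E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol,
#' a bond existing when E < -0.5 kcal/mol. From the bond pattern, residues
#' are labelled with a seven-class alphabet: H (alpha-helix), G (3-10
#' helix), E (extended strand), B (isolated beta-bridge), T (turn),
#' S (bend), C (coil), with precedence H > E > G > B > T > S > C.
#' Structured residues are all classes except coil.
#'
#' Amide hydrogens are constructed geometrically when absent: H is placed
#' 1.0 Angstrom from N along the bisector of the N-C(prev) and N-CA
#' directions, pointing away from the preceding carbonyl -- the standard
#' reconstruction for structures stripped of hydrogens.
#'
#' @name secstruct
NULL

.ss_energy_cutoff <- -0.5   # kcal/mol, Kabsch-Sander bond criterion
.ss_bend_angle <- 70        # degrees, bend (S) threshold over CA(i-2), CA(i), CA(i+2)
.ss_structured <- c("H", "G", "E", "B", "T", "S")

# Backbone bookkeeping: per residue the atom indices of N, CA, C, O, plus
# segment ids (split at chains and at C(i)-N(i+1) distances > 2.5 A).
#' @noRd
backbone_index <- function(x) {
  a <- x$atoms
  nres <- n_residues(x)
  idx <- matrix(NA_integer_, nres, 4, dimnames = list(NULL, c("N", "CA", "C", "O")))
  prot <- which(!a$het)
  for (nm in colnames(idx)) {
    hit <- prot[a$name[prot] == nm]
    idx[a$res_index[hit], nm] <- hit
  }
  complete <- rowSums(is.na(idx)) == 0L
  if (!all(complete)) {
    warning(sum(!complete), " residue(s) lack a complete N/CA/C/O backbone ",
            "and are treated as coil", call. = FALSE)
  }
  list(idx = idx, complete = complete)
}

#' @noRd
backbone_segments <- function(x, xyz, bb) {
  nres <- n_residues(x)
  brk <- rep(TRUE, nres)
  if (nres > 1L) {
    i <- 2:nres
    ok <- bb$complete[i] & bb$complete[i - 1L] &
      x$residues$chain[i] == x$residues$chain[i - 1L]
    gap <- rep(Inf, nres - 1L)
    w <- which(ok)
    if (length(w)) {
      d <- xyz[bb$idx[w + 1L, "N"], , drop = FALSE] -
           xyz[bb$idx[w, "C"], , drop = FALSE]
      gap[w] <- sqrt(rowSums(d^2))
    }
    brk[i] <- gap > 2.5
  }
  cumsum(brk)
}

# Per-trajectory invariants reused by every frame's assignment.
#' @noRd
ss_context <- function(x, xyz1) {
  bb <- backbone_index(x)
  seg <- backbone_segments(x, xyz1, bb)
  nres <- n_residues(x)
  a <- x$atoms
  has_expl_h <- integer(nres) * NA_integer_
  for (i in seq_len(nres)) {
    hi <- which(!a$het & a$res_index == i & a$name == "H")
    if (length(hi)) has_expl_h[i] <- hi[1]
  }
  prev_same <- c(FALSE, seg[-1] == seg[-nres])
  constructible <- bb$complete & is.na(has_expl_h) &
    x$residues$res_name != "PRO" & prev_same
  donor_ok <- bb$complete & (!is.na(has_expl_h) | constructible)
  near <- abs(outer(seq_len(nres), seq_len(nres), "-")) < 2
  same_seg <- outer(seg, seg, "==")
  list(bb = bb, seg = seg, nres = nres, expl_h = has_expl_h,
       constructible = constructible, donor_ok = donor_ok,
       allowed = !near & same_seg)
}

# Amide H coordinates for all residues (NA where undefined).
#' @noRd
amide_h_coords <- function(ctx, xyz) {
  nres <- ctx$nres
  H <- matrix(NA_real_, nres, 3)
  e <- which(!is.na(ctx$expl_h))
  if (length(e)) H[e, ] <- xyz[ctx$expl_h[e], , drop = FALSE]
  cns <- which(ctx$constructible)
  if (length(cns)) {
    N <- xyz[ctx$bb$idx[cns, "N"], , drop = FALSE]
    Cp <- xyz[ctx$bb$idx[cns - 1L, "C"], , drop = FALSE]
    CA <- xyz[ctx$bb$idx[cns, "CA"], , drop = FALSE]
    u <- N - Cp; u <- u / sqrt(rowSums(u^2))
    v <- N - CA; v <- v / sqrt(rowSums(v^2))
    d <- u + v
    nd <- sqrt(rowSums(d^2))
    good <- nd > 1e-6
    H[cns[good], ] <- N[good, , drop = FALSE] + d[good, , drop = FALSE] / nd[good]
  }
  H
}

# Kabsch-Sander energy matrix: E[i, j] is the energy of the bond donated by
# the N-H of residue i to the C=O of residue j; +Inf where not evaluable
# (|i - j| < 2, different segments, missing atoms).
#' @noRd
ks_energy_matrix <- function(ctx, xyz, H) {
  nres <- ctx$nres
  E <- matrix(Inf, nres, nres)
  don <- which(ctx$donor_ok & !is.na(H[, 1]))
  acc <- which(ctx$bb$complete)
  if (!length(don) || !length(acc)) return(E)
  Nd <- xyz[ctx$bb$idx[don, "N"], , drop = FALSE]
  Hd <- H[don, , drop = FALSE]
  Ca <- xyz[ctx$bb$idx[acc, "C"], , drop = FALSE]
  Oa <- xyz[ctx$bb$idx[acc, "O"], , drop = FALSE]
  cd <- function(A, B) {  # cross-distances, floored to avoid 1/r blow-ups
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    pmax(sqrt(pmax(d2, 0)), 0.5)
  }
  Em <- 27.888 * (1 / cd(Oa, Nd) + 1 / cd(Ca, Hd) - 1 / cd(Oa, Hd) - 1 / cd(Ca, Nd))
  E[don, acc] <- t(Em)  # Em is acceptors x donors
  E[!ctx$allowed] <- Inf
  E
}

#' Backbone hydrogen-bond energies of one conformation
#'
#' @param x `md_structure` with complete N/CA/C/O backbones.
#' @param xyz optional coordinates overriding the structure's own.
#' @return n_res x n_res matrix; entry (i, j) is the Kabsch-Sander energy
#'   (kcal/mol) of the bond donated by residue i's amide N-H to residue j's
#'   carbonyl C=O (+Inf where not evaluable). A bond exists where the
#'   energy is below -0.5 kcal/mol.
#' @export
backbone_hbond_energy <- function(x, xyz = NULL) {
  stopifnot(inherits(x, "md_structure"))
  if (is.null(xyz)) xyz <- coords(x)
  ctx <- ss_context(x, xyz)
  ks_energy_matrix(ctx, xyz, amide_h_coords(ctx, xyz))
}

# logical-matrix index shifts: sh(M, di, dj)[i, j] = M[i + di, j + dj]
#' @noRd
shift_mat <- function(M, di, dj) {
  n <- nrow(M)
  out <- matrix(FALSE, n, n)
  si <- seq_len(n) + di; sj <- seq_len(n) + dj
  oki <- si >= 1L & si <= n; okj <- sj >= 1L & sj <= n
  out[oki, okj] <- M[si[oki], sj[okj], drop = FALSE]
  out
}

#' @noRd
shift_vec <- function(v, d) {
  n <- length(v)
  out <- rep(FALSE, n)
  s <- seq_len(n) + d
  ok <- s >= 1L & s <= n
  out[ok] <- v[s[ok]]
  out
}

#' @noRd
assign_ss_frame <- function(ctx, xyz) {
  nres <- ctx$nres
  H <- amide_h_coords(ctx, xyz)
  hb <- ks_energy_matrix(ctx, xyz, H) < .ss_energy_cutoff
  lab <- rep("C", nres)

  # n-turn at i: bond donated by N-H(i+n) to C=O(i)
  turn_at <- function(n) {
    ok <- rep(FALSE, nres)
    if (nres > n) {
      i <- seq_len(nres - n)
      ok[i] <- hb[cbind(i + n, i)]
    }
    ok
  }
  t3 <- turn_at(3L); t4 <- turn_at(4L); t5 <- turn_at(5L)

  # bend (S): C-alpha direction change > 70 degrees over i-2, i, i+2
  if (nres >= 5L) {
    i <- 3:(nres - 2L)
    ok <- ctx$bb$complete[i - 2L] & ctx$bb$complete[i] & ctx$bb$complete[i + 2L] &
      ctx$seg[i - 2L] == ctx$seg[i] & ctx$seg[i] == ctx$seg[i + 2L]
    CA <- matrix(NA_real_, nres, 3)
    cc <- which(ctx$bb$complete)
    CA[cc, ] <- xyz[ctx$bb$idx[cc, "CA"], , drop = FALSE]
    u <- CA[i, , drop = FALSE] - CA[i - 2L, , drop = FALSE]
    v <- CA[i + 2L, , drop = FALSE] - CA[i, , drop = FALSE]
    cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    bend <- ok & !is.na(ang) & ang > .ss_bend_angle
    lab[i[bend]] <- "S"
  }

  # turns (T): residues spanned by any 3-, 4- or 5-turn
  in_turn <- rep(FALSE, nres)
  for (n in c(3L, 4L, 5L)) {
    tn <- switch(as.character(n), "3" = t3, "4" = t4, "5" = t5)
    for (d in seq_len(n - 1L)) in_turn <- in_turn | shift_vec(tn, -d)
  }
  lab[in_turn] <- "T"

  # beta bridges: parallel / antiparallel patterns, |i - j| >= 3
  far <- abs(outer(seq_len(nres), seq_len(nres), "-")) >= 3L
  tb <- t(hb)
  para <- (shift_mat(hb, -1L, 0L) & shift_mat(tb, 1L, 0L)) |
          (shift_mat(tb, 0L, -1L) & shift_mat(hb, 0L, 1L))
  anti <- (hb & tb) |
          (shift_mat(shift_mat(hb, -1L, 0L), 0L, 1L) &
           shift_mat(shift_mat(tb, 1L, 0L), 0L, -1L))
  bridge <- (para | anti) & far
  ladder <- bridge & (shift_mat(bridge, -1L, -1L) | shift_mat(bridge, 1L, 1L) |
                      shift_mat(bridge, -1L, 1L) | shift_mat(bridge, 1L, -1L))
  has_bridge <- rowSums(bridge) > 0L
  is_ladder <- rowSums(ladder) > 0L
  lab[has_bridge] <- "B"

  # 3-10 helix (G): two consecutive 3-turns starting at i mark i..i+2
  g_start <- t3 & shift_vec(t3, -1L)
  g_res <- g_start | shift_vec(g_start, -1L) | shift_vec(g_start, -2L)
  lab[g_res] <- "G"

  # extended strand (E) outranks G and B
  lab[is_ladder] <- "E"

  # alpha-helix (H): two consecutive 4-turns starting at i mark i..i+3
  h_start <- t4 & shift_vec(t4, -1L)
  h_res <- h_start | shift_vec(h_start, -1L) | shift_vec(h_start, -2L) |
           shift_vec(h_start, -3L)
  lab[h_res] <- "H"
  lab
}

#' Assign secondary structure to one conformation
#'
#' @param x `md_structure`.
#' @param xyz optional coordinates overriding the structure's own.
#' @return Character vector of per-residue labels over
#'   `{H, G, E, B, T, S, C}`.
#' @export
assign_ss <- function(x, xyz = NULL) {
  stopifnot(inherits(x, "md_structure"))
  if (is.null(xyz)) xyz <- coords(x)
  assign_ss_frame(ss_context(x, xyz), xyz)
}

#' Secondary-structure timeline of a trajectory
#'
#' @param traj `md_trajectory`.
#' @return Object of class `ss_timeline`: character matrix, frames in rows,
#'   residues in columns.
#' @export
ss_timeline <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  x <- traj$topology
  ctx <- ss_context(x, frame_coords(traj, 1L))
  nf <- n_frames(traj)
  out <- matrix("C", nf, n_residues(x))
  for (f in seq_len(nf)) {
    out[f, ] <- assign_ss_frame(ctx, frame_coords(traj, f))
  }
  colnames(out) <- paste(x$residues$res_name, x$residues$res_id)
  class(out) <- c("ss_timeline", class(out))
  out
}

#' Number-of-structured-residues summary
#'
#' Structured residues are everything except coil (C). A system whose
#' average structured count stays near the initial count (change close to
#' 0) is conformationally stable by this criterion.
#'
#' @param timeline `ss_timeline` from [ss_timeline()].
#' @return List of class `nsr_summary`: `total_residues`,
#'   `initial_structured` (frame 1), `mean_structured`, `sd`,
#'   `change` (mean - initial), `structured_pct`, `coil_pct`
#'   (overall percentages across all frames; they sum to 100), and
#'   `series` (per-frame structured counts).
#' @export
nsr_summary <- function(timeline) {
  m <- unclass(timeline)
  structured <- matrix(m %in% .ss_structured, nrow(m), ncol(m))
  counts <- rowSums(structured)
  total <- ncol(m)
  pct <- 100 * mean(structured)
  structure(list(total_residues = total,
                 initial_structured = counts[1],
                 mean_structured = mean(counts),
                 sd = if (length(counts) > 1L) stats::sd(counts) else 0,
                 change = mean(counts) - counts[1],
                 structured_pct = pct,
                 coil_pct = 100 - pct,
                 series = counts),
            class = "nsr_summary")
}

#' @export
print.nsr_summary <- function(x, ...) {
  cat(sprintf(paste0("structured residues: initial %d, mean %.3f +/- %.3f ",
                     "(change %+.3f) of %d total; structured %.2f%%, coil %.2f%%\n"),
              x$initial_structured, x$mean_structured, x$sd, x$change,
              x$total_residues, x$structured_pct, x$coil_pct))
  invisible(x)
}
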