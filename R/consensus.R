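#' Binding hot-spot consensus
#'
#' Hot-spot residues are identified by combining three evidence streams:
#' (1) docking interaction occurrence -- the number of distinct ligands a
#' residue interacts with, kept when it covers at least half of the ligand
#' set; (2) hydrogen-bond percentage occupancy over the MD trajectory; and
#' (3) per-residue binding free-energy decomposition. Residues are ranked
#' by how many streams support them, with occupancy + energy agreement
#' (the dynamics-based evidence) outranking combinations that rely on the
#' static docking occurrence at equal score.
#'
#' Residues are keyed by their annotation label, e.g. `"His363"`
#' (title-cased three-letter code plus residue number).
#'
#' @name consensus
NULL

#' Residue annotation label
#' @param res_name 3-letter residue code(s).
#' @param res_id residue number(s).
#' @return Character vector like `"His363"`.
#' @export
residue_label <- function(res_name, res_id) {
  paste0(residue_label_vec(res_name), res_id)
}

#' Occurrence counts from a docking interaction table
#'
#' Counts, for every residue, the number of *distinct* ligands with at
#' least one interaction of any class (a ligand contacting a residue
#' through several interaction classes counts once).
#'
#' @param table `interaction_table` (see [read_interaction_table()]).
#' @param n_ligands ligand universe size; defaults to the table's
#'   `n_ligands` attribute.
#' @return data.frame of class `occurrence_counts`, sorted by decreasing
#'   count: `residue` (label), `chain`, `res_id`, `res_name`, `count`,
#'   `annotation` (the `"His363 (13)"` convention); attribute `n_ligands`.
#' @export
occurrence_counts <- function(table, n_ligands = NULL) {
  if (is.null(n_ligands)) n_ligands <- attr(table, "n_ligands")
  if (is.null(n_ligands)) n_ligands <- length(unique(table$ligand_id))
  df <- as.data.frame(table)
  key <- paste(df$chain, df$res_id, df$res_name, sep = "\r")
  lig_key <- paste(key, df$ligand_id, sep = "\r")
  df <- df[!duplicated(lig_key), , drop = FALSE]
  key <- key[!duplicated(lig_key)]
  tab <- table(key)
  first <- !duplicated(key)
  info <- df[first, c("chain", "res_id", "res_name")]
  cnt <- as.integer(tab[match(key[first], names(tab))])
  lab <- residue_label(info$res_name, info$res_id)
  out <- data.frame(residue = lab, chain = info$chain, res_id = info$res_id,
                    res_name = info$res_name, count = cnt,
                    annotation = sprintf("%s (%d)", lab, cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$res_id), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$count >= 0L), all(out$count <= n_ligands))
  attr(out, "n_ligands") <- n_ligands
  class(out) <- c("occurrence_counts", "data.frame")
  out
}

#' Filter occurrence counts by the half-the-ligands rule
#'
#' Keeps residues whose occurrence count is at least `floor(n_ligands / 2)`.
#' Note the floor: for a 15-ligand set the threshold is 7, so a
#' half-the-compounds rule admits residues seen in 7 of 15 ligands (46.7%).
#' This is the inclusive reading consistent with occurrence lists that
#' report 7-of-15 residues as passing; a strict `ceiling(n/2)` rule would
#' exclude them.
#'
#' @param counts `occurrence_counts`.
#' @param n_ligands ligand universe size; defaults to the attribute carried
#'   by `counts`. Must be positive.
#' @return Character vector of residue labels passing the filter.
#' @export
filter_by_occurrence <- function(counts, n_ligands = NULL) {
  if (is.null(n_ligands)) n_ligands <- attr(counts, "n_ligands")
  if (is.null(n_ligands) || n_ligands <= 0) stop("n_ligands must be positive")
  thr <- floor(n_ligands / 2)
  counts$residue[counts$count >= thr]
}

#' Residues with appreciable H-bond occupancy
#'
#' @param table `occupancy_table` from [occupancy_table()], or a data.frame
#'   with residue-level columns `donor_res`, `acceptor_res`, `pct`.
#' @param min_pct minimum residue-level occupancy percentage (default 2.0,
#'   roughly the smallest occupancy worth reporting).
#' @param ligand_res optional label(s) of the ligand residue; when given,
#'   only pairs involving the ligand are considered and the *protein*
#'   partner is reported.
#' @return Character vector of residue labels.
#' @export
occupancy_set <- function(table, min_pct = 2.0, ligand_res = NULL) {
  res <- if (inherits(table, "occupancy_table")) table$residues else table
  if (nrow(res) == 0L) return(character(0))
  keep <- res$pct >= min_pct
  res <- res[keep, , drop = FALSE]
  if (!is.null(ligand_res)) {
    inv <- res$donor_res %in% ligand_res | res$acceptor_res %in% ligand_res
    res <- res[inv, , drop = FALSE]
    partners <- ifelse(res$donor_res %in% ligand_res, res$acceptor_res, res$donor_res)
    return(unique(partners))
  }
  unique(c(res$donor_res, res$acceptor_res))
}

#' Residues with favourable decomposition energy
#'
#' Exactly one of `max_energy` and `top_k` selects the residues: all with
#' contribution at or below `max_energy` (default -1 kcal/mol), or the
#' `top_k` most favourable (lowest-energy) residues.
#'
#' @param table `energy_table`.
#' @param max_energy energy threshold, kcal/mol.
#' @param top_k number of most favourable residues.
#' @return Character vector of residue labels.
#' @export
energy_set <- function(table, max_energy = -1.0, top_k = NULL) {
  if (!is.null(top_k) && !missing(max_energy)) {
    stop("give either max_energy or top_k, not both")
  }
  df <- as.data.frame(table)
  if (nrow(df) == 0L) return(character(0))
  lab <- residue_label(df$res_name, df$res_id)
  if (!is.null(top_k)) {
    ord <- order(df$energy_kcal_mol, df$res_id)
    return(unique(lab[ord])[seq_len(min(top_k, length(unique(lab))))])
  }
  unique(lab[df$energy_kcal_mol <= max_energy])
}

#' Three-evidence hot-spot consensus report
#'
#' @param occurrence_set residue labels passing [filter_by_occurrence()].
#' @param occupancy_set residue labels from [occupancy_set()].
#' @param energy_set residue labels from [energy_set()].
#' @param occupancy_pct optional named numeric vector (label -> residue
#'   occupancy percentage) used as the final tie-break.
#' @return data.frame of class `consensus_report`: `residue`, the three
#'   evidence flags, `evidence_score` (0-3) and `rank`. Sorted by score,
#'   then occupancy+energy agreement, then occupancy percentage, then
#'   label. A warning is raised when the three sets share no residue
#'   universe at all.
#' @export
hotspot_consensus <- function(occurrence_set, occupancy_set, energy_set,
                              occupancy_pct = NULL) {
  universe <- unique(c(occurrence_set, occupancy_set, energy_set))
  if (length(universe) == 0L) stop("all evidence sets are empty")
  overlap <- (occurrence_set %in% c(occupancy_set, energy_set)) |
             any(occupancy_set %in% energy_set)
  if (length(occurrence_set) && length(c(occupancy_set, energy_set)) &&
      !any(overlap)) {
    warning("evidence sets are disjoint; consensus scores will not exceed 1",
            call. = FALSE)
  }
  df <- data.frame(residue = universe,
                   in_occurrence_set = universe %in% occurrence_set,
                   in_occupancy_set = universe %in% occupancy_set,
                   in_energy_set = universe %in% energy_set,
                   stringsAsFactors = FALSE)
  df$evidence_score <- df$in_occurrence_set + df$in_occupancy_set + df$in_energy_set
  dyn_priority <- df$in_occupancy_set & df$in_energy_set
  occ <- if (is.null(occupancy_pct)) rep(0, nrow(df)) else {
    v <- occupancy_pct[df$residue]; v[is.na(v)] <- 0; as.numeric(v)
  }
  ord <- order(-df$evidence_score, -dyn_priority, -occ, df$residue)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("consensus_report", "data.frame")
  df
}
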