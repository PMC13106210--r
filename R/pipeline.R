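#' Orchestration: the full per-system analysis suite
#'
#' Mirrors the usual per-system MD workflow (an apo protein plus its
#' ligand-bound complexes): RMSD, RMSF, radius of gyration, SASA, PCA,
#' DCCM with percentage-area classification, secondary-structure timeline
#' with the structured-residue summary, GROMOS clustering and H-bond
#' statistics, collected into one machine-readable report. Stages are
#' isolated: one failing analysis is recorded as an error string and the
#' remaining stages still run.
#'
#' @name pipeline
NULL

#' Analysis configuration
#'
#' All tunables of the suite in one place. Defaults are the conventional
#' values: 0.2 nm clustering cutoff, 3.5 Angstrom / 30 degree H-bond
#' criteria, +/-0.05 DCCM classification bands, half-the-ligands occurrence
#' filter, 1.4 Angstrom SASA probe with 960 sphere points.
#'
#' @param fit_selection selection used to fit frames for RMSD.
#' @param rmsf_selection selection for RMSF (per-residue with `"calpha"`).
#' @param analysis_selection selection for PCA/DCCM/clustering.
#' @param probe_radius SASA probe radius, Angstrom.
#' @param sasa_points SASA sphere points per atom.
#' @param sasa_stride evaluate SASA every this many frames.
#' @param cluster_cutoff GROMOS cutoff, nm.
#' @param dccm_threshold DCCM classification half-width.
#' @param hbond_distance donor-acceptor cutoff, Angstrom.
#' @param hbond_angle maximum deviation from linearity, degrees.
#' @param occupancy_min_pct residue-level occupancy cutoff, percent.
#' @param energy_max_kcal decomposition energy threshold, kcal/mol.
#' @param seed integer seed recorded in the report (analyses themselves are
#'   deterministic; the seed documents the provenance of synthetic inputs).
#' @param output_dir optional directory for CSV/JSON/PDB outputs.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(fit_selection = "backbone",
                            rmsf_selection = "calpha",
                            analysis_selection = "calpha",
                            probe_radius = 1.4, sasa_points = 960,
                            sasa_stride = 10L,
                            cluster_cutoff = 0.2, dccm_threshold = 0.05,
                            hbond_distance = 3.5, hbond_angle = 30,
                            occupancy_min_pct = 2.0, energy_max_kcal = -1.0,
                            seed = 1L, output_dir = NULL) {
  structure(as.list(environment()), class = "analysis_config")
}

#' @noRd
run_stage <- function(stages, name, expr) {
  stages[[name]] <- tryCatch(expr, error = function(e) {
    structure(list(error = conditionMessage(e)), class = "stage_error")
  })
  stages
}

#' Run the full analysis suite on one system
#'
#' @param traj `md_trajectory` for the system.
#' @param config `analysis_config`.
#' @param label system label used in reports.
#' @return List of class `system_report` with elements `label`, `config`,
#'   `rmsd`, `rmsf`, `rg`, `sasa` (each a `series_summary`), `pca`
#'   (`pca_result`), `dccm_pct` (classification percentages), `nsr`
#'   (`nsr_summary`), `cluster` (named clustering scalars), `hbond_range`
#'   (min/max per-frame bond count) and `occupancy` (`occupancy_table`).
#'   Failed stages hold `list(error = <message>)` instead.
#' @export
run_suite <- function(traj, config = analysis_config(), label = "system") {
  stopifnot(inherits(traj, "md_trajectory"), inherits(config, "analysis_config"))
  st <- list()
  st <- run_stage(st, "rmsd", rmsd_series(traj, config$fit_selection))
  st <- run_stage(st, "rmsf", rmsf_per_residue(traj, config$rmsf_selection))
  st <- run_stage(st, "rg", radius_of_gyration_series(traj))
  st <- run_stage(st, "sasa",
                  sasa_series(traj, probe = config$probe_radius,
                              n_points = config$sasa_points,
                              stride = config$sasa_stride))
  st <- run_stage(st, "pca", trajectory_pca(traj, config$analysis_selection))
  st <- run_stage(st, "dccm_pct", {
    C <- dccm(traj, config$analysis_selection)
    classify_dccm(C, threshold = config$dccm_threshold)
  })
  st <- run_stage(st, "nsr", nsr_summary(ss_timeline(traj)))
  st <- run_stage(st, "cluster",
                  cluster_summary(cluster_trajectory(traj,
                                                     config$analysis_selection,
                                                     cutoff = config$cluster_cutoff)))
  crit <- hbond_criteria(config$hbond_distance, config$hbond_angle)
  htraj <- tryCatch({
    if (nrow(detect_donors_acceptors(traj$topology)$donors) == 0L) {
      protonate_backbone(traj)
    } else traj
  }, error = function(e) traj)
  occ <- tryCatch(occupancy_table(htraj, criteria = crit),
                  error = function(e) structure(list(error = conditionMessage(e)),
                                                class = "stage_error"))
  st <- run_stage(st, "hbond_range", {
    if (inherits(occ, "stage_error")) stop(occ$error)
    counts <- attr(occ, "frame_counts")
    c(min = min(counts), max = max(counts), mean = mean(counts))
  })
  st[["occupancy"]] <- occ
  rep <- structure(c(list(label = label, config = config), st),
                   class = "system_report")
  if (!is.null(config$output_dir)) write_report(rep, config$output_dir)
  rep
}

#' @noRd
summarise_series <- function(s) {
  if (inherits(s, "stage_error")) return(list(error = s$error))
  list(mean_angstrom = s$mean, sd_angstrom = s$sd,
       mean_nm = s$mean_nm, sd_nm = s$sd_nm, n = length(s$values))
}

#' JSON form of a system report
#'
#' Deterministic serialisation (fixed precision, no timestamps): two runs
#' of [run_suite()] on the same inputs give byte-identical JSON.
#'
#' @param report `system_report`.
#' @return JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "system_report"))
  err_or <- function(x, f) if (inherits(x, "stage_error")) list(error = x$error) else f(x)
  out <- list(
    label = report$label,
    rmsd = summarise_series(report$rmsd),
    rmsf = summarise_series(report$rmsf),
    rg = summarise_series(report$rg),
    sasa = if (inherits(report$sasa, "stage_error")) list(error = report$sasa$error) else
      list(mean_angstrom2 = report$sasa$mean, sd_angstrom2 = report$sasa$sd,
           mean_nm2 = report$sasa$mean_nm, sd_nm2 = report$sasa$sd_nm,
           n = length(report$sasa$values)),
    pca = err_or(report$pca, function(p) list(
      pc1_variance_fraction = p$variance_fractions[1],
      pc2_variance_fraction = p$variance_fractions[2],
      pc12_variance_pct = 100 * sum(p$variance_fractions[1:2]))),
    dccm_pct = err_or(report$dccm_pct, function(d) as.list(round(d, 10))),
    nsr = err_or(report$nsr, function(n) list(
      total_residues = n$total_residues, initial = n$initial_structured,
      average = n$mean_structured, std_dev = n$sd, change = n$change,
      structured_pct = n$structured_pct, coil_pct = n$coil_pct)),
    cluster = err_or(report$cluster, as.list),
    hbond_range = err_or(report$hbond_range, as.list),
    occupancy_top = err_or(report$occupancy, function(o)
      utils::head(o$residues, 10L))
  )
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(10),
                                pretty = TRUE))
}

#' Write report artefacts to a directory
#'
#' Emits `report.json` plus per-analysis CSVs (per-frame RMSD/RG/SASA,
#' per-residue RMSF, PC projections, occupancy tables).
#'
#' @param report `system_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(dir, "report.json"))
  wcsv <- function(df, nm) write.csv(df, file.path(dir, nm), row.names = FALSE)
  if (!inherits(report$rmsd, "stage_error")) {
    wcsv(data.frame(frame = seq_along(report$rmsd$values),
                    rmsd_nm = report$rmsd$values_nm), "rmsd.csv")
  }
  if (!inherits(report$rmsf, "stage_error")) {
    wcsv(data.frame(residue = report$rmsf$labels,
                    rmsf_nm = report$rmsf$values_nm), "rmsf.csv")
  }
  if (!inherits(report$rg, "stage_error")) {
    wcsv(data.frame(frame = seq_along(report$rg$values),
                    rg_nm = report$rg$values_nm), "rg.csv")
  }
  if (!inherits(report$sasa, "stage_error")) {
    wcsv(data.frame(frame = attr(report$sasa, "frames"),
                    sasa_nm2 = report$sasa$values_nm), "sasa.csv")
  }
  if (!inherits(report$pca, "stage_error") && !is.null(report$pca$projections)) {
    wcsv(as.data.frame(report$pca$projections), "pca_projections.csv")
  }
  if (!inherits(report$occupancy, "stage_error")) {
    wcsv(report$occupancy$atoms, "occupancy_atoms.csv")
    wcsv(report$occupancy$residues, "occupancy_residues.csv")
  }
  invisible(dir)
}

# Stability metrics and the direction in which "better" points.
.compare_metrics <- list(
  rmsd_mean_nm        = list(get = function(r) r$rmsd$mean_nm, dir = "lower"),
  rmsf_mean_nm        = list(get = function(r) r$rmsf$mean_nm, dir = "lower"),
  rg_mean_nm          = list(get = function(r) r$rg$mean_nm, dir = "lower"),
  sasa_mean_nm2       = list(get = function(r) r$sasa$mean_nm, dir = "lower"),
  pca_pc12_spread     = list(get = function(r) sum(r$pca$eigenvalues[1:2]),
                             dir = "lower"),
  nsr_abs_change      = list(get = function(r) abs(r$nsr$change), dir = "lower"),
  n_clusters          = list(get = function(r) unname(r$cluster["n_clusters"]),
                             dir = "lower"),
  first_cluster_size  = list(get = function(r) unname(r$cluster["first_cluster_size"]),
                             dir = "higher"),
  hbond_max           = list(get = function(r) unname(r$hbond_range["max"]),
                             dir = "higher")
)

#' Rank systems per analysis
#'
#' Orders systems the way stability is conventionally read: lower mean
#' RMSD/RMSF/RG/SASA, smaller PC1+PC2 conformational spread, structured-
#' residue change closest to 0, fewer clusters, larger first cluster and
#' more H-bonds are better. Exact ties share a rank and are flagged rather
#' than broken arbitrarily.
#'
#' @param reports list of `system_report`s with matching successful stages.
#' @param labels optional system labels (default: each report's own).
#' @return data.frame: `analysis`, `system`, `value`, `rank`, `tied`.
#' @export
compare_systems <- function(reports, labels = NULL) {
  if (length(reports) < 2L) stop("need at least 2 reports to compare")
  if (is.null(labels)) labels <- vapply(reports, `[[`, character(1), "label")
  dep_of <- c(rmsd_mean_nm = "rmsd", rmsf_mean_nm = "rmsf", rg_mean_nm = "rg",
              sasa_mean_nm2 = "sasa", pca_pc12_spread = "pca",
              nsr_abs_change = "nsr", n_clusters = "cluster",
              first_cluster_size = "cluster", hbond_max = "hbond_range")
  avail <- lapply(reports, function(r) {
    names(.compare_metrics)[!vapply(dep_of, function(d)
      inherits(r[[d]], "stage_error") || is.null(r[[d]]), logical(1))]
  })
  ok <- Reduce(intersect, avail)
  mismatched <- setdiff(Reduce(union, avail), ok)
  if (length(mismatched)) {
    stop("analysis sets differ between reports; missing in some systems: ",
         paste(mismatched, collapse = ", "))
  }
  missing_any <- setdiff(names(.compare_metrics), ok)
  if (length(ok) == 0L) stop("no analysis is available in every report")
  rows <- list()
  for (nm in ok) {
    spec <- .compare_metrics[[nm]]
    vals <- vapply(reports, spec$get, numeric(1))
    key <- if (spec$dir == "lower") vals else -vals
    rk <- rank(key, ties.method = "min")
    tied <- duplicated(key) | duplicated(key, fromLast = TRUE)
    rows[[nm]] <- data.frame(analysis = nm, system = labels, value = vals,
                             rank = as.integer(rk), tied = tied,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unavailable") <- missing_any
  out
}
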