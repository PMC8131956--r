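# Config-driven orchestration of the full comparative analysis: one
# reference condition versus any number of stress conditions, each with
# replicate trajectories.  Produces the tabular equivalents of the usual
# comparison figures: per-domain RMSD, interface/domain native-contact
# fractions, windowed RMSF, salt-bridge occurrence tables and per-region
# counts, per-strand beta-occupancy change, APR SASA change, and
# per-residue difference maps projected onto structures.
#
# Delta convention everywhere: stress - reference (positive = increase
# under stress).  Replicates are paired by index when counts match;
# otherwise unpaired means are differenced and SEMs combined in
# quadrature.

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$reference))
    stopf("config error: a reference condition is required")
  if (is.null(config$structure))
    stopf("config error: a reference structure path is required")
  config
}

.config_regions <- function(config) {
  r <- config$regions
  map <- domain_map(lapply(r$domains, function(iv) as.numeric(unlist(iv))),
                    lapply(r$interfaces %||% list(), function(p) as.character(unlist(p))))
  smap <- if (!is.null(r$strands))
    strand_map(lapply(r$strands, function(iv) as.numeric(unlist(iv))), map) else NULL
  aprs <- if (!is.null(r$aprs))
    apr_set(lapply(r$aprs, function(iv) as.numeric(unlist(iv))),
            max_residue = max(vapply(map$domains, max, 1))) else NULL
  list(map = map, smap = smap, aprs = aprs)
}

.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full comparative stress analysis from a config
#'
#' The config (YAML file or equivalent list) names a reference condition
#' and zero or more stress conditions, each with replicate multi-model PDB
#' trajectories, plus the region model (domains, interfaces, strands,
#' APRs) and optional parameter overrides.  All module outputs are written
#' as CSV under `out_dir`; per-residue delta-RMSF and delta-Q maps are
#' projected onto PDB B-factors; a manifest JSON records parameters.
#' Re-running on identical inputs yields byte-identical outputs (numbers
#' are written with 6 significant digits).
#'
#' @param config YAML path or list (see `write_toy_fixture()` for a
#'   generated example).
#' @param out_dir output directory.
#' @return invisible list of per-condition reports.
#' @export
run_comparison <- function(config, out_dir) {
  config <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_cond <- c(list(config$reference), config$conditions %||% list())
  for (cond in all_cond) {
    missing <- !file.exists(unlist(cond$trajectories))
    if (any(missing))
      stopf("trajectory file(s) not found for condition '%s': %s", cond$label,
            paste(unlist(cond$trajectories)[missing], collapse = ", "))
  }
  regions <- .config_regions(config)
  map <- regions$map
  pars <- config$parameters %||% list()
  cpar <- do.call(contact_params, pars$contacts %||% list())
  sb_opts <- pars$saltbridge %||% list()
  spar <- salt_bridge_params(cutoff = sb_opts$cutoff %||% 3.2,
                             include_his = sb_opts$include_his %||% FALSE)
  sb_threshold <- sb_opts$threshold %||% 10
  sasa_opts <- pars$sasa %||% list()
  sasa_par <- sasa_params(probe = sasa_opts$probe %||% 1.4,
                          dots = sasa_opts$dots %||% 960L)
  sasa_stride <- sasa_opts$stride %||% 5L
  rmsf_window <- pars$rmsf_window_ns %||% 10
  dt <- config$frame_interval_ns %||% 0.1

  reference <- read_structure(config$structure)
  contact_sets <- lapply(setNames(region_names(map), region_names(map)),
                         function(rg) build_reference_contacts(reference, rg, map, cpar))

  analyse_condition <- function(cond) {
    label <- cond$label
    trajs <- lapply(unlist(cond$trajectories), read_trajectory,
                    frame_interval_ns = dt)
    n_rep <- length(trajs)
    rmsd <- list(); q <- list(); rmsf <- list()
    for (rg in names(map$domains)) {
      series <- lapply(seq_len(n_rep), function(r)
        domain_rmsd_series(trajs[[r]], reference, rg, map, replicate = r))
      rmsd[[rg]] <- list(series = series, agg = aggregate_replicates(series))
      prof <- lapply(seq_len(n_rep), function(r)
        windowed_rmsf(trajs[[r]], rg, map, window_ns = rmsf_window,
                      reference = reference, replicate = r))
      rmsf[[rg]] <- prof
    }
    for (rg in region_names(map)) {
      series <- lapply(seq_len(n_rep), function(r)
        contact_series(trajs[[r]], contact_sets[[rg]], replicate = r))
      q[[rg]] <- list(series = series, agg = aggregate_replicates(series))
    }
    occ <- lapply(trajs, bridge_occurrence, params = spar)
    occ_table <- aggregate_occurrence(occ, threshold = sb_threshold)
    list(label = label, trajs = trajs, n_rep = n_rep, rmsd = rmsd, q = q,
         rmsf = rmsf, occurrence = occ_table,
         region_counts = count_by_region(occ_table, map))
  }

  write_condition <- function(rep) {
    lab <- rep$label
    rmsd_df <- do.call(rbind, lapply(rep$rmsd, `[[`, "agg"))
    .write_table(rmsd_df, file.path(out_dir, sprintf("rmsd_%s.csv", lab)))
    q_df <- do.call(rbind, lapply(rep$q, `[[`, "agg"))
    .write_table(q_df, file.path(out_dir, sprintf("q_%s.csv", lab)))
    rmsf_df <- do.call(rbind, lapply(names(rep$rmsf), function(rg) {
      per_rep <- rep$rmsf[[rg]]
      base <- per_rep[[1]][c("region", "window", "t_start_ns", "t_end_ns", "resno")]
      vals <- sapply(per_rep, `[[`, "rmsf")
      vals <- matrix(vals, ncol = length(per_rep))
      cbind(base, data.frame(mean = rowMeans(vals),
                             sem = if (ncol(vals) > 1)
                               apply(vals, 1, sd) / sqrt(ncol(vals)) else 0,
                             n = ncol(vals)))
    }))
    .write_table(rmsf_df, file.path(out_dir, sprintf("rmsf_%s.csv", lab)))
    occ_df <- as.data.frame(rep$occurrence)
    .write_table(occ_df, file.path(out_dir, sprintf("saltbridge_%s.csv", lab)))
    .write_table(rep$region_counts,
                 file.path(out_dir, sprintf("saltbridge_counts_%s.csv", lab)))
  }

  # mean per-residue quantities used for the projection maps
  residue_rmsf_last <- function(rep) {
    per_res <- list()
    for (rg in names(rep$rmsf)) {
      for (r in seq_along(rep$rmsf[[rg]])) {
        prof <- rep$rmsf[[rg]][[r]]
        last <- prof[prof$window == max(prof$window), ]
        key <- as.character(last$resno)
        for (i in seq_len(nrow(last)))
          per_res[[key[i]]] <- c(per_res[[key[i]]], last$rmsf[i])
      }
    }
    vapply(per_res, mean, 1.0)
  }
  residue_q_final <- function(rep) {
    per_res <- list()
    for (rg in names(contact_sets)) {
      for (tr in rep$trajs) {
        rf <- residue_fraction(tr$coords[, , n_frames(tr)], contact_sets[[rg]])
        for (nm in names(rf)) per_res[[nm]] <- c(per_res[[nm]], rf[[nm]])
      }
    }
    vapply(per_res, mean, 1.0)
  }

  ref_rep <- analyse_condition(config$reference)
  write_condition(ref_rep)
  reports <- list(reference = ref_rep)

  ref_rmsf_res <- residue_rmsf_last(ref_rep)
  ref_q_res <- residue_q_final(ref_rep)

  for (cond in config$conditions %||% list()) {
    rep <- analyse_condition(cond)
    write_condition(rep)
    lab <- rep$label
    paired <- rep$n_rep == ref_rep$n_rep
    if (!paired)
      warnf("condition '%s': replicate count differs from reference; using unpaired deltas", lab)

    # per-domain/interface delta summaries at the final time point
    delta_rows <- lapply(region_names(map), function(rg) {
      a <- rep$q[[rg]]$agg; b <- ref_rep$q[[rg]]$agg
      i <- nrow(a)
      data.frame(region = rg,
                 q_ref = b$mean[i], q_stress = a$mean[i],
                 delta_q = a$mean[i] - b$mean[i],
                 sem = sqrt(a$sem[i]^2 + b$sem[i]^2))
    })
    rmsd_rows <- lapply(names(map$domains), function(rg) {
      a <- rep$rmsd[[rg]]$agg; b <- ref_rep$rmsd[[rg]]$agg
      i <- nrow(a)
      data.frame(region = rg,
                 rmsd_ref = b$mean[i], rmsd_stress = a$mean[i],
                 delta_rmsd = a$mean[i] - b$mean[i],
                 sem = sqrt(a$sem[i]^2 + b$sem[i]^2))
    })
    .write_table(do.call(rbind, delta_rows),
                 file.path(out_dir, sprintf("delta_q_final_%s.csv", lab)))
    .write_table(do.call(rbind, rmsd_rows),
                 file.path(out_dir, sprintf("delta_rmsd_final_%s.csv", lab)))

    # strand occupancy change and APR exposure change
    if (!is.null(regions$smap)) {
      n_use <- min(rep$n_rep, ref_rep$n_rep)
      sc <- strand_occupancy_change(rep$trajs[seq_len(n_use)],
                                    ref_rep$trajs[seq_len(n_use)], regions$smap,
                                    relative = !identical(pars$strand_change, "absolute"))
      sc$change_type <- if (identical(pars$strand_change, "absolute"))
        "percentage_points" else "relative_percent"
      .write_table(sc, file.path(out_dir, sprintf("strand_change_%s.csv", lab)))
    }
    if (!is.null(regions$aprs)) {
      n_use <- min(rep$n_rep, ref_rep$n_rep)
      ac <- apr_sasa_change(rep$trajs[seq_len(n_use)],
                            ref_rep$trajs[seq_len(n_use)], regions$aprs,
                            params = sasa_par, stride = sasa_stride)
      .write_table(ac, file.path(out_dir, sprintf("apr_sasa_change_%s.csv", lab)))
    }

    # per-residue difference maps (stress - reference), projected on the
    # reference structure
    rmsf_res <- residue_rmsf_last(rep)
    shared <- intersect(names(rmsf_res), names(ref_rmsf_res))
    d_rmsf <- rmsf_res[shared] - ref_rmsf_res[shared]
    q_res <- residue_q_final(rep)
    shared_q <- intersect(names(q_res), names(ref_q_res))
    d_q <- q_res[shared_q] - ref_q_res[shared_q]
    .write_table(data.frame(resno = as.integer(shared), delta_rmsf = unname(d_rmsf)),
                 file.path(out_dir, sprintf("delta_rmsf_residue_%s.csv", lab)))
    .write_table(data.frame(resno = as.integer(shared_q), delta_q = unname(d_q)),
                 file.path(out_dir, sprintf("delta_q_residue_%s.csv", lab)))
    suppressWarnings({
      write_score_projection(reference, d_rmsf,
                             file.path(out_dir, sprintf("delta_rmsf_%s.pdb", lab)))
      write_score_projection(reference, d_q,
                             file.path(out_dir, sprintf("delta_q_%s.pdb", lab)))
    })
    reports[[lab]] <- rep
  }

  manifest <- list(
    package = "stressmap",
    version = as.character(utils::packageVersion("stressmap")),
    config = config[setdiff(names(config), c("reference", "conditions"))],
    conditions = vapply(all_cond, `[[`, "", "label"),
    parameters = list(contacts = unclass(cpar), saltbridge = unclass(spar),
                      saltbridge_threshold = sb_threshold,
                      sasa = unclass(sasa_par), sasa_stride = sasa_stride,
                      rmsf_window_ns = rmsf_window))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(reports)
}
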