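# Command-line workbench: run configuration, logging, and the analyze /
# kinetics / thermo / synth entry points used by exec/aggkin.
#
# Exit-code contract (returned as an integer, raised by the exec script):
# 0 ok, 2 bad input, 3 bad configuration.

#' Run configuration with package defaults
#'
#' All defaults match the documented criterion defaults; every value
#' actually used is echoed to the log, because results are
#' criterion-sensitive. Round-trips losslessly through JSON (and YAML if
#' the yaml package is available).
#'
#' @param ... overrides for any field (nested lists merged shallowly)
#' @return object of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(
    input = list(topology = NULL, trajectory = NULL, energy_csv = NULL),
    criteria = list(hb_threshold = -0.5, min_hbonds = 2L,
                    min_beta_residues = 3L, contact_cutoff = 6.5,
                    phi_windows = list(c(-180, 0), c(150, 180)),
                    psi_windows = list(c(-180, -150), c(0, 180)),
                    orientation_dead_zone_deg = 0),
    kinetics = list(rate_bin_width = 5, totals_bin_width = 5,
                    n_star = 5L, hold_time = 500, dissolve_threshold = 2L,
                    align_threshold = -80, align_window = 5000,
                    max_curve_size = 9L),
    thermo = list(temperature = 300, weighting = "per_aggregate",
                  tie_tolerance = 0.5, subsets = 3L),
    output_dir = ".",
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

criteria_from_config <- function(cfg) {
  cr <- cfg$criteria
  default_criteria(
    phi_windows = do.call(rbind, cr$phi_windows),
    psi_windows = do.call(rbind, cr$psi_windows),
    hb_threshold = cr$hb_threshold, min_hbonds = as.integer(cr$min_hbonds),
    min_beta_residues = as.integer(cr$min_beta_residues),
    contact_cutoff = cr$contact_cutoff,
    orientation_dead_zone_deg = cr$orientation_dead_zone_deg)
}

#' Read / write a run configuration
#'
#' JSON is the primary format; files ending in `.yml`/`.yaml` are read
#' with the yaml package when it is installed.
#'
#' @param path config file
#' @param cfg a `run_config`
#' @name config_io
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  }
  do.call(run_config, raw)
}

#' @rdname config_io
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.log_info <- function(...) message("INFO  ", ...)

.log_criteria <- function(cfg) {
  cr <- cfg$criteria
  .log_info("criteria: hb_threshold=", cr$hb_threshold,
            " kcal/mol, min_hbonds=", cr$min_hbonds,
            ", min_beta_residues=", cr$min_beta_residues,
            ", contact_cutoff=", cr$contact_cutoff, " A")
  .log_info("criteria: phi windows ",
            paste(vapply(cr$phi_windows, paste, "", collapse = ".."),
                  collapse = " U "),
            "; psi windows ",
            paste(vapply(cr$psi_windows, paste, "", collapse = ".."),
                  collapse = " U "))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_manifest <- function(cfg, outdir, inputs, outputs) {
  manifest <- list(
    package = "aggkin",
    version = as.character(utils::packageVersion("aggkin")),
    config_hash = digest_config(cfg),
    inputs = inputs, outputs = outputs,
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

digest_config <- function(cfg) {
  # dependency-free stable hash: sum of char codes of the serialized config
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 97 + 1)) %% 2^31)
}

.load_inputs <- function(cfg) {
  if (is.null(cfg$input$topology) || !file.exists(cfg$input$topology))
    return(NULL)
  topo <- load_topology(cfg$input$topology)
  if (is.null(cfg$input$trajectory) || !file.exists(cfg$input$trajectory))
    return(NULL)
  traj <- load_trajectory(cfg$input$trajectory, topo)
  traj
}

partition_to_json_line <- function(p) {
  jsonlite::toJSON(list(time = p$time,
                        clusters = p$clusters,
                        monomers = p$monomers,
                        parallel = p$cluster_parallel),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Per-frame analysis command
#'
#' Computes per-frame metrics, cluster partitions and structure maps, and
#' writes them (TSV / JSON-lines) into the output directory. Deterministic
#' given the configuration.
#'
#' @param cfg a `run_config`
#' @return integer exit status, invisibly: 0 ok, 2 bad input, 3 bad config
#' @export
cmd_analyze <- function(cfg) {
  if (!inherits(cfg, "run_config")) return(invisible(3L))
  traj <- tryCatch(.load_inputs(cfg), error = function(e) {
    message("ERROR ", conditionMessage(e)); NULL
  })
  if (is.null(traj) || n_frames(traj) < 1L) return(invisible(2L))
  .log_criteria(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  crit <- criteria_from_config(cfg)
  ts <- cluster_timeseries(traj, crit)
  write_tsv(ts$metrics, file.path(cfg$output_dir, "metrics.tsv"))
  writeLines(vapply(ts$partitions, partition_to_json_line, ""),
             file.path(cfg$output_dir, "partitions.jsonl"))
  hist_mat <- t(vapply(ts$partitions, function(p) p$size_hist,
                       integer(ts$partitions[[1]]$n_peptides)))
  write_tsv(as.data.frame(hist_mat), file.path(cfg$output_dir,
                                               "size_histogram.tsv"))
  maps <- structure_maps(ts$metrics)
  for (nm in c("last_time", "density", "parallel"))
    write_tsv(as.data.frame(maps[[nm]]),
              file.path(cfg$output_dir, paste0("map_", nm, ".tsv")))
  .write_manifest(cfg, cfg$output_dir, unlist(cfg$input),
                  c("metrics.tsv", "partitions.jsonl", "size_histogram.tsv",
                    "map_last_time.tsv", "map_density.tsv", "map_parallel.tsv"))
  invisible(0L)
}

#' Kinetics command
#'
#' Classifies events along the trajectory, writes events/rates/totals
#' tables, cumulative size curves, nucleation/reversibility episodes, and
#' (when an energy CSV is configured) the aligned mean energy profile.
#'
#' @param cfg a `run_config`
#' @return integer exit status, invisibly
#' @export
cmd_kinetics <- function(cfg) {
  if (!inherits(cfg, "run_config")) return(invisible(3L))
  traj <- tryCatch(.load_inputs(cfg), error = function(e) {
    message("ERROR ", conditionMessage(e)); NULL
  })
  if (is.null(traj) || n_frames(traj) < 2L) return(invisible(2L))
  .log_criteria(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  crit <- criteria_from_config(cfg)
  kin <- cfg$kinetics
  ts <- cluster_timeseries(traj, crit)
  events <- classify_events(ts$partitions)
  write_tsv(events, file.path(cfg$output_dir, "events.tsv"))
  bw <- kin$rate_bin_width
  if (!is.na(traj$save_interval) && bw < traj$save_interval) {
    bw <- traj$save_interval
    .log_info("rate bin width raised to the save interval (", bw, " ps)")
  }
  rs <- rate_series(events, bw, n_max = n_chains(traj$topology),
                    save_interval = traj$save_interval)
  write_tsv(as.data.frame(rs$net_rate),
            file.path(cfg$output_dir, "net_rates.tsv"))
  write_tsv(event_totals(events, kin$totals_bin_width),
            file.path(cfg$output_dir, "event_totals.tsv"))
  write_tsv(cumulative_size_curves(ts$partitions, kin$max_curve_size),
            file.path(cfg$output_dir, "cumulative_curves.tsv"))
  eps <- detect_nucleation_and_reversibility(
    ts$metrics$time, ts$metrics$largest_cluster_size,
    n_star = kin$n_star, hold_time = kin$hold_time,
    dissolve_threshold = kin$dissolve_threshold)
  write_tsv(eps$episodes, file.path(cfg$output_dir, "episodes.tsv"))
  outs <- c("events.tsv", "net_rates.tsv", "event_totals.tsv",
            "cumulative_curves.tsv", "episodes.tsv")
  if (!is.null(cfg$input$energy_csv) && file.exists(cfg$input$energy_csv)) {
    en <- utils::read.csv(cfg$input$energy_csv)
    names(en) <- tolower(names(en))
    if (!all(c("time", "e_total") %in% names(en))) {
      message("ERROR energy CSV must have columns time, E_total")
      return(invisible(2L))
    }
    prof <- align_energy_traces(list(data.frame(time = en$time,
                                                energy = en$e_total)),
                                threshold = kin$align_threshold,
                                window = kin$align_window)
    write_tsv(prof, file.path(cfg$output_dir, "energy_aligned.tsv"))
    outs <- c(outs, "energy_aligned.tsv")
  } else {
    .log_info("no energy CSV configured; energy alignment skipped")
  }
  .write_manifest(cfg, cfg$output_dir, unlist(cfg$input), outs)
  invisible(0L)
}

#' Thermodynamics command
#'
#' Free-energy profiles over aggregate size (both weightings, with
#' subset fluctuation bands), the critical nucleus, the beta-residue
#' free-energy profile, and a CNT fit report (JSON).
#'
#' @param cfg a `run_config`
#' @return integer exit status, invisibly
#' @export
cmd_thermo <- function(cfg) {
  if (!inherits(cfg, "run_config")) return(invisible(3L))
  traj <- tryCatch(.load_inputs(cfg), error = function(e) {
    message("ERROR ", conditionMessage(e)); NULL
  })
  if (is.null(traj) || n_frames(traj) < 1L) return(invisible(2L))
  .log_criteria(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  crit <- criteria_from_config(cfg)
  th <- cfg$thermo
  ts <- cluster_timeseries(traj, crit)
  out <- list()
  for (w in c("per_aggregate", "per_peptide")) {
    sp <- size_probability(ts$partitions, weighting = w,
                           subsets = min(th$subsets, n_frames(traj)))
    prof <- free_energy_profile(sp, th$temperature)
    nuc <- critical_nucleus(prof, tol = th$tie_tolerance)
    f_stderr <- rep(NA_real_, length(prof$f))
    if (!is.null(sp$p_subsets)) {
      fs <- -log(sp$p_subsets)          # per-subset profiles (kB*T)
      fs[!is.finite(fs)] <- NA
      f_stderr <- apply(fs, 2, sd, na.rm = TRUE) / sqrt(nrow(sp$p_subsets))
    }
    df <- data.frame(size = prof$coord, count = sp$counts, p = prof$p,
                     f = prof$f, f_stderr = f_stderr)
    write_tsv(df, file.path(cfg$output_dir,
                            paste0("free_energy_", w, ".tsv")))
    out[[w]] <- list(n_star = nuc$n_star, range = nuc$range,
                     no_nucleus = nuc$no_nucleus)
    if (w == th$weighting && !nuc$no_nucleus && length(which(!is.na(prof$f))) >= 4) {
      fit <- tryCatch(suppressWarnings(cnt_fit(prof)), error = function(e) NULL)
      if (!is.null(fit)) out$cnt_fit <- fit
    }
  }
  bfe <- beta_residue_free_energy(traj, th$temperature, crit,
                                  tol = th$tie_tolerance)
  write_tsv(data.frame(beta_residues = bfe$profile$coord,
                       count = bfe$profile$counts, p = bfe$profile$p,
                       f = bfe$profile$f),
            file.path(cfg$output_dir, "free_energy_beta.tsv"))
  out$beta_critical <- bfe$critical
  jsonlite::write_json(out, file.path(cfg$output_dir, "nucleus_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  .write_manifest(cfg, cfg$output_dir, unlist(cfg$input),
                  c("free_energy_per_aggregate.tsv",
                    "free_energy_per_peptide.tsv", "free_energy_beta.tsv",
                    "nucleus_report.json"))
  invisible(0L)
}

#' Full-pipeline report command
#'
#' Chains [cmd_analyze()], [cmd_kinetics()] and [cmd_thermo()] and renders
#' a Markdown summary of the run into the output directory.
#'
#' @param cfg a `run_config`
#' @return integer exit status, invisibly
#' @export
cmd_report <- function(cfg) {
  s <- cmd_analyze(cfg)
  if (s == 0L) s <- cmd_kinetics(cfg)
  if (s == 0L) s <- cmd_thermo(cfg)
  if (s != 0L) return(invisible(s))
  od <- cfg$output_dir
  metrics <- utils::read.delim(file.path(od, "metrics.tsv"))
  events <- utils::read.delim(file.path(od, "events.tsv"))
  nuc <- jsonlite::read_json(file.path(od, "nucleus_report.json"))
  lines <- c(
    "# aggkin run report", "",
    sprintf("- frames analysed: %d (%.6g .. %.6g ps)", nrow(metrics),
            min(metrics$time), max(metrics$time)),
    sprintf("- final largest cluster: %d peptides",
            metrics$largest_cluster_size[nrow(metrics)]),
    sprintf("- mean beta fraction: %.3f", mean(metrics$beta_fraction)),
    sprintf("- kinetic events: %d (%s)", nrow(events),
            paste(names(table(events$type)), table(events$type),
                  sep = "=", collapse = ", ")),
    sprintf("- critical nucleus (per-aggregate weighting): %s",
            if (isTRUE(nuc$per_aggregate$no_nucleus)) "none detected"
            else paste0(nuc$per_aggregate$n_star, " (range ",
                        paste(unlist(nuc$per_aggregate$range),
                              collapse = "-"), ")")),
    "",
    "Outputs: metrics.tsv, partitions.jsonl, size_histogram.tsv,",
    "map_*.tsv, events.tsv, net_rates.tsv, event_totals.tsv,",
    "cumulative_curves.tsv, episodes.tsv, free_energy_*.tsv,",
    "nucleus_report.json, manifest.json")
  writeLines(lines, file.path(od, "report.md"))
  invisible(0L)
}

#' Synthetic-data command
#'
#' Generates fixtures: `what = "ideal-sheet"` writes a verified sheet
#' PDB, `"random-coil"` a coil box PDB, `"kmc"` a Gillespie trace
#' (event log + snapshot TSVs). Identical seeds give identical outputs.
#'
#' @param cfg a `run_config`
#' @param what fixture kind
#' @param n strands (sheet) or peptides (coil)
#' @param orientation sheet orientation
#' @param preset KMC preset name (`"barrier"` detailed-balance or
#'   `"multiset"`)
#' @return integer exit status, invisibly
#' @export
cmd_synth <- function(cfg, what = c("ideal-sheet", "random-coil", "kmc"),
                      n = 5L, orientation = "parallel",
                      preset = "barrier") {
  if (!inherits(cfg, "run_config")) return(invisible(3L))
  what <- tryCatch(match.arg(what), error = function(e) NA_character_)
  if (is.na(what)) return(invisible(3L))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  if (what == "ideal-sheet") {
    if (!orientation %in% c("parallel", "antiparallel")) return(invisible(3L))
    sh <- build_ideal_sheet(n, orientation)
    write_pdb(sh$frame, file.path(cfg$output_dir, "ideal_sheet.pdb"),
              topo = sh$topology)
    jsonlite::write_json(
      list(n_strands = n, orientation = orientation,
           parallel_fraction = parallel_fraction(sh$partition)),
      file.path(cfg$output_dir, "ideal_sheet_truth.json"),
      auto_unbox = TRUE, digits = NA)
  } else if (what == "random-coil") {
    rc <- build_random_coil(n)
    write_pdb(rc$frame, file.path(cfg$output_dir, "random_coil.pdb"),
              topo = rc$topology)
  } else {
    mode <- switch(preset, barrier = "detailed_balance",
                   multiset = "multiset", NA_character_)
    if (is.na(mode)) {
      message("ERROR unknown KMC preset: ", preset)
      return(invisible(3L))
    }
    trace <- gillespie_aggregation(kmc_config(mode = mode, seed = cfg$seed))
    write_tsv(trace$log, file.path(cfg$output_dir, "kmc_events.tsv"))
    write_tsv(as.data.frame(kmc_size_matrix(trace)),
              file.path(cfg$output_dir, "kmc_snapshots.tsv"))
  }
  invisible(0L)
}
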