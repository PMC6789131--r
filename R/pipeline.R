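#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the pipeline with provenance tracking: values
#' come from package defaults, then a flat key-value YAML config file, then
#' explicit arguments (e.g. command-line flags), in increasing precedence.
#' The exact configuration is serialisable and is written next to the run's
#' outputs, so a run can be reproduced from its output directory alone.
#'
#' @param config_file Optional YAML file of `key: value` pairs.
#' @param ... Explicit overrides (highest precedence).
#' @return A `run_config`: named list with attribute `provenance` (one of
#'   `"default"`, `"config_file"`, `"flag"` per key).
#' @export
run_config <- function(config_file = NULL, ...) {
  defaults <- list(
    mode = "simulate",              # simulate | input
    input_manifest = NA_character_, # TSV: file, label columns (mode = input)
    out_dir = "thermokin-run",
    seed = 1L,
    # generator
    n_residues = 10L, helix = "310", bath_temperature = 300,
    heater_index = 1L, delta_T = 670, heat_duration = 1.0,
    k_backbone = 1.5, k_hbond = 0.5, k_solvent = 0.05,
    temperature_dependent = FALSE, omega = 5, barrier = 0.05,
    n_members = 20L, t_total = 10, noise_scale = 1,
    # analysis
    dt = 0.1, convention = "scaled", surface_factor = 1.5,
    ensemble_mean = TRUE,
    bin_width = 1.0, low_range = c(230, 270), high_range = c(290, 330),
    boundaries = c(15, 30, 50, 77), exclude_below = 4,
    dx = 0.2, n_atoms = 13, heat_capacity = NA_real_,
    front_threshold = 5
  )
  prov <- stats::setNames(rep("default", length(defaults)), names(defaults))
  cfg <- defaults
  if (!is.null(config_file)) {
    file_vals <- yaml::read_yaml(config_file)
    bad <- setdiff(names(file_vals), names(defaults))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    for (k in names(file_vals)) {
      cfg[[k]] <- file_vals[[k]]
      prov[k] <- "config_file"
    }
  }
  flags <- list(...)
  bad <- setdiff(names(flags), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (k in names(flags)) {
    if (!is.null(flags[[k]])) {
      cfg[[k]] <- flags[[k]]
      prov[k] <- "flag"
    }
  }
  if (is.na(cfg$heat_capacity)) {
    cfg$heat_capacity <- 1.5 * mean(cfg$n_atoms) * kB_eV
  }
  structure(cfg, provenance = prov, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<run_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s  [%s]\n", k,
                paste(format(x[[k]], digits = 6), collapse = ","), prov[k]))
  }
  invisible(x)
}

write_run_config <- function(config, path) {
  vals <- unclass(config)
  attributes(vals) <- list(names = names(vals))
  yaml::write_yaml(vals, path)
  invisible(path)
}

log_stage <- function(verbose, ...) {
  if (verbose) message("[thermokin] ", sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Executes, per the configuration: (1) generate a synthetic ensemble or read
#' trajectories from a manifest; (2) coarse-grain to the analysis timescale
#' and build the ensemble temperature-elevation profile; (3) fit
#' time-dependent rates and pairwise fluxes; (4) bin fluxes by effective
#' gradient and fit the transport regimes and barrier profile. All result
#' tables, the exact configuration, and a machine-readable JSON run summary
#' are written under `config$out_dir`. Identical configuration and seed give
#' identical outputs.
#'
#' @param config A `run_config`.
#' @param verbose Log stage progress to stderr (default `TRUE`).
#' @return (Invisibly) a list with the in-memory results: `profile`,
#'   `rate_fits`, `fluxes`, `bins`, `regimes`, `barriers`, `summary`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  topo <- build_topology(config$n_residues, helix = config$helix,
                         n_atoms = config$n_atoms,
                         terminal_factor = config$surface_factor,
                         spacing = config$dx)

  if (identical(config$mode, "simulate")) {
    log_stage(verbose, "simulate: %d members at T_B = %s K",
              config$n_members, format(config$bath_temperature))
    temps <- config$bath_temperature
    ensembles <- lapply(seq_along(temps), function(ti) {
      model <- kinetic_model(
        topo, temps[ti], k_backbone = config$k_backbone,
        k_hbond = config$k_hbond, k_solvent = config$k_solvent,
        temperature_dependent = config$temperature_dependent,
        omega = config$omega, barrier = config$barrier
      )
      simulate_master_equation(
        model, heater_protocol(config$heater_index, config$delta_T,
                               config$heat_duration,
                               record_interval = config$dt),
        t_total = config$t_total, n_members = config$n_members,
        seed = config$seed + 101L * (ti - 1L), noise_scale = config$noise_scale
      )
    })
  } else {
    if (is.na(config$input_manifest)) stop("mode 'input' needs input_manifest", call. = FALSE)
    log_stage(verbose, "read: manifest %s", config$input_manifest)
    man <- readr::read_tsv(config$input_manifest, show_col_types = FALSE)
    paths <- file.path(dirname(config$input_manifest), man$file)
    trajs <- lapply(paths, read_energy_trajectory)
    tb <- vapply(trajs, function(x) attr(x, "bath_temperature"), 0)
    ensembles <- split(trajs, tb)
  }

  log_stage(verbose, "coarse-grain: dt = %g ps", config$dt)
  ensembles <- lapply(ensembles, function(ens) lapply(ens, function(tr) {
    if (min(diff(traj_times(tr))) < config$dt - 1e-12) {
      block_average(tr, config$dt)
    } else tr
  }))

  profile <- ensemble_profile(ensembles[[1]], label = "full")
  write_results(profile, file.path(config$out_dir, "profile.tsv"))

  log_stage(verbose, "fit: %s", if (config$ensemble_mean)
    "ensemble-mean trajectories" else "per-member trajectories")
  fit_one <- function(tr) {
    rates <- fit_rates(tr, topo, convention = config$convention)
    list(rates = rates, fluxes = compute_fluxes(tr, topo, rates))
  }
  fitted <- lapply(ensembles, function(ens) {
    if (config$ensemble_mean) {
      list(fit_one(ensemble_mean_trajectory(ens)))
    } else {
      lapply(ens, fit_one)
    }
  })
  rate_fits <- lapply(fitted, function(g) lapply(g, `[[`, "rates"))
  fluxes <- dplyr::bind_rows(lapply(fitted, function(g)
    dplyr::bind_rows(lapply(g, `[[`, "fluxes"))))
  class(fluxes) <- c("flux_records", class(tibble::tibble()))
  write_results(rate_fits[[1]][[1]], file.path(config$out_dir, "rates.tsv"))
  write_results(fluxes, file.path(config$out_dir, "fluxes.tsv"))

  log_stage(verbose, "regimes: %d flux records", nrow(fluxes))
  bins <- bin_by_gradient(
    fluxes, width = config$bin_width,
    classes = list(low = config$low_range, high = config$high_range)
  )
  regimes <- segment_regimes(bins, boundaries = config$boundaries,
                             spacing = config$dx,
                             heat_capacity = config$heat_capacity,
                             exclude_below = config$exclude_below)
  barriers <- barrier_profile(bins, T_low = mean(config$low_range),
                              T_high = mean(config$high_range))
  write_results(bins, file.path(config$out_dir, "gradient_bins.tsv"))
  write_results(regimes, file.path(config$out_dir, "regimes.tsv"))
  write_results(barriers, file.path(config$out_dir, "barriers.tsv"))

  summary <- list(
    n_ensembles = length(ensembles),
    n_members = vapply(ensembles, length, 0L),
    n_bins_time = length(unique(profile$time)),
    n_flux_records = nrow(fluxes),
    mean_residual = mean(vapply(rate_fits, function(g)
      mean(vapply(g, function(r) glance(r)$mean_residual, 0)), 0)),
    regimes = as.data.frame(tibble::as_tibble(regimes)),
    barrier_mean = if (nrow(barriers)) stats::weighted.mean(
      barriers$barrier, 1 / barriers$barrier_sem^2) else NA_real_
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  log_stage(verbose, "done: outputs in %s", config$out_dir)

  invisible(list(profile = profile, rate_fits = rate_fits, fluxes = fluxes,
                 bins = bins, regimes = regimes, barriers = barriers,
                 summary = summary))
}
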