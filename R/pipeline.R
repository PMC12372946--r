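# Config-file driven pipeline: runs one analysis stage and writes its
# outputs plus a run manifest, for scripted/reproducible use.

#' Run an analysis stage from a config file
#'
#' Reads a YAML or JSON config naming a `stage` and its options, executes
#' it, and writes the results (CSV for tabular outputs, JSON for fit/MCMC
#' results) together with a `manifest.json` recording the resolved
#' parameters, seeds, tolerances, and package version. Floating-point
#' output is serialized at full precision, so identical config + seed gives
#' byte-identical outputs.
#'
#' Stages and their options:
#' * `simulate`: `species`, `config` (name of a config constructor, e.g.
#'   `"human_injection_config"`), `regimen` (options passed to
#'   [standard_regimen()]), `dt_out`.
#' * `fit`: `case` (`"topical"`/`"intravitreal"`), optional `data` (CSV
#'   path; default the bundled porcine measurements).
#' * `mcmc`: as `fit`, plus `n_steps`, `seed`.
#' * `sensitivity`: `parameters`, `regimen_name`, `n_values`.
#' * `sweep`: `mode`, optional `intensities`.
#' * `synth`: `case`, `sd_prop`, `n_rep`, `seed`.
#' Any stage accepts `params` (named overrides of the species defaults).
#'
#' @param config_path Path to the YAML/JSON config.
#' @param out_dir Output directory (created; default a directory named
#'   after the config file).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- if (grepl("\\.ya?ml$", config_path)) {
    yaml::read_yaml(config_path)
  } else {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  }
  if (is.null(cfg$stage)) stop("config must name a `stage`")
  stages <- c("simulate", "fit", "mcmc", "sensitivity", "sweep", "synth")
  if (!cfg$stage %in% stages) {
    stop("unknown stage '", cfg$stage, "'; expected one of ",
         paste(stages, collapse = ", "))
  }
  if (is.null(out_dir)) {
    out_dir <- paste0(sub("\\.(json|ya?ml)$", "", config_path), "_out")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  species <- cfg$species %||% if (cfg$stage %in% c("fit", "mcmc", "synth"))
    "porcine" else "human"
  params <- eye_params(species)
  if (!is.null(cfg$params)) {
    params <- do.call(set_params, c(list(params), as.list(cfg$params)))
  }
  seed <- cfg$seed %||% 1
  write_csv_full <- function(d, file) {
    utils::write.csv(
      as.data.frame(lapply(d, function(col) {
        if (is.double(col)) sprintf("%.17g", col) else col
      })),
      file.path(out_dir, file), row.names = FALSE, quote = FALSE)
  }
  write_json_out <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  load_data <- function() {
    if (is.null(cfg$data)) return(porcine_measurements())
    d <- tibble::as_tibble(utils::read.csv(cfg$data))
    if (!"time_h" %in% names(d) && "time_min" %in% names(d)) {
      d$time_h <- d$time_min / 60
    }
    validate_measurements(d)
    d
  }

  result_files <- switch(cfg$stage,
    simulate = {
      config <- do.call(cfg$config %||% "human_injection_config", list())
      reg <- do.call(standard_regimen, as.list(cfg$regimen))
      sim <- simulate_eye(reg, params, config, dt_out = cfg$dt_out %||% 0.1)
      write_csv_full(sim, "trajectory.csv")
      "trajectory.csv"
    },
    fit = {
      data <- load_data()
      fit <- if ((cfg$case %||% "topical") == "topical") {
        fit_topical(data, params)
      } else {
        fit_intravitreal(data, params)
      }
      write_json_out(list(estimates = as.list(fit$par),
                          objective = fit$objective,
                          converged = fit$converged, case = fit$case),
                     "fit.json")
      "fit.json"
    },
    mcmc = {
      data <- load_data()
      m <- mcmc_permeability(data, params, case = cfg$case %||% "topical",
                             n_steps = cfg$n_steps %||% 1e5, seed = seed)
      td <- tidy(m)
      write_json_out(list(posterior = split(td[-1], td$term),
                          accept_rate = m$accept_rate,
                          n_steps = m$n_steps, seed = m$seed), "mcmc.json")
      "mcmc.json"
    },
    sensitivity = {
      pars <- cfg$parameters %||% sensitivity_ranges()$parameter
      res <- purrr::map_dfr(pars, sweep_parameter,
                            regimen_name = cfg$regimen_name %||% "injections",
                            n_values = cfg$n_values %||% 101, params = params)
      write_csv_full(res, "sensitivity.csv")
      "sensitivity.csv"
    },
    sweep = {
      res <- regimen_sweep(cfg$mode %||% "drops",
                           intensities = cfg$intensities, params = params)
      write_csv_full(res, "sweep.csv")
      "sweep.csv"
    },
    synth = {
      d <- generate_measurements(params, case = cfg$case %||% "topical",
                                 n_rep = cfg$n_rep %||% 3,
                                 sd_prop = cfg$sd_prop %||% 0.2, seed = seed)
      write_csv_full(d, "measurements.csv")
      "measurements.csv"
    }
  )

  manifest <- list(
    stage = cfg$stage,
    config_file = normalizePath(config_path),
    outputs = result_files,
    species = species,
    parameters = params[.param_names],
    seed = seed,
    solver = list(method = "ode45", rtol = 1e-8, atol = 1e-12),
    package_version = as.character(utils::packageVersion("ocuvegf")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_json_out(manifest, "manifest.json")
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
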