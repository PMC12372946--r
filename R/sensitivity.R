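# Local (one-at-a-time) sensitivity analysis and dosing-regimen sweeps for
# the in vivo human eye.

# the three reference regimens used by the sensitivity analysis:
# hourly drops (24/day), a continuously worn lens, and injections at the
# start of weeks 1, 5, and 9, all over a 12-week horizon
.sensitivity_regimen <- function(regimen_name, horizon_h = 12 * 168) {
  switch(regimen_name,
    drops = standard_regimen("drops_at_hours", hours = 0:23,
                             horizon_h = horizon_h),
    lens = standard_regimen("lens_continuous", horizon_h = horizon_h),
    injections = standard_regimen("injections", interval_weeks = 4,
                                  first_week = 1, horizon_h = horizon_h),
    stop("unknown sensitivity regimen: ", regimen_name)
  )
}

.sensitivity_config <- function(regimen_name) {
  switch(regimen_name,
    drops = human_drops_config(),
    lens = human_lens_config(),
    injections = human_injection_config()
  )
}

# refresh the untreated-VEGF initial conditions for a modified parameter
# set (the sweep default: initial conditions stay consistent with the
# parameters being varied)
.refresh_vegf_init <- function(p) {
  ss <- untreated_vegf_steady_state(p)
  p$v_aq_init <- ss[["v_aq"]]
  p$v_vit_init <- ss[["v_vit"]]
  p
}

#' One-at-a-time parameter sweep (sensitivity factors)
#'
#' Varies a single parameter across `n_values` uniformly spaced values over
#' its biologically realistic range (endpoints included), holding all other
#' parameters at their defaults. For each value the model is simulated over
#' `t` in \[0, 12\] weeks under the chosen reference regimen, the maximum /
#' time-weighted mean / minimum of vitreal VEGF and vitreal total drug are
#' taken over weeks \[9, 12\] (by when the solution has settled to a steady
#' state or a regular periodic pattern), and each output's sensitivity
#' factor is its maximum over the sweep divided by its minimum. A factor
#' above 1.5 is flagged significant.
#'
#' By default the untreated VEGF steady state is recomputed for every
#' parameter value so the initial conditions stay consistent with the
#' varied parameter; set `recompute_init = FALSE` to hold the default
#' initial conditions fixed instead.
#'
#' @param param_name Parameter to vary (a [sensitivity_ranges()] name).
#' @param regimen_name `"drops"` (hourly), `"lens"` (worn continuously), or
#'   `"injections"` (weeks 1, 5, 9).
#' @param n_values Number of sweep values (101 for the full analysis).
#' @param params Base human parameter set.
#' @param range Optional `c(lo, hi)` override of the swept range.
#' @param recompute_init Recompute untreated VEGF initial conditions per
#'   value?
#' @param window Summary window, h.
#' @param horizon_h Simulation horizon, h.
#' @param dt_out Output grid, h.
#' @param detail Attach the per-value summaries as attribute `"values"`?
#' @return A tibble with one row per output: `parameter`, `regimen`,
#'   `output` (e.g. `"v_vit_max"`), `factor`, `significant`. Factors are
#'   `Inf` (flagged) when an output's minimum over the sweep is zero.
#' @export
sweep_parameter <- function(param_name, regimen_name = c("drops", "lens", "injections"),
                            n_values = 101, params = eye_params("human"),
                            range = NULL, recompute_init = TRUE,
                            window = c(9, 12) * 168, horizon_h = 12 * 168,
                            dt_out = 0.1, detail = FALSE) {
  regimen_name <- match.arg(regimen_name)
  rng <- sensitivity_ranges()
  if (is.null(range)) {
    row <- rng[rng$parameter == param_name, ]
    if (nrow(row) != 1) stop("unknown parameter: ", param_name)
    range <- c(row$lo, row$hi)
  }
  values <- seq(range[1], range[2], length.out = n_values)
  reg <- .sensitivity_regimen(regimen_name, horizon_h)
  config <- .sensitivity_config(regimen_name)

  summaries <- purrr::map_dfr(values, function(v) {
    p <- do.call(set_params, c(list(params), stats::setNames(list(v), param_name)))
    if (recompute_init) p <- .refresh_vegf_init(p)
    sim <- simulate_eye(reg, p, config, dt_out = dt_out)
    s <- summarize_window(sim, window)
    long <- tidyr::pivot_longer(s, c("max", "mean", "min"),
                                names_to = "stat", values_to = "summary")
    tibble::tibble(value = v,
                   output = paste(long$output, long$stat, sep = "_"),
                   summary = long$summary)
  })

  res <- summaries |>
    dplyr::group_by(.data$output) |>
    dplyr::summarise(
      factor = ifelse(min(.data$summary) > 0,
                      max(.data$summary) / min(.data$summary), Inf),
      .groups = "drop") |>
    dplyr::mutate(parameter = param_name, regimen = regimen_name,
                  significant = .data$factor > 1.5) |>
    dplyr::select("parameter", "regimen", "output", "factor", "significant")
  if (detail) attr(res, "values") <- summaries
  res
}

#' Dosing-regimen sweeps
#'
#' Varies the intensity of a dosing regimen and reports the maximum /
#' time-weighted mean / minimum vitreal VEGF and total drug over the final
#' settled window:
#'
#' * `"drops"`: `n_drop` in 1..16 drops/day (first at 0 h, spacing
#'   `16/n_drop` h); 12-week horizon, summarized over weeks \[9, 12\].
#' * `"lens"`: lenses worn `n_day` in 1..30 days with 1-day breaks;
#'   124-day horizon, summarized over the final complete cycle.
#' * `"injections"`: interval 1..8 weeks, first at the start of week 1;
#'   32-week horizon, summarized over the final complete cycle.
#' * `"drops_injections"`: injections as above plus four drops/day at 4, 8,
#'   12, 16 h.
#' * `"lens_injections"`: injections as above plus lenses worn days 2-7 of
#'   every week.
#'
#' @param mode Regimen family (see above).
#' @param intensities Integer intensities to sweep (default: the full range).
#' @param params Human [eye_params()].
#' @param dt_out Output grid, h.
#' @return A tibble: `mode`, `intensity`, `output`, `max`, `mean`, `min`.
#' @export
regimen_sweep <- function(mode = c("drops", "lens", "injections",
                                   "drops_injections", "lens_injections"),
                          intensities = NULL, params = eye_params("human"),
                          dt_out = 0.1) {
  mode <- match.arg(mode)
  full <- switch(mode, drops = 1:16, lens = 1:30, 1:8)
  if (is.null(intensities)) intensities <- full
  if (!all(intensities %in% full)) {
    stop("intensities for mode '", mode, "' must be integers in ",
         min(full), "..", max(full))
  }

  one <- function(x) {
    if (mode == "drops") {
      t_end <- 12 * 168
      reg <- standard_regimen("drops_daily", n_drop = x, horizon_h = t_end)
      config <- human_drops_config()
      window <- c(9, 12) * 168
    } else if (mode == "lens") {
      t_end <- 124 * 24
      cycle <- (x + 1) * 24
      k <- floor(t_end / cycle)
      reg <- standard_regimen("lens_cycle", n_day = x, n_cycles = k,
                              horizon_h = t_end)
      config <- model_config(TRUE, "constant_norm", "depleting", TRUE, FALSE)
      window <- c((k - 1) * cycle, k * cycle)
    } else {
      t_end <- 32 * 168
      inj <- standard_regimen("injections", interval_weeks = x,
                              first_week = 1, horizon_h = t_end)
      cycle <- x * 168
      k <- floor(t_end / cycle)
      window <- c((k - 1) * cycle, k * cycle)
      if (mode == "injections") {
        reg <- inj
        config <- human_injection_config()
      } else if (mode == "drops_injections") {
        drops <- standard_regimen("drops_at_hours", hours = c(4, 8, 12, 16),
                                  horizon_h = t_end)
        reg <- combine_regimens(inj, drops, params = params)
        config <- human_drops_config()
      } else {
        lens_ev <- tibble::tibble(
          time_h = as.vector(rbind((0:31) * 168 + 24, (0:31) * 168 + 168)),
          kind = rep(c("lens_on", "lens_off"), 32)
        )
        lens_ev <- lens_ev[lens_ev$time_h < t_end, ]
        reg <- combine_regimens(inj, regimen(lens_ev, t_end = t_end),
                                params = params)
        config <- model_config(TRUE, "constant_norm", "depleting", TRUE, FALSE)
      }
    }
    sim <- simulate_eye(reg, params, config, dt_out = dt_out)
    s <- summarize_window(sim, window)
    dplyr::mutate(s, mode = mode, intensity = x, .before = 1)
  }
  purrr::map_dfr(intensities, one)
}
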