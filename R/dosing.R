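# Dosing: state resets for drops, injections, and drug-eluting lenses, and
# the regimen container that schedules them over a simulation horizon.

#' Apply an eye drop to the current state
#'
#' The drop fluid merges and mixes instantaneously with the tear film, so
#' the new tear drug concentration is the volume-weighted average of the
#' pre-drop tear concentration (volume `V_tear_norm`) and the dose
#' concentration (volume `V_drop`); the excess volume then runs off the eye
#' without changing the concentration, leaving the tear volume at
#' `V_tear_res`. Local time resets to zero (the tear volume restarts its
#' linear drainage). All other variables are continuous across the dose.
#'
#' @param state An [eye_state()] (or named numeric vector in its order).
#' @param params An [eye_params()] object.
#' @return The post-drop state.
#' @export
#' @examples
#' apply_drop(eye_state(), eye_params("human"))["r_tear"]  # 1.81e4
apply_drop <- function(state, params) {
  p <- params
  vn <- p$V_tear_norm
  state[["r_tear"]] <- state[["r_tear"]] * vn / (vn + p$V_drop) +
    p$r_dose * p$V_drop / (vn + p$V_drop)
  state
}

#' Apply an intravitreal injection to the current state
#'
#' The injected bolus equilibrates rapidly through the vitreous, raising the
#' vitreal free-drug concentration by `r_dose * V_drop / V_vit`. The
#' injected volume is negligible relative to the vitreous and is assumed
#' drained, so the vitreal volume is unchanged.
#'
#' @inheritParams apply_drop
#' @return The post-injection state.
#' @export
#' @examples
#' apply_injection(eye_state(), eye_params("human"))["r_vit"]   # 207
#' apply_injection(eye_state(), eye_params("porcine"))["r_vit"] # 300
apply_injection <- function(state, params) {
  state[["r_vit"]] <- state[["r_vit"]] + params$r_dose * params$V_drop / params$V_vit
  state
}

#' Insert or remove a drug-eluting contact lens
#'
#' On insertion the tear drug concentration jumps to `r_tear_init` and is
#' held there (constant elution balances tear turnover) at the normal tear
#' volume. On removal the tear concentration resumes its depleting dynamics
#' from its current value.
#'
#' @inheritParams apply_drop
#' @param on `TRUE` to insert, `FALSE` to remove.
#' @return List with elements `state` and `lens_on`.
#' @export
apply_lens <- function(state, params, on) {
  if (on) state[["r_tear"]] <- params$r_tear_init
  list(state = state, lens_on = isTRUE(on))
}

.event_kinds <- c("drop", "injection", "lens_on", "lens_off")

#' Treatment regimen
#'
#' An ordered schedule of treatment events over a simulation horizon.
#' Events at `time_h = 0` are applied to the initial state before
#' integration starts. Consecutive drops must be separated by at least
#' `tau_loss` (so the tear volume has drained back to normal before the
#' next mixing step), and lens insertions/removals must strictly alternate.
#'
#' @param events A data frame with columns `time_h` (global time, h) and
#'   `kind` (one of `"drop"`, `"injection"`, `"lens_on"`, `"lens_off"`), or
#'   `NULL` for an untreated run.
#' @param t_end Simulation horizon, h; must exceed the last event time.
#' @param tau_loss Minimum drop spacing used for validation, h.
#' @return A tibble of class `regimen` with attribute `t_end`.
#' @export
#' @examples
#' regimen(data.frame(time_h = c(0, 672), kind = "injection"), t_end = 1344)
regimen <- function(events = NULL, t_end, tau_loss = 5e-2) {
  if (is.null(events) || nrow(events) == 0) {
    ev <- tibble::tibble(time_h = numeric(0), kind = character(0))
  } else {
    stopifnot(all(c("time_h", "kind") %in% names(events)))
    if (!all(events$kind %in% .event_kinds)) {
      stop("unknown event kind(s): ",
           paste(setdiff(unique(events$kind), .event_kinds), collapse = ", "))
    }
    ev <- tibble::as_tibble(events[c("time_h", "kind")])
    ev <- dplyr::arrange(ev, .data$time_h)
    if (any(ev$time_h < 0)) stop("event times must be non-negative")
    drops <- ev$time_h[ev$kind == "drop"]
    if (length(drops) > 1 && any(diff(drops) < tau_loss - 1e-9)) {
      stop("consecutive drops must be separated by at least tau_loss")
    }
    lens <- ev$kind[ev$kind %in% c("lens_on", "lens_off")]
    if (length(lens) > 0) {
      expected <- rep(c("lens_on", "lens_off"), length.out = length(lens))
      if (!identical(lens, expected)) {
        stop("lens_on/lens_off events must strictly alternate, starting with lens_on")
      }
    }
  }
  if (nrow(ev) > 0 && t_end <= max(ev$time_h)) {
    stop("t_end must exceed the last event time")
  }
  structure(ev, class = c("regimen", class(ev)), t_end = t_end)
}

#' @export
print.regimen <- function(x, ...) {
  cat("<regimen> horizon:", attr(x, "t_end"), "h,", nrow(x), "events\n")
  NextMethod()
}

#' Standard treatment regimens
#'
#' Builders for the treatment schedules studied for the in vivo human eye.
#'
#' * `drops_daily`: `n_drop` drops per day, the first at 0 h each day and
#'   subsequent drops every `16/n_drop` h (a 16-hour waking day), for
#'   `n_days` days.
#' * `drops_at_hours`: one drop per day at each of the given waking hours
#'   (e.g. `hours = 4:7 * 4` reproduces the four-drops-a-day schedule at
#'   4, 8, 12, 16 h).
#' * `lens_cycle`: lenses worn `n_day` days at a time with a 1-day break
#'   between lenses, for `n_cycles` cycles.
#' * `lens_continuous`: a single lens worn for the whole horizon.
#' * `injections`: boluses every `interval_weeks` weeks, the first at the
#'   start of week `first_week` (week k starts at global time (k-1)*168 h),
#'   up to `horizon_weeks`.
#' * `single_dose`: one event of the given kind at t = 0.
#'
#' Combined regimens are built by row-binding event tables, e.g.
#' `combine_regimens()`.
#'
#' @param name Regimen family (see Details).
#' @param n_drop Drops per day, integer in 1..16.
#' @param n_days Number of treated days (drops).
#' @param hours Waking hours (h offsets within each day) for `drops_at_hours`.
#' @param n_day Days each lens is worn, integer in 1..30.
#' @param n_cycles Number of lens cycles.
#' @param interval_weeks Weeks between injections, integer in 1..8.
#' @param first_week Week number of the first injection.
#' @param horizon_weeks,horizon_h Simulation horizon (give one).
#' @param kind Dose kind for `single_dose`.
#' @param params Parameter set (used only for drop-spacing validation).
#' @return A [regimen()].
#' @export
#' @examples
#' standard_regimen("injections", interval_weeks = 4, horizon_weeks = 16)
standard_regimen <- function(name = c("drops_daily", "drops_at_hours", "lens_cycle",
                                      "lens_continuous", "injections", "single_dose"),
                             n_drop = 16, n_days = NULL, hours = NULL,
                             n_day = 30, n_cycles = 4,
                             interval_weeks = 4, first_week = 1,
                             horizon_weeks = NULL, horizon_h = NULL,
                             kind = c("drop", "injection", "lens_on"),
                             params = eye_params("human")) {
  name <- match.arg(name)
  t_end <- if (!is.null(horizon_h)) horizon_h else
    if (!is.null(horizon_weeks)) horizon_weeks * 168 else NULL
  ev <- switch(name,
    drops_daily = {
      if (n_drop < 1 || n_drop > 16 || n_drop != round(n_drop)) {
        stop("n_drop must be an integer in 1..16")
      }
      if (is.null(t_end)) t_end <- 12 * 168
      if (is.null(n_days)) n_days <- ceiling(t_end / 24)
      times <- as.vector(outer((seq_len(n_drop) - 1) * 16 / n_drop,
                               (seq_len(n_days) - 1) * 24, `+`))
      tibble::tibble(time_h = sort(times[times < t_end]), kind = "drop")
    },
    drops_at_hours = {
      if (is.null(hours)) stop("drops_at_hours needs `hours`")
      if (is.null(t_end)) stop("give a horizon")
      if (is.null(n_days)) n_days <- ceiling(t_end / 24)
      times <- as.vector(outer(hours, (seq_len(n_days) - 1) * 24, `+`))
      tibble::tibble(time_h = sort(times[times < t_end]), kind = "drop")
    },
    lens_cycle = {
      if (n_day < 1 || n_day > 30 || n_day != round(n_day)) {
        stop("n_day must be an integer in 1..30")
      }
      cycle_h <- (n_day + 1) * 24
      on <- (seq_len(n_cycles) - 1) * cycle_h
      off <- on + n_day * 24
      if (is.null(t_end)) t_end <- n_cycles * cycle_h
      tibble::tibble(
        time_h = as.vector(rbind(on, off)),
        kind = rep(c("lens_on", "lens_off"), n_cycles)
      )
    },
    lens_continuous = {
      if (is.null(t_end)) stop("give a horizon")
      tibble::tibble(time_h = 0, kind = "lens_on")
    },
    injections = {
      if (interval_weeks < 1 || interval_weeks > 8 ||
          interval_weeks != round(interval_weeks)) {
        stop("interval_weeks must be an integer in 1..8")
      }
      if (is.null(t_end)) stop("give a horizon")
      start <- (first_week - 1) * 168
      step <- interval_weeks * 168
      k <- floor((t_end - start) / step - 1e-9)
      tibble::tibble(time_h = start + step * (0:k), kind = "injection")
    },
    single_dose = {
      kind <- match.arg(kind)
      if (is.null(t_end)) stop("give a horizon")
      tibble::tibble(time_h = 0, kind = kind)
    }
  )
  regimen(ev, t_end = t_end, tau_loss = params$tau_loss)
}

#' Combine regimens
#'
#' Merges the event tables of several regimens into one (the horizon is the
#' maximum). When an injection coincides with a drop, the drop is applied
#' first; the two touch disjoint state variables, so the order is a
#' determinism convention, not a modeling choice.
#'
#' @param ... [regimen()] objects.
#' @param params Parameter set used for validation.
#' @return A [regimen()].
#' @export
combine_regimens <- function(..., params = eye_params("human")) {
  regs <- list(...)
  ev <- dplyr::bind_rows(lapply(regs, function(r) tibble::as_tibble(r)))
  regimen(ev, t_end = max(vapply(regs, attr, numeric(1), "t_end")),
          tau_loss = params$tau_loss)
}

#' Serialize a regimen to JSON
#'
#' @param reg A [regimen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regimen <- function(reg, path) {
  jsonlite::write_json(
    list(t_end = attr(reg, "t_end"),
         events = as.data.frame(reg)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_regimen
#' @export
read_regimen <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- if (length(x$events) == 0) NULL else as.data.frame(x$events)
  regimen(ev, t_end = x$t_end)
}
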