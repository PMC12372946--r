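# Synthetic pseudo-measurements with the design of the ex vivo porcine
# experiment, for parameter-recovery testing of the fitting and MCMC code.

#' Generate synthetic ELISA-like measurements
#'
#' Simulates the chosen ex vivo porcine submodel at known ("true")
#' parameters, then draws `n_rep` noisy replicates per (time, compartment,
#' analyte) and returns their means and sds in the measurement schema of
#' [porcine_measurements()]. The noise is additive Gaussian with
#' `sd = max(sd_floor, sd_prop * signal)`, truncated at zero — mimicking an
#' ELISA with a detection floor (the real data contain exact zeros there).
#' With `sd_prop = sd_floor = 0` the means are the exact model trajectory
#' and the sds are zero.
#'
#' The seed fans out to one stream per replicate, so increasing `n_rep`
#' extends the replicate set without reshuffling earlier replicates.
#'
#' @param true_params Porcine [eye_params()] holding the true values
#'   (including the permeabilities to be recovered).
#' @param case `"topical"` or `"intravitreal"` design.
#' @param times Measurement times, h.
#' @param n_rep Replicates per point.
#' @param sd_prop Proportional noise scale (fraction of the signal).
#' @param sd_floor Absolute noise floor, pmol mL^-1.
#' @param seed RNG seed.
#' @param t_init,init For the intravitreal design, the initialization time
#'   and state (defaults: nominal bolus at t = 0).
#' @return A measurement tibble (`group`, `analyte`, `compartment`,
#'   `time_h`, `mean`, `sd`, `n`).
#' @export
#' @examples
#' p <- eye_params("porcine")
#' generate_measurements(p, "topical", sd_prop = 0, n_rep = 3, seed = 1)
generate_measurements <- function(true_params,
                                  case = c("topical", "intravitreal"),
                                  times = c(1 / 3, 2 / 3, 1, 3.5),
                                  n_rep = 3, sd_prop = 0.2, sd_floor = 0,
                                  seed = 1, t_init = 0, init = NULL) {
  case <- match.arg(case)
  p <- validate_eye_params(true_params)
  if (sd_prop < 0 || sd_floor < 0) stop("noise scales must be non-negative")
  times <- sort(times)

  if (case == "topical") {
    sol <- .lin_sol(.topical_matrix(p$beta_tear_aq_r, p$beta_aq_vit_r, p),
                    c(p$r_dose, 0, 0), times)
    truth <- tibble::tibble(
      group = "topical_cpp", analyte = "RBZ",
      compartment = rep(c("Aq", "Vit"), each = length(times)),
      time_h = rep(times, 2),
      signal = c(sol[2, ], sol[3, ])
    )
  } else {
    if (is.null(init)) {
      init <- c(r_aq = 0, r_vit = p$r_dose * p$V_drop / p$V_vit)
    }
    lam <- p$beta_aq_vit_r * p$A_aq_vit * (1 / p$V_aq + 1 / p$V_vit)
    r_eq <- (p$V_aq * init[["r_aq"]] + p$V_vit * init[["r_vit"]]) /
      (p$V_aq + p$V_vit)
    aq <- r_eq + (init[["r_aq"]] - r_eq) * exp(-lam * (times - t_init))
    vit <- r_eq + (init[["r_vit"]] - r_eq) * exp(-lam * (times - t_init))
    truth <- tibble::tibble(
      group = "invit_plain", analyte = "RBZ",
      compartment = rep(c("Aq", "Vit"), each = length(times)),
      time_h = rep(times, 2),
      signal = c(aq, vit)
    )
  }

  sds <- pmax(sd_floor, sd_prop * truth$signal)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  reps <- vapply(seq_len(n_rep), function(k) {
    set.seed(rep_seeds[k])
    pmax(0, truth$signal + stats::rnorm(nrow(truth), 0, sds))
  }, numeric(nrow(truth)))
  reps <- matrix(reps, nrow = nrow(truth))

  out <- truth
  out$mean <- rowMeans(reps)
  out$sd <- if (n_rep > 1) apply(reps, 1, stats::sd) else 0
  out$n <- n_rep
  if (sd_prop == 0 && sd_floor == 0) {
    out$mean <- truth$signal
    out$sd <- 0
  }
  out$signal <- NULL
  out[, .measurement_cols]
}
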