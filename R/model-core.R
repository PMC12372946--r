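# Core model: state container, mass-action reaction terms, tear-volume
# algebra, and the full ODE right-hand side (reference R implementation;
# simulate_eye() uses the compiled equivalent in src/).

# Order of the integrated state vector. Tear volume is algebraic and is not
# integrated.
.state_names <- c("r_tear", "v_aq", "r_aq", "u_aq", "w_aq",
                  "v_vit", "r_vit", "u_vit", "w_vit")

#' Eye state
#'
#' The nine integrated concentration variables (pmol mL^-1): free drug in
#' the tear film, and VEGF (v), free drug (r), the 1:1 complex VR (u), and
#' the 2:1 complex RVR (w) in the aqueous and vitreous. Tear volume is
#' algebraic (see [tear_volume()]) and is reported alongside trajectories
#' rather than stored here.
#'
#' @param r_tear,v_aq,r_aq,u_aq,w_aq,v_vit,r_vit,u_vit,w_vit Concentrations,
#'   pmol mL^-1; all must be non-negative.
#' @return A named numeric vector of class `eye_state`.
#' @export
eye_state <- function(r_tear = 0, v_aq = 0, r_aq = 0, u_aq = 0, w_aq = 0,
                      v_vit = 0, r_vit = 0, u_vit = 0, w_vit = 0) {
  y <- c(r_tear = r_tear, v_aq = v_aq, r_aq = r_aq, u_aq = u_aq, w_aq = w_aq,
         v_vit = v_vit, r_vit = r_vit, u_vit = u_vit, w_vit = w_vit)
  if (any(y < 0)) stop("eye_state concentrations must be non-negative")
  structure(y, class = "eye_state")
}

#' Mass-action binding/unbinding rates
#'
#' VEGF carries two identical drug-binding sites, each binding with rate
#' `k_on` and unbinding with rate `k_off` independently of the other site's
#' occupancy. Hence free VEGF binds drug at rate `2*k_on*v*r` (two empty
#' sites), the 2:1 complex dissociates at `2*k_off*w` (either arm can
#' leave), and the single-step rates follow by mass action.
#'
#' @param v,r,u,w Concentrations of VEGF, free drug, the 1:1 complex, and
#'   the 2:1 complex (pmol mL^-1); must be non-negative.
#' @param k_on Per-site binding rate, pmol^-1 mL h^-1.
#' @param k_off Per-site unbinding rate, h^-1.
#' @return Named numeric vector `c(dv, dr, du, dw)` of reaction-only rates.
#'   These conserve moles: `dv + du + dw == 0` (VEGF units) and
#'   `dr + du + 2*dw == 0` (drug units).
#' @export
#' @examples
#' reaction_terms(1, 1, 0, 0, k_on = 0.576, k_off = 2.63e-2)
reaction_terms <- function(v, r, u, w, k_on, k_off) {
  if (any(c(v, r, u, w) < 0)) stop("reaction_terms: concentrations must be non-negative")
  bind1 <- 2 * k_on * v * r   # V + R -> VR
  unb1 <- k_off * u           # VR -> V + R
  bind2 <- k_on * r * u       # R + VR -> RVR
  unb2 <- 2 * k_off * w       # RVR -> R + VR
  c(dv = unb1 - bind1,
    dr = (unb1 - bind1) + (unb2 - bind2),
    du = -unb1 + bind1 + unb2 - bind2,
    dw = -unb2 + bind2)
}

#' Tear-film volume
#'
#' Algebraic tear volume as a function of local time (time since the last
#' drop). For the human depleting case, the volume decays linearly from the
#' reservoir volume back to the normal tear-film volume over `tau_loss`; the
#' Heaviside cutoff uses H(0) = 1, so the volume is still at its depleting
#' branch value exactly at `t = tau_loss`. For the ex vivo porcine
#' depleting case, the entire drop runs off (no tear film can be
#' maintained), reaching zero volume at `tau_loss`.
#'
#' @param t_local Time since the last drop, h (non-negative).
#' @param params An [eye_params()] object.
#' @param config A [model_config()] object (uses `tear_volume_mode`).
#' @return Volume, mL (vectorized over `t_local`).
#' @export
tear_volume <- function(t_local, params, config) {
  if (any(t_local < 0)) stop("tear_volume: t_local must be non-negative")
  H <- function(x) as.numeric(x >= 0) # H(0) = 1
  switch(config$tear_volume_mode,
    constant_norm = rep(params$V_tear_norm, length(t_local)),
    depleting_human = params$V_tear_norm +
      (params$V_tear_res - params$V_tear_norm) *
        (1 - t_local / params$tau_loss) * H(params$tau_loss - t_local),
    constant_drop_porcine = rep(params$V_drop, length(t_local)),
    depleting_porcine = params$V_drop *
      (1 - t_local / params$tau_loss) * H(params$tau_loss - t_local)
  )
}

#' ODE right-hand side (reference implementation)
#'
#' Time-derivatives of the nine concentration variables for a given
#' configuration. Per compartment and chemical species the contributions
#' are: mass-action reactions ([reaction_terms()]), first-order decay,
#' tear-to-aqueous drug influx (when the tear compartment is active),
#' symmetric aqueous-vitreous exchange proportional to the concentration
#' difference, aqueous dilution by turnover, retinal VEGF supply, and
#' vitreo-retinal loss of drug species. The tear equation divides by the
#' current (algebraic) tear volume; in the porcine run-off case the tear
#' compartment is frozen once the volume reaches zero.
#'
#' `simulate_eye()` integrates a compiled translation of this function;
#' this R version is exported as the readable reference and for tests.
#'
#' @param t_local Local time since the last drop, h.
#' @param state Named numeric vector in [eye_state()] order.
#' @param params An [eye_params()] object (already ex vivo-resolved if
#'   applicable; see [model_config()]).
#' @param config A [model_config()] object.
#' @return Named numeric vector of derivatives, pmol mL^-1 h^-1.
#' @export
eye_rhs <- function(t_local, state, params, config) {
  p <- params
  y <- state
  d <- stats::setNames(numeric(9), .state_names)

  # tear film
  flux_tear_aq <- 0
  if (config$tear_active) {
    if (config$tear_conc_mode == "held_constant") {
      d["r_tear"] <- 0
      flux_tear_aq <- p$beta_tear_aq_r * p$A_tear_aq * y[["r_tear"]]
    } else {
      Vt <- tear_volume(t_local, p, config)
      if (Vt > 0) {
        d["r_tear"] <- -(p$beta_tear_aq_r * p$A_tear_aq + p$psi_tear) /
          Vt * y[["r_tear"]]
        flux_tear_aq <- p$beta_tear_aq_r * p$A_tear_aq * y[["r_tear"]]
      } # else: volume fully run off; compartment frozen, no corneal flux
    }
  }

  beta_av <- c(v = p$beta_aq_vit_v, r = p$beta_aq_vit_r,
               u = p$beta_aq_vit_u, w = p$beta_aq_vit_w)
  beta_vr <- c(r = p$beta_vit_ret_r, u = p$beta_vit_ret_u, w = p$beta_vit_ret_w)
  delta_aq <- c(v = p$delta_aq_v, r = p$delta_aq_r,
                u = p$delta_aq_u, w = p$delta_aq_w)
  delta_vit <- c(v = p$delta_vit_v, r = p$delta_vit_r,
                 u = p$delta_vit_u, w = p$delta_vit_w)

  rx_aq <- reaction_terms(y[["v_aq"]], y[["r_aq"]], y[["u_aq"]], y[["w_aq"]],
                          p$k_on, p$k_off)
  rx_vit <- reaction_terms(y[["v_vit"]], y[["r_vit"]], y[["u_vit"]], y[["w_vit"]],
                           p$k_on, p$k_off)

  for (sp in c("v", "r", "u", "w")) {
    aq <- paste0(sp, "_aq"); vit <- paste0(sp, "_vit")
    diff_av <- y[[vit]] - y[[aq]]
    exch_aq <- beta_av[[sp]] * p$A_aq_vit / p$V_aq * diff_av
    exch_vit <- -beta_av[[sp]] * p$A_aq_vit / p$V_vit * diff_av
    d[aq] <- rx_aq[[paste0("d", sp)]] - delta_aq[[sp]] * y[[aq]] +
      exch_aq - p$psi_aq / p$V_aq * y[[aq]]
    d[vit] <- rx_vit[[paste0("d", sp)]] - delta_vit[[sp]] * y[[vit]] + exch_vit
    if (sp == "r") d[aq] <- d[aq] + flux_tear_aq / p$V_aq
    if (sp == "v") d[vit] <- d[vit] + p$phi_vit_v / p$V_vit
    if (sp != "v" && beta_vr[[sp]] > 0) {
      # loss to retina/choroid (one-way; choroidal blood flow clears it)
      d[vit] <- d[vit] - beta_vr[[sp]] * p$A_vit_ret / p$V_vit * y[[vit]]
    }
  }

  if (!config$vegf_active) {
    for (nm in c("v_aq", "u_aq", "w_aq", "v_vit", "u_vit", "w_vit")) d[nm] <- 0
    # rebuild the drug equations without reaction terms
    d["r_aq"] <- -p$delta_aq_r * y[["r_aq"]] +
      p$beta_aq_vit_r * p$A_aq_vit / p$V_aq * (y[["r_vit"]] - y[["r_aq"]]) -
      p$psi_aq / p$V_aq * y[["r_aq"]] + flux_tear_aq / p$V_aq
    d["r_vit"] <- -p$delta_vit_r * y[["r_vit"]] -
      p$beta_aq_vit_r * p$A_aq_vit / p$V_vit * (y[["r_vit"]] - y[["r_aq"]])
    if (p$beta_vit_ret_r > 0) {
      d["r_vit"] <- d["r_vit"] - p$beta_vit_ret_r * p$A_vit_ret / p$V_vit * y[["r_vit"]]
    }
  }
  d
}

#' Total drug-equivalent concentration
#'
#' Total ranibizumab R_Tot = r + u + 2w: each 1:1 complex carries one drug
#' molecule and each 2:1 complex carries two.
#'
#' @param r,u,w Free drug, 1:1 complex, and 2:1 complex concentrations.
#' @return Total drug concentration, pmol mL^-1 (vectorized).
#' @export
total_ranibizumab <- function(r, u = 0, w = 0) {
  r + u + 2 * w
}
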