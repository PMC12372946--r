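# Untreated VEGF steady state (no drug anywhere): used for initial
# conditions and as an analytic oracle for the simulator.

#' Untreated VEGF steady state
#'
#' Closed-form steady-state VEGF concentrations in the aqueous and vitreous
#' in the absence of drug. With zero degradation (the default), balancing
#' retinal supply against aqueous dilution gives `v_aq = phi_vit_v / psi_aq`
#' and balancing supply against aqueous-vitreous exchange gives
#' `v_vit = v_aq + phi_vit_v / (beta_aq_vit_v * A_aq_vit)`. With nonzero
#' degradation rates the 2x2 linear balance (exchange = dilution + decay in
#' the aqueous; supply = exchange + decay in the vitreous) is solved
#' directly; the two paths agree when the degradation rates are zero.
#'
#' @param params An [eye_params()] object.
#' @return Named numeric vector `c(v_aq, v_vit)`, pmol mL^-1.
#' @export
#' @examples
#' untreated_vegf_steady_state(eye_params("human"))
untreated_vegf_steady_state <- function(params) {
  p <- validate_eye_params(params)
  if (p$phi_vit_v == 0) return(c(v_aq = 0, v_vit = 0))
  ex <- p$beta_aq_vit_v * p$A_aq_vit
  # steady state of:
  #   0 = -delta_aq_v v_aq + ex/V_aq (v_vit - v_aq) - psi_aq/V_aq v_aq
  #   0 = -delta_vit_v v_vit - ex/V_vit (v_vit - v_aq) + phi/V_vit
  A <- rbind(
    c(-(p$delta_aq_v + (ex + p$psi_aq) / p$V_aq), ex / p$V_aq),
    c(ex / p$V_vit, -(p$delta_vit_v + ex / p$V_vit))
  )
  if (abs(det(A)) < .Machine$double.xmin) {
    stop("no untreated steady state: all VEGF sinks are zero")
  }
  v <- solve(A, c(0, -p$phi_vit_v / p$V_vit))
  c(v_aq = v[1], v_vit = v[2])
}
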