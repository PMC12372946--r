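# Model configurations: which compartments and species are active and how
# the tear film behaves. A configuration plus a parameter set fully
# determines the right-hand side of the ODE system.

#' Model configuration
#'
#' Selects the submodel variant: whether the tear compartment exists
#' (injection-only submodels drop it), how the tear volume evolves, whether
#' the tear drug concentration is held constant (drug-eluting lens worn) or
#' depletes, whether VEGF and its complexes are simulated (permeability
#' fitting runs switch them off), and whether the eye is ex vivo (which
#' forces tear/aqueous turnover, retinal VEGF supply, and retinal loss to
#' zero).
#'
#' @param tear_active Does the tear compartment exist?
#' @param tear_volume_mode One of `"constant_norm"` (normal tear volume,
#'   lens case), `"depleting_human"` (drop drains back to the normal volume
#'   in `tau_loss`), `"constant_drop_porcine"` (full drop volume retained on
#'   the ex vivo cornea), `"depleting_porcine"` (drop runs off completely in
#'   `tau_loss`; the tear compartment is then frozen).
#' @param tear_conc_mode `"held_constant"` (lens worn) or `"depleting"`.
#' @param vegf_active Include VEGF (V) and the complexes VR/RVR?
#' @param ex_vivo Ex vivo eye: no turnover, no VEGF supply, no retinal loss.
#' @return A list of class `model_config`.
#' @export
#' @examples
#' model_config()                     # in vivo human, drops
#' porcine_topical_config()           # ex vivo fitting submodel
model_config <- function(tear_active = TRUE,
                         tear_volume_mode = c("depleting_human", "constant_norm",
                                              "constant_drop_porcine", "depleting_porcine"),
                         tear_conc_mode = c("depleting", "held_constant"),
                         vegf_active = TRUE,
                         ex_vivo = FALSE) {
  tear_volume_mode <- match.arg(tear_volume_mode)
  tear_conc_mode <- match.arg(tear_conc_mode)
  if (tear_conc_mode == "held_constant" && tear_volume_mode != "constant_norm") {
    stop("held_constant tear concentration requires constant_norm tear volume")
  }
  structure(list(
    tear_active = isTRUE(tear_active),
    tear_volume_mode = tear_volume_mode,
    tear_conc_mode = tear_conc_mode,
    vegf_active = isTRUE(vegf_active),
    ex_vivo = isTRUE(ex_vivo)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", as.character(x[[nm]]), "\n")
  invisible(x)
}

#' @rdname model_config
#' @export
human_drops_config <- function(vegf_active = TRUE) {
  model_config(TRUE, "depleting_human", "depleting", vegf_active, FALSE)
}

#' @rdname model_config
#' @export
human_lens_config <- function(vegf_active = TRUE) {
  model_config(TRUE, "constant_norm", "held_constant", vegf_active, FALSE)
}

#' @rdname model_config
#' @export
human_injection_config <- function(vegf_active = TRUE) {
  model_config(FALSE, "constant_norm", "depleting", vegf_active, FALSE)
}

#' @rdname model_config
#' @param tear_volume_mode For the porcine topical submodel, either the
#'   constant-drop-volume case (default; favored by the model fits) or the
#'   depleting run-off case.
#' @export
porcine_topical_config <- function(vegf_active = FALSE,
                                   tear_volume_mode = c("constant_drop_porcine",
                                                        "depleting_porcine")) {
  tear_volume_mode <- match.arg(tear_volume_mode)
  model_config(TRUE, tear_volume_mode, "depleting", vegf_active, TRUE)
}

#' @rdname model_config
#' @export
porcine_injection_config <- function(vegf_active = FALSE) {
  model_config(FALSE, "constant_norm", "depleting", vegf_active, TRUE)
}

# Check that a config and a parameter set are mutually consistent, and
# return the effective parameters (ex vivo zeroes applied).
resolve_params <- function(params, config) {
  validate_eye_params(params)
  stopifnot(inherits(config, "model_config"))
  if (config$ex_vivo && params$species != "porcine") {
    stop("ex_vivo configurations require porcine parameters")
  }
  if (config$tear_active &&
      config$tear_volume_mode %in% c("constant_norm", "depleting_human") &&
      is.na(params$V_tear_norm)) {
    stop("tear_volume_mode ", config$tear_volume_mode,
         " needs V_tear_norm, which is NA for these parameters")
  }
  if (config$ex_vivo) {
    params$psi_tear <- 0
    params$psi_aq <- 0
    params$phi_vit_v <- 0
    params$beta_vit_ret_r <- 0
    params$beta_vit_ret_u <- 0
    params$beta_vit_ret_w <- 0
  }
  params
}
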