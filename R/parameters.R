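# Parameter sets for the human and porcine eye models.
#
# Units used package-wide: time h, volume mL, length cm, area cm^2,
# concentration pmol mL^-1. Since 1 cm^3 = 1 mL, a permeability times an
# area divided by a volume (beta * A / V) is a first-order rate in h^-1
# with no conversion factor.

.param_names <- c(
  "tau_loss", "V_drop", "V_tear_norm", "V_tear_res", "V_aq", "V_vit",
  "A_tear_aq", "A_aq_vit", "A_vit_ret",
  "k_on", "k_off",
  "delta_aq_v", "delta_aq_r", "delta_aq_u", "delta_aq_w",
  "delta_vit_v", "delta_vit_r", "delta_vit_u", "delta_vit_w",
  "beta_tear_aq_r",
  "beta_aq_vit_v", "beta_aq_vit_r", "beta_aq_vit_u", "beta_aq_vit_w",
  "beta_vit_ret_r", "beta_vit_ret_u", "beta_vit_ret_w",
  "phi_vit_v", "psi_tear", "psi_aq",
  "r_dose", "v_aq_init", "v_vit_init", "r_tear_init", "r_vit_init"
)

#' Default model parameters for the human or porcine eye
#'
#' Returns the full parameter set of the three-compartment ranibizumab/VEGF
#' model: geometry (volumes and interface areas), binding kinetics, interface
#' permeabilities, turnover and supply rates, degradation rates, and the dose
#' and initial concentrations. The human column describes the in vivo human
#' eye; the porcine column describes the ex vivo porcine eye used for
#' fitting, in which tear/aqueous turnover, retinal VEGF supply, and
#' vitreo-retinal loss are all zero (no active physiology post mortem).
#'
#' Fields without a porcine counterpart (normal tear-film volume, tear
#' reservoir volume, vitreo-retinal interface area) are `NA` for the porcine
#' eye; the model never uses them in porcine configurations.
#'
#' @param species `"human"` or `"porcine"`.
#' @return A named list of class `eye_params`. Degradation rates
#'   `delta_<compartment>_<species>` default to 0 (a simplifying
#'   assumption) but are retained as parameters because the sensitivity
#'   analysis varies them.
#' @export
#' @examples
#' p <- eye_params("human")
#' p$k_on   # pmol^-1 mL h^-1
eye_params <- function(species = c("human", "porcine")) {
  species <- match.arg(species)
  common <- list(
    tau_loss = 5.00e-2,   # h
    V_drop   = 4.50e-2,   # mL (drop and injection volume)
    k_on     = 0.576,     # pmol^-1 mL h^-1 (per binding site)
    k_off    = 2.63e-2,   # h^-1
    delta_aq_v = 0, delta_aq_r = 0, delta_aq_u = 0, delta_aq_w = 0,
    delta_vit_v = 0, delta_vit_r = 0, delta_vit_u = 0, delta_vit_w = 0,
    beta_aq_vit_v = 0.985,  # cm h^-1
    beta_aq_vit_r = 0.929,
    beta_aq_vit_u = 0.755,
    beta_aq_vit_w = 0.653,
    r_dose = 2.07e4       # pmol mL^-1
  )
  if (species == "human") {
    sp <- list(
      V_tear_norm = 6.35e-3, V_tear_res = 3.00e-2,
      V_aq = 0.160, V_vit = 4.50,
      A_tear_aq = 1.30, A_aq_vit = 0.349, A_vit_ret = 10.9,
      beta_tear_aq_r = 1.10e-6,
      beta_vit_ret_r = 6.80e-4, beta_vit_ret_u = 6.44e-4,
      beta_vit_ret_w = 6.23e-4,
      phi_vit_v = 2.34e-4, psi_tear = 7.20e-2, psi_aq = 0.150,
      v_aq_init = 1.56e-3, v_vit_init = 2.24e-3,
      r_tear_init = 1.81e4, r_vit_init = 2.07e2
    )
  } else {
    sp <- list(
      V_tear_norm = NA_real_, V_tear_res = NA_real_,
      V_aq = 0.310, V_vit = 3.10,
      A_tear_aq = 1.51, A_aq_vit = 0.301, A_vit_ret = NA_real_,
      beta_tear_aq_r = 5.93e-7,
      beta_vit_ret_r = 0, beta_vit_ret_u = 0, beta_vit_ret_w = 0,
      phi_vit_v = 0, psi_tear = 0, psi_aq = 0,
      v_aq_init = 0, v_vit_init = 0,
      r_tear_init = 2.07e4, r_vit_init = 4.29
    )
  }
  p <- c(common, sp)
  p <- p[.param_names]
  p$species <- species
  structure(p, class = "eye_params")
}

#' @export
print.eye_params <- function(x, ...) {
  cat("<eye_params> species:", x$species, "\n")
  vals <- unlist(x[.param_names])
  print(tibble::tibble(parameter = names(vals), value = unname(vals)), n = Inf)
  invisible(x)
}

validate_eye_params <- function(p) {
  stopifnot(inherits(p, "eye_params"))
  miss <- setdiff(.param_names, names(p))
  if (length(miss) > 0) {
    stop("eye_params missing fields: ", paste(miss, collapse = ", "))
  }
  vals <- unlist(p[.param_names])
  bad <- vals < 0 & !is.na(vals)
  if (any(bad)) {
    stop("negative parameter value(s): ", paste(names(vals)[bad], collapse = ", "))
  }
  if (identical(p$species, "human")) {
    if (!(p$V_tear_norm <= p$V_tear_res && p$V_tear_res <= p$V_tear_norm + p$V_drop)) {
      stop("tear volumes must satisfy V_tear_norm <= V_tear_res <= V_tear_norm + V_drop")
    }
  }
  invisible(p)
}

#' Modify a parameter set
#'
#' @param p An [eye_params()] object.
#' @param ... Named replacement values, e.g. `k_on = 1.2`.
#' @return The modified, re-validated parameter set.
#' @export
set_params <- function(p, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), c(.param_names, "species"))
  if (length(unknown) > 0) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- repl
  validate_eye_params(p)
  p
}

#' Write / read a parameter set to a flat key-value file
#'
#' Serializes every parameter (plus the species tag) to JSON or YAML with
#' keys equal to the field names. JSON is written at full double precision,
#' so factory values round-trip bit-exactly.
#'
#' @param p An [eye_params()] object.
#' @param path Output file; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `write_eye_params()` returns `path` invisibly; `read_eye_params()`
#'   returns an [eye_params()] object.
#' @export
write_eye_params <- function(p, path) {
  validate_eye_params(p)
  x <- p[c(.param_names, "species")]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 17)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_eye_params
#' @param path Input file.
#' @export
read_eye_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x <- lapply(x, function(v) if (is.null(v)) NA_real_ else v)
  p <- structure(x[c(.param_names, "species")], class = "eye_params")
  p[.param_names] <- lapply(p[.param_names], as.numeric)
  validate_eye_params(p)
  p
}

#' Biologically realistic parameter ranges for sensitivity analysis
#'
#' One row per tunable parameter of the in vivo human model, with its default
#' value and the range swept in the local sensitivity analysis. Degradation
#' rates share a single range and appear once per compartment/species pair.
#'
#' @return A tibble with columns `parameter`, `default`, `lo`, `hi`.
#' @export
sensitivity_ranges <- function() {
  d <- eye_params("human")
  delta_rows <- tibble::tibble(
    parameter = c("delta_aq_v", "delta_aq_r", "delta_aq_u", "delta_aq_w",
                  "delta_vit_v", "delta_vit_r", "delta_vit_u", "delta_vit_w"),
    default = 0, lo = 0, hi = 0.770
  )
  core <- tibble::tribble(
    ~parameter,        ~lo,       ~hi,
    "tau_loss",        1.67e-2,   8.33e-2,
    "V_drop",          4.05e-2,   4.95e-2,
    "V_tear_norm",     0.340e-2,  1.07e-2,
    "V_tear_res",      2.70e-2,   3.30e-2,
    "V_aq",            0.121,     0.286,
    "V_vit",           3.50,      5.40,
    "A_tear_aq",       1.04,      1.56,
    "A_aq_vit",        0.111,     0.521,
    "A_vit_ret",       9.81,      12.0,
    "k_on",            0.205,     4.21,
    "k_off",           1.40e-2,   3.60e-2,
    "beta_tear_aq_r",  0.990e-6,  1.21e-6,
    "beta_aq_vit_v",   0.887,     1.08,
    "beta_aq_vit_r",   0.836,     1.02,
    "beta_aq_vit_u",   0.680,     0.831,
    "beta_aq_vit_w",   0.588,     0.718,
    "beta_vit_ret_r",  6.12e-4,   7.48e-4,
    "beta_vit_ret_u",  5.80e-4,   7.08e-4,
    "beta_vit_ret_w",  5.61e-4,   6.85e-4,
    "phi_vit_v",       1.02e-4,   4.46e-4,
    "psi_tear",        0.300e-1,  1.32e-1,
    "psi_aq",          0.660e-1,  2.52e-1,
    "r_dose",          1.86e4,    2.28e4
  )
  core$default <- vapply(core$parameter, function(nm) d[[nm]], numeric(1))
  dplyr::bind_rows(core[, c("parameter", "default", "lo", "hi")], delta_rows)
}
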