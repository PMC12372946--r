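# ELISA measurement sets: the bundled ex vivo porcine concentrations and
# the schema shared with the synthetic-data generator.

.measurement_cols <- c("group", "analyte", "compartment", "time_h",
                       "mean", "sd", "n")

#' Ex vivo porcine ELISA measurements
#'
#' Mean and standard deviation of drug (RBZ) and VEGF concentrations in the
#' aqueous and vitreous of ex vivo porcine eyes at 20 min, 40 min, 1 h, and
#' 3.5 h after treatment (n = 3 eyes per point). Groups: `topical_cpp`
#' (topical drop of drug + cell-penetrating peptide), `invit_cpp`
#' (intravitreal drug + CPP), `invit_plain` (intravitreal drug alone), and
#' `control` (intravitreal sterile water; not tied to a time point, so
#' `time_h` is `NA`). Zero means are non-detects (below the ELISA
#' detection limit).
#'
#' @return A tibble with columns `group`, `analyte`, `compartment`,
#'   `time_h`, `mean` (pmol mL^-1), `sd` (pmol mL^-1), `n`.
#' @export
#' @examples
#' porcine_measurements() |> dplyr::filter(group == "topical_cpp", analyte == "RBZ")
porcine_measurements <- function() {
  path <- system.file("extdata", "porcine_elisa.csv", package = "ocuvegf")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$time_h <- d$time_min / 60
  tibble::as_tibble(d[, .measurement_cols])
}

validate_measurements <- function(d) {
  miss <- setdiff(.measurement_cols, names(d))
  if (length(miss) > 0) {
    stop("measurement set missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(d$mean < 0 | d$sd < 0, na.rm = TRUE)) {
    stop("measurement means and sds must be non-negative")
  }
  invisible(d)
}
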