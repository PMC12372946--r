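# broom-style tidiers for fit and MCMC objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a least-squares permeability fit
#'
#' @param x An `eye_fit` from [fit_topical()] or [fit_intravitreal()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate` (cm/h).
#' @export
tidy.eye_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.eye_fit
#' @return `glance()`: one row with `objective` (MSE, pmol^2 mL^-2),
#'   `converged`, `degenerate`, `n_obs`, `case`.
#' @export
glance.eye_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, converged = x$converged,
                 degenerate = x$degenerate, n_obs = nrow(x$data),
                 case = x$case)
}

#' Tidy a Metropolis-Hastings run
#'
#' @param x An `eye_mcmc` from [mcmc_permeability()].
#' @param ... Unused.
#' @return One row per parameter: posterior `mean`, `sd`, and central 95%
#'   interval, in natural (cm/h) units.
#' @export
tidy.eye_mcmc <- function(x, ...) {
  s <- x$samples
  tibble::tibble(
    term = colnames(s),
    mean = colMeans(s),
    sd = apply(s, 2, stats::sd),
    conf.low = apply(s, 2, stats::quantile, 0.025),
    conf.high = apply(s, 2, stats::quantile, 0.975)
  )
}

#' @rdname tidy.eye_mcmc
#' @return `glance()`: one row with `accept_rate`, `n_steps`, `burn_frac`,
#'   `seed`, `case`.
#' @export
glance.eye_mcmc <- function(x, ...) {
  tibble::tibble(accept_rate = x$accept_rate, n_steps = x$n_steps,
                 burn_frac = x$burn_frac, seed = x$seed, case = x$case)
}
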