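# Shared fixtures: parameter sets and a closed-system configuration used by
# the conservation properties.

hp <- eye_params("human")
pp <- eye_params("porcine")

# human parameters with every external source/sink switched off, so total
# VEGF and drug moles are conserved exactly
closed_params <- set_params(hp,
  psi_tear = 0, psi_aq = 0, phi_vit_v = 0, beta_tear_aq_r = 0,
  beta_vit_ret_r = 0, beta_vit_ret_u = 0, beta_vit_ret_w = 0
)

# volume-weighted total moles of VEGF and of drug across both inner
# compartments (the oracles for the conservation tests)
vegf_moles <- function(sim, p = hp) {
  p$V_aq * (sim$v_aq + sim$u_aq + sim$w_aq) +
    p$V_vit * (sim$v_vit + sim$u_vit + sim$w_vit)
}
drug_moles <- function(sim, p = hp) {
  p$V_aq * (sim$r_aq + sim$u_aq + 2 * sim$w_aq) +
    p$V_vit * (sim$r_vit + sim$u_vit + 2 * sim$w_vit)
}

rich_state <- function() {
  eye_state(v_aq = 1.2e-3, r_aq = 0.4, u_aq = 0.08, w_aq = 0.03,
            v_vit = 2.1e-3, r_vit = 1.3, u_vit = 0.15, w_vit = 0.06)
}

# relative-error expectation: all.equal() falls back to absolute
# comparison when the target is smaller than the tolerance, which would
# make checks on small concentrations vacuous
expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual / expected - 1), tol,
                      label = sprintf("|%.6g / %.6g - 1|", actual, expected))
}

# number of well-separated modes in a sample: kernel-density maxima above a
# tenth of the global mode, merging peaks whose intervening valley is
# shallow (finite-chain KDE wiggle, not structure)
n_modes <- function(x, floor_frac = 0.1, valley_frac = 0.8) {
  dens <- stats::density(x, adjust = 2)
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1
  peaks <- peaks[dens$y[peaks] > floor_frac * max(dens$y)]
  if (length(peaks) <= 1) return(length(peaks))
  merged <- peaks[1]
  for (pk in peaks[-1]) {
    prev <- merged[length(merged)]
    valley <- min(dens$y[prev:pk])
    if (valley < valley_frac * min(dens$y[prev], dens$y[pk])) {
      merged <- c(merged, pk)
    } else if (dens$y[pk] > dens$y[prev]) {
      merged[length(merged)] <- pk
    }
  }
  length(merged)
}
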