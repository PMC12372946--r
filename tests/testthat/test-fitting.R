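table5 <- porcine_measurements()

test_that("the bundled measurement set has the experimental design shape", {
  expect_equal(nrow(table5), 52)
  treated <- table5[table5$group != "control", ]
  expect_true(all(treated$n == 3))
  expect_setequal(round(unique(treated$time_h), 6),
                  round(c(1 / 3, 2 / 3, 1, 3.5), 6))
  # spot checks against the published table
  get <- function(g, a, c, t) table5$mean[table5$group == g & table5$analyte == a &
    table5$compartment == c & !is.na(table5$time_h) &
    abs(table5$time_h - t) < 1e-9]
  expect_equal(get("topical_cpp", "RBZ", "Aq", 3.5), 7.14e-2)
  expect_equal(get("topical_cpp", "RBZ", "Aq", 1), 0)
  expect_equal(get("invit_plain", "RBZ", "Aq", 1 / 3), 4.73e-2)
  expect_equal(get("invit_plain", "RBZ", "Vit", 1 / 3), 4.29)
  expect_equal(get("invit_cpp", "VEGF", "Vit", 3.5), 5.01e-5)
})

test_that("the closed-form submodel solutions agree with the ODE simulator", {
  # topical: drop as initial tear concentration, constant drop volume
  times <- c(1 / 3, 2 / 3, 1, 3.5)
  ana <- ocuvegf:::.topical_raq(pp$beta_tear_aq_r, pp$beta_aq_vit_r, pp, times)
  reg <- standard_regimen("single_dose", kind = "drop", horizon_h = 4,
                          params = pp)
  sim <- simulate_eye(reg, pp, porcine_topical_config(), dt_out = 1 / 60)
  num <- approx(sim$time_h, sim$r_aq, xout = times)$y
  expect_equal(num, ana, tolerance = 1e-6)

  # intravitreal: initialized from measured means at 20 min
  ana2 <- ocuvegf:::.invit_raq(pp$beta_aq_vit_r, pp, times[-1], 1 / 3,
                               4.73e-2, 4.29)
  sim2 <- simulate_eye(NULL, pp, porcine_injection_config(), t_end = 4,
                       t0 = 1 / 3, dt_out = 1 / 60,
                       state0 = eye_state(r_aq = 4.73e-2, r_vit = 4.29))
  num2 <- approx(sim2$time_h, sim2$r_aq, xout = times[-1])$y
  expect_equal(num2, ana2, tolerance = 1e-6)
})

test_that("both permeability fits recover the published estimates", {
  f1 <- fit_topical(table5, pp)
  expect_true(f1$converged)
  expect_false(f1$degenerate)
  expect_rel(f1$par[["beta_tear_aq_r"]], 5.93e-7, 0.05)
  expect_rel(f1$par[["beta_aq_vit_r"]], 0.929, 0.05)
  # the non-detect 1 h point was excluded, leaving three fitted means
  expect_equal(nrow(f1$data), 3)

  f2 <- fit_intravitreal(table5, pp)
  expect_rel(f2$par[["beta_aq_vit_r"]], 0.577, 0.05)

  td <- tidy(f1)
  expect_equal(td$term, c("beta_tear_aq_r", "beta_aq_vit_r"))
  g <- glance(f2)
  expect_true(g$objective >= 0)
  expect_equal(g$n_obs, 3)
})

test_that("the optimum is a fixed point of the optimizer", {
  f1 <- fit_topical(table5, pp)
  obj <- function(lq) {
    pred <- ocuvegf:::.topical_raq(10^lq[1], 10^lq[2], pp, f1$data$time_h)
    mean((pred - f1$data$mean)^2)
  }
  re <- stats::optim(log10(f1$par), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-12))
  expect_lt(f1$objective - re$value, 1e-12)
  expect_equal(10^unname(re$par), unname(f1$par), tolerance = 1e-4)
})

test_that("zero-noise synthetic data is recovered to better than 0.1%", {
  truth <- set_params(pp, beta_tear_aq_r = 8e-7, beta_aq_vit_r = 0.7)
  d <- generate_measurements(truth, "topical", sd_prop = 0, seed = 1)
  f <- fit_topical(d, pp)
  expect_rel(f$par[["beta_tear_aq_r"]], 8e-7, 1e-3)
  expect_rel(f$par[["beta_aq_vit_r"]], 0.7, 1e-3)

  truth2 <- set_params(pp, beta_aq_vit_r = 0.45)
  d2 <- generate_measurements(truth2, "intravitreal", sd_prop = 0, seed = 1,
                              t_init = 1 / 3,
                              init = c(r_aq = 4.73e-2, r_vit = 4.29))
  f2 <- fit_intravitreal(d2, pp)
  expect_rel(f2$par[["beta_aq_vit_r"]], 0.45, 1e-3)
})

test_that("a flat objective is flagged as degenerate", {
  # targets already at the mass-weighted equilibrium: any permeability fits
  r_eq <- (pp$V_aq * 4.73e-2 + pp$V_vit * 4.29) / (pp$V_aq + pp$V_vit)
  d <- tibble::tibble(
    group = "invit_plain", analyte = "RBZ",
    compartment = rep(c("Aq", "Vit"), each = 4),
    time_h = rep(c(1 / 3, 2 / 3, 1, 3.5), 2),
    mean = c(r_eq, r_eq, r_eq, r_eq, r_eq, r_eq, r_eq, r_eq),
    sd = 0, n = 3
  )
  f <- fit_intravitreal(d, pp, init = c(r_aq = r_eq, r_vit = r_eq))
  expect_true(f$degenerate)
})

test_that("including VEGF in the topical fit changes the estimates negligibly", {
  # both arms use the full ODE model as the objective, so the only
  # difference is whether VEGF binding competes for the drug
  f0 <- fit_topical(table5, pp)
  d <- ocuvegf:::.fit_data(table5, "topical_cpp")
  reg <- standard_regimen("single_dose", kind = "drop", horizon_h = 3.6,
                          params = pp)
  obj <- function(lq, vegf, p_base) {
    p2 <- set_params(p_base, beta_tear_aq_r = 10^lq[1],
                     beta_aq_vit_r = 10^lq[2])
    sim <- simulate_eye(reg, p2, porcine_topical_config(vegf_active = vegf),
                        dt_out = 1 / 30)
    pred <- stats::approx(sim$time_h, sim$r_aq, xout = d$time_h)$y
    mean((pred - d$mean)^2)
  }
  refit <- function(vegf, p_base) {
    stats::optim(log10(f0$par), obj, vegf = vegf, p_base = p_base,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 500))
  }
  # at the ex vivo defaults the initial VEGF is zero, so adding the VEGF
  # equations changes nothing at all
  expect_equal(10^refit(TRUE, pp)$par, 10^refit(FALSE, pp)$par,
               tolerance = 1e-8)
  # even seeding VEGF at the measured aqueous control level moves the
  # estimates by only a few percent
  p_v <- set_params(pp, v_aq_init = 9.87e-3, v_vit_init = 9.87e-3)
  expect_equal(10^unname(refit(TRUE, p_v)$par),
               10^unname(refit(FALSE, p_v)$par), tolerance = 0.05)
})
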