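test_that("an untreated eye stays at the VEGF steady state; ex vivo stays at zero", {
  sim <- simulate_eye(NULL, hp, human_injection_config(), t_end = 100, dt_out = 1)
  expect_lt(diff(range(sim$v_vit)) / sim$v_vit[1], 1e-3)
  expect_true(all(sim$r_vit == 0))

  sim0 <- simulate_eye(NULL, pp, porcine_injection_config(vegf_active = TRUE),
                       t_end = 10, state0 = eye_state())
  expect_true(all(as.matrix(sim0[, -(1:2)]) == 0))
})

test_that("a single injection collapses vitreal VEGF to the published minimum", {
  reg <- standard_regimen("single_dose", kind = "injection", horizon_h = 24)
  sim <- simulate_eye(reg, hp, human_injection_config())
  expect_equal(max(sim$r_vit), 207, tolerance = 2e-3)
  expect_rel(min(sim$v_vit), 2.21e-7, 0.02)
  # the minimum is reached shortly after the bolus (~tens of minutes)
  expect_lt(sim$time_h[which.min(sim$v_vit)], 1)
  # total drug just after the bolus counts the full dose
  first <- sim[1, ]
  expect_equal(first$r_tot_vit, 207, tolerance = 2e-3)
})

test_that("compiled and reference R integrators agree", {
  reg <- regimen(data.frame(time_h = c(0, 5, 24, 30),
                            kind = c("drop", "injection", "drop", "lens_on")),
                 t_end = 48)
  a <- simulate_eye(reg, hp, human_drops_config(), dt_out = 0.5,
                    rtol = 1e-10, atol = 1e-14)
  b <- simulate_eye(reg, hp, human_drops_config(), dt_out = 0.5,
                    rtol = 1e-10, atol = 1e-14, compiled = FALSE)
  expect_equal(a$time_h, b$time_h)
  am <- as.matrix(a[-1]); bm <- as.matrix(b[-1])
  scale <- matrix(apply(abs(am), 2, max), nrow(am), ncol(am), byrow = TRUE)
  expect_lt(max(abs(am - bm) / (scale + 1e-300), na.rm = TRUE), 1e-4)
})

test_that("closed-system moles are conserved along a trajectory", {
  sim <- simulate_eye(NULL, closed_params, human_injection_config(),
                      t_end = 10, state0 = rich_state())
  expect_lt(diff(range(vegf_moles(sim))) / vegf_moles(sim)[1], 1e-6)
  expect_lt(diff(range(drug_moles(sim))) / drug_moles(sim)[1], 1e-6)
})

test_that("splitting the integration at a zero dose does not change the trajectory", {
  p0 <- set_params(hp, r_dose = 0)
  reg <- regimen(data.frame(time_h = 5, kind = "injection"), t_end = 10)
  a <- simulate_eye(reg, p0, human_injection_config(), dt_out = 0.5,
                    state0 = rich_state())
  b <- simulate_eye(NULL, p0, human_injection_config(), t_end = 10,
                    dt_out = 0.5, state0 = rich_state())
  keep_a <- abs(a$time_h - 5) > 1e-6
  keep_b <- abs(b$time_h - 5) > 1e-6
  am <- as.matrix(a[keep_a, -(1:2)])
  bm <- as.matrix(b[keep_b, -(1:2)])
  expect_equal(am, bm, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("halving the solver tolerances barely moves the summary statistics", {
  reg <- standard_regimen("injections", interval_weeks = 4, horizon_weeks = 4)
  s1 <- summarize_window(simulate_eye(reg, hp, human_injection_config()),
                         c(0, 672))
  s2 <- summarize_window(simulate_eye(reg, hp, human_injection_config(),
                                      rtol = 5e-11, atol = 5e-15),
                         c(0, 672))
  expect_equal(as.matrix(s1[-1]), as.matrix(s2[-1]), tolerance = 1e-3)
})

test_that("sustained topical dosing settles to a regular periodic pattern", {
  reg <- standard_regimen("drops_daily", n_drop = 16, horizon_weeks = 12)
  sim <- simulate_eye(reg, hp, human_drops_config(), dt_out = 0.1)
  s69 <- summarize_window(sim, c(6, 9) * 168)
  s912 <- summarize_window(sim, c(9, 12) * 168)
  expect_equal(as.matrix(s69[-1]), as.matrix(s912[-1]), tolerance = 5e-3)
})

test_that("window summaries use the trapezoidal time average", {
  # constant trajectory: all three statistics equal the constant
  sim <- simulate_eye(NULL, hp, human_injection_config(), t_end = 50, dt_out = 1)
  s <- summarize_window(sim, c(10, 40))
  expect_equal(s$max[s$output == "v_vit"], s$min[s$output == "v_vit"],
               tolerance = 1e-3)
  # sawtooth oracle: piecewise-linear signal with known integral
  fake <- tibble::tibble(
    time_h = c(0, 1, 2, 3, 4),
    v_vit = c(0, 2, 0, 2, 0),
    r_tot_vit = c(1, 1, 5, 1, 1)
  )
  s2 <- summarize_window(fake, c(0, 4))
  expect_equal(s2$mean[s2$output == "v_vit"], 1)       # mean of sawtooth
  expect_equal(s2$mean[s2$output == "r_tot_vit"], 2)   # (1*1+3*2/2... ) / 4
  expect_equal(s2$max, c(2, 5))
  expect_equal(s2$min, c(0, 1))
  expect_error(summarize_window(fake, c(3, 9)), "span")
  expect_error(summarize_window(fake, c(2, 2)), "window")
})

test_that("trajectories carry the algebraic tear volume and dose bracketing", {
  reg <- regimen(data.frame(time_h = 24, kind = "drop"), t_end = 48)
  sim <- simulate_eye(reg, hp, human_drops_config())
  i_pre <- max(which(sim$time_h < 24))
  expect_equal(sim$V_tear[i_pre], hp$V_tear_norm)
  expect_equal(sim$V_tear[i_pre + 1], hp$V_tear_res, tolerance = 1e-6)
  # pre/post drop rows bracket the concentration jump
  expect_lt(sim$r_tear[i_pre], 1)
  expect_equal(sim$r_tear[i_pre + 1], 1.814e4, tolerance = 1e-3)
  expect_true(all(diff(sim$time_h) > 0))
})
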