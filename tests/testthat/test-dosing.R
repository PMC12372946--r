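test_that("drop mixing is the volume-weighted average of tear and dose", {
  s <- apply_drop(eye_state(), hp)
  expect_equal(s[["r_tear"]], 2.07e4 * 4.5e-2 / (6.35e-3 + 4.5e-2))
  expect_equal(s[["r_tear"]], 1.81e4, tolerance = 3e-3)
  # mixing identical fluids is a fixed point
  s2 <- apply_drop(eye_state(r_tear = hp$r_dose), hp)
  expect_equal(s2[["r_tear"]], hp$r_dose)
  # hand-evaluated convex combination
  s3 <- apply_drop(eye_state(r_tear = 1e3), hp)
  expect_equal(s3[["r_tear"]],
               1e3 * 6.35e-3 / 5.135e-2 + 2.07e4 * 4.5e-2 / 5.135e-2)
  expect_equal(s3[["r_tear"]], 1.826e4, tolerance = 1e-3)
  # everything else untouched
  s4 <- apply_drop(rich_state(), hp)
  expect_identical(unclass(s4)[-1], unclass(rich_state())[-1])
})

test_that("an injection raises vitreal drug by the bolus over the vitreal volume", {
  expect_equal(apply_injection(eye_state(), hp)[["r_vit"]],
               2.07e4 * 4.5e-2 / 4.5)
  expect_equal(apply_injection(eye_state(), hp)[["r_vit"]], 2.07e2,
               tolerance = 1e-3)
  expect_equal(apply_injection(eye_state(), pp)[["r_vit"]], 3.00e2,
               tolerance = 2e-3)
  # zero dose leaves the state untouched
  p0 <- set_params(hp, r_dose = 0)
  expect_identical(unclass(apply_injection(rich_state(), p0)),
                   unclass(rich_state()))
})

test_that("lens insertion pins the tear concentration; removal lets it decay", {
  res <- apply_lens(rich_state(), hp, on = TRUE)
  expect_equal(res$state[["r_tear"]], 1.81e4)
  expect_true(res$lens_on)
  # with no loss pathways the concentration stays put after removal
  p0 <- set_params(hp, beta_tear_aq_r = 0, psi_tear = 0)
  reg <- regimen(data.frame(time_h = c(0, 1), kind = c("lens_on", "lens_off")),
                 t_end = 5)
  sim <- simulate_eye(reg, p0, model_config(TRUE, "constant_norm", "depleting"))
  expect_equal(sim$r_tear[nrow(sim)], 1.81e4, tolerance = 1e-9)
  # post-removal decay rate is (beta A + psi_tear) / V_tear_norm
  rate <- (hp$beta_tear_aq_r * hp$A_tear_aq + hp$psi_tear) / hp$V_tear_norm
  expect_equal(rate, 11.34, tolerance = 1e-3)
  reg2 <- regimen(data.frame(time_h = c(0, 1), kind = c("lens_on", "lens_off")),
                  t_end = 1.5)
  sim2 <- simulate_eye(reg2, hp, model_config(TRUE, "constant_norm", "depleting"))
  at <- function(t) sim2$r_tear[which.min(abs(sim2$time_h - t))]
  expect_equal(at(1.4) / at(1.1), exp(-rate * 0.3), tolerance = 1e-6)
})

test_that("regimen validation enforces ordering, spacing, and alternation", {
  expect_error(regimen(data.frame(time_h = c(0, 0.01), kind = "drop"),
                       t_end = 1), "tau_loss")
  expect_error(regimen(data.frame(time_h = 0, kind = "lens_off"), t_end = 1),
               "alternate")
  expect_error(regimen(data.frame(time_h = c(0, 1), kind = c("lens_on", "lens_on")),
                       t_end = 2), "alternate")
  expect_error(regimen(data.frame(time_h = 5, kind = "drop"), t_end = 5),
               "t_end")
  expect_error(regimen(data.frame(time_h = 0, kind = "sip"), t_end = 1),
               "unknown event kind")
  # events are sorted on construction
  r <- regimen(data.frame(time_h = c(3, 1), kind = "injection"), t_end = 10)
  expect_equal(r$time_h, c(1, 3))
})

test_that("standard regimens emit the published schedules", {
  # 4-weekly injections over 16 weeks: starts of weeks 1, 5, 9, 13
  r <- standard_regimen("injections", interval_weeks = 4, horizon_weeks = 16)
  expect_equal(r$time_h, c(0, 672, 1344, 2016))
  # one drop per day at hour 0
  r1 <- standard_regimen("drops_daily", n_drop = 1, n_days = 3, horizon_h = 72)
  expect_equal(r1$time_h, c(0, 24, 48))
  # 16 drops per day at hours 0..15 (spacing 16/16 = 1 h)
  r16 <- standard_regimen("drops_daily", n_drop = 16, n_days = 2, horizon_h = 48)
  expect_equal(r16$time_h, c(0:15, 24 + 0:15))
  # lenses: 30 days on, 1 day off
  rl <- standard_regimen("lens_cycle", n_day = 30, n_cycles = 2, horizon_h = 1500)
  expect_equal(rl$time_h, c(0, 720, 744, 1464))
  expect_equal(rl$kind, rep(c("lens_on", "lens_off"), 2))
  expect_error(standard_regimen("drops_daily", n_drop = 0, horizon_h = 24),
               "1..16")
  expect_error(standard_regimen("lens_cycle", n_day = 31, horizon_h = 1e4),
               "1..30")
  expect_error(standard_regimen("injections", interval_weeks = 9,
                                horizon_weeks = 40), "1..8")
})

test_that("regimens combine and serialize losslessly", {
  inj <- standard_regimen("injections", interval_weeks = 4, horizon_weeks = 8)
  dr <- standard_regimen("drops_at_hours", hours = c(4, 8), horizon_weeks = 8)
  both <- combine_regimens(inj, dr)
  expect_equal(nrow(both), nrow(inj) + nrow(dr))
  expect_equal(attr(both, "t_end"), 8 * 168)
  f <- withr::local_tempfile(fileext = ".json")
  write_regimen(both, f)
  back <- read_regimen(f)
  expect_equal(as.data.frame(back), as.data.frame(both))
  expect_equal(attr(back, "t_end"), attr(both, "t_end"))
})

test_that("doses never change VEGF moles; injections add an exact drug bolus", {
  s <- rich_state()
  vegf_of <- function(st, p) p$V_aq * (st[["v_aq"]] + st[["u_aq"]] + st[["w_aq"]]) +
    p$V_vit * (st[["v_vit"]] + st[["u_vit"]] + st[["w_vit"]])
  expect_equal(vegf_of(apply_drop(s, hp), hp), vegf_of(s, hp))
  expect_equal(vegf_of(apply_injection(s, hp), hp), vegf_of(s, hp))
  drug_vit <- function(st, p) p$V_vit * (st[["r_vit"]] + st[["u_vit"]] + 2 * st[["w_vit"]])
  expect_equal(drug_vit(apply_injection(s, hp), hp) - drug_vit(s, hp),
               hp$r_dose * hp$V_drop)
})
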