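test_that("reaction terms match hand-evaluated mass action and conserve moles", {
  # empty system
  expect_equal(unname(reaction_terms(0, 0, 0, 0, hp$k_on, hp$k_off)),
               rep(0, 4))
  # v = r = 1, no complexes: only the first binding step fires at 2*k_on
  r1 <- reaction_terms(1, 1, 0, 0, k_on = 0.576, k_off = 2.63e-2)
  expect_equal(r1[["dv"]], -1.152)
  expect_equal(r1[["dr"]], -1.152)
  expect_equal(r1[["du"]], 1.152)
  expect_equal(r1[["dw"]], 0)
  expect_error(reaction_terms(-1, 0, 0, 0, 1, 1), "non-negative")

  # mole conservation identities on random states
  set.seed(42)
  for (i in 1:50) {
    x <- stats::runif(4, 0, 10)
    d <- reaction_terms(x[1], x[2], x[3], x[4], hp$k_on, hp$k_off)
    expect_equal(d[["dv"]] + d[["du"]] + d[["dw"]], 0)
    expect_equal(d[["dr"]] + d[["du"]] + 2 * d[["dw"]], 0)
  }
})

test_that("chemical equilibrium is a fixed point with u/(v r) = 2 k_on/k_off", {
  k_on <- 0.576; k_off <- 2.63e-2
  expect_equal(2 * k_on / k_off, 43.8, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:20) {
    v <- stats::runif(1, 1e-4, 5); r <- stats::runif(1, 1e-4, 5)
    u <- (2 * k_on / k_off) * v * r
    w <- (k_on / (2 * k_off)) * r * u
    d <- reaction_terms(v, r, u, w, k_on, k_off)
    expect_equal(unname(d), rep(0, 4), tolerance = 1e-10)
  }
})

test_that("tear volume follows the drainage law in every mode", {
  drops <- human_drops_config()
  expect_equal(tear_volume(0, hp, drops), 3.00e-2)
  expect_equal(tear_volume(hp$tau_loss / 2, hp, drops), 1.8175e-2)
  # H(0) = 1: at exactly tau_loss the depleting branch value is V_tear_norm
  expect_equal(tear_volume(hp$tau_loss, hp, drops), 6.35e-3)
  expect_equal(tear_volume(10, hp, drops), 6.35e-3)
  expect_error(tear_volume(-0.1, hp, drops), "non-negative")

  lens <- human_lens_config()
  expect_equal(tear_volume(c(0, 1, 100), hp, lens), rep(6.35e-3, 3))

  const_p <- porcine_topical_config()
  expect_equal(tear_volume(c(0, 5), pp, const_p), rep(4.5e-2, 2))
  depl_p <- porcine_topical_config(tear_volume_mode = "depleting_porcine")
  expect_equal(tear_volume(0, pp, depl_p), 4.5e-2)
  expect_equal(tear_volume(pp$tau_loss / 2, pp, depl_p), 2.25e-2)
  expect_equal(tear_volume(pp$tau_loss, pp, depl_p), 0)
  expect_equal(tear_volume(1, pp, depl_p), 0)
})

test_that("the RHS reduces to the retinal VEGF source at the zero state", {
  d <- eye_rhs(0, eye_state(), hp, human_drops_config())
  expect_equal(d[["v_vit"]], 2.34e-4 / 4.50)
  expect_rel(d[["v_vit"]], 5.2e-5, 1e-3)
  d_other <- d[setdiff(names(d), "v_vit")]
  expect_equal(unname(d_other), rep(0, 8))

  # ex vivo porcine: no sources at all
  d2 <- eye_rhs(0, eye_state(), pp, porcine_topical_config())
  expect_equal(unname(d2), rep(0, 9))
})

test_that("aqueous-vitreous exchange is antisymmetric in volume-weighted moles", {
  s <- rich_state()
  cfg <- human_injection_config()
  # with only exchange active, V_aq * d(aq) + V_vit * d(vit) must vanish
  p <- set_params(closed_params, k_on = 0, k_off = 0)
  d <- eye_rhs(0, s, p, cfg)
  for (sp in c("v", "r", "u", "w")) {
    flux <- abs(p$V_aq * d[[paste0(sp, "_aq")]])
    expect_lt(abs(p$V_aq * d[[paste0(sp, "_aq")]] +
                    p$V_vit * d[[paste0(sp, "_vit")]]),
              1e-14 * max(flux, 1e-6))
  }
})

test_that("drug-only dynamics equal the full model when no VEGF is present", {
  cfg_full <- porcine_injection_config(vegf_active = TRUE)
  cfg_roff <- porcine_injection_config(vegf_active = FALSE)
  s <- eye_state(r_aq = 0.3, r_vit = 2.5)
  d_full <- eye_rhs(0, s, pp, cfg_full)
  d_roff <- eye_rhs(0, s, pp, cfg_roff)
  expect_equal(d_full[c("r_aq", "r_vit")], d_roff[c("r_aq", "r_vit")])
  expect_equal(unname(d_roff[c("v_aq", "u_aq", "w_aq", "v_vit", "u_vit", "w_vit")]),
               rep(0, 6))
})

test_that("total drug counts both complex stoichiometries", {
  expect_equal(total_ranibizumab(1, 0, 0), 1)
  expect_equal(total_ranibizumab(0, 0, 1), 2)
  expect_equal(total_ranibizumab(c(1, 2), c(1, 0), c(0, 1)), c(2, 4))
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(tear_conc_mode = "held_constant",
                            tear_volume_mode = "depleting_human"),
               "constant_norm")
  expect_error(simulate_eye(NULL, hp, porcine_topical_config(), t_end = 1),
               "porcine")
  expect_error(eye_state(r_tear = -1), "non-negative")
})
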