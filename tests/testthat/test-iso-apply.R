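test_that("dose zero is the identity regardless of flags", {
  m <- build_model("boyett-central")
  m0 <- iso_apply(m, iso_action_set(0))
  expect_identical(m0$parameters, m$parameters)
})

test_that("enabled actions translate into the documented parameter changes", {
  m <- build_model("boyett-central")
  p <- iso_dose_params()
  mi <- iso_apply(m, iso_action_set(50), p)
  expect_equal(mi$parameters[["g_cal"]] / m$parameters[["g_cal"]],
               1 + 0.54 * 50 / 57, tolerance = 1e-12)      # ~1.474
  fk <- iso_fraction_ik(50, p)
  expect_equal(mi$parameters[["g_kr"]], m$parameters[["g_kr"]] * (1 + fk))
  expect_equal(mi$parameters[["g_ks"]], m$parameters[["g_ks"]] * (1 + fk))
  expect_equal(mi$parameters[["g_st"]],
               m$parameters[["g_st"]] * (1 + iso_fraction_ist(50, p)))
  expect_equal(mi$parameters[["shift_f"]], iso_shift_if(50, p))
  expect_equal(mi$parameters[["shift_kr"]], iso_shift_ikr_activation(50, p))
  expect_equal(mi$parameters[["taukr_scale"]], 1 + iso_taukr_factor(50, p))
  expect_gt(mi$parameters[["taukr_scale"]], 0)   # tau' stays positive
  expect_equal(mi$parameters[["p_rel"]], m$parameters[["p_rel"]] * 1.2)
  expect_equal(mi$parameters[["p_up"]], m$parameters[["p_up"]] * 0.8)
})

test_that("disabled actions leave their parameters bit-identical", {
  m <- build_model("boyett-peripheral")
  mi <- iso_apply(m, iso_action_set(120, enable_gk = FALSE, enable_if = FALSE,
                                    enable_ca_handling = FALSE))
  for (nm in c("g_kr", "g_ks", "shift_f", "p_up", "p_rel")) {
    expect_identical(mi$parameters[[nm]], m$parameters[[nm]])
  }
  expect_false(identical(mi$parameters[["g_cal"]], m$parameters[["g_cal"]]))
})

test_that("iso_apply is pure: repeated application from the same input matches", {
  m <- build_model("kurata-central")
  acts <- drop_unsupported_actions(m, iso_action_set(80), quiet = TRUE)
  a <- iso_apply(m, acts)
  b <- iso_apply(m, acts)
  expect_identical(a$parameters, b$parameters)
  # and the input model is untouched
  expect_identical(m$parameters, build_model("kurata-central")$parameters)
})

test_that("actions unsupported by the model raise, or are droppable with notice", {
  kc <- build_model("kurata-central")
  expect_error(iso_apply(kc, iso_action_set(50)),
               class = "sanpace_unsupported_action")
  expect_message(drop_unsupported_actions(kc, iso_action_set(50)),
                 "no ist action")
  acts <- drop_unsupported_actions(kc, iso_action_set(50), quiet = TRUE)
  expect_false(acts$enable_ist)
  expect_silent(iso_apply(kc, acts))
  # Boyett models support everything including I_st
  expect_silent(iso_apply(build_model("boyett-central"), iso_action_set(50)))
})

test_that("tau' remains positive across the full dose range", {
  p <- iso_dose_params()
  doses <- c(0, 10^seq(-1, 5, length.out = 50))
  scales <- 1 + iso_taukr_factor(doses, p)
  expect_true(all(scales >= 1))
  expect_true(all(1 / scales > 0.2))  # at saturation tau' = tau/4
})
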