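test_that("zero dose produces zero response for every curve", {
  p <- iso_dose_params()
  expect_identical(iso_fraction_ical(0, p), 0)
  expect_identical(iso_shift_if(0, p), 0)
  expect_identical(iso_fraction_ik(0, p), 0)
  expect_identical(iso_shift_ikr_activation(0, p), 0)
  expect_identical(iso_taukr_factor(0, p), 0)
  expect_identical(iso_fraction_ist(0, p), 0)
})

test_that("each curve returns exactly half its maximum at its K0.5", {
  p <- iso_dose_params()
  expect_equal(iso_fraction_ical(p$k_ca, p), p$f_ca_max / 2, tolerance = 1e-15)
  expect_equal(iso_fraction_ik(p$k_gk, p), p$f_k_max / 2, tolerance = 1e-15)
  expect_equal(iso_shift_ikr_activation(p$k_kacti, p), p$s_k_max / 2,
               tolerance = 1e-15)
  expect_equal(iso_taukr_factor(p$k_taukr, p), p$dtau_kr_max / 2,
               tolerance = 1e-15)
  expect_equal(iso_fraction_ist(p$k_st, p), p$f_st_max / 2, tolerance = 1e-15)
  # Hill-exponent form: relative tolerance 1e-12
  expect_equal(iso_shift_if(p$k_f, p), p$s_f_max / 2, tolerance = 1e-12)
})

test_that("curves reproduce independently computed scalar values", {
  # frozen from direct arithmetic: fmax * d / (k + d), etc.
  expect_equal(iso_fraction_ical(7), 0.27)
  expect_equal(iso_fraction_ical(63), 0.54 * 63 / 70)  # 0.486
  expect_equal(iso_fraction_ical(63), 0.486, tolerance = 1e-12)
  expect_equal(iso_shift_if(13.5), 4.81, tolerance = 1e-3)
  expect_equal(iso_shift_if(50),
               9.62 * 50^0.392 / (13.5^0.392 + 50^0.392), tolerance = 1e-15)
  expect_equal(iso_fraction_ik(19), 0.935)
  expect_equal(iso_fraction_ik(500), 1.87 * 500 / 519, tolerance = 1e-15)
  expect_equal(iso_shift_ikr_activation(7.5), -7.5)
  expect_equal(iso_shift_ikr_activation(50), -15 * 50 / 57.5, tolerance = 1e-15)
  expect_equal(iso_taukr_factor(24), 1.5)
  expect_equal(iso_taukr_factor(100), 3 * 100 / 124, tolerance = 1e-15)
  expect_equal(iso_fraction_ist(33), 0.5)
  expect_equal(iso_fraction_ist(330), 330 / 363, tolerance = 1e-15)
})

test_that("curves are monotone and saturate at their printed maxima", {
  p <- iso_dose_params()
  doses <- 10^seq(-2, 6, length.out = 200)
  curves <- list(
    list(f = iso_fraction_ical, max = p$f_ca_max, k = p$k_ca),
    list(f = iso_shift_if, max = p$s_f_max, k = p$k_f),
    list(f = iso_fraction_ik, max = p$f_k_max, k = p$k_gk),
    list(f = iso_shift_ikr_activation, max = p$s_k_max, k = p$k_kacti),
    list(f = iso_taukr_factor, max = p$dtau_kr_max, k = p$k_taukr),
    list(f = iso_fraction_ist, max = p$f_st_max, k = p$k_st)
  )
  hill_n <- c(1, p$n_f, 1, 1, 1, 1)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    y <- cv$f(doses, p)
    expect_true(all(diff(abs(y)) > 0))            # strictly increasing magnitude
    expect_true(all(abs(y) <= abs(cv$max) + 1e-12))
    # within 1% of the maximum at the dose where (K/d)^n = 0.01
    # (1e4 x K0.5 for the Hill-1 curves, further out for n_f = 0.392)
    d_sat <- cv$k * 100^(2 / hill_n[i])
    expect_equal(cv$f(d_sat, p), cv$max, tolerance = 0.01)
  }
})

test_that("negative doses and invalid parameters are rejected", {
  expect_error(iso_fraction_ical(-1), ">= 0")
  expect_error(iso_shift_if(c(10, -0.5)), ">= 0")
  expect_error(iso_dose_params(k_ca = 0), "strictly positive")
  expect_error(iso_dose_params(n_f = -1), "n_f")
})

test_that("dose parsing handles unit suffixes", {
  expect_equal(parse_dose("0.05 uM"), 50)
  expect_equal(parse_dose("50 nM"), 50)
  expect_equal(parse_dose("50"), 50)
  expect_equal(parse_dose(c("1 uM", "250 nM")), c(1000, 250))
  expect_equal(parse_dose(0.5), 0.5)
  expect_error(parse_dose("50 mM"), "Cannot parse")
  expect_error(parse_dose("-5 nM"), "Cannot parse|Invalid")
})

test_that("action sets validate their inputs", {
  a <- iso_action_set(50, enable_taukr = FALSE)
  expect_s3_class(a, "iso_action_set")
  expect_false(a$enable_taukr)
  expect_error(iso_action_set(-1), ">= 0")
  expect_error(iso_action_set(c(1, 2)), "scalar")
  expect_error(iso_action_set(10, enable_if = NA), "TRUE or FALSE")
})

test_that("response table is consistent with the scalar curves", {
  tab <- iso_response_table(c(0, 7, 24, 500))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$f_ca, iso_fraction_ical(c(0, 7, 24, 500)))
  expect_equal(tab$d_tau_kr[3], 1.5)
  expect_true(all(tab[1, -1] == 0))
})
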