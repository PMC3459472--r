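short <- list(settle_ms = 6000, window_ms = 4000, output_dt = 0.25)

test_that("a dose grid of only zero gives all-zero deltas", {
  tab <- do.call(dose_response, c(list("boyett-central", 0), short))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$delta_rate_pct, 0)
  expect_equal(tab$delta_mdp_mv, 0)
})

test_that("dose-response includes control, parses units and reports status", {
  tab <- do.call(dose_response, c(list("boyett-central", "0.05 uM"), short))
  expect_equal(tab$dose_nm, c(0, 50))
  expect_true(all(c("status", "delta_rate_pct", "delta_cl_pct",
                    "delta_mdp_mv") %in% names(tab)))
  expect_gt(tab$delta_rate_pct[2], 0)  # ISO accelerates
})

test_that("leave_one_out validates the action name and disables one flag", {
  expect_error(leave_one_out("boyett-central", 50, omit = "nonexistent"),
               "must be one of")
  tab <- do.call(leave_one_out,
                 c(list("boyett-central", 50, omit = "taukr"), short))
  expect_equal(unique(tab$omitted), "taukr")
  full <- do.call(dose_response, c(list("boyett-central", 50), short))
  # removing the deactivation-rate action weakens the chronotropic response
  expect_lt(tab$delta_rate_pct[tab$dose_nm == 50],
            full$delta_rate_pct[full$dose_nm == 50])
})

test_that("omitting an action a model lacks equals the all-actions run", {
  note <- capture.output(
    loo <- do.call(leave_one_out, c(list("kurata-central", 50, omit = "ist"), short)),
    type = "message")
  expect_true(any(grepl("no ist action", note)))
  full <- do.call(dose_response, c(list("kurata-central", 50), short))
  expect_equal(loo$delta_rate_pct, full$delta_rate_pct, tolerance = 1e-12)
})

test_that("only_one_in runs exactly one action and rejects absent ones", {
  expect_error(only_one_in("kurata-central", 50, keep = "ist"),
               class = "sanpace_unsupported_action")
  res <- do.call(only_one_in,
                 c(list("boyett-central", 50, keep = "ca_handling"), short))
  expect_equal(res$kept, "ca_handling")
  expect_true(is.finite(res$delta_rate_pct))
})

test_that("Ca-handling action with unit SR scales is a no-op", {
  p <- iso_dose_params(sr_release_scale = 1, sr_uptake_scale = 1)
  res <- do.call(only_one_in,
                 c(list("boyett-central", 50, keep = "ca_handling", params = p),
                   short))
  expect_equal(res$delta_rate_pct, 0, tolerance = 1e-9)
  expect_equal(res$delta_mdp_mv, 0, tolerance = 1e-9)
})

test_that("I_Ks block experiment reports paired prolongations", {
  tab <- do.call(iks_block_experiment, c(list("boyett-central", "10 nM"), short))
  expect_equal(tab$condition, c("control", "iso"))
  expect_equal(tab$dose_nm, c(0, 10))
  expect_true(all(is.finite(tab$cl_prolongation_pct)))
  # blocking I_Ks never shortens the cycle
  expect_true(all(tab$cl_prolongation_pct > -0.5))
})

test_that("figure-trace export pairs control and treated windows", {
  tab <- export_figure_traces("boyett-central", 50, "taukr-only",
                              window_ms = 800, output_dt = 0.5)
  expect_setequal(unique(tab$condition), c("control", "treated"))
  expect_true(all(c("vm", "i_cal", "i_f", "i_k", "i_kr", "i_naca", "cai")
                  %in% names(tab)))
  # dose 0: treated is identical to control
  tab0 <- export_figure_traces("boyett-central", 0, "all-actions",
                               window_ms = 800, output_dt = 0.5)
  ctrl <- tab0[tab0$condition == "control", "vm"]
  trt <- tab0[tab0$condition == "treated", "vm"]
  expect_identical(ctrl, trt)
})

test_that("experiment cache returns identical results and can be cleared", {
  m <- build_model("kurata-central")
  f1 <- sanpace:::steady_features_cached(m, settle_ms = 6000, window_ms = 4000,
                                         output_dt = 0.25)
  f2 <- sanpace:::steady_features_cached(m, settle_ms = 6000, window_ms = 4000,
                                         output_dt = 0.25)
  expect_identical(f1, f2)
  expect_gt(clear_experiment_cache(), 0)
})
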