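the_cache <- new.env(parent = emptyenv())

steady_features_cached <- function(model, settle_ms = 20000, window_ms = 10000,
                                   output_dt = 0.1, rtol = 1e-7, atol = 1e-9,
                                   use_cache = TRUE) {
  key <- rlang::hash(list(model$name, model$parameters, settle_ms, window_ms,
                          output_dt, rtol, atol))
  if (use_cache && !is.null(the_cache[[key]])) return(the_cache[[key]])
  tr <- run_to_steady(model, settle_ms = settle_ms, window_ms = window_ms,
                      output_dt = output_dt, rtol = rtol, atol = atol)
  conv <- attr(tr, "convergence")
  feats <- if (identical(conv$status, "quiescent")) {
    tibble::tibble(cycle_length = NA_real_, rate = NA_real_, mdp = NA_real_,
                   overshoot = NA_real_, amplitude = NA_real_,
                   apd50 = NA_real_, apd90 = NA_real_, dvdt_max = NA_real_,
                   cai_diastolic = NA_real_, cai_systolic = NA_real_,
                   n_beats_analyzed = 0L)
  } else {
    compute_features(tr)
  }
  feats$status <- conv$status
  feats$converged <- isTRUE(conv$converged)
  if (use_cache) the_cache[[key]] <- feats
  feats
}

#' Clear the in-memory experiment cache
#'
#' Steady-state runs are cached by a content hash of (model name, parameter
#' table, engine settings); clearing is only needed if memory matters.
#' @return Invisibly, the number of entries removed.
#' @export
clear_experiment_cache <- function() {
  n <- length(ls(the_cache))
  rm(list = ls(the_cache), envir = the_cache)
  invisible(n)
}

resolve_actions <- function(model, dose, template = NULL, quiet = TRUE) {
  acts <- if (is.null(template)) {
    iso_action_set(dose)
  } else {
    template$dose <- dose
    template
  }
  drop_unsupported_actions(model, acts, quiet = quiet)
}

#' Concentration-response experiment
#'
#' Runs the model to steady pacing at each ISO dose (the dose-0 control is
#' always included) and reports the action-potential features together with
#' the changes relative to control: `delta_rate_pct` (frequency basis),
#' `delta_cl_pct` (percentage decrease of cycle length) and `delta_mdp_mv`.
#'
#' @param model_name One of [model_names()].
#' @param doses ISO concentrations in nM (numeric) or strings with unit
#'   suffix (see [parse_dose()]).
#' @param actions Optional [iso_action_set()] template whose flags are used
#'   at every dose (its dose field is ignored). Default: all actions enabled.
#' @param params An [iso_dose_params()] object.
#' @param ... Engine settings passed to the steady-state runner
#'   (`settle_ms`, `window_ms`, `output_dt`, `rtol`, `atol`, `use_cache`).
#' @return A tibble with one row per dose. Non-converged or quiescent runs
#'   are flagged in the `status` column, not fatal.
#' @examples
#' \donttest{
#' dose_response("boyett-central", c(5, 50))
#' }
#' @export
dose_response <- function(model_name, doses, actions = NULL,
                          params = iso_dose_params(), ...) {
  doses <- parse_dose(doses)
  doses <- sort(unique(c(0, doses)))
  model <- build_model(model_name)
  rows <- purrr::map(doses, function(d) {
    acts <- resolve_actions(model, d, actions)
    m <- iso_apply(model, acts, params)
    f <- steady_features_cached(m, ...)
    f$dose_nm <- d
    f
  })
  tab <- dplyr::bind_rows(rows)
  ctrl <- tab[tab$dose_nm == 0, ]
  out <- dplyr::bind_cols(
    tibble::tibble(model = model_name, dose_nm = tab$dose_nm),
    tab[setdiff(names(tab), "dose_nm")],
    delta_features(ctrl[rep(1, nrow(tab)), ], tab)
  )
  class(out) <- c("san_dose_response", class(out))
  out
}

#' Leave-one-out dissection: omit a single ISO action
#'
#' As [dose_response()], but with one named action disabled at every dose.
#' Omitting an action the model does not possess (e.g. `ist` on Kurata
#' models) runs with the flag silently off plus an informative notice.
#'
#' @inheritParams dose_response
#' @param omit One of [iso_action_names()].
#' @return A dose-response tibble (see [dose_response()]).
#' @export
leave_one_out <- function(model_name, doses, omit, params = iso_dose_params(),
                          ...) {
  if (!(omit %in% iso_action_names())) {
    rlang::abort(sprintf("`omit` must be one of: %s.",
                         paste(iso_action_names(), collapse = ", ")))
  }
  model <- build_model(model_name)
  if (!(omit %in% model$supports)) {
    rlang::inform(sprintf(
      "Model '%s' has no %s action; omission is a no-op.", model_name, omit))
  }
  args <- list(dose = 0)
  args[[paste0("enable_", omit)]] <- FALSE
  template <- do.call(iso_action_set, args)
  out <- dose_response(model_name, doses, actions = template, params = params, ...)
  out$omitted <- omit
  out
}

#' Single-action dissection: keep exactly one ISO action
#'
#' Runs control and treated steady states with exactly one action enabled.
#'
#' @inheritParams dose_response
#' @param dose ISO concentration (nM or string with unit).
#' @param keep One of [iso_action_names()].
#' @return One-row tibble with features of the treated run and deltas vs
#'   control.
#' @export
only_one_in <- function(model_name, dose, keep, params = iso_dose_params(),
                        ...) {
  if (!(keep %in% iso_action_names())) {
    rlang::abort(sprintf("`keep` must be one of: %s.",
                         paste(iso_action_names(), collapse = ", ")))
  }
  dose <- parse_dose(dose)
  model <- build_model(model_name)
  if (!(keep %in% model$supports)) {
    rlang::abort(sprintf("Model '%s' has no %s action.", model_name, keep),
                 class = "sanpace_unsupported_action")
  }
  args <- as.list(stats::setNames(rep(FALSE, length(iso_action_names())),
                                  paste0("enable_", iso_action_names())))
  args[[paste0("enable_", keep)]] <- TRUE
  acts <- do.call(iso_action_set, c(list(dose = dose), args))
  ctrl <- steady_features_cached(model, ...)
  treat <- steady_features_cached(iso_apply(model, acts, params), ...)
  dplyr::bind_cols(
    tibble::tibble(model = model_name, dose_nm = dose, kept = keep),
    treat,
    delta_features(ctrl, treat)
  )
}

#' I_Ks block experiment
#'
#' Four steady runs (g_Ks normal / zero, crossed with ISO absent / present)
#' reporting the percentage cycle-length prolongation caused by I_Ks block
#' in each condition. Mirrors the pharmacological test in which I_Ks block
#' barely affects control pacing but prolongs the cycle under
#' beta-adrenergic stimulation.
#'
#' @inheritParams dose_response
#' @param dose ISO concentration applied in the ISO arm (nM or unit string).
#' @return A tibble with one row per condition (`control`, `iso`): cycle
#'   lengths with and without block and `cl_prolongation_pct`.
#' @export
iks_block_experiment <- function(model_name, dose, params = iso_dose_params(),
                                 ...) {
  dose <- parse_dose(dose)
  model <- build_model(model_name)
  blocked <- model
  blocked$parameters[["g_ks"]] <- 0
  arm <- function(m, d) {
    acts <- resolve_actions(m, d)
    steady_features_cached(iso_apply(m, acts, params), ...)
  }
  f_ctrl <- arm(model, 0);  f_ctrl_blk <- arm(blocked, 0)
  f_iso <- arm(model, dose); f_iso_blk <- arm(blocked, dose)
  prol <- function(a, b) (b$cycle_length / a$cycle_length - 1) * 100
  tibble::tibble(
    model = model_name,
    condition = c("control", "iso"),
    dose_nm = c(0, dose),
    cl_ms = c(f_ctrl$cycle_length, f_iso$cycle_length),
    cl_blocked_ms = c(f_ctrl_blk$cycle_length, f_iso_blk$cycle_length),
    cl_prolongation_pct = c(prol(f_ctrl, f_ctrl_blk), prol(f_iso, f_iso_blk)),
    status = paste(f_ctrl$status, f_ctrl_blk$status, sep = "/")
  )
}

#' Export aligned control/treated traces for a scenario
#'
#' Produces the paired steady-state traces (control plus treated) used for
#' waveform figures: membrane potential, the main modulated currents and
#' the Ca2+ transient.
#'
#' @inheritParams dose_response
#' @param dose ISO concentration (nM or unit string).
#' @param scenario One of `"all-actions"`, `"no-if-shift"`, `"taukr-only"`,
#'   `"ca-only"`.
#' @param window_ms Length of the exported steady window (default 1500 ms).
#' @param output_dt Sampling interval (default 0.1 ms).
#' @return A tibble: both traces stacked long, with a `condition` column
#'   (`control` / `treated`).
#' @export
export_figure_traces <- function(model_name, dose, scenario = "all-actions",
                                 window_ms = 1500, output_dt = 0.1,
                                 params = iso_dose_params()) {
  scenario <- match.arg(scenario,
                        c("all-actions", "no-if-shift", "taukr-only", "ca-only"))
  dose <- parse_dose(dose)
  model <- build_model(model_name)
  acts <- switch(scenario,
    "all-actions" = iso_action_set(dose),
    "no-if-shift" = iso_action_set(dose, enable_if = FALSE),
    "taukr-only" = iso_action_set(dose, enable_ical = FALSE, enable_if = FALSE,
                                  enable_gk = FALSE, enable_ikr_shift = FALSE,
                                  enable_ist = FALSE, enable_ca_handling = FALSE),
    "ca-only" = iso_action_set(dose, enable_ical = FALSE, enable_if = FALSE,
                               enable_gk = FALSE, enable_ikr_shift = FALSE,
                               enable_taukr = FALSE, enable_ist = FALSE)
  )
  acts <- drop_unsupported_actions(model, acts, quiet = TRUE)
  treated <- iso_apply(model, acts, params)
  one <- function(m, label) {
    tr <- run_to_steady(m, window_ms = window_ms, output_dt = output_dt)
    df <- tibble::as_tibble(tr)
    df$condition <- label
    df
  }
  out <- dplyr::bind_rows(one(model, "control"),
                          if (dose > 0) one(treated, "treated") else {
                            df <- one(model, "treated"); df
                          })
  out$model <- model_name
  out$scenario <- scenario
  out$dose_nm <- dose
  out
}

#' Plot a dose-response table
#'
#' @param object A [dose_response()] result.
#' @param y Which response to plot: `"delta_cl_pct"` (default, percentage
#'   decrease of pacemaking cycle length) or `"delta_rate_pct"`.
#' @param ... Unused.
#' @return A ggplot object with a log-scaled dose axis.
#' @export
autoplot.san_dose_response <- function(object, y = c("delta_cl_pct", "delta_rate_pct"),
                                       ...) {
  y <- match.arg(y)
  dat <- object[object$dose_nm > 0, ]
  lab <- if (y == "delta_cl_pct") "decrease of cycle length (%)" else "rate increase (%)"
  ggplot2::ggplot(dat, ggplot2::aes(.data$dose_nm, .data[[y]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[ISO] (nM)", y = lab, title = unique(dat$model)) +
    ggplot2::theme_minimal()
}
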