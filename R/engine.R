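#' Integrate a SAN cell model and return a uniformly sampled trace
#'
#' Integrates the model's stiff ODE system with [deSolve::ode()] (LSODA by
#' default, compiled right-hand side) and returns membrane potential, all
#' observable currents (pA) and intracellular Ca2+ on a uniform time grid.
#' SAN cells are autonomous: no stimulus current exists anywhere in the
#' engine.
#'
#' @param model A [build_model()] specification (possibly ISO-modified via
#'   [iso_apply()]).
#' @param duration Simulated duration, ms (> 0).
#' @param output_dt Output sampling interval, ms (default 0.1).
#' @param init Optional initial state (defaults to `model$initial_state`).
#' @param rtol,atol Solver tolerances (defaults 1e-7 / 1e-9).
#' @param method deSolve integration method (default `"lsoda"`).
#' @param keep_states Keep the full state matrix as attribute `"states"`.
#' @return A `san_trace` tibble: `time` (ms), `vm` (mV), `cai` (mM) and one
#'   column per observable current (pA).
#' @examples
#' \donttest{
#' tr <- run(build_model("boyett-central"), duration = 2000)
#' }
#' @export
run <- function(model, duration, output_dt = 0.1, init = NULL,
                rtol = 1e-7, atol = 1e-9, method = "lsoda",
                keep_states = FALSE) {
  stopifnot(inherits(model, "san_model"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    rlang::abort("`duration` must be a positive number of milliseconds.")
  }
  if (!is.numeric(output_dt) || output_dt <= 0) {
    rlang::abort("`output_dt` must be > 0 ms.")
  }
  times <- seq(0, duration, by = output_dt)
  if (length(times) < 2L) rlang::abort("`duration` must cover at least one output step.")
  y0 <- if (is.null(init)) model$initial_state else {
    if (!is.null(names(init))) init <- init[model$state_labels]
    stats::setNames(as.double(init), model$state_labels)
  }
  out <- deSolve::ode(
    y = y0, times = times, func = model$derivs_func,
    parms = unname(model$parameters), dllname = "sanpace",
    initfunc = model$init_func,
    nout = length(model$current_names), outnames = model$current_names,
    method = method, rtol = rtol, atol = atol, maxsteps = 50000
  )
  if (nrow(out) < length(times) || anyNA(out[, "v"]) ||
      any(!is.finite(out[, "v"]))) {
    ok <- which(stats::complete.cases(out) & is.finite(out[, "v"]))
    last_t <- if (length(ok)) out[max(ok), "time"] else 0
    rlang::abort(
      sprintf("Solver failed (NaN state or step-size collapse); last valid time %.3f ms.",
              last_t),
      class = "sanpace_solver_failure", last_valid_time = last_t
    )
  }
  df <- tibble::as_tibble(as.data.frame(out))
  trace <- tibble::tibble(time = df$time, vm = df$v, cai = df$cai)
  for (nm in model$current_names) trace[[nm]] <- df[[nm]]
  attr(trace, "model_name") <- model$name
  attr(trace, "output_dt") <- output_dt
  attr(trace, "solver") <- list(method = method, rtol = rtol, atol = atol)
  attr(trace, "final_state") <- stats::setNames(
    as.double(df[nrow(df), model$state_labels]), model$state_labels)
  if (keep_states) attr(trace, "states") <- as.matrix(df[model$state_labels])
  class(trace) <- c("san_trace", class(trace))
  trace
}

#' @export
print.san_trace <- function(x, ...) {
  cat(sprintf("<san_trace> model %s, %.0f ms at %.3g ms resolution\n",
              attr(x, "model_name"), max(x$time) - min(x$time),
              attr(x, "output_dt")))
  conv <- attr(x, "convergence")
  if (!is.null(conv)) {
    cat(sprintf("  steady-state: %s (%d beats, CL %.2f ms)\n",
                conv$status, conv$n_beats,
                if (is.na(conv$cl_mean)) NA_real_ else conv$cl_mean))
  }
  NextMethod()
}

settle_state <- function(model, settle_ms, init, rtol, atol, method) {
  times <- seq(0, settle_ms, by = 10)
  out <- deSolve::ode(
    y = init, times = times, func = model$derivs_func,
    parms = unname(model$parameters), dllname = "sanpace",
    initfunc = model$init_func, nout = 0,
    method = method, rtol = rtol, atol = atol, maxsteps = 50000
  )
  last <- out[nrow(out), ]
  if (anyNA(last) || any(!is.finite(last))) {
    rlang::abort("Solver failed during the settle phase.",
                 class = "sanpace_solver_failure")
  }
  stats::setNames(as.double(last[-1]), model$state_labels)
}

#' Integrate to steady pacing
#'
#' Discards an initial transient, then returns an analysis window sampled at
#' `output_dt` together with a convergence report. Convergence requires the
#' relative difference between successive cycle lengths in the window to stay
#' below `cl_tolerance`. If the window shows fewer than two upstrokes the run
#' is reported as `"quiescent"` ("pacemaking ceased") - a scientific outcome,
#' not an error.
#'
#' @inheritParams run
#' @param settle_ms Transient to discard before analysis (default 20000 ms).
#' @param window_ms Analysis window length (default 10000 ms).
#' @param cl_tolerance Relative cycle-length tolerance (default 0.001 = 0.1%).
#' @param max_extensions Additional settle/analyse rounds before flagging
#'   non-convergence (default 2).
#' @return A `san_trace` with attribute `"convergence"`: a list with
#'   `status` ("converged", "not-converged" or "quiescent"), `converged`,
#'   `n_beats`, `cl_mean` and `cl_max_rel_diff`.
#' @export
run_to_steady <- function(model, settle_ms = 20000, window_ms = 10000,
                          output_dt = 0.1, cl_tolerance = 0.001,
                          max_extensions = 2,
                          rtol = 1e-7, atol = 1e-9, method = "lsoda") {
  stopifnot(inherits(model, "san_model"))
  if (!is.numeric(cl_tolerance) || cl_tolerance <= 0) {
    rlang::abort("`cl_tolerance` must be > 0.")
  }
  state <- model$initial_state
  trace <- NULL
  report <- NULL
  for (round in seq_len(max_extensions + 1L)) {
    state <- settle_state(model, settle_ms, state, rtol, atol, method)
    trace <- run(model, duration = window_ms, output_dt = output_dt,
                 init = state, rtol = rtol, atol = atol, method = method)
    beats <- tryCatch(detect_beats(trace), sanpace_insufficient_beats = function(e) NULL)
    if (is.null(beats)) {
      report <- list(status = "quiescent", converged = FALSE, n_beats = 0L,
                     cl_mean = NA_real_, cl_max_rel_diff = NA_real_)
      break
    }
    cls <- diff(beats$t_upstroke)
    rel <- if (length(cls) >= 2) abs(diff(cls)) / cls[-length(cls)] else Inf
    if (all(utils::tail(rel, 3) < cl_tolerance)) {
      report <- list(status = "converged", converged = TRUE,
                     n_beats = nrow(beats), cl_mean = mean(cls),
                     cl_max_rel_diff = max(utils::tail(rel, 3)))
      break
    }
    report <- list(status = "not-converged", converged = FALSE,
                   n_beats = nrow(beats), cl_mean = mean(cls),
                   cl_max_rel_diff = if (length(rel)) max(utils::tail(rel, 3)) else NA_real_)
  }
  attr(trace, "convergence") <- report
  trace
}

#' Write a trace to tidy CSV with a JSON metadata sidecar
#'
#' @param trace A `san_trace`.
#' @param path Output CSV path; a `.json` sidecar with run metadata (model,
#'   solver settings, convergence) is written next to it.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "san_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  meta <- list(
    model = attr(trace, "model_name"),
    output_dt = attr(trace, "output_dt"),
    solver = attr(trace, "solver"),
    convergence = attr(trace, "convergence")
  )
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Plot a simulation trace
#'
#' @param object A `san_trace`.
#' @param series Columns to plot (default membrane potential plus the main
#'   currents present in the trace).
#' @param ... Unused.
#' @return A ggplot object, one facet per series.
#' @export
autoplot.san_trace <- function(object,
                               series = intersect(
                                 c("vm", "i_cal", "i_f", "i_k", "i_st", "cai"),
                                 names(object)),
                               ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time", dplyr::all_of(series)),
    -"time", names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = series)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = attr(object, "model_name")) +
    ggplot2::theme_minimal()
}
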