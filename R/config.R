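#' Load and validate a run configuration
#'
#' Reads a YAML run specification, rejects unknown keys, fills defaults and
#' normalizes units (doses to nM). A minimal config names only the model:
#'
#' ```yaml
#' model: boyett-central
#' dose: 0.05 uM
#' actions:
#'   taukr: true
#' solver:
#'   rtol: 1.0e-7
#' ```
#'
#' Every action flag omitted from `actions` defaults to `true`.
#'
#' @param path Path to a YAML file.
#' @return A validated run specification (class `san_run_config`): a list
#'   with `model`, `dose_nm`, `actions` (named logical vector), `solver`
#'   (`rtol`, `atol`, `settle_ms`, `window_ms`, `output_dt`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Config file '%s' not found.", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

config_defaults <- function() {
  list(
    dose = 0,
    actions = stats::setNames(as.list(rep(TRUE, length(iso_action_names()))),
                              iso_action_names()),
    solver = list(rtol = 1e-7, atol = 1e-9, settle_ms = 20000,
                  window_ms = 10000, output_dt = 0.1)
  )
}

#' Validate an already-parsed configuration list
#'
#' The programmatic core of [load_config()]: checks keys, fills defaults,
#' normalizes units.
#'
#' @param raw A named list as produced by parsing a config file.
#' @return A `san_run_config`.
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) rlang::abort("Config must be a YAML mapping.")
  allowed <- c("model", "dose", "actions", "solver")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown config key(s): %s.",
                         paste(unknown, collapse = ", ")))
  }
  if (is.null(raw$model)) rlang::abort("Config must name a `model`.")
  if (!(raw$model %in% model_names())) {
    rlang::abort(sprintf("Config key `model`: unknown model '%s'.", raw$model))
  }
  defaults <- config_defaults()
  dose_nm <- parse_dose(raw$dose %||% defaults$dose)
  acts <- defaults$actions
  if (!is.null(raw$actions)) {
    bad <- setdiff(names(raw$actions), iso_action_names())
    if (length(bad)) {
      rlang::abort(sprintf("Config key `actions`: unknown action(s) %s.",
                           paste(bad, collapse = ", ")))
    }
    for (k in names(raw$actions)) {
      if (!is.logical(raw$actions[[k]])) {
        rlang::abort(sprintf("Config key `actions.%s` must be true/false.", k))
      }
      acts[[k]] <- raw$actions[[k]]
    }
  }
  solver <- defaults$solver
  if (!is.null(raw$solver)) {
    bad <- setdiff(names(raw$solver), names(solver))
    if (length(bad)) {
      rlang::abort(sprintf("Config key `solver`: unknown setting(s) %s.",
                           paste(bad, collapse = ", ")))
    }
    for (k in names(raw$solver)) {
      v <- raw$solver[[k]]
      if (!is.numeric(v) || v <= 0) {
        rlang::abort(sprintf("Config key `solver.%s` must be a positive number.", k))
      }
      solver[[k]] <- v
    }
  }
  structure(
    list(model = raw$model, dose_nm = dose_nm,
         actions = unlist(acts), solver = solver),
    class = "san_run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes the resolved specification back to YAML; `load_config()` of the
#' result round-trips to an identical specification.
#'
#' @param config A `san_run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "san_run_config"))
  yaml::write_yaml(list(
    model = config$model,
    dose = paste(config$dose_nm, "nM"),
    actions = as.list(config$actions),
    solver = config$solver
  ), path)
  invisible(path)
}

#' @export
print.san_run_config <- function(x, ...) {
  on <- names(x$actions)[x$actions]
  cat(sprintf("<san_run_config> %s, %g nM; actions: %s\n", x$model, x$dose_nm,
              paste(on, collapse = ", ")))
  invisible(x)
}

#' Execute a run configuration
#'
#' Builds the model, applies the ISO action set, integrates to steady
#' pacing and returns trace plus features. When `out_dir` is given, writes
#' `trace.csv` (+ JSON sidecar), `features.json` and a resolved copy of the
#' configuration for provenance.
#'
#' @param config A `san_run_config` (from [load_config()]).
#' @param out_dir Optional output directory.
#' @param params An [iso_dose_params()] object.
#' @return List with elements `trace` (a `san_trace`) and `features`.
#' @export
run_config <- function(config, out_dir = NULL, params = iso_dose_params()) {
  stopifnot(inherits(config, "san_run_config"))
  model <- build_model(config$model)
  acts <- do.call(iso_action_set, c(
    list(dose = config$dose_nm),
    stats::setNames(as.list(config$actions),
                    paste0("enable_", names(config$actions)))
  ))
  acts <- drop_unsupported_actions(model, acts)
  treated <- iso_apply(model, acts, params)
  sv <- config$solver
  tr <- run_to_steady(treated, settle_ms = sv$settle_ms,
                      window_ms = sv$window_ms, output_dt = sv$output_dt,
                      rtol = sv$rtol, atol = sv$atol)
  feats <- compute_features(tr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace(tr, file.path(out_dir, "trace.csv"))
    jsonlite::write_json(as.list(feats), file.path(out_dir, "features.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    save_config(config, file.path(out_dir, "config.yaml"))
  }
  list(trace = tr, features = feats)
}
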