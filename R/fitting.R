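#' Fit a Hill-type concentration-response curve
#'
#' Least-squares fit of `response = max * dose^n / (k^n + dose^n)` to a
#' dose-response point table, the curve form behind all six ISO relations.
#' The Hill coefficient is fixed at 1 by default (the form of five of the
#' six relations); pass `fix_n = NULL` to estimate it (the I_f-shift case).
#'
#' The fit is deterministic: starting values follow a fixed rule
#' (`max` = maximum response, `k` = median positive dose, `n` = 1) and the
#' optimizer is Levenberg-Marquardt ([minpack.lm::nlsLM()]) with box
#' constraints `max` in (0, 10 * max response], `k` in (0, 1e6], `n` in
#' (0, 5].
#'
#' @param points Data frame with columns `dose` (nM, >= 0) and `response`.
#' @param fix_n Fixed Hill coefficient (default 1); `NULL` to estimate.
#' @return An object of class `hill_fit` with [tidy()], [glance()] and
#'   [augment()] methods.
#' @examples
#' pts <- synthesize_points(max = 0.54, k = 7, doses = c(1, 3, 10, 30, 100))
#' fit_hill(pts)
#' @export
fit_hill <- function(points, fix_n = 1) {
  stopifnot(is.data.frame(points))
  if (!all(c("dose", "response") %in% names(points))) {
    rlang::abort("`points` needs columns `dose` and `response`.")
  }
  dose <- points$dose
  resp <- points$response
  if (any(dose < 0)) rlang::abort("Doses must be >= 0 nM.")
  if (length(dose) < 3) rlang::abort("Need at least 3 points.")
  if (length(unique(dose[dose > 0])) < 2) {
    rlang::abort("Need at least two distinct positive doses.")
  }
  if (stats::sd(resp) == 0) {
    rlang::abort("All responses identical: non-identifiable fit.",
                 class = "sanpace_nonidentifiable")
  }
  rmax0 <- max(abs(resp))
  start <- list(fmax = max(resp), k = stats::median(dose[dose > 0]))
  lower <- c(fmax = -10 * rmax0, k = 1e-9)
  upper <- c(fmax = 10 * rmax0, k = 1e6)
  dat <- data.frame(dose = dose, response = resp)
  if (is.null(fix_n)) {
    start$n <- 1
    lower <- c(lower, n = 1e-6)
    upper <- c(upper, n = 5)
    fit <- minpack.lm::nlsLM(
      response ~ fmax * dose^n / (k^n + dose^n), data = dat,
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  } else {
    fit <- minpack.lm::nlsLM(
      response ~ fmax * dose^fix_n / (k^fix_n + dose^fix_n), data = dat,
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  est <- stats::coef(fit)
  out <- list(
    fmax = unname(est[["fmax"]]),
    k = unname(est[["k"]]),
    n = if (is.null(fix_n)) unname(est[["n"]]) else fix_n,
    n_fixed = !is.null(fix_n),
    fit = fit,
    data = tibble::as_tibble(dat)
  )
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> max %.4g, K0.5 %.4g nM, n %.4g%s; RSS %.4g on %d points\n",
              x$fmax, x$k, x$n, if (x$n_fixed) " (fixed)" else "",
              sum(stats::residuals(x$fit)^2), nrow(x$data)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a Hill fit
#'
#' @param x A [fit_hill()] object.
#' @param ... Unused.
#' @return One row per estimated parameter with estimate and standard error.
#' @export
tidy.hill_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tb <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
  if (x$n_fixed) {
    tb <- dplyr::bind_rows(tb, tibble::tibble(
      term = "n", estimate = x$n, std.error = NA_real_,
      statistic = NA_real_, p.value = NA_real_))
  }
  tb
}

#' @rdname tidy.hill_fit
#' @return For `glance()`: a one-row model summary.
#' @export
glance.hill_fit <- function(x, ...) {
  r <- stats::residuals(x$fit)
  tibble::tibble(
    sigma = summary(x$fit)$sigma,
    rss = sum(r^2),
    nobs = length(r),
    converged = x$fit$convInfo$isConv
  )
}

#' @rdname tidy.hill_fit
#' @return For `augment()`: the data with fitted values and residuals.
#' @export
augment.hill_fit <- function(x, ...) {
  dplyr::mutate(x$data,
                .fitted = stats::fitted(x$fit),
                .resid = stats::residuals(x$fit))
}

#' Synthesize noisy Hill-curve points
#'
#' Fixture generator for parameter-recovery tests: evaluates the Hill curve
#' and adds independent Gaussian noise on the response scale.
#'
#' @param max,k,n Curve parameters (maximum, half-maximal dose in nM, Hill
#'   coefficient).
#' @param doses Dose grid, nM.
#' @param noise_sd Standard deviation of additive Gaussian noise (response
#'   units; 0 = exact points).
#' @param seed Optional integer seed; the generator is deterministic for a
#'   fixed seed and leaves the global RNG state untouched.
#' @return A tibble with columns `dose`, `response`.
#' @examples
#' synthesize_points(9.62, 13.5, n = 0.392, doses = c(5, 50), noise_sd = 0)
#' @export
synthesize_points <- function(max, k, doses, n = 1, noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0, all(doses >= 0))
  mu <- max * doses^n / (k^n + doses^n)
  eps <- if (noise_sd == 0) rep(0, length(doses)) else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
        else assign(".Random.seed", old, envir = globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    stats::rnorm(length(doses), 0, noise_sd)
  }
  tibble::tibble(dose = as.numeric(doses), response = mu + eps)
}

#' Read / write dose-response point tables
#'
#' Two-column delimited text with a one-line header (`dose<TAB>response`).
#'
#' @param path File path.
#' @return `read_points()`: a tibble with `dose` and `response`.
#' @export
read_points <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  if (ncol(df) < 2) rlang::abort("Expected two tab-separated columns.")
  names(df)[1:2] <- c("dose", "response")
  tibble::as_tibble(df[, 1:2])
}

#' @rdname read_points
#' @param points Data frame with `dose` and `response` columns.
#' @export
write_points <- function(points, path) {
  utils::write.table(points[, c("dose", "response")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a Hill fit against its data
#'
#' @param object A [fit_hill()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  pos <- object$data$dose[object$data$dose > 0]
  grid <- tibble::tibble(dose = 10^seq(log10(min(pos) / 3),
                                       log10(max(pos) * 3), length.out = 120))
  grid$response <- object$fmax * grid$dose^object$n /
    (object$k^object$n + grid$dose^object$n)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "response") +
    ggplot2::theme_minimal()
}
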