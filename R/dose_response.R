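#' Fitted constants of the isoprenaline concentration-response relations
#'
#' Constructs the parameter set for the six saturating (Hill-type)
#' concentration-response relations through which isoprenaline (ISO), a
#' beta-adrenoceptor agonist, modulates sinoatrial node (SAN) ionic currents
#' and Ca2+ handling:
#'
#' * fractional increase of the L-type Ca2+ conductance `g_CaL`
#'   (maximum `f_ca_max`, half-maximal concentration `k_ca`),
#' * depolarizing shift of the I_f steady-state activation curve in mV
#'   (maximum `s_f_max`, half-maximal concentration `k_f`, Hill coefficient
#'   `n_f`; the only relation with a non-unity Hill coefficient),
#' * fractional increase of the delayed-rectifier conductances `g_Kr` and
#'   `g_Ks` (maximum `f_k_max`, half-maximal concentration `k_gk`; the same
#'   relation is applied to both conductances),
#' * negative (leftward) shift of the I_Kr steady-state activation curve in mV
#'   (maximum `s_k_max`, half-maximal concentration `k_kacti`),
#' * fractional increase of the I_Kr deactivation rate (maximum
#'   `dtau_kr_max`, half-maximal concentration `k_taukr`); the deactivation
#'   time constant is divided by `1 + d_tau`, see [iso_taukr_factor()],
#' * fractional increase of the sustained inward current conductance `g_st`
#'   (maximum `f_st_max`, half-maximal concentration `k_st`).
#'
#' ISO's action on intracellular Ca2+ handling is modelled dose-independently:
#' whenever the Ca2+-handling action is enabled (and the dose is positive) the
#' maximal SR Ca2+ release flux is scaled by `sr_release_scale` (default +20%)
#' and the SR uptake flux by `sr_uptake_scale` (default -20%).
#'
#' Defaults are the best-fit values obtained from rabbit (and, where rabbit
#' data were unavailable, guinea-pig) SAN voltage-clamp measurements.
#'
#' @param f_ca_max Maximum fractional increase of g_CaL (dimensionless).
#' @param k_ca Half-maximal ISO concentration for the g_CaL action (nM).
#' @param s_f_max Maximum depolarizing shift of I_f activation (mV).
#' @param k_f Half-maximal concentration for the I_f shift (nM).
#' @param n_f Hill coefficient of the I_f shift relation (dimensionless).
#' @param f_k_max Maximum fractional increase of g_Kr / g_Ks.
#' @param k_gk Half-maximal concentration for the g_K action (nM).
#' @param s_k_max Maximum (negative) shift of I_Kr activation (mV).
#' @param k_kacti Half-maximal concentration for the I_Kr activation shift (nM).
#' @param dtau_kr_max Maximum fractional increase of the I_Kr deactivation rate.
#' @param k_taukr Half-maximal concentration for the tau_Kr action (nM).
#' @param f_st_max Maximum fractional increase of g_st.
#' @param k_st Half-maximal concentration for the g_st action (nM).
#' @param sr_release_scale Multiplier applied to the maximal SR Ca2+ release
#'   flux under ISO (dimensionless).
#' @param sr_uptake_scale Multiplier applied to the SR Ca2+ uptake flux under
#'   ISO (dimensionless).
#'
#' @return An object of class `iso_dose_params` (a named list).
#' @examples
#' p <- iso_dose_params()
#' iso_fraction_ical(c(0, 7, 63), p)
#' @export
iso_dose_params <- function(f_ca_max = 0.54, k_ca = 7,
                            s_f_max = 9.62, k_f = 13.5, n_f = 0.392,
                            f_k_max = 1.87, k_gk = 19,
                            s_k_max = -15, k_kacti = 7.5,
                            dtau_kr_max = 3.0, k_taukr = 24,
                            f_st_max = 1.0, k_st = 33,
                            sr_release_scale = 1.20, sr_uptake_scale = 0.80) {
  p <- list(
    f_ca_max = f_ca_max, k_ca = k_ca,
    s_f_max = s_f_max, k_f = k_f, n_f = n_f,
    f_k_max = f_k_max, k_gk = k_gk,
    s_k_max = s_k_max, k_kacti = k_kacti,
    dtau_kr_max = dtau_kr_max, k_taukr = k_taukr,
    f_st_max = f_st_max, k_st = k_st,
    sr_release_scale = sr_release_scale, sr_uptake_scale = sr_uptake_scale
  )
  halfmax <- c("k_ca", "k_f", "k_gk", "k_kacti", "k_taukr", "k_st")
  for (k in names(p)) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || !is.finite(p[[k]])) {
      rlang::abort(sprintf("`%s` must be a finite numeric scalar.", k))
    }
  }
  bad <- halfmax[vapply(p[halfmax], function(x) x <= 0, logical(1))]
  if (length(bad)) {
    rlang::abort(sprintf(
      "Half-maximal concentrations must be strictly positive; offending: %s.",
      paste(bad, collapse = ", ")
    ))
  }
  if (p$n_f <= 0) rlang::abort("Hill coefficient `n_f` must be > 0.")
  if (p$sr_release_scale <= 0 || p$sr_uptake_scale <= 0) {
    rlang::abort("SR flux scale factors must be strictly positive.")
  }
  structure(p, class = "iso_dose_params")
}

#' @export
print.iso_dose_params <- function(x, ...) {
  cat("<iso_dose_params>\n")
  cat(sprintf("  g_CaL increase : max %.3g, K0.5 %.3g nM\n", x$f_ca_max, x$k_ca))
  cat(sprintf("  I_f shift      : max %.3g mV, K0.5 %.3g nM, n %.3g\n",
              x$s_f_max, x$k_f, x$n_f))
  cat(sprintf("  g_Kr/g_Ks incr.: max %.3g, K0.5 %.3g nM\n", x$f_k_max, x$k_gk))
  cat(sprintf("  I_Kr act shift : max %.3g mV, K0.5 %.3g nM\n", x$s_k_max, x$k_kacti))
  cat(sprintf("  tau_Kr rate    : max %.3g, K0.5 %.3g nM\n", x$dtau_kr_max, x$k_taukr))
  cat(sprintf("  g_st increase  : max %.3g, K0.5 %.3g nM\n", x$f_st_max, x$k_st))
  cat(sprintf("  SR release x%.3g, SR uptake x%.3g (dose-independent)\n",
              x$sr_release_scale, x$sr_uptake_scale))
  invisible(x)
}

check_dose <- function(dose, arg = "dose") {
  if (!is.numeric(dose) || any(!is.finite(dose))) {
    rlang::abort(sprintf("`%s` must be finite numeric (nM).", arg))
  }
  if (any(dose < 0)) {
    rlang::abort(sprintf("`%s` must be >= 0 nM (got %s).", arg,
                         paste(dose[dose < 0], collapse = ", ")))
  }
  invisible(dose)
}

hill1 <- function(dose, fmax, k) fmax * dose / (k + dose)

#' ISO concentration-response curves
#'
#' Evaluate the six fitted ISO concentration-response relations. All functions
#' are vectorised over `dose` (in nM), return 0 at dose 0, are monotone in the
#' magnitude of the response, and saturate at the fitted maximum.
#'
#' * `iso_fraction_ical()`: fractional increase of g_CaL (dimensionless).
#' * `iso_shift_if()`: depolarizing shift of the I_f steady-state activation
#'   curve (mV), the only relation with a fitted Hill coefficient.
#' * `iso_fraction_ik()`: fractional increase of g_Kr and g_Ks.
#' * `iso_shift_ikr_activation()`: shift of the I_Kr steady-state activation
#'   curve (mV); negative, i.e. toward more negative potentials.
#' * `iso_taukr_factor()`: fractional increase `d_tau` of the I_Kr
#'   deactivation rate; the deactivation time constant becomes
#'   `tau / (1 + d_tau)`. At the fitted maximum (3.0) the deactivation rate is
#'   quadrupled. (The literal reading "fractional decrease of tau_Kr" cannot
#'   exceed 1 without making tau negative, hence the rate-increase semantics.)
#' * `iso_fraction_ist()`: fractional increase of g_st.
#'
#' @param dose ISO concentration(s), nM; must be >= 0.
#' @param params An [iso_dose_params()] object.
#' @return Numeric vector the length of `dose`.
#' @examples
#' iso_shift_if(13.5)           # half of the 9.62 mV maximum
#' iso_taukr_factor(c(0, 24))   # 0 and half of 3.0
#' @name iso_curves
NULL

#' @rdname iso_curves
#' @export
iso_fraction_ical <- function(dose, params = iso_dose_params()) {
  check_dose(dose)
  hill1(dose, params$f_ca_max, params$k_ca)
}

#' @rdname iso_curves
#' @export
iso_shift_if <- function(dose, params = iso_dose_params()) {
  check_dose(dose)
  dn <- dose^params$n_f
  params$s_f_max * dn / (params$k_f^params$n_f + dn)
}

#' @rdname iso_curves
#' @export
iso_fraction_ik <- function(dose, params = iso_dose_params()) {
  check_dose(dose)
  hill1(dose, params$f_k_max, params$k_gk)
}

#' @rdname iso_curves
#' @export
iso_shift_ikr_activation <- function(dose, params = iso_dose_params()) {
  check_dose(dose)
  hill1(dose, params$s_k_max, params$k_kacti)
}

#' @rdname iso_curves
#' @export
iso_taukr_factor <- function(dose, params = iso_dose_params()) {
  check_dose(dose)
  hill1(dose, params$dtau_kr_max, params$k_taukr)
}

#' @rdname iso_curves
#' @export
iso_fraction_ist <- function(dose, params = iso_dose_params()) {
  check_dose(dose)
  hill1(dose, params$f_st_max, params$k_st)
}

#' Tabulate all six ISO concentration-response curves
#'
#' @param doses ISO concentrations, nM.
#' @param params An [iso_dose_params()] object.
#' @return A tibble with one row per dose and one column per response:
#'   `f_ca`, `s_f_mv`, `f_k`, `s_k_mv`, `d_tau_kr`, `f_st`.
#' @examples
#' iso_response_table(c(0, 5, 50, 500))
#' @export
iso_response_table <- function(doses, params = iso_dose_params()) {
  check_dose(doses, "doses")
  tibble::tibble(
    dose_nm = doses,
    f_ca = iso_fraction_ical(doses, params),
    s_f_mv = iso_shift_if(doses, params),
    f_k = iso_fraction_ik(doses, params),
    s_k_mv = iso_shift_ikr_activation(doses, params),
    d_tau_kr = iso_taukr_factor(doses, params),
    f_st = iso_fraction_ist(doses, params)
  )
}

#' Define which ISO actions are applied at a given dose
#'
#' An action set is an ISO concentration plus seven switches, one per
#' modelled action. It is the unit the dissection experiments manipulate:
#' [leave_one_out()] disables one switch, [only_one_in()] keeps exactly one.
#' With `dose = 0` the action set is a no-op regardless of the flags.
#'
#' @param dose ISO concentration, nM (scalar, >= 0).
#' @param enable_ical Scale g_CaL by `1 + f_Ca`.
#' @param enable_if Shift the I_f steady-state activation curve by `+S_f` mV.
#' @param enable_gk Scale g_Kr and g_Ks by `1 + f_K`.
#' @param enable_ikr_shift Shift I_Kr steady-state activation by `S_K` mV
#'   (negative).
#' @param enable_taukr Divide the I_Kr deactivation time constant by
#'   `1 + d_tau`.
#' @param enable_ist Scale g_st by `1 + f_st` (Boyett-family models only).
#' @param enable_ca_handling Scale the maximal SR Ca2+ release and uptake
#'   fluxes (dose-independent action).
#' @return An object of class `iso_action_set`.
#' @examples
#' iso_action_set(50)                        # all actions on
#' iso_action_set(50, enable_taukr = FALSE)  # leave-one-out
#' @export
iso_action_set <- function(dose,
                           enable_ical = TRUE, enable_if = TRUE,
                           enable_gk = TRUE, enable_ikr_shift = TRUE,
                           enable_taukr = TRUE, enable_ist = TRUE,
                           enable_ca_handling = TRUE) {
  if (length(dose) != 1L) rlang::abort("`dose` must be a scalar (nM).")
  check_dose(dose)
  flags <- list(
    enable_ical = enable_ical, enable_if = enable_if, enable_gk = enable_gk,
    enable_ikr_shift = enable_ikr_shift, enable_taukr = enable_taukr,
    enable_ist = enable_ist, enable_ca_handling = enable_ca_handling
  )
  for (k in names(flags)) {
    if (!rlang::is_bool(flags[[k]])) {
      rlang::abort(sprintf("`%s` must be TRUE or FALSE.", k))
    }
  }
  structure(c(list(dose = dose), flags), class = "iso_action_set")
}

#' @export
print.iso_action_set <- function(x, ...) {
  on <- iso_action_names()[vapply(paste0("enable_", iso_action_names()),
                                  function(k) isTRUE(x[[k]]), logical(1))]
  cat(sprintf("<iso_action_set> dose %g nM; enabled: %s\n", x$dose,
              if (length(on)) paste(on, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Names of the seven modelled ISO actions
#'
#' @return Character vector of action names, in a fixed order:
#'   `ical`, `if`, `gk`, `ikr_shift`, `taukr`, `ist`, `ca_handling`.
#' @export
iso_action_names <- function() {
  c("ical", "if", "gk", "ikr_shift", "taukr", "ist", "ca_handling")
}

#' Parse an ISO dose with unit suffix
#'
#' Accepts a number (taken as nM) or a string with an explicit `nM` or `uM`
#' suffix (micro sign accepted), and returns the concentration in nM.
#'
#' @param x Numeric (nM) or string such as `"0.05 uM"` or `"50 nM"`.
#' @return Dose in nM.
#' @examples
#' parse_dose("0.05 uM")  # 50
#' @export
parse_dose <- function(x) {
  if (is.numeric(x)) {
    check_dose(x)
    return(as.numeric(x))
  }
  if (!is.character(x)) rlang::abort("`x` must be numeric (nM) or a string with unit.")
  vapply(x, function(s) {
    m <- regmatches(s, regexec(
      "^\\s*([0-9.eE+-]+)\\s*(nM|nm|uM|um|µM|µm)?\\s*$", s))[[1]]
    if (length(m) < 2L || m[2] == "") {
      rlang::abort(sprintf("Cannot parse dose '%s'; use e.g. '50 nM' or '0.05 uM'.", s))
    }
    val <- as.numeric(m[2])
    if (is.na(val) || val < 0) rlang::abort(sprintf("Invalid dose value in '%s'.", s))
    unit <- if (length(m) >= 3L && nzchar(m[3])) tolower(m[3]) else "nm"
    if (unit %in% c("um", "µm")) val <- val * 1000
    val
  }, numeric(1), USE.NAMES = FALSE)
}

#' Plot the ISO concentration-response relations
#'
#' @param doses Dose grid, nM (default log-spaced 0.1-1000 nM).
#' @param params An [iso_dose_params()] object.
#' @return A ggplot object: one panel per response, log-scaled dose axis.
#' @export
plot_iso_curves <- function(doses = 10^seq(-1, 3, length.out = 61),
                            params = iso_dose_params()) {
  tab <- iso_response_table(doses, params)
  long <- tidyr::pivot_longer(tab, -"dose_nm",
                              names_to = "response", values_to = "value")
  labs <- c(
    f_ca = "g_CaL fractional increase", s_f_mv = "I_f activation shift (mV)",
    f_k = "g_Kr/g_Ks fractional increase", s_k_mv = "I_Kr activation shift (mV)",
    d_tau_kr = "I_Kr deactivation rate increase", f_st = "g_st fractional increase"
  )
  long$response <- factor(labs[long$response], levels = unname(labs))
  ggplot2::ggplot(long, ggplot2::aes(.data$dose_nm, .data$value)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "[ISO] (nM)", y = NULL,
                  title = "Isoprenaline concentration-response relations") +
    ggplot2::theme_minimal()
}
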