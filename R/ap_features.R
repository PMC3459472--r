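#' Detect action potentials in a trace
#'
#' Beats are delimited by upstroke times: upward crossings of the midpoint
#' between the trace's extreme potentials, refined to sub-sample precision
#' by linear interpolation (for regular action potentials this midpoint
#' crossing sits on the fast upstroke, within a sample or two of the
#' dV/dt maximum, which remains the APD reference instant in
#' [compute_features()]).
#'
#' @param trace A `san_trace` (or any tibble with `time` and `vm`).
#' @return A tibble with one row per complete beat: `t_upstroke` (ms),
#'   `t_next` (following upstroke) and the index range of the beat window.
#' @export
detect_beats <- function(trace) {
  t <- trace$time
  v <- trace$vm
  if (length(t) < 10L) {
    rlang::abort("Trace too short for beat detection.",
                 class = "sanpace_insufficient_beats")
  }
  vr <- range(v)
  if (diff(vr) < 10) {  # < 10 mV excursion: no action potentials
    rlang::abort("Insufficient beats: no action-potential-sized excursions.",
                 class = "sanpace_insufficient_beats")
  }
  thr <- mean(vr)
  cross <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  if (length(cross) < 3L) {
    rlang::abort("Insufficient beats: fewer than two complete cycles.",
                 class = "sanpace_insufficient_beats")
  }
  # sub-sample upstroke times by linear interpolation across the crossing;
  # cycle lengths are then grid-independent
  tc <- t[cross - 1L] + (thr - v[cross - 1L]) *
    (t[cross] - t[cross - 1L]) / (v[cross] - v[cross - 1L])
  tibble::tibble(
    t_upstroke = tc[-length(tc)],
    t_next = tc[-1],
    i_start = cross[-length(cross)],
    i_end = cross[-1] - 1L
  )
}

#' Compute action-potential summary features
#'
#' Features are averaged over the last `n_beats` complete beats. Action
#' potential durations are measured from the instant of maximum dV/dt to the
#' 50% / 90% repolarization levels of that beat's amplitude.
#'
#' @param trace A `san_trace`.
#' @param beats Optional [detect_beats()] table (recomputed if missing).
#' @param n_beats Number of final beats to average (default 5).
#' @return A one-row `san_features` tibble: `cycle_length` (ms), `rate`
#'   (beats/min), `mdp`, `overshoot`, `amplitude` (mV), `apd50`, `apd90`
#'   (ms), `dvdt_max` (mV/ms), `cai_diastolic`, `cai_systolic` (mM) and
#'   `n_beats_analyzed`.
#' @export
compute_features <- function(trace, beats = NULL, n_beats = 5) {
  if (is.null(beats)) beats <- detect_beats(trace)
  if (nrow(beats) < 1L) {
    rlang::abort("Need at least two upstrokes (one complete beat).",
                 class = "sanpace_insufficient_beats")
  }
  use <- utils::tail(seq_len(nrow(beats)), n_beats)
  t <- trace$time; v <- trace$vm
  cai <- if ("cai" %in% names(trace)) trace$cai else NULL
  dvdt <- c(NA_real_, diff(v) / diff(t))

  per_beat <- lapply(use, function(k) {
    w <- beats$i_start[k]:beats$i_end[k]
    vm <- v[w]
    peak_i <- which.max(vm)
    mdp <- min(vm)
    overshoot <- max(vm)
    amp <- overshoot - mdp
    # APD reference: instant of maximum upstroke velocity of this beat
    # (ties resolved to the earliest sample)
    t_ref <- t[w[which.max(round(dvdt[w], 9))]]
    rep_seg <- w[peak_i:length(w)]
    apd_at <- function(frac) {
      lev <- overshoot - frac * amp
      below <- which(v[rep_seg] <= lev)
      if (!length(below)) return(NA_real_)
      i2 <- rep_seg[below[1]]
      if (i2 == rep_seg[1]) return(t[i2] - t_ref)
      # linear interpolation across the crossing
      i1 <- i2 - 1L
      tc <- t[i1] + (lev - v[i1]) * (t[i2] - t[i1]) / (v[i2] - v[i1])
      tc - t_ref
    }
    c(mdp = mdp, overshoot = overshoot, amp = amp,
      apd50 = apd_at(0.5), apd90 = apd_at(0.9),
      dvdt_max = max(dvdt[w], na.rm = TRUE),
      cai_d = if (is.null(cai)) NA_real_ else min(cai[w]),
      cai_s = if (is.null(cai)) NA_real_ else max(cai[w]))
  })
  pb <- do.call(rbind, per_beat)
  cl <- mean(beats$t_next[use] - beats$t_upstroke[use])
  feats <- tibble::tibble(
    cycle_length = cl,
    rate = 60000 / cl,
    mdp = mean(pb[, "mdp"]),
    overshoot = mean(pb[, "overshoot"]),
    amplitude = mean(pb[, "overshoot"]) - mean(pb[, "mdp"]),
    apd50 = mean(pb[, "apd50"]),
    apd90 = mean(pb[, "apd90"]),
    dvdt_max = mean(pb[, "dvdt_max"]),
    cai_diastolic = mean(pb[, "cai_d"]),
    cai_systolic = mean(pb[, "cai_s"]),
    n_beats_analyzed = length(use)
  )
  conv <- attr(trace, "convergence")
  attr(feats, "convergence") <- conv
  class(feats) <- c("san_features", class(feats))
  feats
}

#' Changes in pacemaking features between two runs
#'
#' Rate changes are expressed on a frequency basis,
#' `(rate_treated / rate_control - 1) * 100`; the cycle-length percentage
#' decrease `(1 - CL_treated / CL_control) * 100` is reported alongside.
#' `delta_mdp_mv` is treated minus control in mV (negative = the maximum
#' diastolic potential became more negative, i.e. hyperpolarized).
#'
#' @param control,treated `san_features` rows from converged runs.
#' @return A one-row tibble: `delta_rate_pct`, `delta_cl_pct`,
#'   `delta_mdp_mv`, `delta_overshoot_mv`, `delta_apd50_pct`.
#' @export
delta_features <- function(control, treated) {
  stopifnot(is.data.frame(control), is.data.frame(treated))
  tibble::tibble(
    delta_rate_pct = (treated$rate / control$rate - 1) * 100,
    delta_cl_pct = (1 - treated$cycle_length / control$cycle_length) * 100,
    delta_mdp_mv = treated$mdp - control$mdp,
    delta_overshoot_mv = treated$overshoot - control$overshoot,
    delta_apd50_pct = (treated$apd50 / control$apd50 - 1) * 100
  )
}
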