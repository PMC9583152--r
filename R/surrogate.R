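#' Parameters of the analytic surrogate myocyte
#'
#' The surrogate is a deterministic, piecewise-linear stand-in for a paced
#' ventricular myocyte, built so that every one of the twelve biomarkers
#' has a closed-form value as a function of the per-channel conductance
#' scale factors. It is memoryless (every paced beat is identical) and is
#' tuned for directional realism only: blocking IKr/IKs prolongs the
#' action potential, blocking ICaL shortens it and damps the calcium
#' transient, blocking INa lowers the upstroke.
#'
#' Morphology of one beat (local time t in ms, stimulus at t = 0):
#' \itemize{
#'   \item Vm: rest at `vm_rest`; linear upstroke over `upstroke_ms` to the
#'     peak; flat plateau; linear phase-3 descent back to rest. The
#'     duration factor is
#'     `f = 1 + 0.8 (1 - s_IKr) + 0.3 (1 - s_IKs) - 0.4 (1 - s_ICaL)`,
#'     giving APD90 = `base_apd90 * f` and APD50 = `base_apd50 * f`
#'     (both measured from the upstroke midpoint).
#'   \item Peak: `vm_peak_base - peak_sens_ina * (1 - s_INa)`.
#'   \item Cai: baseline `cai_base`; linear rise over
#'     \[`ca_rise_start`, `ca_rise_start + ca_rise_ms`\] to
#'     `cai_base + ca_amp_base * (0.3 + 0.7 s_ICaL)`; short plateau;
#'     linear decay sized so CaD50 = `base_cad50 * f` and CaD90 =
#'     `base_cad90 * f` from the rise midpoint.
#'   \item Currents: each of the six net-charge currents is a trapezoidal
#'     pulse (2 ms ramps) spanning the plateau, with amplitude
#'     `current_amps[ion] * s_ion` (inward currents negative), so blocking
#'     IKr removes outward charge and lowers qNet.
#' }
#'
#' @param base_apd90,base_apd50 Drug-free action-potential durations, ms.
#' @param vm_rest,vm_peak_base Resting and peak membrane potential, mV.
#' @param upstroke_ms Upstroke duration, ms.
#' @param peak_sens_ina Peak reduction per unit INa block, mV.
#' @param cai_base Diastolic calcium, mM.
#' @param ca_amp_base Drug-free calcium transient amplitude, mM.
#' @param ca_rise_start,ca_rise_ms Transient onset timing, ms.
#' @param base_cad50,base_cad90 Drug-free calcium-transient durations, ms.
#' @param sens Duration sensitivities for IKr, IKs, ICaL (fixed constants
#'   of the surrogate, not fitted to any reference model).
#' @param current_amps Plateau current amplitudes, A/F, named by channel.
#' @param current_ramp_ms Ramp length of the current pulses, ms.
#' @return Parameter list of class `surrogate_params`.
#' @export
surrogate_params <- function(base_apd90 = 270, base_apd50 = 230,
                             vm_rest = -88, vm_peak_base = 33,
                             upstroke_ms = 1, peak_sens_ina = 6,
                             cai_base = 1e-4, ca_amp_base = 3e-4,
                             ca_rise_start = 5, ca_rise_ms = 10,
                             base_cad50 = 280, base_cad90 = 440,
                             sens = c(IKr = 0.8, IKs = 0.3, ICaL = 0.4),
                             current_amps = c(INaL = -0.10, ICaL = -0.45,
                                              IKr = 0.85, IKs = 0.18,
                                              IK1 = 0.25, Ito = 0.15),
                             current_ramp_ms = 2) {
  stopifnot(base_apd90 > base_apd50, base_apd50 > 0,
            all(c("IKr", "IKs", "ICaL") %in% names(sens)),
            setequal(names(current_amps), qnet_channels()))
  structure(list(base_apd90 = base_apd90, base_apd50 = base_apd50,
                 vm_rest = vm_rest, vm_peak_base = vm_peak_base,
                 upstroke_ms = upstroke_ms, peak_sens_ina = peak_sens_ina,
                 cai_base = cai_base, ca_amp_base = ca_amp_base,
                 ca_rise_start = ca_rise_start, ca_rise_ms = ca_rise_ms,
                 base_cad50 = base_cad50, base_cad90 = base_cad90,
                 sens = sens, current_amps = current_amps,
                 current_ramp_ms = current_ramp_ms),
            class = "surrogate_params")
}

# Closed-form beat geometry for one set of scale factors (vectorised over
# rows of a scales matrix). All times local ms; stimulus at t = 0.
surrogate_geometry <- function(scales, params) {
  sc <- if (is.null(dim(scales))) {
    matrix(scales, nrow = 1, dimnames = list(NULL, names(scales)))
  } else as.matrix(scales)
  for (ch in tdp_channels()) if (!ch %in% colnames(sc)) {
    sc <- cbind(sc, stats::setNames(data.frame(rep(1, nrow(sc))), ch))
    sc <- as.matrix(sc)
  }
  if (any(sc < 0 | sc > 1)) stop("conductance scales must lie in [0, 1]")
  p <- params
  f <- 1 + p$sens[["IKr"]] * (1 - sc[, "IKr"]) +
    p$sens[["IKs"]] * (1 - sc[, "IKs"]) -
    p$sens[["ICaL"]] * (1 - sc[, "ICaL"])
  vm_peak <- p$vm_peak_base - p$peak_sens_ina * (1 - sc[, "INa"])
  amp <- vm_peak - p$vm_rest
  t_act <- p$upstroke_ms / 2
  apd50 <- p$base_apd50 * f
  apd90 <- p$base_apd90 * f
  t_desc <- (apd90 - apd50) / 0.4          # phase-3 descent duration
  t_plateau_end <- t_act + apd50 - 0.5 * t_desc
  t_end <- t_plateau_end + t_desc
  ca_amp <- p$ca_amp_base * (0.3 + 0.7 * sc[, "ICaL"])
  ca_onset <- p$ca_rise_start + p$ca_rise_ms / 2
  cad50 <- p$base_cad50 * f
  cad90 <- p$base_cad90 * f
  ca_desc <- (cad90 - cad50) / 0.4
  ca_plateau_end <- ca_onset + cad50 - 0.5 * ca_desc
  ca_end <- ca_plateau_end + ca_desc
  list(scales = sc, f = f, vm_peak = vm_peak, amp = amp, t_act = t_act,
       t_up_end = p$upstroke_ms, t_plateau_end = t_plateau_end,
       t_end = t_end, apd50 = apd50, apd90 = apd90,
       ca_amp = ca_amp, ca_onset = ca_onset,
       ca_rise_end = p$ca_rise_start + p$ca_rise_ms,
       ca_plateau_end = ca_plateau_end, ca_end = ca_end,
       cad50 = cad50, cad90 = cad90)
}

#' Generate one surrogate beat
#'
#' Deterministic single-beat traces for the surrogate myocyte (see
#' [surrogate_params()] for the morphology). Replicated by
#' [paced_simulation()] to any number of beats.
#'
#' @param scales Named per-channel conductance scale factors in \[0, 1\]
#'   (missing channels default to 1).
#' @param params A [surrogate_params()] list.
#' @param cycle_length Beat length, ms.
#' @param dt Grid step, ms.
#' @return List with `vm`, `cai` and `currents` series on the grid
#'   `seq(0, cycle_length - dt, by = dt)`.
#' @export
surrogate_trace <- function(scales, params = surrogate_params(),
                            cycle_length = 2000, dt = 0.1) {
  g <- surrogate_geometry(scales, params)
  if (g$t_end[1] >= cycle_length || g$ca_end[1] >= cycle_length) {
    stop("surrogate beat longer than the cycle length")
  }
  p <- params
  t <- seq(0, cycle_length - dt, by = dt)
  pw <- function(xs, ys) stats::approx(xs, ys, xout = t, rule = 2)$y
  vm <- pw(c(0, g$t_up_end, g$t_plateau_end[1], g$t_end[1], cycle_length),
           c(p$vm_rest, g$vm_peak[1], g$vm_peak[1], p$vm_rest, p$vm_rest))
  cai <- pw(c(0, p$ca_rise_start, g$ca_rise_end, g$ca_plateau_end[1],
              g$ca_end[1], cycle_length),
            c(p$cai_base, p$cai_base, p$cai_base + g$ca_amp[1],
              p$cai_base + g$ca_amp[1], p$cai_base, p$cai_base))
  ramp <- p$current_ramp_ms
  t1 <- g$t_up_end; t2 <- g$t_plateau_end[1]
  currents <- lapply(stats::setNames(nm = qnet_channels()), function(ch) {
    a <- p$current_amps[[ch]] * g$scales[1, ch]
    pw(c(0, t1, t1 + ramp, t2 - ramp, t2, cycle_length),
       c(0, 0, a, a, 0, 0))
  })
  list(vm = vm, cai = cai, currents = currents)
}

#' Closed-form biomarkers of the surrogate myocyte
#'
#' Evaluates all twelve biomarkers analytically from the surrogate's
#' geometry, without synthesising traces. This is the fast path for
#' large sample sweeps; it agrees with trace synthesis followed by
#' [extract_features()] to within one grid step (the equivalence is part
#' of the test suite). qInward is computed against the drug-free
#' geometry as control.
#'
#' @param scales Matrix (or named vector) of per-channel conductance
#'   scale factors; one row per sample.
#' @param params A [surrogate_params()] list.
#' @return Data.frame with the twelve feature columns of
#'   [feature_names()], one row per row of `scales`.
#' @export
surrogate_features <- function(scales, params = surrogate_params()) {
  g <- surrogate_geometry(scales, params)
  p <- params
  ctrl <- surrogate_geometry(
    stats::setNames(rep(1, length(tdp_channels())), tdp_channels()), params)
  ramp <- p$current_ramp_ms
  pulse_len <- (g$t_plateau_end - g$t_up_end - ramp) / 1000   # s
  ctrl_len <- (ctrl$t_plateau_end - ctrl$t_up_end - ramp) / 1000
  qnet <- pulse_len * as.vector(
    g$scales[, qnet_channels(), drop = FALSE] %*%
      p$current_amps[qnet_channels()])
  q_ratio <- function(ch) {
    (abs(p$current_amps[[ch]]) * g$scales[, ch] * pulse_len) /
      (abs(p$current_amps[[ch]]) * ctrl_len)
  }
  data.frame(
    dvmdt_max = g$amp / p$upstroke_ms,
    dvmdt_max_repol = -g$amp / (g$t_end - g$t_plateau_end),
    vm_peak = g$vm_peak,
    apd90 = g$apd90, apd50 = g$apd50, apd_tri = g$apd90 - g$apd50,
    ca_peak = p$cai_base + g$ca_amp,
    cad90 = g$cad90, cad50 = g$cad50, cad_tri = g$cad90 - g$cad50,
    qnet = qnet,
    qinward = 0.5 * (q_ratio("ICaL") + q_ratio("INaL")))
}
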