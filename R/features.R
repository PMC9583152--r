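#' Names of the twelve in silico biomarkers
#'
#' Six action-potential features (upstroke velocity, repolarisation
#' velocity, peak potential, APD90, APD50, APD triangulation), four
#' calcium features (peak, CaD90, CaD50, CaD triangulation) and two ionic
#' charge features (qNet, qInward).
#'
#' @return Character vector of length 12.
#' @export
feature_names <- function() {
  c("dvmdt_max", "dvmdt_max_repol", "vm_peak", "apd90", "apd50", "apd_tri",
    "ca_peak", "cad90", "cad50", "cad_tri", "qnet", "qinward")
}

#' Cut one beat out of a trace bundle
#'
#' @param bundle A `trace_bundle` from [paced_simulation()].
#' @param beat_index Retained beat number (1-based).
#' @return Object of class `beat_slice`: local `time` (0 at the stimulus),
#'   `vm`, `cai`, `currents`, `dt`, `beat_index`.
#' @export
beat_slice <- function(bundle, beat_index) {
  stopifnot(inherits(bundle, "trace_bundle"),
            beat_index >= 1, beat_index <= bundle$n_beats)
  spb <- as.integer(round(bundle$cycle_length / bundle$dt))
  i0 <- bundle$beat_offsets[beat_index]
  idx <- i0:(i0 + spb - 1L)
  structure(list(time = (seq_len(spb) - 1) * bundle$dt,
                 vm = bundle$vm[idx], cai = bundle$cai[idx],
                 currents = lapply(bundle$currents, `[`, idx),
                 dt = bundle$dt, cycle_length = bundle$cycle_length,
                 beat_index = beat_index),
            class = "beat_slice")
}

# Centred first difference on the output grid (one-sided at the ends).
grid_slope <- function(x, dt) {
  n <- length(x)
  s <- numeric(n)
  s[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  s[1] <- (x[2] - x[1]) / dt
  s[n] <- (x[n] - x[n - 1]) / dt
  s
}

# Time of maximal slope. On piecewise-linear traces the discrete maximum
# is attained over a run of grid points; the centre of the run containing
# the argmax is returned so the timing is unbiased for linear ramps.
time_of_max_slope <- function(time, slope) {
  mx <- max(slope)
  tol <- 1e-9 * max(1, abs(mx))
  at_max <- slope >= mx - tol
  i <- which.max(slope)
  lo <- i; while (lo > 1 && at_max[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(slope) && at_max[hi + 1]) hi <- hi + 1
  mean(time[c(lo, hi)])
}

# First downward crossing of `level` after index `from`, linearly
# interpolated; NA if the series never falls below the level.
first_crossing_below <- function(time, x, level, from) {
  n <- length(x)
  idx <- which(x[(from + 1):n] < level)
  if (length(idx) == 0) return(NA_real_)
  i <- from + idx[1]
  if (x[i - 1] <= level) return(time[i - 1])  # previous sample on the level
  time[i - 1] + (time[i] - time[i - 1]) * (x[i - 1] - level) / (x[i - 1] - x[i])
}

#' Pick the worst beat of a bundle (steepest repolarisation)
#'
#' Scans the retained beats and returns the one whose phase-3
#' repolarisation is steepest, i.e. whose minimum dVm/dt after the AP
#' peak is most negative. This is the beat reflecting the worst situation
#' for the myocyte (e.g. incipient early after-depolarisation); ties are
#' broken towards the latest beat.
#'
#' @param bundle A `trace_bundle`.
#' @return Retained beat index (1-based).
#' @export
select_worst_beat <- function(bundle) {
  stopifnot(inherits(bundle, "trace_bundle"), bundle$n_beats >= 1)
  worst <- vapply(seq_len(bundle$n_beats), function(b) {
    beat <- beat_slice(bundle, b)
    s <- grid_slope(beat$vm, beat$dt)
    i_peak <- which.max(beat$vm)
    if (i_peak >= length(s)) return(Inf)
    min(s[(i_peak + 1):length(s)])
  }, numeric(1))
  best <- min(worst)
  max(which(worst <= best + 1e-12 * max(1, abs(best))))
}

#' Action-potential features of one beat
#'
#' Computes upstroke velocity (`dvmdt_max`, the maximum centred-difference
#' slope), repolarisation velocity (`dvmdt_max_repol`, the minimum slope
#' after the AP peak; negative in normal beats), `vm_peak`, and the
#' interpolated durations `apd90`/`apd50` measured from the activation
#' time (centre of the maximal-slope run) to the first fall below
#' `vm_peak - (x/100) * amplitude`, where the amplitude is taken against
#' the membrane potential at stimulus onset of the same beat.
#' `apd_tri = apd90 - apd50`. A beat that never repolarises below the
#' APD90 level yields `NA` durations (repolarisation failure marker), not
#' an error.
#'
#' @param beat A [beat_slice()].
#' @param detection_floor Minimum upstroke slope (mV/ms) for a beat to
#'   count as stimulated; below it an error "no AP" is thrown.
#' @return Named numeric vector of the six AP features.
#' @export
ap_features <- function(beat, detection_floor = 5) {
  stopifnot(inherits(beat, "beat_slice"))
  s <- grid_slope(beat$vm, beat$dt)
  dvmdt_max <- max(s)
  if (!is.finite(dvmdt_max) || dvmdt_max < detection_floor) {
    stop("no AP: maximum upstroke slope ", signif(dvmdt_max, 3),
         " mV/ms below detection floor")
  }
  t_act <- time_of_max_slope(beat$time, s)
  i_act <- max(1L, which(beat$time >= t_act)[1])
  i_peak <- (i_act - 1L) + which.max(beat$vm[i_act:length(beat$vm)])
  vm_peak <- beat$vm[i_peak]
  amp <- vm_peak - beat$vm[1]
  dvmdt_max_repol <- if (i_peak < length(s)) {
    min(s[(i_peak + 1):length(s)])
  } else NA_real_
  dur <- function(frac) {
    tc <- first_crossing_below(beat$time, beat$vm, vm_peak - frac * amp, i_peak)
    if (is.na(tc)) NA_real_ else tc - t_act
  }
  apd90 <- dur(0.90)
  apd50 <- dur(0.50)
  c(dvmdt_max = dvmdt_max, dvmdt_max_repol = dvmdt_max_repol,
    vm_peak = vm_peak, apd90 = apd90, apd50 = apd50,
    apd_tri = apd90 - apd50)
}

#' Calcium-transient features of one beat
#'
#' `ca_peak` is the maximum intracellular calcium; `cad90`/`cad50` are the
#' interpolated durations from the transient onset (centre of the maximal
#' dCai/dt run) to the first decay below
#' `ca_peak - (x/100) * (ca_peak - diastolic)`, with the diastolic level
#' taken at stimulus onset; `cad_tri = cad90 - cad50`.
#'
#' @param beat A [beat_slice()].
#' @return Named numeric vector of the four Ca features.
#' @export
ca_features <- function(beat) {
  stopifnot(inherits(beat, "beat_slice"))
  if (diff(range(beat$cai)) <= 0) stop("no transient: flat calcium trace")
  s <- grid_slope(beat$cai, beat$dt)
  t_on <- time_of_max_slope(beat$time, s)
  i_on <- max(1L, which(beat$time >= t_on)[1])
  i_peak <- (i_on - 1L) + which.max(beat$cai[i_on:length(beat$cai)])
  ca_peak <- beat$cai[i_peak]
  dia <- beat$cai[1]
  dur <- function(frac) {
    tc <- first_crossing_below(beat$time, beat$cai,
                               ca_peak - frac * (ca_peak - dia), i_peak)
    if (is.na(tc)) NA_real_ else tc - t_on
  }
  cad90 <- dur(0.90)
  cad50 <- dur(0.50)
  c(ca_peak = ca_peak, cad90 = cad90, cad50 = cad50,
    cad_tri = cad90 - cad50)
}

# Trapezoidal integral of a series sampled at dt ms; returns (value) * s.
trapz_ms <- function(x, dt) sum((x[-1] + x[-length(x)]) / 2) * dt / 1000

#' Net charge carried by the six qNet currents over one beat
#'
#' Trapezoidal integral over the beat window of
#' INaL + ICaL + IKr + IKs + IK1 + Ito, time in seconds and current in
#' A/F, i.e. the result is in uC/uF.
#'
#' @param beat A [beat_slice()].
#' @return qNet in uC/uF.
#' @export
qnet <- function(beat) {
  stopifnot(inherits(beat, "beat_slice"))
  missing <- setdiff(qnet_channels(), names(beat$currents))
  if (length(missing) > 0) {
    stop("missing current(s): ", paste(missing, collapse = ", "))
  }
  inet <- Reduce(`+`, beat$currents[qnet_channels()])
  trapz_ms(inet, beat$dt)
}

#' Fractional inward charge retained under drug (qInward)
#'
#' The mean, over the two inward currents INaL and ICaL, of the drugged
#' beat's absolute trapezoidal charge divided by the control beat's:
#' `0.5 * (qCaL_drug / qCaL_control + qNaL_drug / qNaL_control)`.
#' Absolute magnitudes are used so the sign convention of inward currents
#' cannot flip the ratio; 1 means no change.
#'
#' @param beat Drugged [beat_slice()].
#' @param control_beat Drug-free [beat_slice()].
#' @return Dimensionless ratio >= 0.
#' @export
qinward <- function(beat, control_beat) {
  q <- function(b, ch) {
    if (!ch %in% names(b$currents)) stop("missing current(s): ", ch)
    abs(trapz_ms(b$currents[[ch]], b$dt))
  }
  qc_ctrl <- q(control_beat, "ICaL"); qn_ctrl <- q(control_beat, "INaL")
  if (qc_ctrl == 0 || qn_ctrl == 0) {
    stop("degenerate control: zero inward charge in the control beat")
  }
  0.5 * (q(beat, "ICaL") / qc_ctrl + q(beat, "INaL") / qn_ctrl)
}

#' All twelve biomarkers of a bundle's worst beat
#'
#' Convenience wrapper: selects the worst beat of `bundle` (and of
#' `control_bundle` for qInward), then assembles the full feature vector.
#'
#' @param bundle Drugged `trace_bundle`.
#' @param control_bundle Drug-free `trace_bundle` (for qInward).
#' @param detection_floor Passed to [ap_features()].
#' @return Named numeric vector over [feature_names()].
#' @export
extract_features <- function(bundle, control_bundle,
                             detection_floor = 5) {
  beat <- beat_slice(bundle, select_worst_beat(bundle))
  ctrl <- beat_slice(control_bundle, select_worst_beat(control_bundle))
  out <- c(ap_features(beat, detection_floor), ca_features(beat),
           qnet = qnet(beat), qinward = qinward(beat, ctrl))
  out[feature_names()]
}

#' Average feature vectors over the four concentration multiples
#'
#' Component-wise arithmetic mean of exactly four feature vectors (the
#' 1-4 x Cmax doses of one drug and one uncertainty sample). A component
#' missing at any dose (repolarisation failure) stays missing in the
#' average, so unreliable biomarkers are excluded rather than diluted.
#'
#' @param per_dose List of four named feature vectors.
#' @return Named feature vector of the same components.
#' @export
average_over_concentrations <- function(per_dose) {
  if (length(per_dose) != 4) {
    stop("expected exactly 4 per-dose feature vectors, got ", length(per_dose))
  }
  m <- do.call(cbind, per_dose)
  rowMeans(m, na.rm = FALSE)
}
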