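# Programmatic fixtures: piecewise-linear beats with closed-form feature
# values, assembled directly into trace_bundle objects.

piecewise <- function(t, xs, ys) {
  keep <- !duplicated(xs)
  stats::approx(xs[keep], ys[keep], xout = t, rule = 2)$y
}

# A single-beat (or multi-beat) bundle from per-beat series lists.
make_bundle <- function(vm_beats, cai_beats = NULL, current_beats = NULL,
                        dt = 0.1, cycle_length = NULL) {
  if (!is.list(vm_beats)) vm_beats <- list(vm_beats)
  n_beats <- length(vm_beats)
  spb <- length(vm_beats[[1]])
  if (is.null(cycle_length)) cycle_length <- spb * dt
  if (is.null(cai_beats)) {
    cai_beats <- lapply(vm_beats, function(v) rep(1e-4, length(v)))
  }
  if (!is.list(cai_beats)) cai_beats <- list(cai_beats)
  zeros <- lapply(stats::setNames(nm = qnet_channels()),
                  function(ch) rep(0, spb))
  if (is.null(current_beats)) current_beats <- list(zeros)
  if (!is.null(names(current_beats))) current_beats <- list(current_beats)
  current_beats <- lapply(current_beats, function(cur) {
    out <- zeros
    out[names(cur)] <- cur
    out
  })
  rep_full <- function(lst) do.call(c, lst)
  structure(list(
    dt = dt, cycle_length = cycle_length, n_beats = n_beats,
    vm = rep_full(vm_beats),
    cai = rep_full(cai_beats),
    currents = lapply(stats::setNames(nm = qnet_channels()), function(ch) {
      do.call(c, lapply(rep(seq_len(n_beats), length.out = n_beats),
                        function(b) current_beats[[min(b, length(current_beats))]][[ch]]))
    }),
    beat_offsets = (seq_len(n_beats) - 1L) * spb + 1L),
    class = "trace_bundle")
}

# Trapezoidal action potential: rest, linear upstroke over [t0, t0+1],
# flat plateau to t0+200, linear fall to rest at t0+300.
trapezoid_vm <- function(dt = 0.1, cycle_length = 400, t0 = 0,
                         rest = -85, peak = 35) {
  t <- seq(0, cycle_length - dt, by = dt)
  piecewise(t, c(0, t0, t0 + 1, t0 + 200, t0 + 300, cycle_length),
            c(rest, rest, peak, peak, rest, rest))
}

# Closed-form oracle for the trapezoid: activation at the upstroke
# midpoint, APDx from the analytic level crossings on the descent.
trapezoid_oracle <- function(t0 = 0, rest = -85, peak = 35) {
  amp <- peak - rest
  t_act <- t0 + 0.5
  cross <- function(frac) {
    level <- peak - frac * amp
    (t0 + 200) + (peak - level) / (amp / 100)   # descent slope amp/100 per ms
  }
  c(dvmdt_max = amp / 1, dvmdt_max_repol = -amp / 100, vm_peak = peak,
    apd90 = cross(0.90) - t_act, apd50 = cross(0.50) - t_act,
    apd_tri = 0.4 * amp / (amp / 100))
}

# Triangular calcium transient: baseline, linear rise over [t0, t0+10] to
# the peak, linear decay back to baseline at t0+400.
triangle_cai <- function(dt = 0.1, cycle_length = 500, t0 = 0,
                         base = 1e-4, peak = 4e-4) {
  t <- seq(0, cycle_length - dt, by = dt)
  piecewise(t, c(0, t0, t0 + 10, t0 + 400, cycle_length),
            c(base, base, peak, base, base))
}

# Closed-form oracle for the triangle under the centre-of-run onset
# convention (onset = midpoint of the linear rise).
triangle_oracle <- function(t0 = 0, base = 1e-4, peak = 4e-4) {
  amp <- peak - base
  onset <- t0 + 5
  decay_slope <- amp / 390
  cross <- function(frac) (t0 + 10) + frac * amp / decay_slope
  c(ca_peak = peak, cad90 = cross(0.90) - onset,
    cad50 = cross(0.50) - onset,
    cad_tri = cross(0.90) - cross(0.50))
}

# A grid-aligned trapezoidal current pulse (exact under the trapezoid rule).
pulse_current <- function(dt = 0.1, cycle_length = 400, amp = 0.1,
                          t_on = 100, t_off = 200, ramp = 1) {
  t <- seq(0, cycle_length - dt, by = dt)
  piecewise(t, c(0, t_on, t_on + ramp, t_off - ramp, t_off, cycle_length),
            c(0, 0, amp, amp, 0, 0))
}

# Brute-force all-pairs AUC oracle with half-credit ties.
auc_bruteforce <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

fresh_drug_table <- function() {
  read_drug_table(system.file("extdata", "cipa_drugs.csv", package = "tdprisk"))
}
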