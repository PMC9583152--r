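# Extractor correctness is checked against closed-form oracles on
# piecewise-linear fixtures whose level crossings solve analytically.

test_that("AP features match the trapezoid fixture's analytic values", {
  dt <- 0.1
  b <- make_bundle(trapezoid_vm(dt = dt), dt = dt)
  got <- ap_features(beat_slice(b, 1))
  want <- trapezoid_oracle()
  expect_equal(got[["dvmdt_max"]], want[["dvmdt_max"]], tolerance = 1e-9)
  expect_equal(got[["dvmdt_max_repol"]], want[["dvmdt_max_repol"]],
               tolerance = 1e-9)
  expect_equal(got[["vm_peak"]], want[["vm_peak"]], tolerance = 1e-12)
  # durations within one grid step of the analytic crossings
  expect_lt(abs(got[["apd90"]] - want[["apd90"]]), dt)
  expect_lt(abs(got[["apd50"]] - want[["apd50"]]), dt)
  expect_lt(abs(got[["apd_tri"]] - want[["apd_tri"]]), dt)
  expect_identical(got[["apd_tri"]], got[["apd90"]] - got[["apd50"]])
})

test_that("AP features are invariant to time translation of the beat", {
  dt <- 0.1
  f20 <- ap_features(beat_slice(
    make_bundle(trapezoid_vm(dt = dt, t0 = 20, cycle_length = 500),
                dt = dt), 1))
  f70 <- ap_features(beat_slice(
    make_bundle(trapezoid_vm(dt = dt, t0 = 70, cycle_length = 500),
                dt = dt), 1))
  expect_equal(f20, f70, tolerance = 1e-9)
})

test_that("AP extraction flags flat beats and repolarisation failure", {
  dt <- 0.1
  flat <- make_bundle(rep(-85, 4000), dt = dt)
  expect_error(ap_features(beat_slice(flat, 1)), "no AP")
  # upstroke then a plateau that never repolarises -> NA durations, no error
  t <- seq(0, 400 - dt, by = dt)
  stuck <- piecewise(t, c(0, 1, 400), c(-85, 35, 35))
  f <- ap_features(beat_slice(make_bundle(stuck, dt = dt), 1))
  expect_true(is.na(f[["apd90"]]))
  expect_true(is.na(f[["apd50"]]))
  expect_equal(f[["dvmdt_max"]], 120, tolerance = 1e-9)
})

test_that("Ca features match the triangular fixture's analytic values", {
  dt <- 0.1
  vm <- trapezoid_vm(dt = dt, cycle_length = 500)
  b <- make_bundle(vm, triangle_cai(dt = dt), dt = dt)
  got <- ca_features(beat_slice(b, 1))
  want <- triangle_oracle()
  expect_equal(got[["ca_peak"]], want[["ca_peak"]], tolerance = 1e-12)
  expect_lt(abs(got[["cad90"]] - want[["cad90"]]), dt)
  expect_lt(abs(got[["cad50"]] - want[["cad50"]]), dt)
  expect_lt(abs(got[["cad_tri"]] - want[["cad_tri"]]), dt)
  expect_identical(got[["cad_tri"]], got[["cad90"]] - got[["cad50"]])
  expect_error(ca_features(beat_slice(make_bundle(vm, rep(1e-4, length(vm)),
                                                  dt = dt), 1)),
               "no transient")
})

test_that("Ca durations are invariant to amplitude scaling", {
  dt <- 0.1
  vm <- trapezoid_vm(dt = dt, cycle_length = 500)
  base <- ca_features(beat_slice(make_bundle(vm, triangle_cai(dt = dt),
                                             dt = dt), 1))
  doubled <- ca_features(beat_slice(make_bundle(
    vm, triangle_cai(dt = dt, peak = 7e-4), dt = dt), 1))
  expect_equal(doubled[["cad50"]], base[["cad50"]], tolerance = 1e-9)
  expect_equal(doubled[["cad90"]], base[["cad90"]], tolerance = 1e-9)
  expect_equal(doubled[["ca_peak"]] - 1e-4, 2 * (base[["ca_peak"]] - 1e-4),
               tolerance = 1e-9)
})

test_that("features converge under grid refinement", {
  coarse <- c(ap_features(beat_slice(make_bundle(trapezoid_vm(dt = 0.1),
                                                 dt = 0.1), 1)),
              ca_features(beat_slice(make_bundle(
                trapezoid_vm(dt = 0.1, cycle_length = 500),
                triangle_cai(dt = 0.1), dt = 0.1), 1)))
  fine <- c(ap_features(beat_slice(make_bundle(trapezoid_vm(dt = 0.05),
                                               dt = 0.05), 1)),
            ca_features(beat_slice(make_bundle(
              trapezoid_vm(dt = 0.05, cycle_length = 500),
              triangle_cai(dt = 0.05), dt = 0.05), 1)))
  expect_true(all(abs(fine - coarse) / pmax(abs(coarse), 1e-12) < 0.001))
})

test_that("interpolated crossings agree with a brute-force grid scan", {
  dt <- 0.1
  set.seed(31)
  for (i in 1:10) {
    peak <- runif(1, 20, 45)
    b <- make_bundle(trapezoid_vm(dt = dt, peak = peak), dt = dt)
    beat <- beat_slice(b, 1)
    f <- ap_features(beat)
    amp <- peak - (-85)
    for (frac in c(0.5, 0.9)) {
      level <- peak - frac * amp
      i_peak <- which.max(beat$vm)
      after <- which(beat$vm < level & seq_along(beat$vm) > i_peak)[1]
      scan_time <- beat$time[after]   # first grid point below the level
      apd_name <- if (frac == 0.5) "apd50" else "apd90"
      t_act <- 0.45   # centre of the discrete maximal-slope run
      expect_lt(abs((f[[apd_name]] + t_act) - scan_time), dt + 1e-12)
    }
  }
})

test_that("qNet integrates the six-current sum exactly on linear fixtures", {
  dt <- 0.1
  cl <- 400
  zero_beat <- make_bundle(trapezoid_vm(dt = dt), dt = dt)
  expect_equal(qnet(beat_slice(zero_beat, 1)), 0)

  # single near-rectangular current, closed-form trapezoid area
  cur <- pulse_current(dt = dt, amp = 0.1, t_on = 100, t_off = 200, ramp = 1)
  b <- make_bundle(trapezoid_vm(dt = dt), current_beats = list(IKr = cur),
                   dt = dt)
  expect_equal(qnet(beat_slice(b, 1)), 0.1 * (100 - 1) / 1000,
               tolerance = 1e-12)

  # superposition: qnet of a sum is the sum of qnets (random fixtures)
  set.seed(17)
  for (i in 1:5) {
    amps <- rnorm(6, 0, 0.3)
    curs <- lapply(stats::setNames(amps, qnet_channels()), function(a) {
      pulse_current(dt = dt, amp = a, t_on = runif(1, 10, 150),
                    t_off = runif(1, 200, 380), ramp = 2)
    })
    ball <- make_bundle(trapezoid_vm(dt = dt), current_beats = curs, dt = dt)
    total <- qnet(beat_slice(ball, 1))
    parts <- vapply(qnet_channels(), function(ch) {
      bone <- make_bundle(trapezoid_vm(dt = dt),
                          current_beats = curs[ch], dt = dt)
      qnet(beat_slice(bone, 1))
    }, numeric(1))
    expect_equal(total, sum(parts), tolerance = 1e-10)
  }

  incomplete <- make_bundle(trapezoid_vm(dt = dt), dt = dt)
  incomplete$currents$IKs <- NULL
  expect_error(qnet(beat_slice(incomplete, 1)), "IKs")
})

test_that("qInward averages the fractional inward charges", {
  dt <- 0.1
  mk <- function(scale_cal, scale_nal) {
    make_bundle(trapezoid_vm(dt = dt),
                current_beats = list(
                  ICaL = pulse_current(dt = dt, amp = -0.4 * scale_cal),
                  INaL = pulse_current(dt = dt, amp = -0.1 * scale_nal)),
                dt = dt)
  }
  ctrl <- beat_slice(mk(1, 1), 1)
  expect_equal(qinward(ctrl, ctrl), 1.0)
  expect_equal(qinward(beat_slice(mk(0.5, 0.5), 1), ctrl), 0.5,
               tolerance = 1e-12)
  expect_equal(qinward(beat_slice(mk(0.8, 0.4), 1), ctrl), 0.6,
               tolerance = 1e-12)
  degenerate <- beat_slice(make_bundle(trapezoid_vm(dt = dt), dt = dt), 1)
  expect_error(qinward(ctrl, degenerate), "degenerate control")
})

test_that("worst-beat selection finds the steepest repolarisation, ties latest", {
  dt <- 0.1
  # beat with descent over 100 ms (slope -1.2) vs over 80 ms (slope -1.5)
  t <- seq(0, 400 - dt, by = dt)
  slow <- piecewise(t, c(0, 1, 200, 300, 400), c(-85, 35, 35, -85, -85))
  steep <- piecewise(t, c(0, 1, 200, 280, 400), c(-85, 35, 35, -85, -85))
  b <- make_bundle(list(slow, slow, steep, slow, slow), dt = dt)
  expect_equal(select_worst_beat(b), 3)
  ties <- make_bundle(list(slow, slow, slow), dt = dt)
  expect_equal(select_worst_beat(ties), 3)   # all equal -> latest
  single <- make_bundle(steep, dt = dt)
  expect_equal(select_worst_beat(single), 1)
})

test_that("concentration averaging is the component mean with NA propagation", {
  v <- stats::setNames(as.numeric(1:12), feature_names())
  expect_equal(average_over_concentrations(list(v, v, v, v)), v)
  vs <- lapply(c(300, 310, 320, 330), function(a) {
    w <- v; w[["apd90"]] <- a; w
  })
  expect_equal(average_over_concentrations(vs)[["apd90"]], 315)
  vs[[2]][["cad90"]] <- NA_real_
  out <- average_over_concentrations(vs)
  expect_true(is.na(out[["cad90"]]))
  expect_equal(out[["apd90"]], 315)
  expect_error(average_over_concentrations(vs[1:3]), "exactly 4")
})
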