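test_that("packaged reference drug table parses into 28 records with the right splits", {
  drugs <- fresh_drug_table()
  expect_length(drugs, 28)
  splits <- vapply(drugs, `[[`, character(1), "split")
  expect_equal(sum(splits == "train"), 12)
  expect_equal(sum(splits == "test"), 16)
  risks <- vapply(drugs, function(d) as.character(d$risk_label), character(1))
  expect_equal(as.vector(table(risks)[c("high", "intermediate", "low")]),
               c(8L, 11L, 9L))
  dof <- drugs[[which(vapply(drugs, `[[`, character(1), "drug_name") ==
                        "Dofetilide")]]
  expect_equal(dof$cmax, 2)
  expect_length(dof$blocks, 0)  # no block table supplied -> all unblocked
})

test_that("drug table reader rejects malformed input with named errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines("drug,cmax_nM,risk,split", empty)
  expect_error(read_drug_table(empty), "no drug rows")

  nocmax <- tempfile(fileext = ".csv")
  writeLines(c("drug,cmax_nM,risk,split", "FooMycin,,high,train"), nocmax)
  expect_error(read_drug_table(nocmax), "FooMycin")

  drugs <- tempfile(fileext = ".csv")
  writeLines(c("drug,cmax_nM,risk,split", "FooMycin,10,high,train"), drugs)
  badchan <- tempfile(fileext = ".csv")
  writeLines(c("drug,channel,ic50_nM,hill", "FooMycin,IKq,5,1"), badchan)
  expect_error(read_drug_table(drugs, block_file = badchan), "IKr")
  negic <- tempfile(fileext = ".csv")
  writeLines(c("drug,channel,ic50_nM,hill", "FooMycin,IKr,-5,1"), negic)
  expect_error(read_drug_table(drugs, block_file = negic), "IC50")
})

test_that("remaining-conductance fraction follows the Hill pore-block law", {
  expect_equal(inhibition_factor(0, 50, 1.2), 1.0)
  for (h in c(0.5, 1, 2, 4)) {
    expect_equal(inhibition_factor(50, 50, h), 0.5)
  }
  expect_equal(inhibition_factor(100, 50, 1), 1 / 3)
  expect_error(inhibition_factor(-1, 50, 1), "non-negative")
  expect_error(inhibition_factor(1, -50, 1), "positive")
  # strictly decreasing in dose, range (0, 1]
  set.seed(101)
  for (i in 1:20) {
    ic50 <- exp(runif(1, log(0.1), log(1e4)))
    h <- exp(runif(1, log(0.3), log(4)))
    doses <- sort(exp(runif(50, log(1e-3), log(1e6))))
    v <- inhibition_factor(doses, ic50, h)
    expect_true(all(diff(v) < 0))
    expect_true(all(v > 0 & v <= 1))
  }
})

test_that("Hill fit round-trips noiseless curves and flags degenerate input", {
  set.seed(7)
  for (i in 1:25) {
    ic50 <- exp(runif(1, log(1), log(1e4)))
    h <- exp(runif(1, log(0.4), log(3)))
    d <- c(0.1, 1, 10, 100) * ic50
    y <- 1 - inhibition_factor(d, ic50, h)
    fit <- fit_hill(data.frame(dose_nM = d, inhibition = y))
    expect_lt(abs(fit$ic50 - ic50) / ic50, 1e-6)
    expect_lt(abs(fit$hill_h - h) / h, 1e-6)
    expect_lt(fit$residual_sd, 1e-7)
  }
  expect_error(fit_hill(data.frame(dose_nM = c(1, 10, 100),
                                   inhibition = c(0.5, 0.5, 0.5))),
               "no dose response")
  expect_error(fit_hill(data.frame(dose_nM = c(1, 10),
                                   inhibition = c(0.2, 0.8))),
               "underdetermined")
  expect_error(fit_hill(data.frame(dose_nM = c(1, 1, 1, 10),
                                   inhibition = c(0.1, 0.12, 0.11, 0.8))),
               "underdetermined")
})

test_that("Hill fit agrees with an independent nonlinear least-squares solver", {
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  for (i in 1:10) {
    ic50 <- exp(runif(1, log(5), log(500)))
    h <- exp(runif(1, log(0.5), log(2.5)))
    d <- c(0.05, 0.3, 1, 5, 30) * ic50
    y <- pmin(pmax(1 - inhibition_factor(d, ic50, h) + rnorm(5, 0, 0.04), 0), 1)
    mine <- fit_hill(data.frame(dose_nM = d, inhibition = y))
    ref <- minpack.lm::nlsLM(
      y ~ 1 - 1 / (1 + (d / exp(lic))^exp(lh)),
      start = list(lic = log(ic50), lh = log(h)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    expect_equal(mine$ic50, exp(coef(ref)[["lic"]]), tolerance = 1e-4)
    expect_equal(mine$hill_h, exp(coef(ref)[["lh"]]), tolerance = 1e-4)
  }
})

test_that("bootstrap uncertainty cloud honours its contract", {
  d <- c(0.1, 1, 10, 100) * 40
  y0 <- 1 - inhibition_factor(d, 40, 1.1)
  block_clean <- drug_channel_block("drugA", "IKr",
                                    raw_points = data.frame(dose_nM = d,
                                                            inhibition = y0))
  # zero residual noise -> all samples identical to the point estimate
  s0 <- sample_hill_uncertainty(block_clean, n = 2000, seed = 5)
  expect_equal(nrow(s0$samples), 2000)
  expect_lt(diff(range(s0$samples$ic50)), 1e-9)
  expect_lt(diff(range(s0$samples$hill_h)), 1e-9)

  set.seed(9)
  noisy <- pmin(pmax(y0 + rnorm(4, 0, 0.05), 0), 1)
  block <- drug_channel_block("drugA", "IKr",
                              raw_points = data.frame(dose_nM = d,
                                                      inhibition = noisy))
  s1 <- sample_hill_uncertainty(block, n = 500, seed = 5)
  s2 <- sample_hill_uncertainty(block, n = 500, seed = 5)
  expect_identical(s1$samples, s2$samples)          # same seed, same cloud
  expect_true(all(s1$samples$ic50 > 0 & s1$samples$hill_h > 0))
  expect_error(sample_hill_uncertainty(block, n = 0), "n must be")

  # dispersion shrinks with the residual noise (continuity of the resampler)
  mild <- pmin(pmax(y0 + rnorm(4, 0, 0.005), 0), 1)
  block_mild <- drug_channel_block("drugA", "IKr",
                                   raw_points = data.frame(dose_nM = d,
                                                           inhibition = mild))
  s3 <- sample_hill_uncertainty(block_mild, n = 500, seed = 5)
  expect_lt(sd(log(s3$samples$ic50)), sd(log(s1$samples$ic50)))

  # 2.5-97.5 percentile band of the implied curves contains the point fit
  fit <- fit_hill(block$raw_points)
  grid <- exp(seq(log(min(d)), log(max(d)), length.out = 9))
  curves <- sapply(seq_len(nrow(s1$samples)), function(i) {
    1 - inhibition_factor(grid, s1$samples$ic50[i], s1$samples$hill_h[i])
  })
  point <- 1 - inhibition_factor(grid, fit$ic50, fit$hill_h)
  lo <- apply(curves, 1, quantile, 0.025)
  hi <- apply(curves, 1, quantile, 0.975)
  expect_true(all(point >= lo - 1e-9 & point <= hi + 1e-9))
})

test_that("parametric fallback draws positive lognormal clouds per seed stream", {
  block <- drug_channel_block("drugB", "ICaL", ic50 = 120, hill_h = 0.9)
  s <- sample_hill_uncertainty(block, n = 1000, seed = 2, cv = 0.2)
  expect_true(all(s$samples$ic50 > 0))
  expect_equal(median(s$samples$ic50), 120, tolerance = 0.05)
  # different channel key -> different stream under the same master seed
  block2 <- drug_channel_block("drugB", "IKr", ic50 = 120, hill_h = 0.9)
  s2 <- sample_hill_uncertainty(block2, n = 1000, seed = 2, cv = 0.2)
  expect_false(identical(s$samples$ic50, s2$samples$ic50))
})

test_that("hill sample sets serialise to the flat CSV dialect", {
  block <- drug_channel_block("drugB", "ICaL", ic50 = 120, hill_h = 0.9)
  s <- sample_hill_uncertainty(block, n = 10, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_hill_samples(list(s), path)
  back <- read.csv(path)
  expect_equal(nrow(back), 10)
  expect_equal(names(back), c("drug", "channel", "sample_index",
                              "ic50_nM", "hill"))
  expect_equal(back$ic50_nM, s$samples$ic50)
})
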