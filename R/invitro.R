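#' One drug x channel Hill description of channel block
#'
#' Holds the fitted half-maximal inhibitory concentration and Hill
#' coefficient for one drug acting on one ion channel, optionally together
#' with the raw dose-inhibition measurements the fit came from.
#'
#' @param drug_name Drug identifier.
#' @param channel One of [tdp_channels()].
#' @param ic50 IC50 in nM, > 0 (may be `NULL` when only raw points are given).
#' @param hill_h Hill coefficient, > 0 (may be `NULL` as above).
#' @param raw_points Optional data.frame with columns `dose_nM` (> 0) and
#'   `inhibition` (fractional block in \[0, 1\]).
#' @return An object of class `drug_channel_block`.
#' @export
drug_channel_block <- function(drug_name, channel, ic50 = NULL, hill_h = NULL,
                               raw_points = NULL) {
  if (!channel %in% tdp_channels()) {
    stop("unknown channel '", channel, "'; accepted: ",
         paste(tdp_channels(), collapse = ", "))
  }
  if (!is.null(ic50) && (!is.finite(ic50) || ic50 <= 0)) {
    stop("ic50 must be positive for ", drug_name, "/", channel)
  }
  if (!is.null(hill_h) && (!is.finite(hill_h) || hill_h <= 0)) {
    stop("hill_h must be positive for ", drug_name, "/", channel)
  }
  if (!is.null(raw_points)) {
    stopifnot(all(c("dose_nM", "inhibition") %in% names(raw_points)))
    if (any(raw_points$inhibition < 0 | raw_points$inhibition > 1)) {
      stop("raw inhibition values must lie in [0, 1] (",
           drug_name, "/", channel, ")")
    }
    if (any(raw_points$dose_nM <= 0)) {
      stop("raw doses must be positive (", drug_name, "/", channel, ")")
    }
  }
  structure(list(drug_name = drug_name, channel = channel, ic50 = ic50,
                 hill_h = hill_h, raw_points = raw_points),
            class = "drug_channel_block")
}

#' One drug of the reference set: Cmax, ordinal risk label, channel blocks
#'
#' @param drug_name Drug identifier.
#' @param cmax Maximum free therapeutic plasma concentration, nM, > 0.
#'   Simulated doses are the integer multiples 1-4 x Cmax.
#' @param risk_label One of `"low"`, `"intermediate"`, `"high"`.
#' @param split `"train"` or `"test"`.
#' @param blocks Named list of [drug_channel_block()] objects, one per
#'   measured channel; channels absent from the list are treated as
#'   unblocked (conductance multiplier 1).
#' @return An object of class `drug_record`.
#' @export
drug_record <- function(drug_name, cmax, risk_label, split = "train",
                        blocks = list()) {
  if (!is.finite(cmax) || cmax <= 0) {
    stop("missing or non-positive Cmax for drug '", drug_name, "'")
  }
  risk <- as_risk(risk_label)
  if (is.na(risk)) stop("missing risk label for drug '", drug_name, "'")
  if (!split %in% c("train", "test")) stop("split must be 'train' or 'test'")
  if (length(blocks) > 0) {
    names(blocks) <- vapply(blocks, function(b) b$channel, character(1))
  }
  structure(list(drug_name = drug_name, cmax = cmax, risk_label = risk,
                 split = split, blocks = blocks),
            class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat(sprintf("<drug_record> %s  Cmax %g nM  risk %s  split %s  channels: %s\n",
              x$drug_name, x$cmax, as.character(x$risk_label), x$split,
              if (length(x$blocks)) paste(names(x$blocks), collapse = ",")
              else "(none)"))
  invisible(x)
}

#' Read a CiPA-style drug table (and optional channel-block tables)
#'
#' The drug-level file has columns `drug`, `cmax_nM`, `risk`, `split`.
#' An optional summary block file has columns `drug`, `channel`, `ic50_nM`,
#' `hill`; an optional raw block file has columns `drug`, `channel`,
#' `dose_nM`, `inhibition` (several rows per drug-channel). Channels not
#' present in either file are recorded as unblocked.
#'
#' @param drug_file Path to the drug-level CSV.
#' @param block_file Optional path to the Hill-summary CSV.
#' @param raw_file Optional path to the raw dose-inhibition CSV.
#' @return List of [drug_record()] objects, one per drug.
#' @examples
#' drugs <- read_drug_table(system.file("extdata", "cipa_drugs.csv",
#'                                      package = "tdprisk"))
#' length(drugs)  # 28 reference drugs
#' @export
read_drug_table <- function(drug_file, block_file = NULL, raw_file = NULL) {
  if (!file.exists(drug_file)) stop("file not found: ", drug_file)
  tab <- utils::read.csv(drug_file, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no drug rows in ", drug_file)
  need <- c("drug", "cmax_nM", "risk", "split")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(tab$cmax_nM)) {
    stop("missing Cmax for drug(s): ",
         paste(tab$drug[is.na(tab$cmax_nM)], collapse = ", "))
  }

  blocks_by_drug <- list()
  if (!is.null(block_file)) {
    bl <- utils::read.csv(block_file, stringsAsFactors = FALSE)
    if (any(bl$ic50_nM <= 0)) {
      stop("non-positive IC50 in block table for drug(s): ",
           paste(unique(bl$drug[bl$ic50_nM <= 0]), collapse = ", "))
    }
    for (i in seq_len(nrow(bl))) {
      b <- drug_channel_block(bl$drug[i], bl$channel[i],
                              ic50 = bl$ic50_nM[i], hill_h = bl$hill[i])
      blocks_by_drug[[bl$drug[i]]] <- c(blocks_by_drug[[bl$drug[i]]], list(b))
    }
  }
  if (!is.null(raw_file)) {
    rw <- utils::read.csv(raw_file, stringsAsFactors = FALSE)
    for (key in unique(paste(rw$drug, rw$channel, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- rw[rw$drug == parts[1] & rw$channel == parts[2], , drop = FALSE]
      b <- drug_channel_block(parts[1], parts[2],
                              raw_points = sub[, c("dose_nM", "inhibition")])
      blocks_by_drug[[parts[1]]] <- c(blocks_by_drug[[parts[1]]], list(b))
    }
  }

  lapply(seq_len(nrow(tab)), function(i) {
    drug_record(tab$drug[i], tab$cmax_nM[i], tab$risk[i], tab$split[i],
                blocks = blocks_by_drug[[tab$drug[i]]] %||% list())
  })
}

# ---- Hill least squares ------------------------------------------------

# Vectorised damped Gauss-Newton least squares for the Hill inhibition
# curve y = plogis(h * (log d - log ic50)), parameterised in
# (u, v) = (log ic50, log h) so positivity is structural. `y` is an
# n_dose x m matrix: m independent curves sharing the dose grid are fitted
# simultaneously (the bootstrap path fits 2,000 at once).
# Returns list(ic50, hill_h, converged, rss) of length-m vectors.
hill_ls <- function(doses, y, max_iter = 500L, tol = 1e-18) {
  y <- as.matrix(y)
  n <- length(doses)
  m <- ncol(y)
  stopifnot(nrow(y) == n, all(doses > 0))
  l <- log(doses)

  # start from the logit-scale linearisation
  z <- qlogis(pmin(pmax(y, 1e-4), 1 - 1e-4))
  lc <- l - mean(l)
  h0 <- as.vector(crossprod(lc, z)) / sum(lc^2)
  h0[!is.finite(h0) | h0 <= 0.05] <- 0.5
  u <- mean(l) - colMeans(z) / h0
  v <- log(h0)

  sse_of <- function(u, v, cols = seq_len(m)) {
    k <- length(u)
    mu <- plogis(exp(rep(v, each = n)) * (rep(l, k) - rep(u, each = n)))
    dim(mu) <- c(n, k)
    list(mu = mu, sse = colSums((y[, cols, drop = FALSE] - mu)^2))
  }
  cur <- sse_of(u, v)
  lambda <- rep(1e-3, m)
  active <- rep(TRUE, m)

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    h <- exp(v)
    s <- outer(l, u, "-") * rep(h, each = n)      # n x m
    mu <- plogis(s)
    w <- mu * (1 - mu)
    r <- y - mu
    J1 <- -rep(h, each = n) * w                   # d mu / d u
    J2 <- s * w                                   # d mu / d v
    A11 <- colSums(J1 * J1); A12 <- colSums(J1 * J2); A22 <- colSums(J2 * J2)
    b1 <- colSums(J1 * r);   b2 <- colSums(J2 * r)
    g2 <- b1^2 + b2^2                             # squared gradient/2 norm

    step_ok <- rep(FALSE, m)
    for (k in 1:8) {  # Levenberg damping: retry rejected replicates
      idx <- active & !step_ok
      if (!any(idx)) break
      d11 <- A11[idx] + lambda[idx]; d22 <- A22[idx] + lambda[idx]
      det <- d11 * d22 - A12[idx]^2
      du <- (d22 * b1[idx] - A12[idx] * b2[idx]) / det
      dv <- (d11 * b2[idx] - A12[idx] * b1[idx]) / det
      ut <- u[idx] + du; vt <- pmin(pmax(v[idx] + dv, -6), 6)
      trial <- sse_of(ut, vt, cols = which(idx))
      better <- trial$sse <= cur$sse[idx] + 1e-15
      take <- which(idx)[better]
      if (length(take) > 0) {
        u[take] <- ut[better]; v[take] <- vt[better]
        cur$sse[take] <- trial$sse[better]
        lambda[take] <- pmax(lambda[take] / 3, 1e-10)
        step_ok[take] <- TRUE
      }
      lambda[which(idx)[!better]] <- lambda[which(idx)[!better]] * 10
    }
    active[g2 < tol] <- FALSE
  }

  # final gradient check for the convergence flag
  h <- exp(v)
  s <- outer(l, u, "-") * rep(h, each = n)
  mu <- plogis(s); w <- mu * (1 - mu); r <- y - mu
  g2 <- colSums(-rep(h, each = n) * w * r)^2 + colSums(s * w * r)^2
  list(ic50 = exp(u), hill_h = exp(v),
       converged = is.finite(g2) & g2 < 1e-8, rss = cur$sse)
}

#' Fit a Hill curve to raw dose-inhibition points
#'
#' Ordinary nonlinear least squares of
#' `inhibition = 1 - 1 / (1 + (dose / ic50)^h)` on the original inhibition
#' scale, via damped Gauss-Newton in (log IC50, log h).
#'
#' @param points Data.frame (or list of pairs) with columns `dose_nM` and
#'   `inhibition`; at least 3 points at 3 distinct positive doses.
#' @return List of class `hill_fit`: `ic50`, `hill_h`, `residual_sd`
#'   (sqrt(RSS / (n - 2)), fuel for the bootstrap resampler), `fitted`,
#'   `residuals`, `points`, `converged`.
#' @examples
#' d <- c(5, 50, 500, 5000)
#' y <- 1 - inhibition_factor(d, ic50 = 50, hill_h = 1.2)
#' fit_hill(data.frame(dose_nM = d, inhibition = y))
#' @export
fit_hill <- function(points) {
  pts <- as.data.frame(points)
  if (!all(c("dose_nM", "inhibition") %in% names(pts))) {
    names(pts)[1:2] <- c("dose_nM", "inhibition")
  }
  pts <- pts[is.finite(pts$dose_nM) & is.finite(pts$inhibition), , drop = FALSE]
  if (length(unique(pts$dose_nM[pts$dose_nM > 0])) < 3) {
    stop("underdetermined: need >= 3 distinct positive doses")
  }
  if (diff(range(pts$inhibition)) == 0) {
    stop("no dose response: all inhibition values identical")
  }
  fit <- hill_ls(pts$dose_nM, matrix(pts$inhibition, ncol = 1))
  mu <- plogis(fit$hill_h * (log(pts$dose_nM) - log(fit$ic50)))
  res <- pts$inhibition - mu
  structure(list(ic50 = fit$ic50, hill_h = fit$hill_h,
                 residual_sd = sqrt(sum(res^2) / (nrow(pts) - 2)),
                 fitted = mu, residuals = res, points = pts,
                 converged = fit$converged),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> IC50 = %.4g nM, h = %.4g, residual SD = %.3g (n = %d)\n",
              x$ic50, x$hill_h, x$residual_sd, nrow(x$points)))
  invisible(x)
}

#' Bootstrap uncertainty cloud for one drug-channel Hill curve
#'
#' Quantifies in vitro uncertainty as `n` resampled (IC50, h) pairs.
#' When raw dose-inhibition points are available the sampler is a residual
#' bootstrap: fitted values plus resampled fit residuals are refitted per
#' replicate, so IC50 and h are drawn jointly and their correlation is
#' preserved. Without raw points a lognormal parametric fallback around
#' the point estimates is used, controlled by `cv`.
#'
#' @param block A [drug_channel_block()].
#' @param n Number of samples (default 2000).
#' @param seed Master seed; the actual stream is derived from
#'   (seed, drug, channel) so per-drug results do not depend on the order
#'   drugs are processed in.
#' @param cv Coefficient of variation for the parametric fallback
#'   (applied to both IC50 and h), default 0.1.
#' @return Object of class `hill_sample_set` with a `samples` data.frame
#'   (`ic50`, `hill_h`), all positive; same seed reproduces the same set.
#' @export
sample_hill_uncertainty <- function(block, n = 2000, seed = 1L, cv = 0.1) {
  if (n < 1) stop("n must be >= 1")
  sub_seed <- derive_seed(seed, paste(block$drug_name, block$channel))
  if (!is.null(block$raw_points)) {
    fit <- fit_hill(block$raw_points)
    res <- fit$residuals
    if (max(abs(res)) < 1e-12) {
      samples <- data.frame(ic50 = rep(fit$ic50, n),
                            hill_h = rep(fit$hill_h, n))
    } else {
      nd <- length(fit$fitted)
      ystar <- with_seed(sub_seed, {
        matrix(fit$fitted, nd, n) +
          matrix(sample(res, nd * n, replace = TRUE), nd, n)
      })
      ystar <- pmin(pmax(ystar, 0), 1)
      refit <- hill_ls(fit$points$dose_nM, ystar)
      if (mean(refit$converged) < 0.5) {
        stop("unstable uncertainty: bootstrap refit diverged in ",
             round(100 * mean(!refit$converged)), "% of replicates (",
             block$drug_name, "/", block$channel, ")")
      }
      samples <- data.frame(ic50 = refit$ic50, hill_h = refit$hill_h)
    }
  } else if (!is.null(block$ic50) && !is.null(block$hill_h)) {
    sdlog <- sqrt(log(1 + cv^2))
    samples <- with_seed(sub_seed, data.frame(
      ic50 = block$ic50 * exp(rnorm(n, -sdlog^2 / 2, sdlog)),
      hill_h = block$hill_h * exp(rnorm(n, -sdlog^2 / 2, sdlog))))
  } else {
    stop("block has neither raw points nor (ic50, hill_h) point estimates")
  }
  structure(list(drug_name = block$drug_name, channel = block$channel,
                 samples = samples, n_samples = n, seed = seed),
            class = "hill_sample_set")
}

#' @export
print.hill_sample_set <- function(x, ...) {
  cat(sprintf("<hill_sample_set> %s/%s: %d samples, IC50 median %.4g nM, h median %.3g\n",
              x$drug_name, x$channel, x$n_samples,
              stats::median(x$samples$ic50), stats::median(x$samples$hill_h)))
  invisible(x)
}

#' Serialise Hill sample sets to the flat CSV interchange format
#'
#' One row per (drug, channel, sample_index) with columns
#' `drug, channel, sample_index, ic50_nM, hill`.
#'
#' @param sets List of `hill_sample_set` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hill_samples <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    data.frame(drug = s$drug_name, channel = s$channel,
               sample_index = seq_len(s$n_samples),
               ic50_nM = s$samples$ic50, hill = s$samples$hill_h)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
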