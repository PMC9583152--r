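#' Fit a single-feature proportional-odds ordinal regression
#'
#' Maximum-likelihood fit of the three-level cumulative-logit model
#' \deqn{P(Y \le j \mid x) = \mathrm{logistic}(\zeta_j - \beta x), \quad
#'   j \in \{low, intermediate\},}
#' with the cutpoint ordering enforced structurally through the
#' reparameterisation \eqn{\zeta_2 = \zeta_1 + e^\delta}. The negative
#' log-likelihood is minimised by damped Newton iterations with an
#' analytic gradient (finite-difference Hessian) and a halving line
#' search, so the recorded log-likelihood trace is non-decreasing; three
#' deterministic restarts from perturbed starts guard against poor basins,
#' the best likelihood winning. `x` is standardised internally and the
#' coefficients mapped back, so fits are equivariant under affine
#' rescaling of the feature.
#'
#' The feature-unit decision thresholds are \eqn{TH_j = \zeta_j / \beta}:
#' TH1 separates low from intermediate/high risk and TH2 separates high
#' from intermediate/low. When the feature decreases with risk
#' (\eqn{\beta < 0}), TH1 > TH2.
#'
#' Complete separation does not raise an error: the fit is returned with
#' `converged = FALSE` and a diagnostic, and thresholds are absent.
#'
#' @param x Numeric feature values; rows with missing `x` are dropped
#'   (the count is kept in `n_dropped`).
#' @param y Risk labels coercible by [as_risk()]; all three classes must
#'   be present.
#' @param feature_name Stored label for reporting.
#' @param max_iter Newton iteration cap per restart.
#' @param grad_tol Convergence threshold on the sup-norm of the
#'   per-observation mean gradient.
#' @return Object of class `olr_fit`: `beta`, `zeta` (two increasing
#'   cutpoints), `th1`, `th2`, `converged`, `loglik`, `fit_log`
#'   (log-likelihood trace of the winning restart), `n`, `n_dropped`,
#'   `diagnostic`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 0), rnorm(200, 5), rnorm(200, 10))
#' y <- rep(c("low", "intermediate", "high"), each = 200)
#' fit <- fit_olr(x, y)
#' thresholds(fit)   # near the equal-probability boundaries 2.5 and 7.5
#' @export
fit_olr <- function(x, y, feature_name = NULL,
                    max_iter = 200L, grad_tol = 1e-8) {
  if (is.null(feature_name)) {
    feature_name <- paste(deparse(substitute(x)), collapse = " ")
    if (nchar(feature_name) > 30) feature_name <- "feature"
  }
  y <- as_risk(y)
  keep <- is.finite(x) & !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- as.integer(y[keep])
  if (length(unique(y)) < 3) {
    stop("all three risk classes must be present in the training labels")
  }
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) s <- 1
  xs <- (x - m) / s
  n <- length(xs)

  nll_grad <- function(th) {
    b <- th[1]; z1 <- th[2]; z2 <- z1 + exp(th[3])
    a1 <- z1 - b * xs; a2 <- z2 - b * xs
    F1 <- plogis(a1); F2 <- plogis(a2)
    p <- cbind(F1, F2 - F1, 1 - F2)
    pi <- pmax(p[cbind(seq_len(n), y)], 1e-300)
    # analytic gradient of the negative log-likelihood
    g_z1 <- g_z2 <- g_b <- numeric(n)
    i1 <- y == 1; i2 <- y == 2; i3 <- y == 3
    g_z1[i1] <- 1 - F1[i1]
    g_b[i1] <- -xs[i1] * (1 - F1[i1])
    f1 <- F1 * (1 - F1); f2 <- F2 * (1 - F2)
    g_z1[i2] <- -f1[i2] / pi[i2]
    g_z2[i2] <- f2[i2] / pi[i2]
    g_b[i2] <- xs[i2] * (f1[i2] - f2[i2]) / pi[i2]
    g_z2[i3] <- -F2[i3]
    g_b[i3] <- xs[i3] * F2[i3]
    grad_ll <- c(sum(g_b), sum(g_z1) + sum(g_z2), sum(g_z2) * exp(th[3]))
    list(nll = -sum(log(pi)), grad = -grad_ll)
  }

  run_newton <- function(start) {
    th <- start
    cur <- nll_grad(th)
    trace <- -cur$nll
    for (iter in seq_len(max_iter)) {
      g <- cur$grad
      if (max(abs(g)) / n < grad_tol) break
      # finite-difference Hessian of the 3-parameter NLL
      H <- matrix(0, 3, 3)
      eps <- 1e-5 * pmax(abs(th), 1)
      for (j in 1:3) {
        tp <- th; tp[j] <- tp[j] + eps[j]
        H[, j] <- (nll_grad(tp)$grad - g) / eps[j]
      }
      H <- (H + t(H)) / 2
      step <- tryCatch(solve(H + diag(1e-10, 3), g),
                       error = function(e) g / sqrt(sum(g^2)))
      if (any(!is.finite(step))) step <- g / sqrt(sum(g^2))
      # halving line search: accept only NLL decreases
      alpha <- 1
      for (k in 1:40) {
        cand <- th - alpha * step
        cand[3] <- min(cand[3], 20)
        trial <- nll_grad(cand)
        if (is.finite(trial$nll) && trial$nll <= cur$nll) break
        alpha <- alpha / 2
      }
      if (!is.finite(trial$nll) || trial$nll > cur$nll) break
      th <- cand; cur <- trial
      trace <- c(trace, -cur$nll)
    }
    list(th = th, nll = cur$nll, grad = cur$grad, trace = trace)
  }

  p1 <- mean(y == 1); p12 <- mean(y <= 2)
  z1_0 <- qlogis(min(max(p1, 1e-3), 1 - 1e-3))
  z2_0 <- qlogis(min(max(p12, 1e-3), 1 - 1e-3))
  gap0 <- log(max(z2_0 - z1_0, 0.1))
  starts <- list(c(0.1, z1_0, gap0),
                 c(1, z1_0 - 0.5, gap0 + 0.5),
                 c(-1, z1_0 + 0.5, gap0 - 0.5))
  fits <- lapply(starts, run_newton)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "nll"))]]

  th <- best$th
  beta_s <- th[1]; z1_s <- th[2]; z2_s <- z1_s + exp(th[3])
  beta <- beta_s / s
  zeta <- c(z1_s + beta_s * m / s, z2_s + beta_s * m / s)
  converged <- max(abs(best$grad)) / n < grad_tol && all(is.finite(th))
  diagnostic <- if (converged) "" else {
    "no interior optimum reached (possible complete separation)"
  }
  structure(list(
    feature_name = feature_name, beta = beta, zeta = zeta,
    th1 = if (converged && beta != 0) zeta[1] / beta else NA_real_,
    th2 = if (converged && beta != 0) zeta[2] / beta else NA_real_,
    converged = converged, loglik = -best$nll, fit_log = best$trace,
    n = n, n_dropped = n_dropped, diagnostic = diagnostic,
    scale = list(center = m, sd = s)),
    class = "olr_fit")
}

#' @export
print.olr_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<olr_fit> %s: beta = %.4g, zeta = (%.4g, %.4g), TH1 = %.4g, TH2 = %.4g (n = %d)\n",
      x$feature_name, x$beta, x$zeta[1], x$zeta[2], x$th1, x$th2, x$n))
  } else {
    cat(sprintf("<olr_fit> %s: NOT CONVERGED (%s)\n",
                x$feature_name, x$diagnostic))
  }
  invisible(x)
}

#' Feature-unit risk thresholds of a fitted ordinal model
#'
#' TH_j = zeta_j / beta: the feature values at which the cumulative
#' probability of the lower class group is exactly one half. TH1 marks
#' the low vs intermediate/high boundary and TH2 the high vs
#' intermediate/low boundary; when the feature decreases with risk
#' (beta < 0) TH1 exceeds TH2.
#'
#' @param model A converged `olr_fit`.
#' @return Named numeric `c(th1, th2)`.
#' @export
thresholds <- function(model) {
  stopifnot(inherits(model, "olr_fit"))
  if (!model$converged) stop("model did not converge; thresholds undefined")
  if (model$beta == 0) stop("uninformative feature: beta is zero")
  c(th1 = model$zeta[1] / model$beta, th2 = model$zeta[2] / model$beta)
}

#' Class membership probabilities under a fitted ordinal model
#'
#' @param model A converged `olr_fit`.
#' @param x Feature values (vectorised).
#' @return Matrix with columns `low`, `intermediate`, `high`; rows sum
#'   to 1.
#' @export
class_probabilities <- function(model, x) {
  stopifnot(inherits(model, "olr_fit"))
  if (!model$converged) stop("model did not converge")
  c1 <- plogis(model$zeta[1] - model$beta * x)
  c2 <- plogis(model$zeta[2] - model$beta * x)
  cbind(low = c1, intermediate = c2 - c1, high = 1 - c2)
}

#' Classify feature values into the three TdP risk levels
#'
#' Implements the cumulative rule: low when P(Y <= low | x) >= 1/2, high
#' when P(Y <= intermediate | x) < 1/2, intermediate otherwise. This is
#' equivalent to comparing x against (TH1, TH2) oriented by the sign of
#' beta.
#'
#' @param model A converged `olr_fit`.
#' @param x Feature values (vectorised).
#' @return Ordered factor of risk labels.
#' @export
predict_class <- function(model, x) {
  stopifnot(inherits(model, "olr_fit"))
  if (!model$converged) stop("model did not converge")
  c1 <- plogis(model$zeta[1] - model$beta * x)
  c2 <- plogis(model$zeta[2] - model$beta * x)
  lab <- ifelse(c1 >= 0.5, "low", ifelse(c2 < 0.5, "high", "intermediate"))
  as_risk(lab)
}

#' Serialise fitted ordinal models as a flat table
#'
#' One row per model with columns `feature, beta, zeta1, zeta2, th1, th2,
#' converged`; non-converged models carry NA thresholds (rendered as
#' dashes by [report()]).
#'
#' @param models List of `olr_fit` objects.
#' @param path Output CSV path; `NULL` returns the data.frame only.
#' @return The data.frame, invisibly if written.
#' @export
write_olr_models <- function(models, path = NULL) {
  df <- do.call(rbind, lapply(models, function(mdl) {
    data.frame(feature = mdl$feature_name, beta = mdl$beta,
               zeta1 = mdl$zeta[1], zeta2 = mdl$zeta[2],
               th1 = mdl$th1, th2 = mdl$th2, converged = mdl$converged)
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
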