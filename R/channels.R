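#' Ion channels handled by the pipeline
#'
#' The seven currents for which dose-inhibition data are recorded
#' (fast and late sodium, rapid and slow delayed rectifier potassium,
#' inward rectifier, transient outward, L-type calcium), and the six of
#' them whose charge enters the net-charge biomarker qNet.
#'
#' @return Character vector of channel identifiers.
#' @export
tdp_channels <- function() {
  c("INa", "INaL", "IKr", "IKs", "IK1", "Ito", "ICaL")
}

#' @rdname tdp_channels
#' @export
qnet_channels <- function() {
  c("INaL", "ICaL", "IKr", "IKs", "IK1", "Ito")
}

#' Three-level ordinal TdP risk labels, low < intermediate < high
#' @return Ordered factor levels.
#' @export
risk_levels <- function() c("low", "intermediate", "high")

#' Coerce risk labels to the canonical ordered factor
#'
#' @param x Character or factor vector of risk labels.
#' @return Ordered factor with levels low < intermediate < high.
#' @export
as_risk <- function(x) {
  x <- tolower(as.character(x))
  bad <- setdiff(unique(x[!is.na(x)]), risk_levels())
  if (length(bad) > 0) {
    stop("unknown risk label(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(risk_levels(), collapse = " < "))
  }
  factor(x, levels = risk_levels(), ordered = TRUE)
}

#' Fraction of channel conductance remaining under drug block
#'
#' Pore-block Hill model: the multiplier applied to a channel's maximum
#' conductance at drug concentration `dose` is
#' \deqn{IF(D) = 1 / (1 + (D / IC50)^h).}
#' Despite the name "inhibition factor" used in the CiPA literature, this
#' is the conductance fraction that REMAINS: it is 1 at zero dose and 1/2
#' at the IC50.
#'
#' @param dose Drug concentration (nM), >= 0. Vectorised.
#' @param ic50 Half-maximal inhibitory concentration (nM), > 0.
#' @param hill_h Hill coefficient, > 0.
#' @return Remaining conductance fraction in (0, 1].
#' @examples
#' inhibition_factor(0, 50, 1.2)    # 1: no drug, no block
#' inhibition_factor(50, 50, 3)     # 0.5 at the IC50 for any h
#' @export
inhibition_factor <- function(dose, ic50, hill_h) {
  stopifnot(is.numeric(dose), is.numeric(ic50), is.numeric(hill_h))
  if (any(dose < 0)) stop("dose must be non-negative")
  if (any(ic50 <= 0)) stop("ic50 must be positive")
  if (any(hill_h <= 0)) stop("hill_h must be positive")
  1 / (1 + (dose / ic50)^hill_h)
}
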