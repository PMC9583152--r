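#' Specification of a synthetic in vitro drug cohort
#'
#' Describes how to simulate a class-structured cohort of dose-inhibition
#' measurements. Each drug draws a true (IC50, h) per measured channel
#' from class-conditional lognormal distributions of the IC50/Cmax ratio:
#' high-risk drugs block IKr at therapeutic concentrations, low-risk
#' drugs spare IKr but tend to block ICaL (calcium-blocker-like), and
#' intermediate drugs sit between. Inhibition is then observed at four
#' doses spanning the curve with additive Gaussian noise, clipped to
#' \[0, 1\].
#'
#' @param drugs Drug-level data.frame (`drug`, `cmax_nM`, `risk`,
#'   `split`); defaults to the packaged 28-drug reference table.
#' @param ratio_medians Matrix of median IC50/Cmax ratios, rows `low`,
#'   `intermediate`, `high`, columns the measured channels.
#' @param sdlog_drug Drug-to-drug lognormal spread of the ratios.
#' @param hill_meanlog,hill_sdlog Lognormal law of the true Hill
#'   coefficients.
#' @param noise_sd Gaussian measurement noise on inhibition fractions.
#' @param dose_span Measurement doses as multiples of the true IC50.
#' @param seed Master seed.
#' @return List of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(
    drugs = NULL,
    ratio_medians = rbind(low = c(IKr = 100, ICaL = 4, INaL = 10),
                          intermediate = c(IKr = 4, ICaL = 15, INaL = 20),
                          high = c(IKr = 0.7, ICaL = 30, INaL = 20)),
    sdlog_drug = 0.5, hill_meanlog = 0, hill_sdlog = 0.15,
    noise_sd = 0.03, dose_span = c(0.1, 1, 10, 100), seed = 1L) {
  if (is.null(drugs)) {
    drugs <- utils::read.csv(system.file("extdata", "cipa_drugs.csv",
                                         package = "tdprisk"),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(risk_levels() %in% rownames(ratio_medians)),
            noise_sd >= 0, sdlog_drug >= 0,
            all(table(drugs$risk) >= 1))
  structure(list(drugs = drugs, ratio_medians = ratio_medians,
                 sdlog_drug = sdlog_drug, hill_meanlog = hill_meanlog,
                 hill_sdlog = hill_sdlog, noise_sd = noise_sd,
                 dose_span = dose_span, seed = seed),
            class = "synth_cohort_spec")
}

#' Simulate a class-structured in vitro cohort with raw dose-inhibition data
#'
#' Generates one [drug_record()] per drug of the spec, each carrying raw
#' dose-inhibition points for the measured channels; ground-truth
#' (IC50, h) values are attached as the `"truth"` attribute for recovery
#' testing. The same seed reproduces the same cohort exactly.
#'
#' @param spec A [synth_cohort_spec()].
#' @return List of `drug_record`s with attribute `truth` (data.frame
#'   `drug`, `channel`, `ic50_true`, `hill_true`).
#' @export
synth_invitro_cohort <- function(spec = synth_cohort_spec()) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  channels <- colnames(spec$ratio_medians)
  truth <- list()
  records <- lapply(seq_len(nrow(spec$drugs)), function(i) {
    d <- spec$drugs[i, ]
    blocks <- lapply(channels, function(ch) {
      sd_ch <- derive_seed(spec$seed, paste("cohort", d$drug, ch))
      with_seed(sd_ch, {
        ratio <- spec$ratio_medians[as.character(d$risk), ch] *
          exp(rnorm(1, 0, spec$sdlog_drug))
        ic50 <- ratio * d$cmax_nM
        h <- exp(rnorm(1, spec$hill_meanlog, spec$hill_sdlog))
        doses <- spec$dose_span * ic50
        inh <- 1 - inhibition_factor(doses, ic50, h) +
          rnorm(length(doses), 0, spec$noise_sd)
        truth[[paste(d$drug, ch)]] <<- data.frame(
          drug = d$drug, channel = ch, ic50_true = ic50, hill_true = h)
        drug_channel_block(d$drug, ch, raw_points = data.frame(
          dose_nM = doses, inhibition = pmin(pmax(inh, 0), 1)))
      })
    })
    drug_record(d$drug, d$cmax_nM, d$risk, d$split, blocks = blocks)
  })
  attr(records, "truth") <- do.call(rbind, unname(truth))
  records
}

#' Gaussian class-structured feature bank for classifier testing
#'
#' Builds a feature bank directly (without any simulation): per-drug
#' feature clouds are drawn from Gaussians around class mean vectors,
#' with an optional drug-level random offset so drugs within a class are
#' not identical. The output has the exact shape the classifier stages
#' consume: one row per (drug, sample_index) with the twelve feature
#' columns plus `risk` and `split`.
#'
#' @param class_means Matrix with rows `low`, `intermediate`, `high` and
#'   one column per feature (any subset of [feature_names()]).
#' @param sds Within-drug sample SD per feature (recycled).
#' @param n_per_drug Samples per drug (default 2000).
#' @param drugs_per_class Named counts of drugs per class.
#' @param train_per_class Named counts assigned to the train split
#'   (the rest are test).
#' @param drug_sd Drug-level offset SD in units of `sds`.
#' @param seed Master seed.
#' @param dataset_name Stored in the `dataset` column.
#' @return Feature-bank data.frame.
#' @export
synth_feature_bank <- function(class_means, sds, n_per_drug = 2000,
                               drugs_per_class = c(low = 5, intermediate = 7,
                                                   high = 4),
                               train_per_class = c(low = 2, intermediate = 3,
                                                   high = 2),
                               drug_sd = 0.5, seed = 1L,
                               dataset_name = "synthetic") {
  stopifnot(n_per_drug >= 1, all(risk_levels() %in% rownames(class_means)))
  feats <- colnames(class_means)
  sds <- rep(sds, length.out = length(feats))
  out <- list()
  for (cl in risk_levels()) {
    for (j in seq_len(drugs_per_class[[cl]])) {
      drug <- sprintf("%s_%02d", cl, j)
      rows <- with_seed(derive_seed(seed, paste("bank", drug)), {
        offset <- rnorm(length(feats), 0, drug_sd * sds)
        m <- matrix(rnorm(n_per_drug * length(feats)), n_per_drug) %*%
          diag(length(feats))
        sweep(sweep(m, 2, sds, `*`), 2, class_means[cl, ] + offset, `+`)
      })
      df <- as.data.frame(rows)
      names(df) <- feats
      df <- cbind(data.frame(dataset = dataset_name, drug = drug,
                             sample_index = seq_len(n_per_drug)),
                  df)
      df$risk <- cl
      df$split <- if (j <= train_per_class[[cl]]) "train" else "test"
      out[[drug]] <- df
    }
  }
  bank <- do.call(rbind, out)
  rownames(bank) <- NULL
  bank
}
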