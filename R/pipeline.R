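#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run: the cohort source, pacing
#' protocol, uncertainty-sample and dose bookkeeping, evaluation repeats
#' and the master seed. Defaults follow the reference protocol: 2000 ms
#' cycle length, 10,000 conditioning beats, 1,000 recorded beats at
#' 0.1 ms resolution keeping the last 250, 2,000 Hill samples per
#' drug-channel, doses 1-4 x Cmax, 10,000 evaluation repeats.
#'
#' @param cohort_spec A [synth_cohort_spec()] (synthetic source), or
#'   `NULL` to use `drug_file`/`raw_file`.
#' @param drug_file,raw_file Optional CSV paths for a measured cohort
#'   (see [read_drug_table()]).
#' @param backend Myocyte backend, `"surrogate"`.
#' @param feature_mode `"closed_form"` (analytic surrogate biomarkers;
#'   fast path for large sweeps) or `"trace"` (synthesise traces and run
#'   the extractors; use with reduced `n_hill_samples`).
#' @param cycle_length,n_prebeats,n_beats,dt,keep_last Pacing protocol.
#' @param n_hill_samples Uncertainty samples per drug-channel.
#' @param dose_multiples Integer Cmax multiples (default 1:4).
#' @param n_repeats Evaluation repeats.
#' @param features Feature columns to fit and evaluate (default all 12).
#' @param seed Master seed; all stage streams derive from it.
#' @param outdir Output directory for stage artifacts; `NULL` keeps
#'   everything in memory.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(cohort_spec = NULL, drug_file = NULL, raw_file = NULL,
                       backend = "surrogate",
                       feature_mode = c("closed_form", "trace"),
                       cycle_length = 2000, n_prebeats = 10000,
                       n_beats = 1000, dt = 0.1, keep_last = 250,
                       n_hill_samples = 2000, dose_multiples = 1:4,
                       n_repeats = 10000, features = feature_names(),
                       seed = 1L, outdir = NULL) {
  feature_mode <- match.arg(feature_mode)
  if (any(c(cycle_length, n_beats, dt, keep_last, n_hill_samples,
            n_repeats) <= 0) || n_prebeats < 0) {
    stop("all protocol counts must be positive")
  }
  spb <- cycle_length / dt
  if (abs(spb - round(spb)) > 1e-9) stop("dt must divide cycle_length")
  if (keep_last > n_beats) stop("keep_last must be <= n_beats")
  if (is.null(cohort_spec) && is.null(drug_file)) {
    cohort_spec <- synth_cohort_spec(seed = seed)
  }
  structure(list(cohort_spec = cohort_spec, drug_file = drug_file,
                 raw_file = raw_file, backend = backend,
                 feature_mode = feature_mode, cycle_length = cycle_length,
                 n_prebeats = n_prebeats, n_beats = n_beats, dt = dt,
                 keep_last = keep_last, n_hill_samples = n_hill_samples,
                 dose_multiples = dose_multiples, n_repeats = n_repeats,
                 features = features, seed = seed, outdir = outdir),
            class = "run_config")
}

#' Compute the per-drug feature bank from an in vitro cohort
#'
#' For every drug: draw the Hill uncertainty cloud per measured channel,
#' convert each (IC50, h) sample into per-channel conductance scale
#' factors at each Cmax multiple, obtain the twelve biomarkers per dose
#' (analytically or by trace extraction on the worst beat), and average
#' across the doses. The bank has one row per (drug, sample_index):
#' `n_hill_samples x dose count` biomarker evaluations per drug collapse
#' to `n_hill_samples` averaged feature vectors.
#'
#' @param records List of [drug_record()]s with raw points (or Hill
#'   summaries).
#' @param config A [run_config()].
#' @return Feature-bank data.frame (`dataset`, `drug`, `sample_index`,
#'   twelve features, `risk`, `split`), with attribute
#'   `biomarkers_per_drug` = samples x doses.
#' @export
compute_feature_bank <- function(records, config = run_config()) {
  params <- surrogate_params()
  model0 <- cell_model(config$backend, params)
  state0 <- run_to_steady_state(model0, n_beats = config$n_prebeats,
                                cycle_length = config$cycle_length,
                                cache_dir = config$outdir)
  n <- config$n_hill_samples
  ctrl_bundle <- NULL
  if (config$feature_mode == "trace") {
    ctrl_bundle <- paced_simulation(model0, state0, n_beats = config$n_beats,
                                    cycle_length = config$cycle_length,
                                    dt = config$dt, keep_last = 1)
  }
  bank <- lapply(records, function(rec) {
    sets <- lapply(rec$blocks, sample_hill_uncertainty, n = n,
                   seed = config$seed)
    per_dose <- lapply(config$dose_multiples, function(k) {
      scales <- matrix(1, n, length(tdp_channels()),
                       dimnames = list(NULL, tdp_channels()))
      for (s in sets) {
        scales[, s$channel] <- scales[, s$channel] *
          inhibition_factor(k * rec$cmax, s$samples$ic50, s$samples$hill_h)
      }
      if (config$feature_mode == "closed_form") {
        as.matrix(surrogate_features(scales, params))
      } else {
        t(vapply(seq_len(n), function(i) {
          mdl <- model0
          mdl$scales[colnames(scales)] <- scales[i, ]
          bundle <- paced_simulation(mdl, state0, n_beats = config$n_beats,
                                     cycle_length = config$cycle_length,
                                     dt = config$dt, keep_last = 1)
          extract_features(bundle, ctrl_bundle)
        }, numeric(12)))
      }
    })
    avg <- Reduce(`+`, per_dose) / length(per_dose)
    df <- as.data.frame(avg)
    names(df) <- feature_names()
    cbind(data.frame(dataset = "synthetic", drug = rec$drug_name,
                     sample_index = seq_len(n)),
          df,
          data.frame(risk = as.character(rec$risk_label), split = rec$split))
  })
  bank <- do.call(rbind, bank)
  rownames(bank) <- NULL
  attr(bank, "biomarkers_per_drug") <- n * length(config$dose_multiples)
  bank
}

#' Run the full risk-classification pipeline
#'
#' Stages: cohort (synthetic or file-based) -> Hill uncertainty clouds ->
#' drug-block biomarkers averaged over the Cmax multiples -> per-feature
#' proportional-odds fits on the train split -> repeated bootstrap
#' evaluation on the test split. When `config$outdir` is set, stage
#' artifacts (feature bank, fitted models, threshold table, performance
#' summaries) are written as CSV along with a manifest recording the
#' configuration, seed and a content checksum; a rerun with the same
#' config reproduces the same checksum.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_run`: `records`, `bank`, `models`
#'   (per feature), `summaries` (per feature `repeat_summary`),
#'   `threshold_table`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  records <- if (!is.null(config$drug_file)) {
    read_drug_table(config$drug_file, raw_file = config$raw_file)
  } else {
    synth_invitro_cohort(config$cohort_spec)
  }
  bank <- compute_feature_bank(records, config)

  train <- bank[bank$split == "train", , drop = FALSE]
  models <- lapply(stats::setNames(nm = config$features), function(fe) {
    fit <- tryCatch(fit_olr(train[[fe]], train$risk, feature_name = fe),
                    error = function(e) {
                      structure(list(feature_name = fe, beta = NA_real_,
                                     zeta = c(NA_real_, NA_real_),
                                     th1 = NA_real_, th2 = NA_real_,
                                     converged = FALSE, loglik = NA_real_,
                                     fit_log = numeric(0), n = 0L,
                                     n_dropped = 0L,
                                     diagnostic = conditionMessage(e)),
                                class = "olr_fit")
                    })
    fit
  })
  summaries <- lapply(models, function(mdl) {
    if (!mdl$converged) return(NULL)
    evaluate_repeats(mdl, bank, n_repeats = config$n_repeats,
                     seed = config$seed)
  })
  threshold_table <- write_olr_models(models)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(bank, file.path(config$outdir, "feature_bank.csv"),
                     row.names = FALSE)
    utils::write.csv(threshold_table,
                     file.path(config$outdir, "thresholds.csv"),
                     row.names = FALSE)
    perf <- do.call(rbind, lapply(summaries[!vapply(summaries, is.null,
                                                    logical(1))],
                                  function(s) {
                                    cbind(feature = s$feature, s$metrics)
                                  }))
    utils::write.csv(perf, file.path(config$outdir, "performance.csv"),
                     row.names = FALSE)
    manifest <- c(
      sprintf("seed=%d", config$seed),
      sprintf("backend=%s", config$backend),
      sprintf("feature_mode=%s", config$feature_mode),
      sprintf("n_hill_samples=%d", config$n_hill_samples),
      sprintf("n_repeats=%d", config$n_repeats),
      sprintf("n_drugs=%d", length(records)),
      sprintf("bank_rows=%d", nrow(bank)),
      sprintf("bank_checksum=%.10e",
              sum(as.matrix(bank[feature_names()]), na.rm = TRUE)))
    writeLines(manifest, file.path(config$outdir, "manifest.txt"))
  }
  structure(list(records = records, bank = bank, models = models,
                 summaries = summaries, threshold_table = threshold_table,
                 config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d drugs, %d bank rows, %d fitted features\n",
              length(x$records), nrow(x$bank),
              sum(vapply(x$models, `[[`, logical(1), "converged"))))
  invisible(x)
}

#' Render the report tables of a completed run directory
#'
#' Reads the stage artifacts written by [run_pipeline()] and returns the
#' two report tables: the per-feature TH1/TH2 threshold table and the
#' per-feature performance table with "median (min-max)" cells; cells of
#' non-converged fits are printed as dashes.
#'
#' @param run_dir Output directory of a completed run.
#' @return List with `thresholds` and `performance` data.frames.
#' @export
report <- function(run_dir) {
  need <- c(thresholds = "thresholds.csv", performance = "performance.csv")
  paths <- file.path(run_dir, need)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing artifact(s) for stage(s): ",
         paste(names(need)[missing], collapse = ", "))
  }
  th <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  th$th1 <- ifelse(th$converged, sprintf("%.4g", th$th1), "-")
  th$th2 <- ifelse(th$converged, sprintf("%.4g", th$th2), "-")
  perf <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(split(perf, perf$feature), function(p) {
    get_cell <- function(metric, cl) {
      row <- p[p$metric == metric & p$class == cl, ]
      if (nrow(row) == 0 || !is.finite(row$median)) return("-")
      sprintf("%.2f (%.2f–%.2f)", row$median, row$min, row$max)
    }
    data.frame(feature = p$feature[1],
               acc = get_cell("accuracy", "overall"),
               auc_low = get_cell("auc", "low"),
               auc_intermediate = get_cell("auc", "intermediate"),
               auc_high = get_cell("auc", "high"),
               f1_low = get_cell("f1", "low"),
               f1_intermediate = get_cell("f1", "intermediate"),
               f1_high = get_cell("f1", "high"))
  }))
  rownames(cells) <- NULL
  unfit <- setdiff(th$feature, cells$feature)
  if (length(unfit) > 0) {
    dash <- cells[rep(NA_integer_, length(unfit)), , drop = FALSE]
    dash[] <- "-"
    dash$feature <- unfit
    cells <- rbind(cells, dash)
    rownames(cells) <- NULL
  }
  list(thresholds = th[, c("feature", "th1", "th2")], performance = cells)
}
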