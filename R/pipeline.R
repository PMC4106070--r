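# End-to-end experiment orchestration: split -> band selection -> features
# -> scaling -> pretraining -> softmax -> fine-tuning -> segment-level
# sensitivity/specificity with multi-trial aggregation and parameter sweeps.

#' Experiment configuration
#'
#' Bundles every knob of one detection experiment.  `layer_sizes` starts at
#' the flattened cross-power dimension N^2 and defaults to
#' `c(N^2, 50, 10)`; trials share one train/test split and differ only in
#' network initialisation.
#'
#' @param synth a [synth_config()] describing the data source.
#' @param n_seizure,n_nonseizure dataset composition (defaults 1000/4000).
#' @param window_s segment length in seconds.
#' @param n_train_per_class training segments drawn per class (default 750).
#' @param bands candidate [band()] list for selection.
#' @param welch [welch_params()] for the spectral estimator.
#' @param layer_sizes encoder sizes; `NULL` means `c(N^2, 50, 10)`.
#' @param ae an [ae_config()]; its `loss_type` picks R-SAE vs S-SAE.
#' @param n_trials number of trials to average (default 10).
#' @param seed master seed: seeds the generator, the split and the
#'   per-trial initialisations.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(synth = synth_config(),
                              n_seizure = 1000L, n_nonseizure = 4000L,
                              window_s = 5, n_train_per_class = 750L,
                              bands = named_bands(),
                              welch = welch_params(),
                              layer_sizes = NULL,
                              ae = ae_config(),
                              n_trials = 10L, seed = 1L) {
  stopifnot(n_trials >= 1L)
  if (is.null(layer_sizes)) layer_sizes <- c(synth$n_channels^2, 50L, 10L)
  if (layer_sizes[1L] != synth$n_channels^2) {
    stop_rsae("layer_sizes[1] must equal n_channels^2")
  }
  structure(list(synth = synth, n_seizure = n_seizure,
                 n_nonseizure = n_nonseizure, window_s = window_s,
                 n_train_per_class = n_train_per_class, bands = bands,
                 welch = welch, layer_sizes = layer_sizes, ae = ae,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Segment-level sensitivity and specificity
#'
#' Sensitivity is the fraction of true seizure segments detected,
#' `TP / (TP + FN)`; specificity the fraction of nonseizure segments
#' correctly classified, `TN / (TN + FP)`.
#'
#' @param predicted,truth character vectors of `"seizure"` /
#'   `"nonseizure"` labels of equal length; `truth` must contain both
#'   classes.
#' @return list with `sensitivity` and `specificity` in `[0, 1]`.
#' @export
sensitivity_specificity <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop_rsae("predicted and truth must have equal length")
  }
  if (!all(c("seizure", "nonseizure") %in% truth)) {
    stop_rsae("truth must contain both classes; a metric would be undefined")
  }
  tp <- sum(predicted == "seizure" & truth == "seizure")
  fn <- sum(predicted == "nonseizure" & truth == "seizure")
  tn <- sum(predicted == "nonseizure" & truth == "nonseizure")
  fp <- sum(predicted == "seizure" & truth == "nonseizure")
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

# Pooled Fisher discriminant ratio of a feature matrix: all entries of all
# seizure rows form one scalar sample, likewise nonseizure.
pooled_feature_fdr <- function(features, labels) {
  fdr_score(as.vector(features[labels == "seizure", , drop = FALSE]),
            as.vector(features[labels == "nonseizure", , drop = FALSE]))
}

# Split the dataset, select the band on the training split only, compute
# and scale features.  Everything fitted here sees zero test-set data.
prepare_trial_data <- function(segments, config, split_seed) {
  split <- split_train_test(segments, config$n_train_per_class, split_seed)
  fs <- config$synth$fs
  sel <- select_band(split$train, config$bands, fs, config$welch)
  feats <- cross_power_features(c(split$train, split$test), list(sel),
                                fs, config$welch)[[1L]]
  n_train <- length(split$train)
  raw_train <- feats[seq_len(n_train), , drop = FALSE]
  raw_test <- feats[-seq_len(n_train), , drop = FALSE]
  scaler <- fit_scaler(raw_train)
  list(band = sel, scaler = scaler,
       x_train = apply_scaler(scaler, raw_train),
       x_test = apply_scaler(scaler, raw_test),
       y_train = segment_labels(split$train),
       y_test = segment_labels(split$test))
}

#' Run one detection trial
#'
#' Executes the full protocol on a prepared dataset: seeded train/test
#' split, band selection and scaler fitting on the training split only,
#' layer-wise pretraining, softmax training (metrics "before
#' fine-tuning"), joint fine-tuning (metrics "after"), and held-out
#' evaluation.  Deterministic given `split_seed` and `init_seed`; two
#' calls differing only in `config$ae$loss_type` reuse identical splits
#' and initial weights.
#'
#' @param segments labelled list of `eeg_segment` objects.
#' @param config an [experiment_config()].
#' @param split_seed seed of the train/test split.
#' @param init_seed seed of the network initialisation.
#' @param prepared optional result of a previous trial's data preparation
#'   (same `split_seed`), to share the spectral work across trials.
#' @return list with `band`, `scaler`, `net`, `metrics_before`,
#'   `metrics_after`, `fdr_before`, `fdr_after` and the `prepared` data.
#' @export
run_trial <- function(segments, config, split_seed, init_seed,
                      prepared = NULL) {
  prep <- prepared %||% prepare_trial_data(segments, config, split_seed)
  ae <- config$ae
  ae$seed <- init_seed
  net0 <- pretrain_stack(prep$x_train, config$layer_sizes, ae)
  net0 <- train_softmax(net0, prep$x_train, prep$y_train, ae)
  before <- sensitivity_specificity(predict_labels(net0, prep$x_test),
                                    prep$y_test)
  fdr_before <- pooled_feature_fdr(extract_features(net0, prep$x_train),
                                   prep$y_train)
  net <- fine_tune(net0, prep$x_train, prep$y_train, ae)
  after <- sensitivity_specificity(predict_labels(net, prep$x_test),
                                   prep$y_test)
  fdr_after <- pooled_feature_fdr(extract_features(net, prep$x_train),
                                  prep$y_train)
  list(band = prep$band, scaler = prep$scaler, net = net,
       metrics_before = before, metrics_after = after,
       fdr_before = fdr_before, fdr_after = fdr_after, prepared = prep)
}

#' Run a multi-trial detection experiment
#'
#' Generates the synthetic dataset under the master seed, fixes one
#' train/test split, and repeats [run_trial()] `n_trials` times with
#' different derived initialisation seeds, reporting per-trial
#' sensitivity/specificity plus mean and standard deviation (before and
#' after fine-tuning).
#'
#' @param config an [experiment_config()].
#' @param segments optional pre-generated dataset (bypasses the
#'   generator).
#' @return a `detection_metrics` object: per-trial data frame, aggregated
#'   means/sds, the selected band and the last trained network.
#' @export
run_experiment <- function(config, segments = NULL) {
  seeds <- derive_seeds(config$seed, config$n_trials + 1L)
  split_seed <- seeds[1L]
  trial_seeds <- seeds[-1L]
  if (is.null(segments)) {
    synth <- config$synth
    synth$seed <- config$seed
    segments <- make_labeled_dataset(synth, config$n_seizure,
                                     config$n_nonseizure, config$window_s)
  }
  prep <- NULL
  rows <- vector("list", config$n_trials)
  last <- NULL
  for (t in seq_len(config$n_trials)) {
    tr <- run_trial(segments, config, split_seed, trial_seeds[t],
                    prepared = prep)
    prep <- tr$prepared
    rows[[t]] <- data.frame(
      trial = t,
      sensitivity = tr$metrics_after$sensitivity,
      specificity = tr$metrics_after$specificity,
      sensitivity_before = tr$metrics_before$sensitivity,
      specificity_before = tr$metrics_before$specificity,
      fdr_before = tr$fdr_before, fdr_after = tr$fdr_after)
    last <- tr
  }
  trials <- do.call(rbind, rows)
  agg <- function(col) {
    s <- stats::sd(trials[[col]])
    c(mean = mean(trials[[col]]), sd = if (is.na(s)) 0 else s)
  }
  structure(list(trials = trials,
                 sensitivity = agg("sensitivity"),
                 specificity = agg("specificity"),
                 sensitivity_before = agg("sensitivity_before"),
                 specificity_before = agg("specificity_before"),
                 band = last$band, net = last$net, scaler = last$scaler,
                 config = config),
            class = "detection_metrics")
}

format_pm <- function(stat) {
  sprintf("%.2f ± %.1e", stat[["mean"]], if (is.na(stat[["sd"]])) 0 else stat[["sd"]])
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> %d trial(s), band %s (%g-%g Hz)\n",
              nrow(x$trials), x$band$name, x$band$lb, x$band$ub))
  cat("  sensitivity: ", format_pm(x$sensitivity),
      "  (before fine-tuning ", format_pm(x$sensitivity_before), ")\n", sep = "")
  cat("  specificity: ", format_pm(x$specificity),
      "  (before fine-tuning ", format_pm(x$specificity_before), ")\n", sep = "")
  invisible(x)
}

#' Sweep one model parameter across an experiment
#'
#' Re-runs [run_experiment()] for each value of the swept parameter with
#' everything else fixed: `"q"` varies the top (output) layer width,
#' `"sigma"` the MCC kernel size.
#'
#' @param config an [experiment_config()].
#' @param parameter `"q"` or `"sigma"`.
#' @param values numeric vector of parameter values.
#' @param segments optional pre-generated dataset reused across values.
#' @return tidy data frame: one row per value with mean/sd
#'   sensitivity/specificity before and after fine-tuning.
#' @export
sweep_parameter <- function(config, parameter = c("q", "sigma"), values,
                            segments = NULL) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1L)
  if (is.null(segments)) {
    synth <- config$synth
    synth$seed <- config$seed
    segments <- make_labeled_dataset(synth, config$n_seizure,
                                     config$n_nonseizure, config$window_s)
  }
  rows <- lapply(values, function(v) {
    cfg <- config
    if (parameter == "q") {
      cfg$layer_sizes[length(cfg$layer_sizes)] <- as.integer(v)
    } else {
      cfg$ae$sigma <- v
    }
    res <- run_experiment(cfg, segments = segments)
    data.frame(parameter = parameter, value = v,
               sensitivity_mean = res$sensitivity[["mean"]],
               sensitivity_sd = res$sensitivity[["sd"]],
               specificity_mean = res$specificity[["mean"]],
               specificity_sd = res$specificity[["sd"]],
               sensitivity_before_mean = res$sensitivity_before[["mean"]],
               specificity_before_mean = res$specificity_before[["mean"]])
  })
  do.call(rbind, rows)
}
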