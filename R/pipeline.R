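# End-to-end orchestration: conditioning -> feature extraction -> training
# and streaming evaluation of the 4 x 2 grid of feature methods (RMS, WP,
# DFA, MM) and classifiers (NN, SVM). Feature ticks are aligned across
# channels so every tick yields one complete 6-dimensional classifier input:
# RMS ticks every `step` samples, DFA every window, MM every sample, and WP
# events are sample-and-held onto the per-sample grid.

FEATURE_METHODS <- c("RMS", "WP", "DFA", "MM")
CLASSIFIERS <- c("NN", "SVM")

#' Pipeline configuration
#'
#' @param feature_method one of `"RMS"`, `"WP"`, `"DFA"`, `"MM"`.
#' @param classifier `"NN"` or `"SVM"`.
#' @param rms,wp,dfa,wavelet,activation,hill sub-configurations (defaults:
#'   [rms_config()], [wp_config()], [dfa_config()], [wavelet_config()],
#'   [make_activation_params()], [hill_params()]).
#' @param kernel [kernel_spec()] for the SVM.
#' @param c_penalty SVM box constraint (default 1).
#' @param svm_tol SMO KKT tolerance (default 1e-3).
#' @param nn_config options passed to [nn_train()].
#' @param train_cap maximum training vectors; larger sets are uniformly
#'   subsampled with the pipeline seed (default 50000, the practical limit
#'   for real-time-capable support-vector counts).
#' @param highpass_hz conditioning high-pass cutoff (default 20).
#' @param conditioning `"streaming"` (causal high-pass, default -- keeps the
#'   whole pipeline causal so streaming predictions are prefix-consistent)
#'   or `"batch"` (zero-phase).
#' @param seed pipeline seed (subsampling, NN initialization).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(feature_method = "MM", classifier = "SVM",
                            rms = rms_config(), wp = wp_config(),
                            dfa = dfa_config(), wavelet = wavelet_config(),
                            activation = make_activation_params(),
                            hill = hill_params(), kernel = kernel_spec(),
                            c_penalty = 1, svm_tol = 1e-3,
                            nn_config = list(), train_cap = 50000,
                            highpass_hz = 20,
                            conditioning = c("streaming", "batch"),
                            seed = 1) {
  conditioning <- match.arg(conditioning)
  feature_method <- match.arg(feature_method, FEATURE_METHODS)
  classifier <- match.arg(classifier, CLASSIFIERS)
  if (train_cap <= 0) stop("train_cap must be positive", call. = FALSE)
  structure(list(feature_method = feature_method, classifier = classifier,
                 rms = rms, wp = wp, dfa = dfa, wavelet = wavelet,
                 activation = activation, hill = hill, kernel = kernel,
                 c_penalty = c_penalty, svm_tol = svm_tol,
                 nn_config = nn_config, train_cap = train_cap,
                 highpass_hz = highpass_hz, conditioning = conditioning,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

sample_and_hold <- function(stream, n) {
  out <- numeric(n)
  if (n_ticks(stream) == 0) return(out)
  val <- 0
  j <- 1
  ticks <- stream$tick_times
  vals <- as.numeric(stream$values)
  for (t in seq_len(n)) {
    while (j <= length(ticks) && ticks[j] <= t) {
      val <- vals[j]
      j <- j + 1
    }
    out[t] <- val
  }
  out
}

#' Extract aligned multichannel features
#'
#' Conditions the recording and applies the configured feature method to
#' every channel on a shared tick grid, so each tick carries one scalar per
#' channel (the classifier input). Ticks inherit the motion label of the
#' sample at their tick time.
#'
#' @param recording a labeled or unlabeled [emg_recording()] (raw; it is
#'   conditioned internally).
#' @param config a [pipeline_config()].
#' @param conditioned set to TRUE if `recording` is already conditioned.
#' @return a multichannel [feature_stream()].
#' @export
extract_features <- function(recording, config = pipeline_config(),
                             conditioned = FALSE) {
  rec <- if (conditioned) recording else
    condition(recording, highpass_hz = config$highpass_hz,
              mode = config$conditioning %||% "streaming")
  n <- n_samples(rec)
  method <- config$feature_method
  if (method == "MM") {
    return(mm_features(rec, config$activation, config$hill))
  }
  per_channel <- lapply(seq_len(nrow(rec$samples)), function(i) {
    ch <- rec$samples[i, ]
    switch(method,
           RMS = rms_features(ch, config$rms),
           DFA = dfa_features(ch, config$dfa),
           WP = wp_features(ch, config$wavelet, config$wp))
  })
  if (method == "WP") {
    vals <- t(vapply(per_channel, sample_and_hold, numeric(n), n = n))
    ticks <- seq_len(n)
    raw_counts <- vapply(per_channel, n_ticks, integer(1))
  } else {
    ticks <- per_channel[[1]]$tick_times
    vals <- t(vapply(per_channel, function(s) as.numeric(s$values),
                     numeric(length(ticks))))
    raw_counts <- rep(length(ticks), length(per_channel))
  }
  out <- feature_stream(vals, ticks, method,
                        labels = if (!is.null(rec$labels)) rec$labels[ticks],
                        channels = rec$channels)
  attr(out, "raw_event_counts") <- raw_counts
  out
}

assemble_vectors <- function(streams) {
  x <- do.call(rbind, lapply(streams, function(s) t(s$values)))
  y <- unlist(lapply(streams, function(s) s$labels))
  trial <- rep(seq_along(streams),
               vapply(streams, n_ticks, integer(1)))
  list(x = x, y = y, trial = trial)
}

#' Train a classifier on labeled recordings
#'
#' Extracts features from every training recording, assembles per-tick
#' 6-dimensional labeled vectors, subsamples uniformly (seeded) down to
#' `config$train_cap` when necessary, and trains the configured classifier.
#'
#' @param train list of labeled [emg_recording()]s.
#' @param config a [pipeline_config()].
#' @return list with `model`, `report` (training accuracy, confusion,
#'   vectors used, features per second per channel, `n_support` or weight
#'   count, config echo) and `streams` (the extracted feature streams).
#' @export
run_training <- function(train, config = pipeline_config()) {
  streams <- lapply(train, extract_features, config = config)
  av <- assemble_vectors(streams)
  if (is.null(av$y)) stop("pipeline error: training recordings must be ",
                          "labeled", call. = FALSE)
  if (nrow(av$x) == 0) stop("pipeline error: empty feature set",
                            call. = FALSE)
  keep <- seq_len(nrow(av$x))
  if (length(keep) > config$train_cap) {
    keep <- with_seed(config$seed,
                      sort(sample(length(keep), config$train_cap)))
  }
  x <- av$x[keep, , drop = FALSE]
  y <- av$y[keep]
  model <- if (config$classifier == "NN") {
    nn_train(x, y, seed = config$seed, config = config$nn_config)
  } else {
    svm_train(x, y, kernel = config$kernel, c_penalty = config$c_penalty,
              tol = config$svm_tol)
  }
  pred <- if (config$classifier == "NN") nn_predict(model, x)$label else
    svm_predict(model, x)$label
  acc <- accuracy(pred, y)
  rate <- train[[1]]$rate_hz
  dur <- n_samples(train[[1]]) / rate
  report <- list(
    train_accuracy = acc$accuracy, confusion = acc$confusion,
    n_vectors = nrow(x),
    features_per_s = mean(attr(streams[[1]], "raw_event_counts") %||%
                            n_ticks(streams[[1]])) / dur,
    model_size = if (config$classifier == "SVM") model$n_support else
      length(model$hidden_weights) + length(model$output_weights) +
        length(model$hidden_bias) + length(model$output_bias),
    feature_method = config$feature_method, classifier = config$classifier,
    seed = config$seed)
  list(model = model, report = report, streams = streams)
}

predict_labels <- function(model, x) {
  if (inherits(model, "nn_model")) nn_predict(model, x)$label
  else svm_predict(model, x)$label
}

#' Streaming evaluation on held-out recordings
#'
#' Simulates the on-line loop: every feature tick yields a 6-dimensional
#' vector built causally from data up to that tick (all extractors are
#' causal by construction), which is classified and compared to the tick's
#' label. Per-loop wall time is measured over a subset of individual
#' predictions; it is informational only (hardware-dependent).
#'
#' @param test list of labeled [emg_recording()]s.
#' @param model a trained `nn_model` or `svm_model`.
#' @param config the [pipeline_config()] used in training (feature method
#'   must match the model).
#' @param majority_vote also report per-trial majority-vote accuracy
#'   (default FALSE; the headline metric is per-tick).
#' @param latency_ticks number of single-tick predictions to time
#'   (default 100).
#' @return an `evaluation_report` list: pooled and per-trial accuracy, 9x9
#'   confusion matrix, latency stats (seconds per prediction loop), kernel
#'   evaluations per loop for SVM, config echo.
#' @export
run_online <- function(test, model, config = pipeline_config(),
                       majority_vote = FALSE, latency_ticks = 100) {
  if ((config$classifier == "NN") != inherits(model, "nn_model")) {
    stop("config error: classifier/model mismatch", call. = FALSE)
  }
  streams <- lapply(test, extract_features, config = config)
  av <- assemble_vectors(streams)
  if (is.null(av$y)) stop("pipeline error: test recordings must be labeled",
                          call. = FALSE)
  pred <- predict_labels(model, av$x)
  acc <- accuracy(pred, av$y)
  per_trial <- vapply(seq_along(streams), function(i) {
    sel <- av$trial == i
    accuracy(pred[sel], av$y[sel])$accuracy
  }, numeric(1))
  trial_majority <- NULL
  if (majority_vote) {
    maj <- vapply(seq_along(streams), function(i) {
      p <- pred[av$trial == i & av$y != 9L]
      as.integer(names(which.max(table(p))))
    }, integer(1))
    truth_m <- vapply(seq_along(streams), function(i) {
      y <- av$y[av$trial == i]
      as.integer(names(which.max(table(y[y != 9L]))))
    }, integer(1))
    trial_majority <- mean(maj == truth_m)
  }
  nt <- min(latency_ticks, nrow(av$x))
  t0 <- proc.time()[["elapsed"]]
  times <- vapply(seq_len(nt), function(i) {
    s <- proc.time()[["elapsed"]]
    predict_labels(model, av$x[i, , drop = FALSE])
    proc.time()[["elapsed"]] - s
  }, numeric(1))
  structure(list(
    accuracy = acc$accuracy, confusion = acc$confusion,
    per_trial_accuracy = per_trial, trial_majority_accuracy = trial_majority,
    latency_mean_s = mean(times), latency_median_s = stats::median(times),
    kernel_evals_per_loop = if (inherits(model, "svm_model"))
      model$n_support else NA_integer_,
    n_ticks = nrow(av$x), feature_method = config$feature_method,
    classifier = config$classifier, seed = config$seed,
    wall_s = proc.time()[["elapsed"]] - t0),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report %s+%s> accuracy %.3f over %d ticks\n",
              x$feature_method, x$classifier, x$accuracy, x$n_ticks))
  invisible(x)
}

#' Compare all eight method combinations
#'
#' Trains and evaluates every feature-method x classifier combination on the
#' same train/test split and tabulates accuracies, feature rates, model size
#' and latency.
#'
#' @param train,test lists of labeled [emg_recording()]s.
#' @param config a base [pipeline_config()] whose sub-configurations are
#'   reused for every combination.
#' @return data.frame with 8 rows: `feature_method`, `classifier`,
#'   `train_accuracy`, `test_accuracy`, `features_per_s`, `model_size`
#'   (support vectors or weight count), `latency_mean_s`,
#'   `latency_median_s`.
#' @export
run_comparison <- function(train, test, config = pipeline_config()) {
  rows <- list()
  for (fm in FEATURE_METHODS) {
    for (cl in CLASSIFIERS) {
      cfg <- config
      cfg$feature_method <- fm
      cfg$classifier <- cl
      tr <- run_training(train, cfg)
      ev <- run_online(test, tr$model, cfg)
      rows[[length(rows) + 1]] <- data.frame(
        feature_method = fm, classifier = cl,
        train_accuracy = tr$report$train_accuracy,
        test_accuracy = ev$accuracy,
        features_per_s = tr$report$features_per_s,
        model_size = tr$report$model_size,
        latency_mean_s = ev$latency_mean_s,
        latency_median_s = ev$latency_median_s)
    }
  }
  do.call(rbind, rows)
}

#' Save a trained model to JSON
#'
#' @param model an `nn_model` or `svm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "nn_model")) {
    obj <- list(type = "nn",
                hidden_weights = model$hidden_weights,
                hidden_bias = model$hidden_bias,
                output_weights = model$output_weights,
                output_bias = model$output_bias,
                mu = model$mu, center = model$center, scale = model$scale,
                training_meta = model$training_meta)
  } else if (inherits(model, "svm_model")) {
    obj <- list(type = "svm", sv = model$sv, classes = model$classes,
                n_support = model$n_support,
                kernel = unclass(model$kernel), c_penalty = model$c_penalty,
                machines = lapply(model$machines, function(m) {
                  m[c("pos", "neg", "bias", "coef", "sv_pos")]
                }))
  } else stop("unsupported model type", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON path.
#' @return the reconstructed `nn_model` or `svm_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "nn") {
    structure(list(
      hidden_weights = as.matrix(obj$hidden_weights),
      hidden_bias = as.numeric(obj$hidden_bias),
      output_weights = as.matrix(obj$output_weights),
      output_bias = as.numeric(obj$output_bias),
      mu = obj$mu, center = as.numeric(obj$center),
      scale = as.numeric(obj$scale),
      training_meta = obj$training_meta), class = "nn_model")
  } else if (obj$type == "svm") {
    machines <- lapply(seq_len(nrow(obj$machines)), function(i) {
      list(pos = obj$machines$pos[i], neg = obj$machines$neg[i],
           bias = obj$machines$bias[i],
           coef = as.numeric(obj$machines$coef[[i]]),
           sv_pos = as.integer(obj$machines$sv_pos[[i]]))
    })
    kernel <- structure(list(type = obj$kernel$type,
                             gamma = obj$kernel$gamma),
                        class = "kernel_spec")
    structure(list(machines = machines, sv = as.matrix(obj$sv),
                   classes = as.integer(obj$classes),
                   n_support = as.integer(obj$n_support),
                   kernel = kernel, c_penalty = obj$c_penalty),
              class = "svm_model")
  } else stop("unknown model type in ", path, call. = FALSE)
}

#' Split a generated dataset into train and test trials
#'
#' Splits by whole trials within each motion: trial indices `1..n_train` go
#' to the training set, the rest to the test set.
#'
#' @param recordings list from [generate_dataset()].
#' @param n_train training trials per motion.
#' @return list with `train` and `test` recording lists.
#' @export
split_by_trial <- function(recordings, n_train) {
  trial <- vapply(recordings, function(r) attr(r, "trial"), integer(1))
  list(train = recordings[trial <= n_train],
       test = recordings[trial > n_train])
}
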