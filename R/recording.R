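# Core domain types: multichannel sEMG recordings, motion labels, feature
# streams, plus the shared conditioning chain (high-pass, rectify, MVC
# normalize) and accuracy accounting.

#' Canonical muscle channel names
#'
#' The six recorded muscles, in canonical order: flexor carpi radialis (FCR),
#' flexor carpi ulnaris (FCU), extensor carpi radialis (ECR), extensor carpi
#' ulnaris (ECU), biceps brachii (BB) and triceps brachii (TB).
#'
#' @export
EMG_CHANNELS <- c("FCR", "FCU", "ECR", "ECU", "BB", "TB")

#' Motion label codes
#'
#' Nine motion classes: eight upper-limb motions plus rest. Codes 1--9 map
#' bijectively onto motion names; code 9 is the relax (rest) class.
#'
#' @export
MOTION_LABELS <- c(
  "elbow flexion"      = 1L,
  "elbow extension"    = 2L,
  "forearm pronation"  = 3L,
  "forearm supination" = 4L,
  "wrist flexion"      = 5L,
  "wrist extension"    = 6L,
  "wrist abduction"    = 7L,
  "wrist adduction"    = 8L,
  "relax"              = 9L
)

#' Convert between motion codes and names
#'
#' @param x integer codes in 1..9 or character motion names.
#' @return the complementary representation (names for codes, codes for names).
#' @examples
#' motion_name(9)       # "relax"
#' motion_code("relax") # 9
#' @export
motion_name <- function(x) {
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 1L) || any(x > 9L)) {
    stop("motion codes must be integers in 1..9", call. = FALSE)
  }
  names(MOTION_LABELS)[x]
}

#' @rdname motion_name
#' @export
motion_code <- function(x) {
  out <- MOTION_LABELS[match(x, names(MOTION_LABELS))]
  if (any(is.na(out))) stop("unknown motion name(s): ",
                            paste(setdiff(x, names(MOTION_LABELS)), collapse = ", "),
                            call. = FALSE)
  unname(out)
}

#' Construct a multichannel sEMG recording
#'
#' An `emg_recording` holds a channels-by-time amplitude matrix (raw mV or
#' MVC-normalized, dimensionless), the sampling rate, channel names, optional
#' per-sample motion labels and per-channel maximum-voluntary-contraction
#' (MVC) normalization constants.
#'
#' @param samples numeric matrix, one row per channel, one column per sample.
#' @param rate_hz sampling frequency in Hz (default 1000).
#' @param channels character vector of channel names, one per row.
#' @param labels optional integer vector of per-sample motion codes in 1..9,
#'   one per column of `samples`.
#' @param mvc per-channel positive MVC constants (default all 1).
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, rate_hz = 1000, channels = EMG_CHANNELS,
                          labels = NULL, mvc = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  if (length(channels) != nrow(samples)) {
    stop("channel count (", length(channels), ") does not match sample rows (",
         nrow(samples), ")", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != ncol(samples)) {
      stop("labels must have one entry per time sample", call. = FALSE)
    }
    if (any(is.na(labels)) || any(labels < 1L) || any(labels > 9L)) {
      stop("labels must be motion codes in 1..9", call. = FALSE)
    }
  }
  if (is.null(mvc)) mvc <- rep(1, nrow(samples))
  if (length(mvc) != nrow(samples) || any(!is.finite(mvc)) || any(mvc <= 0)) {
    stop("mvc must hold one strictly positive constant per channel",
         call. = FALSE)
  }
  rownames(samples) <- channels
  structure(
    list(samples = samples, rate_hz = rate_hz, channels = channels,
         labels = labels, mvc = as.numeric(mvc)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording> ", nrow(x$samples), " channels x ", ncol(x$samples),
      " samples @ ", x$rate_hz, " Hz\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = 1:9))
    cat("  labels:", paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param x an `emg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(x) ncol(x$samples)

#' Read a recording from delimited text
#'
#' Reads a comma-delimited file with one header row. Channel columns are
#' matched by name against `schema$channels` and returned in canonical order;
#' a column named `schema$label_col` (default `"label"`), when present, is
#' read as per-sample motion labels.
#'
#' @param path file path.
#' @param schema list with elements `channels` (character, default
#'   [EMG_CHANNELS]) and optionally `label_col` and `rate_hz`.
#' @return an [emg_recording()].
#' @export
read_recording <- function(path, schema = list()) {
  channels <- schema$channels %||% EMG_CHANNELS
  label_col <- schema$label_col %||% "label"
  rate_hz <- schema$rate_hz %||% 1000
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  missing_ch <- setdiff(channels, names(df))
  if (length(missing_ch) > 0) {
    stop("schema error: file ", path, " lacks channel column(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  for (ch in channels) {
    v <- df[[ch]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad) > 0) {
      stop("parse error: non-numeric value in column '", ch, "', row ",
           bad[1], call. = FALSE)
    }
  }
  samples <- t(as.matrix(df[channels]))
  labels <- if (label_col %in% names(df)) as.integer(df[[label_col]]) else NULL
  emg_recording(samples, rate_hz = rate_hz, channels = channels,
                labels = labels, mvc = schema$mvc %||% NULL)
}

#' Write a recording to delimited text
#'
#' @param x an `emg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  df <- as.data.frame(t(x$samples))
  names(df) <- x$channels
  if (!is.null(x$labels)) df$label <- x$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Condition a raw recording for feature extraction
#'
#' Applies the standard pre-classification chain: a high-pass filter to
#' remove DC offsets and low-frequency motion artifact, full-wave
#' rectification, and division by per-channel MVC constants so the output is
#' a dimensionless activation-like signal in approximately \[0, 1\].
#'
#' @param raw an `emg_recording`.
#' @param highpass_hz high-pass cutoff in Hz (default 20); must be below the
#'   Nyquist frequency. The filter is a 2nd-order Butterworth: zero-phase in
#'   batch mode, causal in streaming mode.
#' @param mvc per-channel positive MVC constants; defaults to `raw$mvc`.
#' @param mode `"batch"` (zero-phase) or `"streaming"` (causal single pass).
#' @return a conditioned `emg_recording` with nonnegative samples and
#'   `mvc = 1` (already applied).
#' @export
condition <- function(raw, highpass_hz = 20, mvc = NULL, mode = c("batch", "streaming")) {
  mode <- match.arg(mode)
  if (highpass_hz <= 0 || highpass_hz >= raw$rate_hz / 2) {
    stop("highpass_hz must lie in (0, Nyquist)", call. = FALSE)
  }
  mvc <- mvc %||% raw$mvc
  if (length(mvc) == 1) mvc <- rep(mvc, nrow(raw$samples))
  if (any(!is.finite(mvc)) || any(mvc <= 0)) {
    stop("parameter error: mvc must be strictly positive per channel",
         call. = FALSE)
  }
  coefs <- butter2(highpass_hz, raw$rate_hz, type = "high")
  out <- raw$samples
  for (i in seq_len(nrow(out))) {
    f <- if (mode == "batch") filtfilt2(coefs, out[i, ]) else
      biquad_filter(coefs, out[i, ])
    out[i, ] <- abs(f) / mvc[i]
  }
  emg_recording(out, rate_hz = raw$rate_hz, channels = raw$channels,
                labels = raw$labels, mvc = rep(1, nrow(out)))
}

#' Classification accuracy and confusion matrix
#'
#' Accuracy is the number of correctly recognized results divided by the
#' total number of results. The full 9x9 confusion matrix (rows = truth,
#' columns = predicted) is returned alongside.
#'
#' @param predicted integer motion codes.
#' @param truth integer motion codes, same length.
#' @return list with `accuracy` (fraction in \[0, 1\]) and `confusion`
#'   (9x9 integer matrix).
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("input error: predicted and truth must have equal length",
         call. = FALSE)
  }
  if (length(truth) == 0) stop("input error: empty label sequences",
                               call. = FALSE)
  lv <- 1:9
  confusion <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(truth = lv, predicted = lv)
  list(accuracy = sum(diag(confusion)) / length(truth), confusion = confusion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
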