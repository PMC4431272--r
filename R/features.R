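# Time-domain feature extractors: windowed RMS, Weight Peaks (thresholded
# zero crossings -> peak/valley magnitudes -> recursive weighting, applied
# per wavelet-packet node), and single-scale windowed detrended fluctuation
# analysis (DFA). Each extractor returns a feature_stream; multichannel
# assembly lives in the pipeline module.

#' Construct a feature stream
#'
#' A `feature_stream` holds per-channel scalar features on a shared grid of
#' feature ticks. Tick times are 1-based sample indices into the source
#' recording and are strictly increasing; at every tick each channel
#' contributes exactly one scalar, so a six-muscle recording yields the
#' 6-dimensional classifier input.
#'
#' @param values numeric matrix, one row per channel, one column per tick.
#' @param tick_times integer sample indices, one per column.
#' @param method feature method tag: `"RMS"`, `"WP"`, `"DFA"` or `"MM"`.
#' @param labels optional per-tick motion codes.
#' @param channels optional channel names.
#' @return object of class `feature_stream`.
#' @export
feature_stream <- function(values, tick_times, method,
                           labels = NULL, channels = NULL) {
  values <- matrix(as.numeric(values), nrow = if (is.matrix(values))
    nrow(values) else 1)
  if (ncol(values) != length(tick_times)) {
    stop("one tick time per feature column required", call. = FALSE)
  }
  if (length(tick_times) > 1 && any(diff(tick_times) <= 0)) {
    stop("tick_times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(tick_times)) {
    stop("labels must align with tick_times", call. = FALSE)
  }
  if (!is.null(channels)) rownames(values) <- channels
  structure(list(values = values, tick_times = as.integer(tick_times),
                 method = method, labels = labels),
            class = "feature_stream")
}

#' @export
print.feature_stream <- function(x, ...) {
  cat("<feature_stream ", x$method, "> ", nrow(x$values), " channel(s) x ",
      ncol(x$values), " ticks\n", sep = "")
  invisible(x)
}

#' Number of feature ticks
#' @param x a `feature_stream`.
#' @return integer tick count.
#' @export
n_ticks <- function(x) ncol(x$values)

#' Write a feature stream to CSV
#'
#' Columns: `tick_time`, one column per channel, and `label` when present.
#'
#' @param x a `feature_stream`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_stream <- function(x, path) {
  df <- data.frame(tick_time = x$tick_times)
  vals <- as.data.frame(t(x$values))
  names(vals) <- rownames(x$values) %||% paste0("ch", seq_len(nrow(x$values)))
  df <- cbind(df, vals)
  if (!is.null(x$labels)) df$label <- x$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' RMS feature configuration
#'
#' @param window analysis window length in samples (default 100).
#' @param step increment between windows in samples (default 25).
#' @return an `rms_config` list.
#' @export
rms_config <- function(window = 100, step = 25) {
  if (step < 1 || window < step) stop("require window >= step >= 1",
                                      call. = FALSE)
  structure(list(window = as.integer(window), step = as.integer(step)),
            class = "rms_config")
}

#' Windowed RMS features
#'
#' Root-mean-square over an overlapping window of `window` samples advanced
#' by `step` samples. Windows are causal: the i-th tick falls at sample
#' `min(i * step, n)` and covers the up-to-`window` trailing samples ending
#' there, so short head windows use the history available. 1000 samples at
#' the defaults (window 100, step 25) give exactly 40 features.
#'
#' @param signal conditioned single-channel series.
#' @param config an [rms_config()].
#' @return one-channel [feature_stream()], method `"RMS"`.
#' @export
rms_features <- function(signal, config = rms_config()) {
  n <- length(signal)
  if (n < 1) stop("input error: empty signal", call. = FALSE)
  ticks <- pmin(seq_len(ceiling(n / config$step)) * config$step, n)
  csum <- c(0, cumsum(signal^2))
  lo <- pmax(ticks - config$window, 0L)
  vals <- sqrt((csum[ticks + 1] - csum[lo + 1]) / (ticks - lo))
  feature_stream(vals, ticks, "RMS")
}

#' Weight Peaks configuration
#'
#' @param zc_threshold minimum amplitude difference between adjacent samples
#'   for a sign change to count as a zero crossing (MVC-normalized units,
#'   default 0.01).
#' @param smooth_n recursive weighting constant n: each new peak enters with
#'   weight 1/n against (n-1)/n for the running value (default 5, set
#'   empirically).
#' @return a `wp_config` list.
#' @export
wp_config <- function(zc_threshold = 0.01, smooth_n = 5) {
  if (zc_threshold < 0) stop("zc_threshold must be >= 0", call. = FALSE)
  if (smooth_n < 1) stop("smooth_n must be >= 1", call. = FALSE)
  structure(list(zc_threshold = zc_threshold, smooth_n = as.integer(smooth_n)),
            class = "wp_config")
}

#' Thresholded zero crossings
#'
#' Returns the (1-based) indices `i` at which the signal crosses zero with
#' sufficient amplitude: `sign(s[i] * s[i+1]) < 0` (strict sign change) and
#' `|s[i] - s[i+1]| >= threshold`. The count of returned indices is the ZC
#' statistic.
#'
#' @param signal numeric series, length >= 2.
#' @param threshold nonnegative amplitude gate.
#' @return integer index vector (possibly empty).
#' @export
zero_crossings <- function(signal, threshold = 0.01) {
  n <- length(signal)
  if (n < 2) stop("input error: need at least 2 samples", call. = FALSE)
  s1 <- signal[-n]
  s2 <- signal[-1]
  which(s1 * s2 < 0 & abs(s1 - s2) >= threshold)
}

#' Peaks and valleys between consecutive zero crossings
#'
#' For each pair of consecutive crossings, takes the extremum of the samples
#' strictly after the first crossing up to and including the second: the
#' maximum when `max + min >= 0`, otherwise the negated minimum, so all
#' outputs are nonnegative magnitudes.
#'
#' @param signal numeric series.
#' @param zc sorted crossing indices from [zero_crossings()].
#' @return data.frame with `value` (peak magnitude), `peak_at` (sample index
#'   of the extremum) and `known_at` (the crossing index at which the peak
#'   is finalized, used for causal tick placement). Zero rows when fewer
#'   than two crossings.
#' @export
extract_peaks <- function(signal, zc) {
  if (length(zc) < 2) {
    return(data.frame(value = numeric(0), peak_at = integer(0),
                      known_at = integer(0)))
  }
  k <- length(zc) - 1
  value <- numeric(k)
  peak_at <- integer(k)
  for (i in seq_len(k)) {
    idx <- (zc[i] + 1L):zc[i + 1]
    seg <- signal[idx]
    if (max(seg) + min(seg) >= 0) {
      value[i] <- max(seg)
      peak_at[i] <- idx[which.max(seg)]
    } else {
      value[i] <- -min(seg)
      peak_at[i] <- idx[which.min(seg)]
    }
  }
  data.frame(value = value, peak_at = peak_at, known_at = zc[-1])
}

#' Recursive peak weighting
#'
#' Left-to-right recursive smoothing `P[i+1] <- (n-1)/n * P[i] + 1/n *
#' P[i+1]` where the right-hand `P[i]` is the already-updated value (an
#' order-1 IIR pass). The first element is unchanged; `n = 1` is the
#' identity.
#'
#' @param peaks numeric peak magnitudes.
#' @param smooth_n weighting constant n >= 1.
#' @return weighted sequence, same length.
#' @export
weight_peaks <- function(peaks, smooth_n = 5) {
  if (smooth_n < 1) stop("smooth_n must be >= 1", call. = FALSE)
  m <- length(peaks)
  if (m == 0) return(numeric(0))
  if (smooth_n == 1 || m == 1) return(peaks)
  as.numeric(stats::filter(peaks / smooth_n, (smooth_n - 1) / smooth_n,
                           method = "recursive", init = peaks[1]))
}

#' Weight Peaks features over wavelet-packet nodes
#'
#' Runs the zero-crossing / peak-extraction / recursive-weighting chain on
#' the reconstruction of every terminal wavelet-packet node (the nodes carry
#' different frequency bands, so their peak rates differ) and merges the
#' per-node weighted peaks into one time-ordered event stream. Ticks are the
#' crossing indices at which each peak is finalized, keeping the stream
#' causal; when several nodes finalize a peak at the same sample the largest
#' weighted magnitude is kept. On broadband sEMG-like input the merged
#' stream fires at roughly 90% of the samples.
#'
#' @param signal conditioned single-channel series.
#' @param wavelet_cfg a [wavelet_config()].
#' @param wp_cfg a [wp_config()].
#' @return one-channel [feature_stream()], method `"WP"`.
#' @export
wp_features <- function(signal, wavelet_cfg = wavelet_config(),
                        wp_cfg = wp_config()) {
  tree <- wpt_decompose(signal, wavelet_cfg)
  events_t <- integer(0)
  events_v <- numeric(0)
  for (node in 0:(2^wavelet_cfg$level - 1)) {
    recon <- wpt_reconstruct_node(tree, node)
    zc <- zero_crossings(recon, wp_cfg$zc_threshold)
    pk <- extract_peaks(recon, zc)
    if (nrow(pk) == 0) next
    events_t <- c(events_t, pk$known_at)
    events_v <- c(events_v, weight_peaks(pk$value, wp_cfg$smooth_n))
  }
  if (length(events_t) == 0) {
    return(feature_stream(matrix(numeric(0), nrow = 1), integer(0), "WP"))
  }
  ticks <- sort(unique(events_t))
  vals <- vapply(split(events_v, events_t), max, numeric(1))
  feature_stream(vals[as.character(ticks)], ticks, "WP")
}

#' DFA configuration
#'
#' @param window_l disjoint window length L in samples (default 100).
#' @return a `dfa_config` list.
#' @export
dfa_config <- function(window_l = 100) {
  if (window_l < 3) stop("window_l must be >= 3", call. = FALSE)
  structure(list(window_l = as.integer(window_l)), class = "dfa_config")
}

#' DFA profile (integrated, mean-removed series)
#'
#' @param x numeric segment.
#' @return cumulative sum of `x - mean(x)`; the last element is 0 up to
#'   floating-point error.
#' @export
dfa_profile <- function(x) {
  if (length(x) == 0) stop("input error: empty segment", call. = FALSE)
  cumsum(x - mean(x))
}

#' DFA fluctuation of one window
#'
#' Fits a least-squares line `X_j ~ a * j + b` over `j = 1..L` and returns
#' the RMS residual `F(L) = sqrt(mean((X_j - a*j - b)^2))`.
#'
#' @param x_profile integrated window of length L >= 3.
#' @return scalar fluctuation, >= 0.
#' @export
dfa_fluctuation <- function(x_profile) {
  l <- length(x_profile)
  if (l < 3) stop("parameter error: window must hold at least 3 points",
                  call. = FALSE)
  j <- seq_len(l)
  jc <- j - mean(j)
  a <- sum(jc * x_profile) / sum(jc^2)
  b <- mean(x_profile) - a * mean(j)
  sqrt(mean((x_profile - a * j - b)^2))
}

#' Windowed DFA features
#'
#' Partitions the signal into disjoint windows of `window_l` samples
#' (trailing partial window dropped), integrates each window around its own
#' mean, and reports the detrended RMS fluctuation of each: one feature per
#' window, ticked at the window's last sample. 1000 samples at L = 100 give
#' 10 features.
#'
#' @param signal conditioned single-channel series.
#' @param config a [dfa_config()].
#' @return one-channel [feature_stream()], method `"DFA"`.
#' @export
dfa_features <- function(signal, config = dfa_config()) {
  l <- config$window_l
  if (length(signal) < l) {
    stop("input error: signal shorter than one DFA window", call. = FALSE)
  }
  nw <- length(signal) %/% l
  vals <- vapply(seq_len(nw), function(w) {
    dfa_fluctuation(dfa_profile(signal[((w - 1) * l + 1):(w * l)]))
  }, numeric(1))
  feature_stream(vals, seq_len(nw) * l, "DFA")
}
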