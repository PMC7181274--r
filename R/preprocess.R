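#' Forward-fill missing values in a recording
#'
#' Replaces every missing entry by the most recent non-missing value in the
#' same channel. Leading missing entries, which have no predecessor, are set
#' to 0 (neutral after the networks' input batch-normalisation layer). The
#' missing mask is cleared. Idempotent.
#'
#' @param rec A `sensor_recording`.
#' @return The recording with no missing values and an all-FALSE mask.
#' @export
fill_missing <- function(rec) {
  stopifnot(inherits(rec, "sensor_recording"))
  V <- rec$values
  for (ch in seq_len(ncol(V))) {
    x <- V[, ch]
    miss <- is.na(x) | rec$missing_mask[, ch]
    if (!any(miss)) next
    x[miss] <- NA_real_
    # index of the last non-missing sample at or before each position
    idx <- cumsum(!is.na(x))
    filled <- c(0, x[!is.na(x)])[idx + 1]
    V[, ch] <- filled
  }
  rec$values <- V
  rec$missing_mask[] <- FALSE
  rec
}

#' Downsample a recording by averaging sample groups
#'
#' Averages the values over non-overlapping groups of `factor` consecutive
#' samples (mild anti-aliasing compared with plain decimation). Each group's
#' label is the majority label within the group, ties broken by the label of
#' the group's last sample. The trailing partial group is dropped and the
#' sampling rate divided by `factor`.
#'
#' @param rec A `sensor_recording` with no missing values (apply
#'   [fill_missing()] first).
#' @param factor Integer >= 1.
#' @return The downsampled `sensor_recording`.
#' @export
downsample <- function(rec, factor) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (length(factor) != 1 || factor < 1 || factor != as.integer(factor))
    stop_invalid("downsample factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  L <- nrow(rec$values)
  n_out <- L %/% factor
  if (n_out == 0) stop_invalid("recording shorter than one downsampling group")
  keep <- seq_len(n_out * factor)
  grp <- rep(seq_len(n_out), each = factor)
  V <- apply(rec$values[keep, , drop = FALSE], 2,
             function(x) tapply(x, grp, mean))
  V <- matrix(V, n_out, ncol(rec$values))
  labs <- vapply(seq_len(n_out), function(g) {
    gl <- rec$labels[keep][grp == g]
    majority_label(gl)
  }, integer(1))
  new_sensor_recording(V, matrix(FALSE, n_out, ncol(V)), labs,
                       sampling_rate = rec$sampling_rate / factor,
                       channel_names = rec$channel_names)
}

# majority label with ties broken by the last sample's label
majority_label <- function(labs) {
  tab <- table(labs)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) == 1) return(top)
  last <- labs[length(labs)]
  if (last %in% top) last else top[1]
}

#' Slice a recording into fixed-length sliding windows
#'
#' Windows are 0-based half-open intervals `[start, start + T)` with starts
#' `0, stride, 2*stride, ...`; the count is `floor((L - T)/stride) + 1` when
#' `L >= T`, else 0 (with a warning). Each window's label is the majority of
#' its per-sample labels, ties broken by the window's last sample.
#'
#' @param rec A `sensor_recording` with no missing values.
#' @param window_length Window length T in samples (>= 1).
#' @param stride Hop between window starts in samples (>= 1).
#' @return A `window_set`.
#' @export
slide_windows <- function(rec, window_length, stride) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (window_length < 1 || stride < 1)
    stop_invalid("window_length and stride must be >= 1")
  if (any(rec$missing_mask) || anyNA(rec$values))
    stop_invalid("recording contains missing values; apply fill_missing() first")
  T <- as.integer(window_length); stride <- as.integer(stride)
  L <- nrow(rec$values); C <- ncol(rec$values)
  if (L < T) {
    warning(sprintf("recording length %d < window length %d: empty window set", L, T))
    return(new_window_set(array(0, dim = c(0, T, C)), integer(0), stride,
                          rec$sampling_rate, rec$channel_names))
  }
  n <- (L - T) %/% stride + 1L
  starts <- (seq_len(n) - 1L) * stride          # 0-based
  data <- array(0, dim = c(n, T, C))
  labels <- integer(n)
  for (i in seq_len(n)) {
    rows <- (starts[i] + 1L):(starts[i] + T)
    data[i, , ] <- rec$values[rows, , drop = FALSE]
    labels[i] <- majority_label(rec$labels[rows])
  }
  new_window_set(data, labels, stride, rec$sampling_rate, rec$channel_names)
}

#' Rank channels by variance
#'
#' Orders channels by descending variance computed over all samples of all
#' windows, ties broken by ascending channel index. Used to restrict training
#' to the most informative sensor channels.
#'
#' @param ws A `window_set` with at least 2 windows.
#' @return Integer vector of 1-based channel indices, highest variance first.
#' @export
rank_channels_by_variance <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  if (dim(ws$data)[1] < 2) stop_invalid("need >= 2 windows to rank channels")
  C <- dim(ws$data)[3]
  v <- vapply(seq_len(C), function(ch) stats::var(as.vector(ws$data[, , ch])),
              numeric(1))
  order(-v, seq_len(C))
}

#' Keep the top-n ranked channels
#'
#' Retains the first `n` channels of `ranking`, preserving their original
#' relative order in the data tensor.
#'
#' @param ws A `window_set`.
#' @param ranking Channel ranking from [rank_channels_by_variance()].
#' @param n Number of channels to keep, `1 <= n <= C`.
#' @return The reduced `window_set`.
#' @export
select_top_channels <- function(ws, ranking, n) {
  stopifnot(inherits(ws, "window_set"))
  C <- dim(ws$data)[3]
  if (n < 1 || n > C) stop_invalid("n must be in [1, number of channels]")
  keep <- sort(ranking[seq_len(n)])
  new_window_set(ws$data[, , keep, drop = FALSE], ws$labels, ws$stride,
                 ws$sampling_rate, ws$channel_names[keep])
}
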