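#' Configuration for the synthetic sensor-data generator
#'
#' Describes a population of windowed multichannel oscillatory signals with
#' class-specific frequency/phase structure, per-frame amplitude and phase
#' jitter (intra-class variability), additive Gaussian noise, optional
#' time-reversed near-duplicate classes (activities such as opening versus
#' closing a door differ mainly in their temporal direction), optional class
#' imbalance with a majority NULL (background) class, and missing values.
#'
#' Class indices are 0-based everywhere in this package: classes are
#' `0, ..., n_classes - 1`, and when `null_class = TRUE` the NULL class is
#' appended with id `n_classes`.
#'
#' @param n_classes Number of activity classes (>= 2), excluding the NULL class.
#' @param channels Number of sensor channels (>= 1).
#' @param sampling_rate Sampling rate in Hz.
#' @param window_length Window length T in samples (>= 2).
#' @param n_windows_per_class Nominal windows per class; the total
#'   `n_windows_per_class * number of classes` is redistributed according to
#'   `class_proportions`.
#' @param base_frequencies Matrix `[n_classes x channels]` of positive
#'   oscillation frequencies (Hz), one per class per channel. Defaults to a
#'   fixed spread that keeps classes separable; members of a reversed pair
#'   share the first class's row.
#' @param phases Matrix `[n_classes x channels]` of template phase offsets in
#'   radians. Defaulted deterministically.
#' @param amplitude_jitter_sd Per-frame, per-channel multiplicative amplitude
#'   jitter standard deviation (dimensionless, >= 0).
#' @param phase_jitter_sd Per-frame phase jitter standard deviation in radians
#'   (shared across channels within a frame, modelling a shifted time origin).
#' @param noise_sd Additive white Gaussian noise standard deviation in signal
#'   units (>= 0).
#' @param reversed_pairs List of length-2 integer vectors of 0-based class ids
#'   `c(a, b)`: class `b`'s template is the time reversal of class `a`'s.
#' @param class_proportions Optional simplex weights over all classes
#'   (including the NULL class when present). Default: uniform, or 60% NULL /
#'   40% split evenly when `null_class = TRUE`.
#' @param null_class If TRUE, append a majority background class whose
#'   template is zero (pure low-amplitude noise).
#' @param missing_rate Fraction in [0, 1) of entries set missing in generated
#'   recordings (independently per entry).
#' @param rng_seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 6,
                             channels = 3,
                             sampling_rate = 30,
                             window_length = 32,
                             n_windows_per_class = 100,
                             base_frequencies = NULL,
                             phases = NULL,
                             amplitude_jitter_sd = 0.3,
                             phase_jitter_sd = 0.8,
                             noise_sd = 0.4,
                             reversed_pairs = list(c(0L, 1L)),
                             class_proportions = NULL,
                             null_class = FALSE,
                             missing_rate = 0,
                             rng_seed = 1L) {
  if (n_classes < 2) stop_invalid("n_classes must be >= 2")
  if (channels < 1) stop_invalid("channels must be >= 1")
  if (window_length < 2) stop_invalid("window_length must be >= 2 samples")
  if (amplitude_jitter_sd < 0 || phase_jitter_sd < 0 || noise_sd < 0)
    stop_invalid("jitter and noise standard deviations must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_invalid("missing_rate must be in [0, 1)")

  if (is.null(base_frequencies)) {
    base_frequencies <- outer(seq_len(n_classes) - 1, seq_len(channels) - 1,
                              function(c, ch) 0.7 + 0.45 * c + 0.2 * ch)
  }
  base_frequencies <- matrix(base_frequencies, n_classes, channels)
  if (any(base_frequencies <= 0)) stop_invalid("base_frequencies must be positive")
  if (is.null(phases)) {
    phases <- outer(seq_len(n_classes) - 1, seq_len(channels) - 1,
                    function(c, ch) (0.9 * c + 2.1 * ch) %% (2 * pi))
  }
  phases <- matrix(phases, n_classes, channels)

  for (pr in reversed_pairs) {
    if (length(pr) != 2 || pr[1] == pr[2] ||
        any(pr < 0) || any(pr >= n_classes))
      stop_invalid("reversed_pairs entries must be two distinct class ids in [0, n_classes)")
    # the reversed class inherits its partner's template parameters
    base_frequencies[pr[2] + 1, ] <- base_frequencies[pr[1] + 1, ]
    phases[pr[2] + 1, ] <- phases[pr[1] + 1, ]
  }

  n_eff <- n_classes + as.integer(null_class)
  if (is.null(class_proportions)) {
    class_proportions <- if (null_class) {
      c(rep(0.4 / n_classes, n_classes), 0.6)
    } else rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_eff)
    stop_invalid("class_proportions must have one weight per class (incl. NULL class)")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop_invalid("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop_invalid("class_proportions must be non-negative")

  structure(list(
    n_classes = as.integer(n_classes), channels = as.integer(channels),
    sampling_rate = sampling_rate, window_length = as.integer(window_length),
    n_windows_per_class = as.integer(n_windows_per_class),
    base_frequencies = base_frequencies, phases = phases,
    amplitude_jitter_sd = amplitude_jitter_sd,
    phase_jitter_sd = phase_jitter_sd, noise_sd = noise_sd,
    reversed_pairs = lapply(reversed_pairs, as.integer),
    class_proportions = class_proportions,
    null_class = isTRUE(null_class),
    missing_rate = missing_rate, rng_seed = as.integer(rng_seed)
  ), class = "synthetic_config")
}

# total number of class ids including the NULL class
n_total_classes <- function(cfg) cfg$n_classes + as.integer(cfg$null_class)

# is `cls` (0-based) the second member of a reversed pair? returns partner or NA
reversal_partner <- function(cfg, cls) {
  for (pr in cfg$reversed_pairs) if (pr[2] == cls) return(pr[1])
  NA_integer_
}

#' Noise-free class template
#'
#' Returns the deterministic template (no jitter, no noise) of a class: one
#' sinusoid per channel at the class/channel frequency and phase, with the
#' time axis reversed for the second member of a reversed pair, and all zeros
#' for the NULL class.
#'
#' @param cfg A [synthetic_config()].
#' @param class 0-based class id.
#' @param length Template length in samples (default the window length).
#' @return Numeric matrix `[length x channels]`.
#' @export
class_template <- function(cfg, class, length = cfg$window_length) {
  frame_for_class(cfg, class, length, amp = rep(1, cfg$channels), delta = 0)
}

# one frame: template with amplitude vector `amp` and shared phase shift `delta`
frame_for_class <- function(cfg, cls, len, amp, delta) {
  C <- cfg$channels
  if (cfg$null_class && cls == cfg$n_classes) return(matrix(0, len, C))
  partner <- reversal_partner(cfg, cls)
  base <- if (is.na(partner)) cls else partner
  t <- seq_len(len) - 1
  X <- matrix(0, len, C)
  for (ch in seq_len(C)) {
    X[, ch] <- amp[ch] * sin(2 * pi * cfg$base_frequencies[base + 1, ch] *
                               t / cfg$sampling_rate +
                               cfg$phases[base + 1, ch] + delta)
  }
  if (!is.na(partner)) X <- X[rev(seq_len(len)), , drop = FALSE]
  X
}

# largest-remainder apportionment of `total` items into proportions `p`
apportion <- function(total, p) {
  raw <- total * p
  n <- floor(raw)
  rem <- total - sum(n)
  if (rem > 0) {
    take <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[take] <- n[take] + 1
  }
  as.integer(n)
}

#' Generate a labelled window set
#'
#' Draws `n_windows_per_class * n_classes` fixed-length frames (redistributed
#' across classes by `class_proportions`). Each frame is its class template
#' with per-frame amplitude and phase jitter plus additive Gaussian noise;
#' classes listed in `reversed_pairs` use the time-reversed template.
#'
#' @param cfg A [synthetic_config()].
#' @return A `window_set`: list with `data` (array `[N x T x C]`), `labels`
#'   (0-based integer vector), `window_length`, `stride` (NA for directly
#'   generated windows), `sampling_rate`, `channel_names`.
#' @export
generate_windows <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_eff <- n_total_classes(cfg)
  total <- cfg$n_windows_per_class * n_eff
  counts <- apportion(total, cfg$class_proportions)
  T <- cfg$window_length; C <- cfg$channels
  data <- array(0, dim = c(sum(counts), T, C))
  labels <- integer(sum(counts))
  with_seed(cfg$rng_seed, {
    i <- 1L
    for (cls in seq_len(n_eff) - 1L) {
      for (k in seq_len(counts[cls + 1])) {
        amp <- 1 + stats::rnorm(C, sd = cfg$amplitude_jitter_sd)
        delta <- stats::rnorm(1, sd = cfg$phase_jitter_sd)
        X <- frame_for_class(cfg, cls, T, amp, delta)
        if (cfg$noise_sd > 0)
          X <- X + matrix(stats::rnorm(T * C, sd = cfg$noise_sd), T, C)
        data[i, , ] <- X
        labels[i] <- cls
        i <- i + 1L
      }
    }
  })
  new_window_set(data, labels, stride = NA_integer_,
                 sampling_rate = cfg$sampling_rate,
                 channel_names = default_channel_names(C))
}

#' Generate a continuous labelled recording
#'
#' Concatenates labelled activity segments (several contiguous segments per
#' class, interleaved round-robin) into one continuous multichannel recording,
#' then inserts missing values independently per entry at `missing_rate`.
#' Suitable for exercising [fill_missing()] and [slide_windows()].
#'
#' @param cfg A [synthetic_config()].
#' @param segments_per_class Number of contiguous segments each class's
#'   allocation is split into (default 4).
#' @return A `sensor_recording`: list with `values` (`[L x C]`, missing entries
#'   NA), `missing_mask` (`[L x C]` logical), `labels` (0-based, per sample),
#'   `sampling_rate`, `channel_names`. The segment plan is attached as
#'   attribute `"segments"` (data.frame with `class`, `start`, `length`).
#' @export
generate_recording <- function(cfg, segments_per_class = 4L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$missing_rate >= 1) stop_invalid("missing_rate must be < 1")
  n_eff <- n_total_classes(cfg)
  total_len <- cfg$n_windows_per_class * cfg$window_length * n_eff
  per_class <- apportion(total_len, cfg$class_proportions)
  C <- cfg$channels

  # segment plan: split each class allocation, interleave round-robin
  plan <- list()
  for (cls in seq_len(n_eff) - 1L) {
    len <- per_class[cls + 1]
    if (len == 0) next
    k <- min(segments_per_class, len)
    seg_len <- apportion(len, rep(1 / k, k))
    for (j in seq_len(k)) {
      plan[[length(plan) + 1]] <- list(class = cls, round = j,
                                       length = seg_len[j])
    }
  }
  ord <- order(vapply(plan, `[[`, 1L, "round"),
               vapply(plan, `[[`, 1L, "class"))
  plan <- plan[ord]

  L <- sum(vapply(plan, `[[`, 1L, "length"))
  values <- matrix(0, L, C)
  labels <- integer(L)
  seg_df <- data.frame(class = integer(0), start = integer(0),
                       length = integer(0))
  with_seed(cfg$rng_seed, {
    pos <- 1L
    for (seg in plan) {
      len <- seg$length
      if (len == 0) next
      amp <- 1 + stats::rnorm(C, sd = cfg$amplitude_jitter_sd)
      delta <- stats::rnorm(1, sd = cfg$phase_jitter_sd)
      X <- frame_for_class(cfg, seg$class, len, amp, delta)
      if (cfg$noise_sd > 0)
        X <- X + matrix(stats::rnorm(len * C, sd = cfg$noise_sd), len, C)
      values[pos:(pos + len - 1), ] <- X
      labels[pos:(pos + len - 1)] <- seg$class
      seg_df <- rbind(seg_df, data.frame(class = seg$class, start = pos - 1L,
                                         length = len))
      pos <- pos + len
    }
    mask <- matrix(FALSE, L, C)
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(L * C) < cfg$missing_rate, L, C)
      values[mask] <- NA_real_
    }
    rec <- new_sensor_recording(values, mask, labels,
                                sampling_rate = cfg$sampling_rate,
                                channel_names = default_channel_names(C))
    attr(rec, "segments") <- seg_df
    rec
  })
}

default_channel_names <- function(C) sprintf("ch%d", seq_len(C))

# ---- containers ------------------------------------------------------------

new_window_set <- function(data, labels, stride, sampling_rate,
                           channel_names) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels))
  structure(list(data = data, labels = as.integer(labels),
                 window_length = dim(data)[2], stride = stride,
                 sampling_rate = sampling_rate,
                 channel_names = channel_names),
            class = "window_set")
}

new_sensor_recording <- function(values, missing_mask, labels, sampling_rate,
                                 channel_names) {
  stopifnot(nrow(values) == length(labels),
            all(dim(values) == dim(missing_mask)))
  structure(list(values = values, missing_mask = missing_mask,
                 labels = as.integer(labels), sampling_rate = sampling_rate,
                 channel_names = channel_names),
            class = "sensor_recording")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<window_set> %d windows x %d samples x %d channels, %d classes, %g Hz\n",
              d[1], d[2], d[3], length(unique(x$labels)), x$sampling_rate))
  invisible(x)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d samples x %d channels, %g Hz, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              100 * mean(x$missing_mask)))
  invisible(x)
}
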