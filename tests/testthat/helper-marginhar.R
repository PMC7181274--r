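# Shared fixtures and independent oracles used across the suite.

# small, quick-to-train synthetic task (3 well-separated classes)
quick_syn <- function(n_classes = 3, n_per_class = 30, seed = 2,
                      channels = 2, window_length = 16, ...) {
  synthetic_config(n_classes = n_classes, channels = channels,
                   window_length = window_length,
                   n_windows_per_class = n_per_class,
                   amplitude_jitter_sd = 0.1, phase_jitter_sd = 0.2,
                   noise_sd = 0.2, reversed_pairs = list(),
                   rng_seed = seed, ...)
}

# small architectures for training tests
quick_net <- function(kind, head = "arcmargin", ...) {
  switch(kind,
    mlp = network_config("mlp", head, mlp_fc_sizes = c(16, 16, 16), ...),
    cnn = network_config("cnn", head,
                         cnn_blocks = list(c(5, 1, 8, 2), c(3, 1, 8, 2)),
                         cnn_fc_size = 16, ...),
    lstm = network_config("lstm", head, lstm_hidden = 10, lstm_fc_size = 16,
                          ...),
    hybrid = network_config("hybrid", head, hybrid_block = c(5, 1, 8, 2),
                            hybrid_lstm_hidden = 10, hybrid_fc_size = 16, ...))
}

# nearest-template oracle classifier for generated windows
oracle_classify <- function(ws, cfg) {
  n <- cfg$n_classes + as.integer(cfg$null_class)
  tpl <- lapply(seq_len(n) - 1L, function(cl)
    as.vector(class_template(cfg, cl)))
  vapply(seq_len(dim(ws$data)[1]), function(i) {
    x <- as.vector(ws$data[i, , ])
    sims <- vapply(tpl, function(tt) cosine_similarity(x, tt), numeric(1))
    which.max(sims) - 1L
  }, integer(1))
}

# brute-force metrics from raw label vectors (independent of the package's
# confusion-matrix path)
brute_metrics <- function(y_true, y_pred, n) {
  prec <- rec <- f1 <- w <- numeric(n)
  N <- length(y_true)
  for (c in 0:(n - 1)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_len(N)) {
      if (y_pred[i] == c && y_true[i] == c) tp <- tp + 1
      if (y_pred[i] == c && y_true[i] != c) fp <- fp + 1
      if (y_pred[i] != c && y_true[i] == c) fn <- fn + 1
    }
    prec[c + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[c + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c + 1] <- if (prec[c + 1] + rec[c + 1] > 0)
      2 * prec[c + 1] * rec[c + 1] / (prec[c + 1] + rec[c + 1]) else 0
    w[c + 1] <- sum(y_true == c) / N
  }
  list(acc = mean(y_true == y_pred), fw = sum(w * f1), fm = mean(f1))
}

# exhaustive sliding-window enumeration oracle
enumerate_windows <- function(values, labels, T, stride) {
  L <- nrow(values)
  out <- list()
  start <- 0
  while (start + T <= L) {
    rows <- (start + 1):(start + T)
    lab_tab <- table(labels[rows])
    top <- as.integer(names(lab_tab)[lab_tab == max(lab_tab)])
    lab <- if (length(top) == 1) top else {
      last <- labels[rows[T]]
      if (last %in% top) last else top[1]
    }
    out[[length(out) + 1]] <- list(data = values[rows, , drop = FALSE],
                                   label = lab, start = start)
    start <- start + stride
  }
  out
}

# exhaustive threshold-grid oracle for class acceptance calibration
oracle_threshold <- function(sims, is_pos) {
  grid <- seq(0.1, 0.9, by = 0.1)
  f1 <- vapply(grid, function(tau) {
    tp <- sum(is_pos & sims >= tau)
    fp <- sum(!is_pos & sims >= tau)
    fn <- sum(is_pos & sims < tau)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  grid[max(which(f1 == max(f1)))]
}

# random LossBatch cosines/labels
random_batch <- function(B, n, cos_range = c(-1, 1)) {
  list(cosines = matrix(stats::runif(B * n, cos_range[1], cos_range[2]), B, n),
       labels = sample(0:(n - 1), B, replace = TRUE))
}
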