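#' Stratified split of a window set
#'
#' Splits windows into named subsets with the given proportions within every
#' class (largest-remainder apportionment per class), after a seeded shuffle.
#'
#' @param ws A `window_set`.
#' @param props Named numeric vector of proportions summing to 1, e.g.
#'   `c(train = .5, val = .2, enroll = .15, test = .15)`.
#' @param rng_seed Integer seed.
#' @return Named list of `window_set`s.
#' @export
split_window_set <- function(ws, props, rng_seed = 1L) {
  stopifnot(inherits(ws, "window_set"), abs(sum(props) - 1) < 1e-9)
  assign_idx <- with_seed(rng_seed, {
    out <- character(dim(ws$data)[1])
    for (cls in unique(ws$labels)) {
      idx <- which(ws$labels == cls)
      idx <- sample(idx)
      counts <- apportion(length(idx), props)
      out[idx] <- rep(names(props), counts)
    }
    out
  })
  stats::setNames(lapply(names(props), function(nm) {
    keep <- which(assign_idx == nm)
    new_window_set(ws$data[keep, , , drop = FALSE], ws$labels[keep],
                   ws$stride, ws$sampling_rate, ws$channel_names)
  }), names(props))
}

#' Class-by-class cosine-similarity heatmap
#'
#' Entry `(a, b)` is the mean cosine similarity over all cross pairs of
#' features from classes `a` and `b`; the diagonal uses distinct pairs only
#' (so it is comparable with the off-diagonal) and is `NA` for classes with a
#' single feature. Symmetric. With a discriminative feature space the
#' diagonal (intra-class) dominates the off-diagonal (inter-class).
#'
#' @param features Matrix `[N x d]`.
#' @param labels 0-based class labels, length N.
#' @return Symmetric matrix `[n x n]` with class-id dimnames.
#' @export
cosine_similarity_heatmap <- function(features, labels) {
  X <- normalize_rows_quiet(as.matrix(features))
  classes <- sort(unique(labels))
  n <- length(classes)
  H <- matrix(NA_real_, n, n, dimnames = list(classes, classes))
  sums <- t(vapply(classes, function(cl)
    colSums(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) {
      k <- counts[a]
      if (k >= 2) H[a, a] <- (sum(sums[a, ]^2) - k) / (k * (k - 1))
    } else {
      H[a, b] <- sum(sums[a, ] * sums[b, ]) / (counts[a] * counts[b])
    }
  }
  H
}

#' Intra- versus inter-class similarity summary
#'
#' @param features Matrix `[N x d]`.
#' @param labels 0-based class labels.
#' @return List with `intra` (mean of the heatmap diagonal) and `inter` (mean
#'   of its off-diagonal entries).
#' @export
similarity_summary <- function(features, labels) {
  H <- cosine_similarity_heatmap(features, labels)
  list(intra = mean(diag(H), na.rm = TRUE),
       inter = mean(H[row(H) != col(H)], na.rm = TRUE))
}

# per-label F1 for character label vectors (used by the open-set protocol,
# where predictions may be "NEW")
f1_per_label <- function(y_true, y_pred, labels) {
  vapply(labels, function(l) {
    tp <- sum(y_true == l & y_pred == l)
    fp <- sum(y_true != l & y_pred == l)
    fn <- sum(y_true == l & y_pred != l)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Margin sweep
#'
#' Trains one arcmargin model per margin value at a fixed seed, evaluates the
#' weighted F1 on a held-out test split, and returns a tidy table. The row
#' whose margin equals the architecture's conventional default (MLP 0.5,
#' CNN 0.2, LSTM 0.5, hybrid 0.3) is annotated.
#'
#' @param syn_cfg A [synthetic_config()] describing the data.
#' @param net_cfg A [network_config()] (head forced to `"arcmargin"`).
#' @param tc A [train_config()].
#' @param margins Margin grid in radians.
#' @param out_dir Optional directory for `margin_sweep.csv` + manifest.
#' @return data.frame with columns `margin`, `weighted_f1`, `average_f1`,
#'   `accuracy`, `is_reference_default`.
#' @export
run_margin_sweep <- function(syn_cfg, net_cfg, tc = train_config(),
                             margins = seq(0, 0.5, by = 0.1),
                             out_dir = NULL) {
  defaults <- c(mlp = 0.5, cnn = 0.2, lstm = 0.5, hybrid = 0.3)
  ws <- generate_windows(syn_cfg)
  sp <- split_window_set(ws, c(train = 0.7, test = 0.3),
                         rng_seed = syn_cfg$rng_seed)
  n <- n_total_classes(syn_cfg)
  res <- do.call(rbind, lapply(margins, function(m) {
    cfg <- net_cfg
    cfg$head <- "arcmargin"
    cfg$margin <- m
    model <- build_network(cfg, dim(ws$data)[2:3], n)
    model <- train_network(model, sp$train, tc)
    pred <- predict(model, sp$test)
    cm <- confusion_matrix(sp$test$labels, pred$labels, n)
    data.frame(margin = m, weighted_f1 = weighted_f1(cm),
               average_f1 = average_f1(cm), accuracy = accuracy(cm))
  }))
  res$is_reference_default <- abs(res$margin - defaults[[net_cfg$kind]]) < 1e-12
  if (!is.null(out_dir)) {
    write_experiment_outputs(out_dir, "margin_sweep", res,
                             list(syn = unclass(syn_cfg),
                                  net = unclass(net_cfg), train = unclass(tc),
                                  margins = margins))
  }
  res
}

#' Hold-one-class-out open-set experiment
#'
#' Trains on all classes except `held_out_class`, builds the feature database
#' (center and/or cluster methods across a grid of seed counts), calibrates
#' per-class thresholds on a validation split, enrolls the held-out class
#' from a disjoint enrollment split, and classifies a test split containing
#' all classes. A closed-set control (trained on all classes, same database
#' pipeline, no enrollment) is run for comparison.
#'
#' @param syn_cfg A [synthetic_config()].
#' @param net_cfg A [network_config()].
#' @param tc A [train_config()].
#' @param held_out_class 0-based id of the class treated as new.
#' @param methods Seed-selection methods to run.
#' @param seed_counts Grid of seeds per class.
#' @param out_dir Optional output directory.
#' @return data.frame with columns `method`, `n_seeds`, `class` (`"NEW"` for
#'   the held-out class), `f1`, `setting` (`"open"` or `"closed"`).
#' @export
run_open_set_experiment <- function(syn_cfg, net_cfg, tc = train_config(),
                                    held_out_class = n_total_classes(syn_cfg) - 1L,
                                    methods = c("center", "cluster"),
                                    seed_counts = 3L, out_dir = NULL) {
  n <- n_total_classes(syn_cfg)
  if (held_out_class < 0 || held_out_class >= n)
    stop_invalid("held_out_class out of range")
  ws <- generate_windows(syn_cfg)
  sp <- split_window_set(ws, c(train = 0.5, val = 0.2, enroll = 0.15,
                               test = 0.15), rng_seed = syn_cfg$rng_seed)
  shape <- dim(ws$data)[2:3]
  known <- setdiff(seq_len(n) - 1L, held_out_class)

  subset_ws <- function(w, classes) {
    keep <- which(w$labels %in% classes)
    new_window_set(w$data[keep, , , drop = FALSE], w$labels[keep], w$stride,
                   w$sampling_rate, w$channel_names)
  }

  # open-set model: held-out class absent from training and validation
  train_open <- subset_ws(sp$train, known)
  stopifnot(!held_out_class %in% train_open$labels)
  model_open <- train_network(build_network(net_cfg, shape, n), train_open, tc)
  # closed-set control: all classes
  model_closed <- train_network(build_network(net_cfg, shape, n), sp$train, tc)

  val_open <- subset_ws(sp$val, known)
  f_train_open <- extract_features(model_open, train_open)
  f_val_open <- extract_features(model_open, val_open)
  f_enroll <- extract_features(model_open,
                               subset_ws(sp$enroll, held_out_class))
  f_test_open <- extract_features(model_open, sp$test)

  f_train_closed <- extract_features(model_closed, sp$train)
  f_val_closed <- extract_features(model_closed, sp$val)
  f_test_closed <- extract_features(model_closed, sp$test)

  true_open <- ifelse(sp$test$labels == held_out_class, "NEW",
                      as.character(sp$test$labels))
  rows <- list()
  for (method in methods) for (k in seed_counts) {
    db <- build_feature_db(f_train_open, train_open$labels,
                           f_val_open, val_open$labels,
                           method = method, n_seeds = k,
                           rng_seed = tc$rng_seed)
    db <- enroll_new_class(db, f_enroll, class_id = held_out_class,
                           method = method, n_seeds = k,
                           rng_seed = tc$rng_seed)
    pred <- openset_classify_all(f_test_open, db)
    pred <- ifelse(pred == as.character(held_out_class), "NEW", pred)
    lvl <- c(as.character(known), "NEW")
    f1o <- f1_per_label(true_open, pred, lvl)
    rows[[length(rows) + 1]] <- data.frame(method = method, n_seeds = k,
                                           class = lvl, f1 = f1o,
                                           setting = "open")

    db_c <- build_feature_db(f_train_closed, sp$train$labels,
                             f_val_closed, sp$val$labels,
                             method = method, n_seeds = k,
                             rng_seed = tc$rng_seed)
    pred_c <- openset_classify_all(f_test_closed, db_c)
    f1c <- f1_per_label(as.character(sp$test$labels), pred_c,
                        as.character(seq_len(n) - 1L))
    rows[[length(rows) + 1]] <- data.frame(method = method, n_seeds = k,
                                           class = as.character(seq_len(n) - 1L),
                                           f1 = f1c, setting = "closed")
  }
  res <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write_experiment_outputs(out_dir, "open_set", res,
                             list(syn = unclass(syn_cfg),
                                  net = unclass(net_cfg), train = unclass(tc),
                                  held_out_class = held_out_class,
                                  methods = methods,
                                  seed_counts = seed_counts))
  }
  res
}

#' Two-dimensional embedding experiment
#'
#' Trains softmax- and arcmargin-headed twins whose feature layer is 2 units
#' wide at an equal seed, and exports the test features in Euclidean and
#' angular (unit-normalized) form together with the minimal inter-class
#' angular gap between the learned class-weight directions of each head.
#'
#' @param syn_cfg A [synthetic_config()].
#' @param net_cfg A [network_config()]; its feature-layer width is forced
#'   to 2.
#' @param tc A [train_config()].
#' @param out_dir Optional output directory.
#' @return List with `features` (data.frame: `head`, `space`, `x`, `y`,
#'   `label`) and `min_angular_gap` (named numeric, radians, per head).
#' @export
run_embedding_2d <- function(syn_cfg, net_cfg, tc = train_config(),
                             out_dir = NULL) {
  net_cfg <- set_feature_width(net_cfg, 2L)
  ws <- generate_windows(syn_cfg)
  sp <- split_window_set(ws, c(train = 0.7, test = 0.3),
                         rng_seed = syn_cfg$rng_seed)
  n <- n_total_classes(syn_cfg)
  shape <- dim(ws$data)[2:3]
  out_feat <- list(); gaps <- c()
  for (head in c("softmax", "arcmargin")) {
    cfg <- net_cfg
    cfg$head <- head
    model <- train_network(build_network(cfg, shape, n), sp$train, tc)
    f <- extract_features(model, sp$test)
    fa <- normalize_rows_quiet(f)
    out_feat[[head]] <- rbind(
      data.frame(head = head, space = "euclidean", x = f[, 1], y = f[, 2],
                 label = sp$test$labels),
      data.frame(head = head, space = "angular", x = fa[, 1], y = fa[, 2],
                 label = sp$test$labels))
    gaps[head] <- min_angular_gap(head_class_directions(model))
  }
  res <- list(features = do.call(rbind, out_feat), min_angular_gap = gaps)
  if (!is.null(out_dir)) {
    write_experiment_outputs(out_dir, "embedding_2d", res$features,
                             list(syn = unclass(syn_cfg),
                                  net = unclass(net_cfg), train = unclass(tc),
                                  min_angular_gap = as.list(gaps)))
  }
  res
}

#' Minimal pairwise angular gap between class directions
#'
#' @param W Matrix of class-direction rows.
#' @return Smallest pairwise angle in radians.
#' @export
min_angular_gap <- function(W) {
  S <- cosine_matrix(W, W)
  min(acos(pmin(1, pmax(-1, S[upper.tri(S)]))))
}

# force the designated feature layer's width to `w`
set_feature_width <- function(cfg, w) {
  switch(cfg$kind,
         mlp = { cfg$mlp_fc_sizes[1] <- w; cfg },
         cnn = { cfg$cnn_fc_size <- w; cfg },
         lstm = { cfg$lstm_fc_size <- w; cfg },
         hybrid = { cfg$hybrid_fc_size <- w; cfg })
}

# results CSV + JSON manifest (config, seeds, package version) for re-runs
write_experiment_outputs <- function(out_dir, name, table, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
  manifest <- list(experiment = name, config = config,
                   package_version = as.character(utils::packageVersion("marginhar")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
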