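#' Center seed of a class feature set
#'
#' Returns the index of the feature whose mean cosine similarity to all other
#' features of the set (self excluded) is highest — the most central exemplar
#' on the unit hypersphere. Ties break to the lowest index; a singleton set
#' returns index 1.
#'
#' @param features Matrix `[k x d]`, one feature per row (k >= 1).
#' @return 1-based row index of the center-seed feature.
#' @export
center_seed <- function(features) {
  features <- as.matrix(features)
  k <- nrow(features)
  if (k == 0) stop_invalid("empty feature set")
  if (k == 1) return(1L)
  S <- cosine_matrix(features, features)
  mean_sim <- (rowSums(S) - diag(S)) / (k - 1)
  which.max(mean_sim)   # which.max takes the first (lowest index) on ties
}

#' Center-method seed selection
#'
#' The center-seed feature plus `n_random` distinct other features sampled
#' uniformly without replacement (the "random-seed" features), deterministic
#' given `rng_seed`.
#'
#' @param features Matrix `[k x d]`.
#' @param n_random Number of additional random seeds, `<= k - 1`.
#' @param rng_seed Integer seed.
#' @return Matrix of seed vectors, center seed first.
#' @export
select_center_seeds <- function(features, n_random = 0L, rng_seed = 1L) {
  features <- as.matrix(features)
  k <- nrow(features)
  if (n_random > k - 1)
    stop_invalid("n_random must be <= number of features - 1")
  ci <- center_seed(features)
  extra <- integer(0)
  if (n_random > 0) {
    pool <- setdiff(seq_len(k), ci)
    extra <- with_seed(rng_seed, sample(pool, n_random))
  }
  features[c(ci, extra), , drop = FALSE]
}

#' Cluster-method seed selection (k-means++ / Lloyd)
#'
#' L2-normalizes the features (so Euclidean clustering orders points as cosine
#' similarity does), initialises k centers with the k-means++ rule, then runs
#' Lloyd iterations until the centers move less than `tol` or 100 iterations,
#' and returns the centers as seed vectors.
#'
#' @param features Matrix `[k_points x d]`.
#' @param k Number of cluster seeds, `1 <= k <=` number of features.
#' @param rng_seed Integer seed (k-means++ sampling).
#' @param tol Convergence tolerance on total squared center movement.
#' @return Matrix `[k x d]` of cluster-seed features.
#' @export
select_cluster_seeds <- function(features, k, rng_seed = 1L, tol = 1e-6) {
  X <- normalize_rows_quiet(as.matrix(features))
  n <- nrow(X)
  if (k < 1 || k > n) stop_invalid("k must be in [1, number of features]")
  with_seed(rng_seed, {
    centers <- kmeanspp_init(X, k)
    for (it in seq_len(100)) {
      d2 <- sq_dist(X, centers)
      assign <- max.col(-d2, ties.method = "first")
      new_centers <- centers
      for (j in seq_len(k)) {
        pts <- X[assign == j, , drop = FALSE]
        if (nrow(pts) > 0) {
          new_centers[j, ] <- colMeans(pts)
        } else {
          # re-seed an empty cluster at the point farthest from its center
          far <- which.max(d2[cbind(seq_len(n), assign)])
          new_centers[j, ] <- X[far, ]
        }
      }
      moved <- sum((new_centers - centers)^2)
      centers <- new_centers
      if (moved < tol) break
    }
    centers
  })
}

# k-means++ initialisation: first center uniform, then proportional to the
# squared distance to the nearest chosen center
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(sq_dist(X, centers[seq_len(j - 1), , drop = FALSE]), 1, min)
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[pick, ]
  }
  centers
}

# squared Euclidean distances between rows of X and rows of Cn
sq_dist <- function(X, Cn) {
  xx <- rowSums(X^2); cc <- rowSums(Cn^2)
  d2 <- outer(xx, cc, "+") - 2 * X %*% t(Cn)
  pmax(d2, 0)
}

#' Similarity of a feature to a class's seeds
#'
#' Maximum cosine similarity between the feature and any seed of the class
#' (nearest-prototype aggregation).
#'
#' @param feature Numeric vector of length d.
#' @param seeds Matrix `[k x d]` of seed vectors (k >= 1).
#' @return Scalar similarity in `[-1, 1]`.
#' @export
class_similarity <- function(feature, seeds) {
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0) stop_invalid("empty seed set")
  max(cosine_matrix(matrix(feature, 1), seeds))
}

#' Feature database for open-set recognition
#'
#' @param feature_dim Feature dimension d.
#' @param method Seed-selection method tag, `"center"` or `"cluster"`.
#' @return An empty `feature_db`.
#' @export
feature_db <- function(feature_dim, method = c("center", "cluster")) {
  method <- match.arg(method)
  structure(list(feature_dim = as.integer(feature_dim), method = method,
                 classes = list(), tau_new = NA_real_),
            class = "feature_db")
}

#' Build a feature database from labelled training features
#'
#' Selects seed features per class by the center method (center seed plus
#' random seeds) or the cluster method (k-means++ cluster centers), then
#' calibrates each class's acceptance threshold on a validation split.
#'
#' @param train_features Matrix `[N x d]` of features of training samples.
#' @param train_labels 0-based class labels.
#' @param val_features,val_labels Validation split used for threshold
#'   calibration (see [calibrate_class_threshold()]).
#' @param method `"center"` or `"cluster"`.
#' @param n_seeds Seeds per class: center method uses the center seed plus
#'   `n_seeds - 1` random seeds; cluster method uses `n_seeds` cluster centers.
#' @param rng_seed Integer seed.
#' @return A `feature_db` with one entry (`seeds`, `tau`) per training class.
#' @export
build_feature_db <- function(train_features, train_labels,
                             val_features, val_labels,
                             method = c("center", "cluster"),
                             n_seeds = 3L, rng_seed = 1L) {
  method <- match.arg(method)
  train_features <- as.matrix(train_features)
  db <- feature_db(ncol(train_features), method)
  for (cls in sort(unique(train_labels))) {
    feats <- train_features[train_labels == cls, , drop = FALSE]
    ns <- min(n_seeds, nrow(feats))
    seeds <- if (method == "center") {
      select_center_seeds(feats, n_random = ns - 1L,
                          rng_seed = rng_seed + cls)
    } else {
      select_cluster_seeds(feats, k = ns, rng_seed = rng_seed + cls)
    }
    db$classes[[as.character(cls)]] <- list(seeds = seeds, tau = NA_real_,
                                            predefined = TRUE)
  }
  for (cls in sort(unique(train_labels))) {
    db$classes[[as.character(cls)]]$tau <-
      calibrate_class_threshold(val_features, val_labels, cls, db)
  }
  db
}

#' Calibrate a class's acceptance threshold
#'
#' Scans candidate thresholds `0.1, 0.2, ..., 0.9`. For each candidate, a
#' validation sample is accepted as class `c` iff its [class_similarity()] to
#' the class's seeds is `>= tau`; the F1 of this binary accept-vs-rest
#' decision is computed and the `tau` with the highest F1 wins, ties broken
#' toward the largest `tau` (stricter acceptance favours novelty detection).
#'
#' @param val_features Matrix `[N x d]`.
#' @param val_labels 0-based labels; class `c` must be present.
#' @param c 0-based class id to calibrate.
#' @param db A `feature_db` containing seeds for class `c`.
#' @return The selected threshold `tau_c`.
#' @export
calibrate_class_threshold <- function(val_features, val_labels, c, db) {
  if (!any(val_labels == c))
    stop_invalid("class ", c, " absent from validation labels")
  seeds <- db$classes[[as.character(c)]]$seeds
  if (is.null(seeds)) stop_invalid("class ", c, " not in the database")
  sims <- apply(as.matrix(val_features), 1, class_similarity, seeds = seeds)
  is_pos <- val_labels == c
  grid <- seq(0.1, 0.9, by = 0.1)
  f1 <- vapply(grid, function(tau) {
    acc <- sims >= tau
    tp <- sum(acc & is_pos); fp <- sum(acc & !is_pos)
    fn <- sum(!acc & is_pos)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  # ties -> largest tau
  grid[max(which(f1 == max(f1)))]
}

#' New-activity threshold from enrollment samples
#'
#' The first quantile (25th percentile, linear interpolation) of the cosine
#' similarities over all unordered distinct pairs of the new activity's
#' features: a lower bound on how self-similar the new class is.
#'
#' @param new_features Matrix `[k x d]`, k >= 2.
#' @return Threshold `tau_new`.
#' @export
new_class_threshold <- function(new_features) {
  X <- as.matrix(new_features)
  k <- nrow(X)
  if (k < 2) stop_invalid("need >= 2 features to set the new-class threshold")
  S <- cosine_matrix(X, X)
  sims <- S[upper.tri(S)]
  unname(stats::quantile(sims, 0.25, type = 7))
}

#' Enroll a new activity into the database
#'
#' Selects seeds for the new class by the requested method, sets the
#' new-activity threshold from the enrollment samples' pairwise similarities,
#' and extends the database. Re-enrolling an existing class id replaces its
#' entry.
#'
#' @param db A trained `feature_db`.
#' @param new_features Matrix `[k x d]`, k >= 2, of enrollment features.
#' @param class_id 0-based id for the new class.
#' @param method `"center"` or `"cluster"` (default: the database's method).
#' @param n_seeds Seeds for the new class.
#' @param rng_seed Integer seed.
#' @return The extended `feature_db`.
#' @export
enroll_new_class <- function(db, new_features, class_id,
                             method = db$method, n_seeds = 3L,
                             rng_seed = 1L) {
  if (!method %in% c("center", "cluster"))
    stop_invalid("unknown seed-selection method: ", method)
  X <- as.matrix(new_features)
  if (nrow(X) < 2) stop_invalid("need >= 2 enrollment features")
  ns <- min(n_seeds, nrow(X))
  seeds <- if (method == "center") {
    select_center_seeds(X, n_random = ns - 1L, rng_seed = rng_seed)
  } else {
    select_cluster_seeds(X, k = ns, rng_seed = rng_seed)
  }
  db$tau_new <- new_class_threshold(X)
  db$classes[[as.character(class_id)]] <- list(seeds = seeds,
                                               tau = db$tau_new,
                                               predefined = FALSE)
  db
}

#' Open-set classification of one feature
#'
#' Finds the database class `c*` with the highest [class_similarity()] `v`
#' (ties to the lowest class id). If `c*` is a predefined (training-set)
#' class and `v` falls below that class's acceptance threshold `tau_c*` while
#' exceeding the new-activity threshold `tau_new`, the sample is labelled
#' `"NEW"`; otherwise the label is `c*`. The case `v <= tau_new` falls through
#' to `c*` and is flagged in the prediction record (`ambiguous = TRUE`), since
#' such a sample matches neither the known classes nor the new activity well.
#'
#' @param feature Numeric vector of length d.
#' @param db A `feature_db` with at least one class.
#' @return List of class `openset_prediction`: `label` (class id as integer,
#'   or the string `"NEW"`), `best_class`, `best_similarity`, `ambiguous`.
#' @export
openset_classify <- function(feature, db) {
  if (length(db$classes) == 0) stop_invalid("empty feature database")
  ids <- as.integer(names(db$classes))
  ord <- order(ids)
  sims <- vapply(db$classes[ord], function(e)
    class_similarity(feature, e$seeds), numeric(1))
  best <- which.max(sims)         # first max -> lowest class id
  v <- sims[best]
  entry <- db$classes[ord][[best]]
  cstar <- ids[ord][best]
  label <- cstar
  ambiguous <- FALSE
  if (isTRUE(entry$predefined) && !is.na(db$tau_new) &&
      v < entry$tau && v > db$tau_new) {
    label <- "NEW"
  } else if (isTRUE(entry$predefined) && !is.na(db$tau_new) &&
             v < entry$tau && v <= db$tau_new) {
    ambiguous <- TRUE
  }
  structure(list(label = label, best_class = cstar, best_similarity = v,
                 ambiguous = ambiguous),
            class = "openset_prediction")
}

#' Open-set classification of a feature matrix
#'
#' @param features Matrix `[N x d]`.
#' @param db A `feature_db`.
#' @return Character vector of length N: class ids as strings, or `"NEW"`.
#' @export
openset_classify_all <- function(features, db) {
  apply(as.matrix(features), 1, function(f)
    as.character(openset_classify(f, db)$label))
}
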