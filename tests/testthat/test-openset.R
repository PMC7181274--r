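test_that("center seed maximises mean similarity to the rest of the set", {
  feats <- rbind(c(1, 0), c(0, 1), c(0.7071, 0.7071))
  expect_equal(center_seed(feats), 3)
  expect_equal(center_seed(matrix(c(2, 5), 1)), 1)               # singleton
  expect_equal(center_seed(matrix(1, 4, 3)), 1)                  # tie -> first
  expect_error(center_seed(matrix(0, 0, 2)), "empty")

  # brute-force agreement on random sets
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:20, 1)
    X <- matrix(rnorm(k * 4), k, 4)
    S <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b)
      cosine_similarity(X[a, ], X[b, ])))
    mean_sim <- (rowSums(S) - diag(S)) / (k - 1)
    expect_equal(center_seed(X), which.max(mean_sim))
  }
})

test_that("center-method selection adds distinct random seeds", {
  set.seed(22)
  X <- matrix(rnorm(12 * 3), 12, 3)
  ci <- center_seed(X)
  expect_equal(select_center_seeds(X, 0), X[ci, , drop = FALSE])
  s1 <- select_center_seeds(X, 4, rng_seed = 5)
  s2 <- select_center_seeds(X, 4, rng_seed = 5)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 5)
  expect_false(any(duplicated(s1)))
  # exhaustion returns the whole set
  all_of <- select_center_seeds(X, nrow(X) - 1, rng_seed = 1)
  expect_equal(nrow(all_of), nrow(X))
  expect_error(select_center_seeds(X, 12), "n_random")
})

test_that("cluster seeds are k-means++ / Lloyd centers of normalized points", {
  # two tight, well-separated groups
  set.seed(23)
  g1 <- matrix(rep(c(5, 0.2), each = 6), 6) + matrix(rnorm(12, sd = 0.01), 6)
  g2 <- matrix(rep(c(-0.2, 3), each = 6), 6) + matrix(rnorm(12, sd = 0.01), 6)
  X <- rbind(g1, g2)
  Xn <- X / sqrt(rowSums(X^2))
  centers <- select_cluster_seeds(X, 2, rng_seed = 1)
  expected <- rbind(colMeans(Xn[1:6, ]), colMeans(Xn[7:12, ]))
  # match centers to expected group means irrespective of order
  d <- as.matrix(dist(rbind(centers, expected)))[1:2, 3:4]
  expect_lt(min(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1]), 1e-3)

  # k = 1 is the mean of normalized points
  expect_equal(as.vector(select_cluster_seeds(X, 1, rng_seed = 2)),
               colMeans(Xn), tolerance = 1e-9)

  # k = set size returns the normalized points themselves (up to order)
  small <- matrix(rnorm(8), 4, 2)
  cs <- select_cluster_seeds(small, 4, rng_seed = 3)
  sn <- small / sqrt(rowSums(small^2))
  expect_equal(cs[order(cs[, 1]), ], sn[order(sn[, 1]), ], tolerance = 1e-9)

  expect_error(select_cluster_seeds(X, 0, rng_seed = 1), "k must")
  expect_error(select_cluster_seeds(X, 13, rng_seed = 1), "k must")
  expect_identical(select_cluster_seeds(X, 3, rng_seed = 4),
                   select_cluster_seeds(X, 3, rng_seed = 4))
})

test_that("cluster seeds agree with stats::kmeans as an independent check", {
  set.seed(24)
  X <- rbind(matrix(rnorm(20, mean = 3, sd = 0.1), 10, 2),
             matrix(rnorm(20, mean = -3, sd = 0.1), 10, 2))
  Xn <- X / sqrt(rowSums(X^2))
  ours <- select_cluster_seeds(X, 2, rng_seed = 1)
  km <- stats::kmeans(Xn, centers = ours, iter.max = 100,
                      algorithm = "Lloyd")
  expect_equal(km$centers[order(km$centers[, 1]), ],
               ours[order(ours[, 1]), ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("class similarity is the max cosine over seeds", {
  seeds <- rbind(c(1, 0), c(0, 1))
  expect_equal(class_similarity(c(1, 0), seeds), 1)
  expect_equal(class_similarity(c(-1, 0) + c(0, 0), rbind(c(0, 1))), 0)
  expect_equal(class_similarity(c(0.6, 0.8), seeds), 0.8)
  expect_error(class_similarity(c(1, 0), matrix(0, 0, 2)), "empty")
})

test_that("threshold calibration scans the 0.1..0.9 grid, ties to largest", {
  db <- feature_db(2, "center")
  db$classes[["0"]] <- list(seeds = matrix(c(1, 0), 1), tau = NA,
                            predefined = TRUE)
  # positives at cos 0.95 and 0.90, negatives at 0.2 and 0.1
  ang <- function(s) c(s, sqrt(1 - s^2))
  vf <- rbind(ang(0.95), ang(0.90), ang(0.2), ang(0.1))
  vl <- c(0, 0, 1, 1)
  expect_equal(calibrate_class_threshold(vf, vl, 0, db), 0.9)

  # single positive at 0.55 and no negatives: all accepting taus give F1=1
  expect_equal(calibrate_class_threshold(matrix(ang(0.55), 1), 0, 0, db), 0.5)

  # positives all below every negative: still the grid argmax, per the oracle
  vf2 <- rbind(ang(0.15), ang(0.85), ang(0.9))
  vl2 <- c(0, 1, 1)
  sims2 <- apply(vf2, 1, class_similarity, seeds = db$classes[["0"]]$seeds)
  expect_equal(calibrate_class_threshold(vf2, vl2, 0, db),
               oracle_threshold(sims2, vl2 == 0))

  expect_error(calibrate_class_threshold(vf, c(1, 1, 1, 1), 0, db), "absent")

  # random sets match the exhaustive grid oracle
  set.seed(25)
  for (i in 1:20) {
    vf3 <- matrix(rnorm(30), 15, 2)
    vl3 <- sample(0:1, 15, replace = TRUE)
    if (!any(vl3 == 0)) vl3[1] <- 0
    sims3 <- apply(vf3, 1, class_similarity, seeds = db$classes[["0"]]$seeds)
    expect_equal(calibrate_class_threshold(vf3, vl3, 0, db),
                 oracle_threshold(sims3, vl3 == 0))
  }
})

test_that("new-class threshold is the first quartile of pairwise cosines", {
  expect_equal(new_class_threshold(matrix(1, 3, 2)), 1)
  # two features at a 60-degree angle: single pair, similarity 0.5
  two <- rbind(c(1, 0), c(cos(pi / 3), sin(pi / 3)))
  expect_equal(new_class_threshold(two), 0.5, tolerance = 1e-12)
  expect_error(new_class_threshold(matrix(1, 1, 2)), ">= 2")

  # interpolated-quantile oracle on random sets
  set.seed(26)
  for (i in 1:10) {
    X <- matrix(rnorm(24), 8, 3)
    sims <- c()
    for (a in 1:7) for (b in (a + 1):8)
      sims <- c(sims, cosine_similarity(X[a, ], X[b, ]))
    expect_equal(new_class_threshold(X),
                 unname(stats::quantile(sims, 0.25, type = 7)),
                 tolerance = 1e-12)
  }
})

test_that("enrollment extends the database and is idempotent per class id", {
  set.seed(27)
  train <- rbind(matrix(rnorm(20, 5), 10, 2), matrix(rnorm(20, -5), 10, 2))
  labs <- rep(0:1, each = 10)
  db <- build_feature_db(train, labs, train, labs, method = "center",
                         n_seeds = 2)
  expect_equal(length(db$classes), 2)

  newf <- matrix(rnorm(16, c(8, -8)), 8, 2)
  db2 <- enroll_new_class(db, newf, class_id = 2, n_seeds = 2, rng_seed = 1)
  expect_equal(length(db2$classes), 3)
  expect_false(is.na(db2$tau_new))
  # an enrolled feature classifies as the new class
  pred <- openset_classify(db2$classes[["2"]]$seeds[1, ], db2)
  expect_equal(pred$label, 2)
  # re-enrolling the same id replaces, not grows
  db3 <- enroll_new_class(db2, newf, class_id = 2, n_seeds = 2, rng_seed = 2)
  expect_equal(length(db3$classes), 3)
  expect_error(enroll_new_class(db, newf, 2, method = "bogus"), "method")
})

test_that("the two-branch decision rule follows the stated thresholds", {
  db <- feature_db(2, "center")
  db$classes[["0"]] <- list(seeds = matrix(c(1, 0), 1), tau = 0.7,
                            predefined = TRUE)
  db$tau_new <- 0.4
  ang <- function(s) c(s, sqrt(1 - s^2))

  # below tau_c, above tau_new -> NEW
  p1 <- openset_classify(ang(0.55), db)
  expect_equal(p1$label, "NEW")
  expect_equal(p1$best_class, 0)
  # above tau_c -> the class
  expect_equal(openset_classify(ang(0.9), db)$label, 0)
  # below both -> the otherwise-branch returns the class, flagged ambiguous
  p3 <- openset_classify(ang(0.3), db)
  expect_equal(p3$label, 0)
  expect_true(p3$ambiguous)
  expect_error(openset_classify(c(1, 0), feature_db(2)), "empty")
})

test_that("with zero thresholds and no new class the rule is nearest-seed", {
  set.seed(28)
  db <- feature_db(3, "center")
  for (cl in 0:3) {
    db$classes[[as.character(cl)]] <- list(seeds = matrix(rnorm(6), 2, 3),
                                           tau = 0, predefined = TRUE)
  }
  X <- matrix(rnorm(30), 10, 3)
  pred <- openset_classify_all(X, db)
  nearest <- apply(X, 1, function(f) {
    sims <- vapply(0:3, function(cl)
      class_similarity(f, db$classes[[as.character(cl)]]$seeds), numeric(1))
    as.character(which.max(sims) - 1L)
  })
  expect_equal(pred, nearest)
})
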