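test_that("architectures build with consistent shapes across grids", {
  # window-length grid x channel counts, all four bodies, scaled-down sizes
  for (T in c(32, 64, 96)) for (C in c(1, 9, 107)) {
    for (kind in c("mlp", "cnn", "lstm", "hybrid")) {
      cfg <- quick_net(kind)
      model <- build_network(cfg, c(T, C), 4, rng_seed = 1)
      X <- array(rnorm(2 * T * C), c(2, T, C))
      ws <- marginhar:::new_window_set(X, c(0L, 1L), NA_integer_, 30,
                                       sprintf("ch%d", seq_len(C)))
      p <- predict(model, ws)
      expect_equal(dim(p$scores), c(2, 4))
      f <- extract_features(model, ws)
      expect_equal(dim(f), c(2, model$feature_dim))
    }
  }
})

test_that("default MLP exposes a 2000-wide feature layer", {
  model <- build_network(network_config("mlp"), c(64, 9), 17)
  expect_equal(model$feature_dim, 2000)
})

test_that("default CNN block stack leaves a positive time extent at T = 64", {
  # symbolic shape oracle: 64 -conv11-> 54 -pool2-> 27 -conv10-> 18 -pool3->
  # 6 -conv6-> 1 -pool1-> 1
  t_len <- 64
  for (b in list(c(11, 1, 50, 2), c(10, 1, 40, 3), c(6, 1, 30, 1))) {
    t_len <- (t_len - b[1]) %/% b[2] + 1
    t_len <- t_len %/% max(1, b[4])
  }
  expect_equal(t_len, 1)
  model <- build_network(network_config("cnn"), c(64, 9), 17)
  expect_true(inherits(model, "marginhar_model"))
  # but a too-short window is rejected
  expect_error(build_network(network_config("cnn"), c(8, 9), 17),
               "kernel|time axis")
})

test_that("feature width can be overridden to 2", {
  cfg <- network_config("cnn", "arcmargin",
                        cnn_blocks = list(c(5, 1, 8, 2), c(3, 1, 8, 2)),
                        cnn_fc_size = 2)
  model <- build_network(cfg, c(16, 2), 3)
  X <- array(rnorm(3 * 16 * 2), c(3, 16, 2))
  ws <- marginhar:::new_window_set(X, c(0L, 1L, 2L), NA_integer_, 30,
                                   c("a", "b"))
  expect_equal(ncol(extract_features(model, ws)), 2)
})

test_that("training separates two synthetic classes and is deterministic", {
  cfg <- quick_syn(n_classes = 2, n_per_class = 40)
  ws <- generate_windows(cfg)
  tc <- train_config(epochs = 10, batch_size = 20, rng_seed = 3)
  model <- build_network(quick_net("mlp"), c(16, 2), 2)
  trained <- train_network(model, ws, tc)
  expect_length(trained$loss_history, 10)
  expect_lt(trained$loss_history[10], trained$loss_history[1])
  p <- predict(trained, ws)
  expect_gte(mean(p$labels == ws$labels), 0.95)
  # bitwise-deterministic given the seed
  trained2 <- train_network(model, ws, tc)
  expect_identical(trained$loss_history, trained2$loss_history)
  expect_identical(predict(trained2, ws)$labels, p$labels)

  empty <- marginhar:::new_window_set(array(0, c(0, 16, 2)), integer(0),
                                      NA_integer_, 30, c("a", "b"))
  expect_error(train_network(model, empty, tc), "empty")
  onecls <- marginhar:::new_window_set(ws$data[1:5, , , drop = FALSE],
                                       rep(0L, 5), NA_integer_, 30,
                                       c("a", "b"))
  expect_error(train_network(model, onecls, tc), "2 classes")
})

test_that("prediction returns proper probabilities and stable ties", {
  cfg <- quick_syn()
  ws <- generate_windows(cfg)
  model <- train_network(build_network(quick_net("cnn"), c(16, 2), 3), ws,
                         train_config(epochs = 6, batch_size = 32,
                                      rng_seed = 4))
  p <- predict(model, ws)
  expect_equal(rowSums(p$scores), rep(1, nrow(p$scores)), tolerance = 1e-6)
  # duplicate inputs get identical predictions
  dup <- marginhar:::new_window_set(ws$data[c(1, 1), , , drop = FALSE],
                                    ws$labels[c(1, 1)], NA_integer_, 30,
                                    ws$channel_names)
  pd <- predict(model, dup)
  expect_identical(pd$labels[1], pd$labels[2])
  expect_equal(pd$scores[1, ], pd$scores[2, ])
  # wrong shape is rejected
  bad <- marginhar:::new_window_set(array(0, c(2, 8, 2)), c(0L, 1L),
                                    NA_integer_, 30, c("a", "b"))
  expect_error(predict(model, bad), "shape")
})

test_that("MLP features are post-ReLU, embedding features unconstrained", {
  cfg <- quick_syn()
  ws <- generate_windows(cfg)
  tc <- train_config(epochs = 4, batch_size = 32, rng_seed = 5)
  mlp <- train_network(build_network(quick_net("mlp"), c(16, 2), 3), ws, tc)
  expect_true(all(extract_features(mlp, ws) >= 0))
  cnn <- train_network(build_network(quick_net("cnn"), c(16, 2), 3), ws, tc)
  f <- extract_features(cnn, ws)
  expect_equal(ncol(f), 16)
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  for (spec in list(c("mlp", "arcmargin"), c("cnn", "softmax"),
                    c("lstm", "arcmargin"), c("hybrid", "softmax"))) {
    cfg <- switch(spec[1],
      mlp = network_config("mlp", spec[2], mlp_fc_sizes = c(5, 4, 4)),
      cnn = network_config("cnn", spec[2], cnn_blocks = list(c(3, 1, 3, 2)),
                           cnn_fc_size = 5),
      lstm = network_config("lstm", spec[2], lstm_hidden = 4, lstm_fc_size = 5),
      hybrid = network_config("hybrid", spec[2], hybrid_block = c(3, 1, 3, 2),
                              hybrid_lstm_hidden = 4, hybrid_fc_size = 5))
    m <- build_network(cfg, c(8, 2), 3, rng_seed = 7)
    X <- array(rnorm(4 * 8 * 2), c(4, 8, 2)); y <- c(0L, 1L, 2L, 1L)
    loss_at <- function(mm) {
      fw <- marginhar:::body_forward(mm, X, train = TRUE)
      marginhar:::head_loss(mm$head, fw$out, y)$loss
    }
    fw <- marginhar:::body_forward(m, X, train = TRUE)
    hl <- marginhar:::head_loss(m$head, fw$out, y)
    grads <- marginhar:::body_backward(m, fw$caches, hl$dF)
    eps <- 1e-5
    for (i in seq_along(m$layers)) {
      for (nm in names(grads[[i]])) {
        p <- m$layers[[i]]$params[[nm]]
        for (j in sample(length(p), min(3, length(p)))) {
          m2 <- m; m2$layers[[i]]$params[[nm]][j] <- p[j] + eps
          m3 <- m; m3$layers[[i]]$params[[nm]][j] <- p[j] - eps
          num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
          expect_equal(grads[[i]][[nm]][j], num, tolerance = 1e-3)
        }
      }
    }
  }
})

test_that("saved models reload and predict identically", {
  cfg <- quick_syn()
  ws <- generate_windows(cfg)
  model <- train_network(build_network(quick_net("lstm"), c(16, 2), 3), ws,
                         train_config(epochs = 3, batch_size = 32,
                                      rng_seed = 6))
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  reloaded <- load_model(path)
  expect_equal(predict(reloaded, ws), predict(model, ws))
})
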