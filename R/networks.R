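#' Network architecture configuration
#'
#' Describes one of the four reference architectures. Defaults follow the
#' standard settings for body-worn-sensor windows: an MLP with three
#' 2000-unit dense layers; a CNN with three temporal convolution blocks
#' (kernel, stride, kernels, pool) = (11,1,50,2), (10,1,40,3), (6,1,30,1) and
#' a 1000-unit dense layer; a 2-layer LSTM with 600 hidden units (one cell per
#' window sample) and a 512-unit dense layer; and a hybrid with one (11,1,50,2)
#' convolution block feeding a 2-layer LSTM (600 hidden) and a 512-unit dense
#' layer. Every model starts with an input batch-normalisation layer; dense
#' layers are followed by ReLU; convolution blocks are conv + ReLU + max-pool.
#' The head is either a plain fully-connected softmax layer or an arcmargin
#' layer (normalized cosine logits, bias 0, scale `s`, additive angular
#' margin `m` applied to the true class during training only).
#'
#' The "feature layer" — whose post-activation output feeds the open-set
#' feature database — is the first dense layer for the MLP and the dense layer
#' immediately preceding the head for the CNN/LSTM/hybrid models.
#'
#' @param kind One of `"mlp"`, `"cnn"`, `"lstm"`, `"hybrid"`.
#' @param head `"softmax"` or `"arcmargin"`.
#' @param mlp_fc_sizes Integer vector of MLP dense-layer widths.
#' @param cnn_blocks List of `c(kernel, stride, n_kernels, pool)` per block.
#' @param cnn_fc_size CNN dense-layer width.
#' @param lstm_hidden,lstm_layers,lstm_fc_size LSTM settings.
#' @param hybrid_block,hybrid_lstm_hidden,hybrid_lstm_layers,hybrid_fc_size
#'   Hybrid settings.
#' @param scale Arcmargin rescale factor s (default 30).
#' @param margin Additive angular margin m in radians (default 0.3).
#' @return Object of class `network_config`.
#' @export
network_config <- function(kind = c("mlp", "cnn", "lstm", "hybrid"),
                           head = c("softmax", "arcmargin"),
                           mlp_fc_sizes = c(2000, 2000, 2000),
                           cnn_blocks = list(c(11, 1, 50, 2),
                                             c(10, 1, 40, 3),
                                             c(6, 1, 30, 1)),
                           cnn_fc_size = 1000,
                           lstm_hidden = 600, lstm_layers = 2,
                           lstm_fc_size = 512,
                           hybrid_block = c(11, 1, 50, 2),
                           hybrid_lstm_hidden = 600, hybrid_lstm_layers = 2,
                           hybrid_fc_size = 512,
                           scale = 30, margin = 0.3) {
  kind <- match.arg(kind)
  head <- match.arg(head)
  sizes <- c(mlp_fc_sizes, cnn_fc_size, lstm_hidden, lstm_fc_size,
             hybrid_lstm_hidden, hybrid_fc_size,
             unlist(cnn_blocks), hybrid_block)
  if (any(sizes <= 0)) stop_invalid("all layer sizes must be positive")
  if (scale <= 0) stop_invalid("scale s must be positive")
  if (margin < 0 || margin >= pi) stop_invalid("margin m must be in [0, pi)")
  structure(list(kind = kind, head = head, mlp_fc_sizes = mlp_fc_sizes,
                 cnn_blocks = cnn_blocks, cnn_fc_size = cnn_fc_size,
                 lstm_hidden = lstm_hidden, lstm_layers = lstm_layers,
                 lstm_fc_size = lstm_fc_size, hybrid_block = hybrid_block,
                 hybrid_lstm_hidden = hybrid_lstm_hidden,
                 hybrid_lstm_layers = hybrid_lstm_layers,
                 hybrid_fc_size = hybrid_fc_size,
                 scale = scale, margin = margin),
            class = "network_config")
}

#' Training configuration
#'
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size B (default 100; the last partial batch is
#'   trained on).
#' @param rng_seed Seed for the orthogonal initialisation and epoch shuffles;
#'   training is deterministic given the seed.
#' @param shuffle Shuffle sample order each epoch.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 100, rng_seed = 1L,
                         shuffle = TRUE) {
  if (epochs < 1 || batch_size < 1)
    stop_invalid("epochs and batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed), shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Build a network
#'
#' Assembles the layer graph for a window shape `(T, C)`: input batch norm,
#' the architecture body, and the classification head. Parameters are
#' orthogonally initialised from `rng_seed` ([train_network()] re-initialises
#' with the training seed).
#'
#' @param cfg A [network_config()].
#' @param window_shape `c(T, C)`: samples per window and channels.
#' @param n_classes Number of classes.
#' @param rng_seed Seed for the initial parameter draw.
#' @return Object of class `marginhar_model`.
#' @export
build_network <- function(cfg, window_shape, n_classes, rng_seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  T <- as.integer(window_shape[1]); C <- as.integer(window_shape[2])
  if (T < 1 || C < 1) stop_invalid("window_shape must be positive")
  layers <- list(layer_bn(C))
  feature_index <- NA_integer_

  add_conv_block <- function(layers, t_len, c_in, block) {
    k <- block[1]; stride <- block[2]; nk <- block[3]; p <- block[4]
    if (k > t_len)
      stop_invalid("convolution kernel ", k, " exceeds time extent ", t_len)
    layers <- c(layers, list(layer_conv(c_in, k, stride, nk), layer_relu()))
    t_len <- conv_out_len(t_len, k, stride)
    if (p > 1) {
      if (pool_out_len(t_len, p) < 1)
        stop_invalid("pooling collapses the time axis below 1")
      layers <- c(layers, list(layer_pool(p)))
      t_len <- pool_out_len(t_len, p)
    }
    list(layers = layers, t_len = t_len, c_out = nk)
  }

  if (cfg$kind == "mlp") {
    layers <- c(layers, list(layer_flatten()))
    d <- T * C
    for (i in seq_along(cfg$mlp_fc_sizes)) {
      layers <- c(layers, list(layer_fc(d, cfg$mlp_fc_sizes[i]), layer_relu()))
      d <- cfg$mlp_fc_sizes[i]
      if (i == 1) feature_index <- length(layers)  # post-activation of FC 1
    }
    feature_dim <- cfg$mlp_fc_sizes[1]
    head_dim <- d
  } else if (cfg$kind == "cnn") {
    t_len <- T; c_in <- C
    for (block in cfg$cnn_blocks) {
      r <- add_conv_block(layers, t_len, c_in, block)
      layers <- r$layers; t_len <- r$t_len; c_in <- r$c_out
    }
    # the embedding FC before the head is linear (no ReLU): an activation
    # there would confine features to the non-negative orthant and cap the
    # achievable angular separation between classes
    layers <- c(layers, list(layer_flatten(),
                             layer_fc(t_len * c_in, cfg$cnn_fc_size)))
    feature_index <- length(layers)
    feature_dim <- head_dim <- cfg$cnn_fc_size
  } else if (cfg$kind == "lstm") {
    d_in <- C
    for (i in seq_len(cfg$lstm_layers)) {
      layers <- c(layers, list(layer_lstm(d_in, cfg$lstm_hidden)))
      d_in <- cfg$lstm_hidden
    }
    layers <- c(layers, list(layer_last_step(),
                             layer_fc(d_in, cfg$lstm_fc_size)))
    feature_index <- length(layers)
    feature_dim <- head_dim <- cfg$lstm_fc_size
  } else { # hybrid
    r <- add_conv_block(layers, T, C, cfg$hybrid_block)
    layers <- r$layers
    # conv output sliced along time: each slice (the filter responses at one
    # time step, in filter order) is one LSTM input vector
    d_in <- r$c_out
    for (i in seq_len(cfg$hybrid_lstm_layers)) {
      layers <- c(layers, list(layer_lstm(d_in, cfg$hybrid_lstm_hidden)))
      d_in <- cfg$hybrid_lstm_hidden
    }
    layers <- c(layers, list(layer_last_step(),
                             layer_fc(d_in, cfg$hybrid_fc_size)))
    feature_index <- length(layers)
    feature_dim <- head_dim <- cfg$hybrid_fc_size
  }

  head <- if (cfg$head == "softmax") {
    list(kind = "softmax",
         params = list(W = matrix(0, head_dim, n_classes), b = rep(0, n_classes)))
  } else {
    list(kind = "arcmargin", s = cfg$scale, m = cfg$margin,
         params = list(W = matrix(0, n_classes, head_dim)))
  }

  model <- structure(list(cfg = cfg, layers = layers, head = head,
                          feature_index = feature_index,
                          feature_dim = feature_dim,
                          n_classes = as.integer(n_classes),
                          input_shape = c(T = T, C = C),
                          loss_history = numeric(0), trained = FALSE),
                     class = "marginhar_model")
  with_seed(rng_seed, init_model_params(model))
}

init_model_params <- function(model) {
  model$layers <- lapply(model$layers, init_layer_params)
  dmn <- dim(model$head$params$W)
  model$head$params$W <- orthogonal_matrix(dmn[1], dmn[2])
  if (!is.null(model$head$params$b)) model$head$params$b[] <- 0
  model
}

# forward through the body; returns feature-layer output, final body output,
# caches, and the model (updated BN running stats)
body_forward <- function(model, X, train) {
  caches <- vector("list", length(model$layers))
  out <- X
  features <- NULL
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], out, train)
    out <- r$out
    caches[[i]] <- r$cache
    model$layers[[i]] <- r$layer
    if (i == model$feature_index) features <- out
  }
  list(out = out, features = features, caches = caches, model = model)
}

body_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[i]], caches[[i]], dout)
    grads[[i]] <- r$grads
    dout <- r$dX
  }
  grads
}

# head loss + gradients wrt head input and head params; labels 0-based
head_loss <- function(head, F, labels) {
  B <- nrow(F)
  n <- if (head$kind == "softmax") ncol(head$params$W) else nrow(head$params$W)
  Y <- matrix(0, B, n)
  Y[cbind(seq_len(B), labels + 1L)] <- 1
  if (head$kind == "softmax") {
    logits <- sweep(F %*% head$params$W, 2, head$params$b, "+")
    loss <- plain_softmax_loss(logits, labels)
    P <- softmax_rows(logits)
    dlogits <- (P - Y) / B
    list(loss = loss,
         dF = dlogits %*% t(head$params$W),
         grads = list(W = t(F) %*% dlogits, b = colSums(dlogits)))
  } else {
    nf <- pmax(sqrt(rowSums(F^2)), 1e-12)
    nw <- pmax(sqrt(rowSums(head$params$W^2)), 1e-12)
    Fn <- F / nf
    Wn <- head$params$W / nw
    cos_ <- Fn %*% t(Wn)
    cos_[cos_ > 1] <- 1
    cos_[cos_ < -1] <- -1
    idx <- cbind(seq_len(B), labels + 1L)
    ct <- cos_[idx]
    cos_m <- cos_
    cos_m[idx] <- apply_additive_angular_margin(ct, head$m)
    logits <- head$s * cos_m
    loss <- plain_softmax_loss(logits, labels)
    P <- softmax_rows(logits)
    dcos <- head$s * (P - Y) / B
    # chain through the margin on the true-class entries
    sin_t <- pmax(sqrt(pmax(0, 1 - ct^2)), 1e-6)
    dmargin <- ifelse(ct < cos(pi - head$m), 1,
                      cos(head$m) + ct / sin_t * sin(head$m))
    dcos[idx] <- dcos[idx] * dmargin
    # gradients through the row normalisations
    dF <- (dcos %*% Wn - rowSums(dcos * cos_) * Fn) / nf
    dW <- (t(dcos) %*% Fn - colSums(dcos * cos_) * Wn) / nw
    list(loss = loss, dF = dF, grads = list(W = dW))
  }
}

softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

#' Train a network
#'
#' Orthogonally (re-)initialises all parameters from the training seed and
#' runs minibatch gradient descent with the ADADELTA optimiser (rho 0.9,
#' eps 1e-6, initial step 1) on the head's loss: softmax cross-entropy, or the
#' additive angular margin loss for arcmargin heads. The last partial
#' minibatch is trained on. Deterministic given the seed.
#'
#' @param model A [build_network()] model.
#' @param ws A `window_set` with labels covering at least 2 classes.
#' @param tc A [train_config()].
#' @return The trained model, with `loss_history` (per-epoch mean loss).
#' @export
train_network <- function(model, ws, tc = train_config()) {
  stopifnot(inherits(model, "marginhar_model"), inherits(ws, "window_set"))
  N <- dim(ws$data)[1]
  if (N == 0) stop_invalid("empty window set")
  if (length(unique(ws$labels)) < 2)
    stop_invalid("training labels must cover at least 2 classes")
  if (any(ws$labels < 0 | ws$labels >= model$n_classes))
    stop_invalid("labels out of range for the model's class count")

  with_seed(tc$rng_seed, {
    model <- init_model_params(model)
    opt_layers <- lapply(model$layers, function(l) adadelta_init(l$params))
    opt_head <- adadelta_init(model$head$params)
    loss_hist <- numeric(tc$epochs)

    for (ep in seq_len(tc$epochs)) {
      ord <- if (tc$shuffle) sample.int(N) else seq_len(N)
      ep_loss <- 0
      n_seen <- 0
      for (b0 in seq(1, N, by = tc$batch_size)) {
        idx <- ord[b0:min(b0 + tc$batch_size - 1, N)]
        X <- ws$data[idx, , , drop = FALSE]
        y <- ws$labels[idx]
        fw <- body_forward(model, X, train = TRUE)
        model <- fw$model
        hl <- head_loss(model$head, fw$out, y)
        ep_loss <- ep_loss + hl$loss * length(idx)
        n_seen <- n_seen + length(idx)
        grads <- body_backward(model, fw$caches, hl$dF)
        for (i in seq_along(model$layers)) {
          if (length(grads[[i]]) == 0) next
          up <- adadelta_update(model$layers[[i]]$params, grads[[i]],
                                opt_layers[[i]])
          model$layers[[i]]$params <- up$params
          opt_layers[[i]] <- up$state
        }
        up <- adadelta_update(model$head$params, hl$grads, opt_head)
        model$head$params <- up$params
        opt_head <- up$state
      }
      loss_hist[ep] <- ep_loss / n_seen
    }
    model$loss_history <- loss_hist
    model$trained <- TRUE
    model
  })
}

#' Predict classes and per-class scores
#'
#' Softmax heads return softmax probabilities of the dense logits; arcmargin
#' heads return the softmax over `s * cos(theta_j)` — the margin is a training
#' device only and is not applied at inference. Labels are the argmax, ties
#' broken toward the lowest class index.
#'
#' @param object A trained `marginhar_model`.
#' @param ws A `window_set`.
#' @param ... Unused.
#' @return List with `labels` (0-based) and `scores` (`[N x n]`, rows sum
#'   to 1).
#' @export
predict.marginhar_model <- function(object, ws, ...) {
  stopifnot(inherits(ws, "window_set"))
  if (!identical(unname(dim(ws$data)[2:3]), unname(as.integer(object$input_shape))))
    stop_invalid("window shape does not match the model's input shape")
  fw <- body_forward(object, ws$data, train = FALSE)
  scores <- if (object$head$kind == "softmax") {
    softmax_rows(sweep(fw$out %*% object$head$params$W, 2,
                       object$head$params$b, "+"))
  } else {
    softmax_rows(object$head$s * cosine_matrix(fw$out, object$head$params$W))
  }
  list(labels = max.col(scores, ties.method = "first") - 1L, scores = scores)
}

#' Extract feature-layer outputs
#'
#' Returns the outputs of the designated feature layer: the post-ReLU first
#' dense layer for the MLP (whose output feeds further hidden layers), or the
#' linear embedding layer immediately before the head for the CNN/LSTM/hybrid
#' models. The head — including any arcmargin layer — is bypassed.
#'
#' @param model A `marginhar_model`.
#' @param ws A `window_set`.
#' @return Matrix `[N x feature_dim]`.
#' @export
extract_features <- function(model, ws) {
  stopifnot(inherits(model, "marginhar_model"), inherits(ws, "window_set"))
  fw <- body_forward(model, ws$data, train = FALSE)
  fw$features
}

#' Class-weight directions of the head
#'
#' Rows are the per-class weight vectors of the final classification layer
#' (softmax: transposed dense weights; arcmargin: the cosine-head weight
#' rows), row-normalized — the class "directions" on the unit hypersphere.
#'
#' @param model A `marginhar_model`.
#' @return Matrix `[n_classes x head_dim]` with unit-norm rows.
#' @export
head_class_directions <- function(model) {
  W <- if (model$head$kind == "softmax") t(model$head$params$W)
       else model$head$params$W
  normalize_rows_quiet(W)
}

#' @export
print.marginhar_model <- function(x, ...) {
  cat(sprintf("<marginhar_model> %s + %s head, input %dx%d, %d classes, %s\n",
              x$cfg$kind, x$head$kind, x$input_shape[1], x$input_shape[2],
              x$n_classes,
              if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                                     length(x$loss_history),
                                     utils::tail(x$loss_history, 1))
              else "untrained"))
  invisible(x)
}
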