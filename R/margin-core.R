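#' Margin head configuration
#'
#' Holds the parameters of the normalized-cosine classification head: the
#' class-weight matrix `W` (one unit-norm row per class), the rescaling factor
#' `s` applied after feature/weight normalisation, and the additive angular
#' margin `m` (radians) added to the true-class angle during training. The
#' bias is fixed at 0.
#'
#' @param feature_dim Feature dimension d.
#' @param n_classes Number of classes n.
#' @param scale Rescale factor s > 0 (default 30, the convention of cosine
#'   margin heads; the head's logits are `s * cos(theta)`).
#' @param margin Additive angular margin m in radians, `0 <= m < pi`
#'   (default 0.3).
#' @param class_weights Optional `[n x d]` matrix; rows are normalized to unit
#'   norm. Defaults to a seeded random orthonormal set.
#' @param rng_seed Seed for the default weight draw.
#' @return An object of class `margin_head_config`.
#' @export
margin_head_config <- function(feature_dim, n_classes, scale = 30,
                               margin = 0.3, class_weights = NULL,
                               rng_seed = 1L) {
  if (scale <= 0) stop_invalid("scale s must be positive")
  if (margin < 0 || margin >= pi) stop_invalid("margin m must be in [0, pi)")
  if (is.null(class_weights)) {
    class_weights <- with_seed(rng_seed,
                               orthogonal_matrix(n_classes, feature_dim))
  }
  class_weights <- matrix(class_weights, n_classes, feature_dim)
  class_weights <- normalize_rows_quiet(class_weights)
  structure(list(feature_dim = as.integer(feature_dim),
                 n_classes = as.integer(n_classes),
                 scale = scale, margin = margin,
                 class_weights = class_weights, bias = 0),
            class = "margin_head_config")
}

#' Cosine logits between features and class weights
#'
#' Row-normalizes the features and the class-weight matrix and returns their
#' inner products, i.e. `cos(theta_j)` for every sample/class pair, clamped to
#' `[-1, 1]` against floating-point drift. The cosines are invariant to
#' positive rescaling of the input features.
#'
#' @param features Numeric matrix `[B x d]`.
#' @param cfg A [margin_head_config()] with matching `feature_dim`.
#' @return Matrix `[B x n]` of cosines.
#' @export
cosine_logits <- function(features, cfg) {
  features <- as.matrix(features)
  if (ncol(features) != cfg$feature_dim)
    stop_invalid("feature dimension mismatch: got ", ncol(features),
                 ", head expects ", cfg$feature_dim)
  cosine_matrix(features, cfg$class_weights)
}

#' Additive angular margin on a cosine
#'
#' Computes `cos(theta + m)` from `cos(theta)` via the identity
#' `cos(theta)cos(m) - sin(theta)sin(m)` with `sin(theta) =
#' sqrt(1 - cos(theta)^2)`. When `theta + m` would exceed `pi` (i.e.
#' `cos(theta) < cos(pi - m)`), the linear fallback `cos(theta) - m sin(m)` is
#' used instead, which keeps the penalty monotone in `theta` where the cosine
#' would otherwise fold back.
#'
#' @param cos_t Cosine(s) of the target angle, in `[-1, 1]`.
#' @param m Margin in radians, `0 <= m < pi`.
#' @return `cos(theta + m)` (vectorised).
#' @export
apply_additive_angular_margin <- function(cos_t, m) {
  if (m < 0 || m >= pi) stop_invalid("margin m must be in [0, pi)")
  if (any(abs(cos_t) > 1 + 1e-6)) stop_invalid("|cos_t| must be <= 1")
  cos_t <- pmin(1, pmax(-1, cos_t))
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  out <- cos_t * cos(m) - sin_t * sin(m)
  fold <- cos_t < cos(pi - m)
  out[fold] <- cos_t[fold] - m * sin(m)
  out
}

#' Softmax cross-entropy loss
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class, computed with log-sum-exp stabilisation.
#'
#' @param logits Numeric matrix `[B x n]`.
#' @param labels 0-based integer vector of true classes, length B.
#' @return Non-negative scalar loss.
#' @export
plain_softmax_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  B <- nrow(logits)
  if (B == 0) stop_invalid("empty batch")
  if (length(labels) != B) stop_invalid("labels length must equal batch size")
  if (any(labels < 0 | labels >= ncol(logits)))
    stop_invalid("labels out of range [0, n)")
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  true_logit <- logits[cbind(seq_len(B), labels + 1L)]
  mean(lse - true_logit)
}

#' Normalized (rescaled cosine) softmax loss
#'
#' Softmax cross-entropy over `s * cos(theta_j)`: after feature and weight
#' normalisation the prediction relies only on the angles, rescaled by `s`.
#'
#' @param cosines Matrix `[B x n]` of cosines in `[-1, 1]`.
#' @param labels 0-based true classes.
#' @param scale Rescale factor s > 0.
#' @return Non-negative scalar loss.
#' @export
normalized_softmax_loss <- function(cosines, labels, scale = 30) {
  check_cosines(cosines)
  if (scale <= 0) stop_invalid("scale s must be positive")
  plain_softmax_loss(scale * as.matrix(cosines), labels)
}

#' Additive angular margin (arcmargin) loss
#'
#' Replaces each sample's true-class cosine `cos(theta_y)` by
#' `cos(theta_y + m)` (see [apply_additive_angular_margin()]), rescales all
#' logits by `s`, and applies softmax cross-entropy. Equals
#' [normalized_softmax_loss()] when `m = 0`. Demanding the same predicted
#' probability at a smaller angle forces intra-class compactness and
#' inter-class separation on the unit hypersphere.
#'
#' @param cosines Matrix `[B x n]` of cosines in `[-1, 1]`.
#' @param labels 0-based true classes.
#' @param scale Rescale factor s > 0.
#' @param margin Margin m in radians, `0 <= m < pi`.
#' @return Non-negative scalar loss.
#' @export
arc_margin_loss <- function(cosines, labels, scale = 30, margin = 0.3) {
  check_cosines(cosines)
  cosines <- as.matrix(cosines)
  B <- nrow(cosines)
  if (B == 0) stop_invalid("empty batch")
  if (length(labels) != B) stop_invalid("labels length must equal batch size")
  idx <- cbind(seq_len(B), labels + 1L)
  cosines[idx] <- apply_additive_angular_margin(cosines[idx], margin)
  plain_softmax_loss(scale * cosines, labels)
}

check_cosines <- function(cosines) {
  if (any(abs(cosines) > 1 + 1e-6))
    stop_invalid("cosines must lie in [-1, 1]")
  invisible(TRUE)
}

# random orthogonal (semi-orthogonal for non-square) matrix, rows x cols
orthogonal_matrix <- function(r, c) {
  n <- max(r, c)
  A <- matrix(stats::rnorm(n * min(r, c)), n, min(r, c))
  qrd <- qr(A)
  Q <- qr.Q(qrd)
  # sign-correct so the distribution is Haar, not biased by qr's convention
  Q <- Q %*% diag(sign(diag(qr.R(qrd))), min(r, c))
  if (r >= c) Q[seq_len(r), , drop = FALSE] else t(Q)[seq_len(r), , drop = FALSE]
}
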