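#' Row-wise L2 normalisation
#'
#' Divides each row of a matrix by `max(||row||_2, eps)` so that non-zero rows
#' come out with unit Euclidean norm. Zero rows are returned unchanged (as zero
#' rows) with a warning, since they carry no direction.
#'
#' @param M Numeric matrix (rows are vectors to normalise).
#' @param eps Norm floor guarding against division by zero.
#' @return Matrix of the same shape with unit-norm (or zero) rows.
#' @export
normalize_rows <- function(M, eps = 1e-12) {
  M <- as.matrix(M)
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) {
    warning("normalize_rows: zero row(s) left as zero vectors")
  }
  M / pmax(nrm, eps)
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in [-1, 1]; 0 if either vector is zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(-1, sum(a * b) / (na * nb)))
}

# Pairwise cosine similarity matrix between rows of A and rows of B.
cosine_matrix <- function(A, B) {
  An <- normalize_rows_quiet(A)
  Bn <- normalize_rows_quiet(B)
  S <- An %*% t(Bn)
  S[S > 1] <- 1
  S[S < -1] <- -1
  S
}

# normalize_rows without the zero-row warning, for internal hot paths
normalize_rows_quiet <- function(M, eps = 1e-12) {
  M <- as.matrix(M)
  M / pmax(sqrt(rowSums(M^2)), eps)
}

# arg checking helper
stop_invalid <- function(...) stop(..., call. = FALSE)

# draw a seeded RNG substream without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
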