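# Adaptive noise-augmented attention: adaptive noise statistics, discrete
# Gaussian kernel, attention-map convolution, and the stochastic training /
# deterministic inference augmentation paths.

#' Adaptive noise statistics of an attention matrix
#'
#' The noise mean is the arithmetic mean of the valid block of the per-head
#' attention score matrix; for a row-stochastic matrix this is always
#' 1/valid_len. The noise standard deviation is the square root of the sum
#' of squared deviations over the valid block divided by D, where D is
#' n^2 - 1 under the default \code{"elements_minus_one"} denominator (the
#' sample estimator over all n^2 entries) or n - 1 under
#' \code{"as_printed"}.
#'
#' @param A an \linkS4class{AttentionMatrix} (or plain square matrix).
#' @param cfg an \linkS4class{AugmentationConfig}; only
#'   \code{variance_denominator} is consulted.
#' @param scope identifier recorded on the result.
#' @return a \linkS4class{NoiseParams}.
#' @export
computeNoiseParams <- function(A, cfg = augConfig(), scope = "unscoped") {
  if (is(A, "AttentionMatrix")) {
    v <- A@valid_len
    s <- A@scores
  } else {
    s <- as.matrix(A)
    v <- nrow(s)
  }
  if (v < 2L)
    stop("valid_len < 2: adaptive noise variance is undefined")
  blk <- s[seq_len(v), seq_len(v), drop = FALSE]
  mu <- mean(blk)
  ss <- sum((blk - mu)^2)
  D <- switch(cfg@variance_denominator,
              elements_minus_one = as.numeric(v)^2 - 1,
              as_printed = as.numeric(v) - 1)
  new("NoiseParams", mu = mu, sigma_gn = sqrt(ss / D), scope = scope)
}

#' Build the discrete 2D Gaussian smoothing kernel
#'
#' Side length follows the event-horizon rule k = round(2*pi*sigma_eh)
#' clamped to >= 1 (sigma_eh = 1.0 gives k = 6; sigma_eh = 0.33 gives
#' k = 2). Weights are the isotropic Gaussian density evaluated at centered
#' integer offsets -floor(k/2) .. ceil(k/2)-1, optionally scaled to sum 1.
#'
#' @param sigma_eh event-horizon width, > 0.
#' @param normalized scale weights to sum 1 (default TRUE).
#' @return a \linkS4class{SmoothingKernel}.
#' @export
buildKernel <- function(sigma_eh, normalized = TRUE) {
  if (!is.numeric(sigma_eh) || length(sigma_eh) != 1L || sigma_eh <= 0)
    stop("sigma_eh must be a single positive number")
  k <- max(1L, as.integer(round(2 * pi * sigma_eh)))
  off <- kernelOffsets(k)
  w <- outer(off, off, function(u, v)
    exp(-0.5 * (u^2 + v^2) / sigma_eh^2) / (2 * pi * sigma_eh^2))
  if (normalized) w <- w / sum(w)
  new("SmoothingKernel", sigma_eh = sigma_eh, size_k = k, weights = w,
      normalized = normalized)
}

# Centered support offsets: odd k -> symmetric, even k -> one extra cell
# on the negative side (anchored up-left of center).
kernelOffsets <- function(k) (-(k %/% 2)):(ceiling(k / 2) - 1L)

#' Smooth an attention map with a 2D kernel
#'
#' Convolves the leading valid_len x valid_len block of M with the kernel,
#' zero-padding at the block boundary, and returns a same-size matrix.
#' Positions outside the valid block remain exactly 0, so no mass leaks
#' into padding.
#'
#' @param M square numeric matrix.
#' @param kern a \linkS4class{SmoothingKernel}.
#' @param valid_len number of valid leading rows/columns (default all).
#' @return matrix of the same dimensions as M.
#' @export
smoothAttention <- function(M, kern, valid_len = nrow(M)) {
  M <- as.matrix(M)
  n <- nrow(M)
  v <- as.integer(valid_len)
  if (v > n) stop("valid_len exceeds matrix size")
  if (kern@size_k > 2L * v)
    warning("kernel larger than twice the valid region: heavy smoothing")
  if (v == 0L) return(M * 0)
  blk <- M[seq_len(v), seq_len(v), drop = FALSE]
  B <- bandOperator(kern, v)
  out <- matrix(0, n, n)
  out[seq_len(v), seq_len(v)] <- B %*% blk %*% t(B)
  out
}

# The isotropic Gaussian kernel is separable: w[u,s] = g(u) * g(s) up to
# the overall scale, so the zero-padded 2D convolution factors into two
# banded Toeplitz multiplies, out = B blk B^T with
# B[i, p] = scale^{1/2} * g(i - p) for i - p in the support offsets.
# Cached per (kernel, valid_len) -- training loops reuse the same sizes.
bandOperator <- local({
  cache <- new.env(parent = emptyenv())
  function(kern, v) {
    key <- sprintf("%.17g|%d|%d|%d", kern@sigma_eh, kern@size_k,
                   kern@normalized, v)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    off <- kernelOffsets(kern@size_k)
    g <- exp(-0.5 * off^2 / kern@sigma_eh^2)
    scale <- sum(kern@weights) / sum(outer(g, g))   # recover overall scale
    g <- g * sqrt(scale)
    B <- matrix(0, v, v)
    for (a in seq_along(off)) {
      u <- off[a]
      i <- max(1L, 1L + u):min(v, v + u)
      if (i[1] > i[length(i)]) next
      B[cbind(i, i - u)] <- g[a]
    }
    cache[[key]] <- B
    B
  }
})

# Transposed convolution: gradient of the smoothing w.r.t. its input,
# dIn = B^T dOut B.
smoothBackward <- function(dOut, kern, valid_len = nrow(dOut)) {
  n <- nrow(dOut)
  v <- as.integer(valid_len)
  if (v == 0L) return(dOut * 0)
  B <- bandOperator(kern, v)
  out <- matrix(0, n, n)
  out[seq_len(v), seq_len(v)] <-
    crossprod(B, dOut[seq_len(v), seq_len(v), drop = FALSE]) %*% B
  out
}

#' Stochastic training-path augmentation
#'
#' ANAA adds i.i.d. Normal(mu, sigma_gn^2) noise -- with (mu, sigma_gn)
#' recomputed from the current matrix -- to the valid block and convolves
#' the result with the smoothing kernel. RNA performs the noise step only.
#' Mode "none" is a bit-exact identity. Rows are deliberately not
#' renormalized and scores are not clipped. Noise is drawn fresh from the
#' current RNG state on every call.
#'
#' @param A an \linkS4class{AttentionMatrix}.
#' @param cfg an \linkS4class{AugmentationConfig} with \code{training = TRUE}.
#' @param kern optional precomputed \linkS4class{SmoothingKernel}
#'   (built from \code{cfg@sigma_eh} when missing).
#' @return plain numeric matrix of augmented scores.
#' @export
augmentTrain <- function(A, cfg, kern = NULL) {
  stopifnot(is(A, "AttentionMatrix"), is(cfg, "AugmentationConfig"))
  if (!cfg@training) stop("augmentTrain requires cfg@training = TRUE")
  if (cfg@mode == "none") return(A@scores)
  v <- A@valid_len
  np <- computeNoiseParams(A, cfg)
  out <- A@scores
  G <- matrix(rnorm(v * v, mean = np@mu, sd = np@sigma_gn), v, v)
  out[seq_len(v), seq_len(v)] <- out[seq_len(v), seq_len(v)] + G
  if (cfg@mode == "ANAA") {
    if (is.null(kern)) kern <- buildKernel(cfg@sigma_eh, cfg@kernel_normalized)
    out <- smoothAttention(out, kern, v)
  }
  out
}

#' Deterministic inference-path augmentation
#'
#' At evaluation the noise is replaced by its expected value mu, recomputed
#' from the current matrix: ANAA smooths A + mu, RNA returns A + mu, mode
#' "none" returns A unchanged. Identical inputs give identical outputs.
#'
#' @inheritParams augmentTrain
#' @param cfg an \linkS4class{AugmentationConfig} with \code{training = FALSE}.
#' @return plain numeric matrix of augmented scores.
#' @export
augmentEval <- function(A, cfg, kern = NULL) {
  stopifnot(is(A, "AttentionMatrix"), is(cfg, "AugmentationConfig"))
  if (cfg@training) stop("augmentEval requires cfg@training = FALSE")
  if (cfg@mode == "none") return(A@scores)
  v <- A@valid_len
  np <- computeNoiseParams(A, cfg)
  out <- A@scores
  out[seq_len(v), seq_len(v)] <- out[seq_len(v), seq_len(v)] + np@mu
  if (cfg@mode == "ANAA") {
    if (is.null(kern)) kern <- buildKernel(cfg@sigma_eh, cfg@kernel_normalized)
    out <- smoothAttention(out, kern, v)
  }
  out
}

#' Export kernel weights as a plain-text matrix
#'
#' @param kern a \linkS4class{SmoothingKernel}.
#' @param path output file path (whitespace-separated text).
#' @return invisibly, the path.
#' @export
exportKernel <- function(kern, path) {
  write.table(kern@weights, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
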