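# Comparison augmentations: naive attention masking (pre-softmax -Inf with
# probability p), DropAttention (span-expanded masking), and calibrated
# uniform noise on embeddings / feed-forward inputs. All are training-time
# only; every baseline is an identity map at evaluation.

#' Naive attention masking
#'
#' Sets each valid pre-softmax logit to -Inf independently with probability
#' p, so the corresponding post-softmax weight is exactly 0. Rows that
#' would become entirely masked are restored unmasked (the softmax would
#' otherwise be undefined).
#'
#' @param logits pre-softmax score matrix.
#' @param p masking probability in [0, 1].
#' @param valid_len number of valid leading rows/columns.
#' @return logits with masked entries set to a large negative value.
#' @export
naiveMask <- function(logits, p, valid_len = nrow(logits)) {
  v <- as.integer(valid_len)
  if (p <= 0 || v == 0L) return(logits)
  M <- matrix(runif(v * v) < p, v, v)
  full <- rowSums(M) == v
  M[full, ] <- FALSE
  out <- logits
  blk <- out[seq_len(v), seq_len(v), drop = FALSE]
  blk[M] <- NEG_INF
  out[seq_len(v), seq_len(v)] <- blk
  out
}

#' DropAttention span masking
#'
#' Draws mask seeds as in \code{\link{naiveMask}} and expands each seed at
#' column j to the run of columns j .. min(j + omega - 1, valid_len) in the
#' same row. omega = 1 reduces exactly to naive masking. Fully masked rows
#' are restored unmasked.
#'
#' @inheritParams naiveMask
#' @param omega span length along the key axis (>= 1).
#' @return masked logits.
#' @export
dropAttention <- function(logits, p, omega, valid_len = nrow(logits)) {
  v <- as.integer(valid_len)
  omega <- as.integer(omega)
  if (omega < 1L) stop("omega must be >= 1")
  if (p <= 0 || v == 0L) return(logits)
  seeds <- matrix(runif(v * v) < p, v, v)
  M <- matrix(FALSE, v, v)
  for (off in 0:(omega - 1L)) {
    jmax <- v - off
    if (jmax < 1L) break
    M[, (1L + off):v] <- M[, (1L + off):v] | seeds[, seq_len(jmax), drop = FALSE]
  }
  full <- rowSums(M) == v
  M[full, ] <- FALSE
  out <- logits
  blk <- out[seq_len(v), seq_len(v), drop = FALSE]
  blk[M] <- NEG_INF
  out[seq_len(v), seq_len(v)] <- blk
  out
}

#' Calibrated uniform embedding noise
#'
#' Adds i.i.d. Uniform(-1, 1) noise scaled by alpha_scale / sqrt(n * d) to
#' an n x d embedded sequence (the calibration of the cited
#' embedding-noise fine-tuning method). Training-time only; callers apply
#' the identity at evaluation.
#'
#' @param E embedded sequence, n x d.
#' @param alpha_scale noise magnitude (>= 0; 0 is the identity).
#' @return perturbed embeddings.
#' @export
embedNoise <- function(E, alpha_scale) {
  if (alpha_scale == 0) return(E)
  n <- nrow(E); d <- ncol(E)
  E + matrix(runif(n * d, -1, 1), n, d) * (alpha_scale / sqrt(n * d))
}

#' Calibrated uniform feed-forward noise
#'
#' Same calibration as \code{\link{embedNoise}}, applied to the
#' feed-forward sublayer input.
#'
#' @param H hidden activations, n x d.
#' @inheritParams embedNoise
#' @return perturbed activations.
#' @export
ffnNoise <- function(H, alpha_scale) embedNoise(H, alpha_scale)
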