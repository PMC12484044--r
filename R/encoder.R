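# Compact multi-head Transformer encoder with an augmentation injection
# point on every attention head, an MLM head for pre-training and a [CLS]
# classification head for fine-tuning. Forward and backward passes are
# hand-implemented on base-R matrices; one sequence at a time (variable
# lengths, no cross-sample padding during training).

LN_EPS <- 1e-5
NEG_INF <- -1e30

#' Initialize an encoder state
#'
#' BERT-style initialization: all projection/embedding weights drawn
#' Normal(0, 0.02^2), biases zero, layer-norm gain 1 / bias 0.
#'
#' @param config an \linkS4class{EncoderConfig}.
#' @param seed integer initialization seed.
#' @param vocab_hash optional hash tying the state to a vocabulary.
#' @return an \linkS4class{EncoderState} in "pretraining" mode.
#' @export
initEncoder <- function(config, seed = 1L, vocab_hash = "") {
  set.seed(seed)
  g <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  d <- config@d_model; H <- config@n_heads
  dk <- config@d_k; dv <- config@d_v; dff <- 4L * d
  p <- list(tok_emb = g(config@vocab_size, d),
            pos_emb = g(config@max_len, d))
  for (l in seq_len(config@n_layers)) {
    p[[sprintf("L%d_Wq", l)]] <- g(d, H * dk)
    p[[sprintf("L%d_Wk", l)]] <- g(d, H * dk)
    p[[sprintf("L%d_Wv", l)]] <- g(d, H * dv)
    p[[sprintf("L%d_Wo", l)]] <- g(H * dv, d)
    p[[sprintf("L%d_ln1_g", l)]] <- rep(1, d)
    p[[sprintf("L%d_ln1_b", l)]] <- rep(0, d)
    p[[sprintf("L%d_W1", l)]] <- g(d, dff)
    p[[sprintf("L%d_b1", l)]] <- rep(0, dff)
    p[[sprintf("L%d_W2", l)]] <- g(dff, d)
    p[[sprintf("L%d_b2", l)]] <- rep(0, d)
    p[[sprintf("L%d_ln2_g", l)]] <- rep(1, d)
    p[[sprintf("L%d_ln2_b", l)]] <- rep(0, d)
  }
  p$mlm_W <- g(d, config@vocab_size)
  p$mlm_b <- rep(0, config@vocab_size)
  p$cls_w <- rnorm(d, sd = 0.02)
  p$cls_b <- 0
  new("EncoderState", config = config, params = p, mode = "pretraining",
      vocab_hash = vocab_hash, history = list())
}

softmaxRows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

lnForward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * istd
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, istd = istd)
}

lnBackward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dx = cache$istd * (dxhat - m1 - xhat * m2),
       dg = colSums(dY * xhat), db = colSums(dY))
}

# Resolve the augmentation argument: NULL / AugmentationConfig(mode none|
# RNA|ANAA) / BaselineConfig. Returns a normalized descriptor.
resolveAug <- function(aug, training) {
  if (is.null(aug)) return(list(family = "none"))
  if (is(aug, "AugmentationConfig")) {
    if (aug@mode == "none") return(list(family = "none"))
    kern <- NULL
    if (aug@mode == "ANAA")
      kern <- buildKernel(aug@sigma_eh, aug@kernel_normalized)
    return(list(family = "core", cfg = aug, kern = kern))
  }
  if (is(aug, "BaselineConfig")) {
    if (!training) return(list(family = "none"))  # baselines: identity at eval
    return(list(family = "baseline", cfg = aug))
  }
  stop("aug must be NULL, an AugmentationConfig or a BaselineConfig")
}

# Apply the core augmentation to a bare row-stochastic matrix A (valid
# block only, v x v). Returns the augmented matrix; stochastic when
# training, deterministic expected-value path otherwise.
applyCoreAug <- function(A, desc, training) {
  cfg <- desc$cfg
  v <- nrow(A)
  mu <- mean(A)
  out <- A
  if (training) {
    D <- if (cfg@variance_denominator == "elements_minus_one")
      as.numeric(v)^2 - 1 else as.numeric(v) - 1
    sgn <- sqrt(sum((A - mu)^2) / D)
    out <- out + matrix(rnorm(v * v, mu, sgn), v, v)
  } else {
    out <- out + mu
  }
  if (cfg@mode == "ANAA")
    out <- smoothAttention(out, desc$kern, v)
  out
}

#' One self-attention head, standalone
#'
#' Computes scaled dot-product attention for a single head from explicit
#' weights, applies the configured augmentation to the post-softmax score
#' matrix, and returns both the (augmented-matrix) head output and the
#' pre-augmentation attention scores. Padded key columns are excluded from
#' the softmax and zeroed in the returned matrix.
#'
#' @param X embedded sequence, n x d_model.
#' @param Wq,Wk,Wv projection matrices (d_model x d_k / d_v).
#' @param valid_len number of non-padding positions.
#' @param aug NULL or an \linkS4class{AugmentationConfig}.
#' @param training logical; selects the stochastic vs deterministic path.
#' @return list with \code{H} (n x d_v) and \code{A}
#'   (\linkS4class{AttentionMatrix}, pre-augmentation).
#' @export
selfAttentionHead <- function(X, Wq, Wk, Wv, valid_len = nrow(X),
                              aug = NULL, training = FALSE) {
  n <- nrow(X)
  v <- as.integer(valid_len)
  Xv <- X[seq_len(v), , drop = FALSE]
  Q <- Xv %*% Wq; K <- Xv %*% Wk; V <- Xv %*% Wv
  S <- tcrossprod(Q, K) / sqrt(ncol(Wq))
  A <- softmaxRows(S)
  desc <- resolveAug(aug, training)
  Atil <- if (desc$family == "core") applyCoreAug(A, desc, training) else A
  Hv <- Atil %*% V
  H <- matrix(0, n, ncol(Wv))
  H[seq_len(v), ] <- Hv
  Afull <- matrix(0, n, n)
  Afull[seq_len(v), seq_len(v)] <- A
  list(H = H, A = AttentionMatrix(Afull, v, check_stochastic = FALSE))
}

# Pre-softmax masking for the naive-mask / DropAttention baselines.
maskLogits <- function(S, cfg) {
  v <- nrow(S)
  if (cfg@kind == "naive_mask")
    naiveMask(S, cfg@p, valid_len = v)
  else
    dropAttention(S, cfg@p, cfg@omega, valid_len = v)
}

# Full encoder forward over one token sequence. tokens are 0-based ids,
# PAD (0) allowed only as a suffix. Returns hidden states (n x d, padded
# rows zero), optional retained attention matrices, and a cache for the
# backward pass.
encForward <- function(state, tokens, aug = NULL, training = FALSE,
                       collect = FALSE, keep_cache = FALSE) {
  cfg <- state@config
  p <- state@params
  n <- length(tokens)
  if (n > cfg@max_len) stop("sequence longer than max_len")
  v <- sum(tokens != 0L)
  if (v == 0L) stop("sequence has no non-padding tokens")
  if (any(tokens[seq_len(v)] == 0L))
    stop("PAD tokens are only allowed as a suffix")
  ids <- tokens[seq_len(v)] + 1L
  desc <- resolveAug(aug, training)
  H <- cfg@n_heads; dk <- cfg@d_k; dv <- cfg@d_v; d <- cfg@d_model
  drop_p <- if (training) cfg@dropout else 0

  X <- p$tok_emb[ids, , drop = FALSE] + p$pos_emb[seq_len(v), , drop = FALSE]
  if (desc$family == "baseline" && desc$cfg@kind == "embed_noise")
    X <- embedNoise(X, desc$cfg@alpha_scale)
  cache <- list(ids = ids, v = v, n = n, desc = desc, X0 = X,
                drop_p = drop_p, layers = vector("list", cfg@n_layers))
  attn <- if (collect) list() else NULL

  for (l in seq_len(cfg@n_layers)) {
    lay <- list(Xin = X)
    Qall <- X %*% p[[sprintf("L%d_Wq", l)]]
    Kall <- X %*% p[[sprintf("L%d_Wk", l)]]
    Vall <- X %*% p[[sprintf("L%d_Wv", l)]]
    lay$Qall <- Qall; lay$Kall <- Kall; lay$Vall <- Vall
    Cc <- matrix(0, v, H * dv)
    lay$A <- vector("list", H); lay$Atil <- vector("list", H)
    for (h in seq_len(H)) {
      qi <- ((h - 1L) * dk + 1L):(h * dk)
      vi <- ((h - 1L) * dv + 1L):(h * dv)
      S <- tcrossprod(Qall[, qi, drop = FALSE], Kall[, qi, drop = FALSE]) /
        sqrt(dk)
      if (desc$family == "baseline" &&
          desc$cfg@kind %in% c("naive_mask", "drop_attention"))
        S <- maskLogits(S, desc$cfg)
      A <- softmaxRows(S)
      Atil <- if (desc$family == "core") applyCoreAug(A, desc, training) else A
      Cc[, vi] <- Atil %*% Vall[, vi, drop = FALSE]
      lay$A[[h]] <- A
      lay$Atil[[h]] <- Atil
      if (collect) {
        Afull <- matrix(0, n, n)
        Afull[seq_len(v), seq_len(v)] <- if (desc$family == "core") Atil else A
        attn[[sprintf("layer%d_head%d", l, h)]] <- Afull
      }
    }
    lay$C <- Cc
    O <- Cc %*% p[[sprintf("L%d_Wo", l)]]
    if (drop_p > 0) {
      lay$mO <- matrix(rbinom(v * d, 1L, 1 - drop_p), v, d) / (1 - drop_p)
      O <- O * lay$mO
    }
    R1 <- X + O
    ln1 <- lnForward(R1, p[[sprintf("L%d_ln1_g", l)]],
                     p[[sprintf("L%d_ln1_b", l)]])
    Y <- ln1$y
    lay$ln1 <- ln1[c("xhat", "istd")]
    Yf <- Y
    if (desc$family == "baseline" && desc$cfg@kind == "ffn_noise")
      Yf <- ffnNoise(Yf, desc$cfg@alpha_scale)
    lay$Yf <- Yf
    F1 <- Yf %*% p[[sprintf("L%d_W1", l)]] +
      rep(p[[sprintf("L%d_b1", l)]], each = v)
    lay$relu_mask <- F1 > 0
    Hr <- F1 * lay$relu_mask
    if (drop_p > 0) {
      lay$mH <- matrix(rbinom(length(Hr), 1L, 1 - drop_p),
                       nrow(Hr), ncol(Hr)) / (1 - drop_p)
      Hr <- Hr * lay$mH
    }
    lay$Hr <- Hr
    F2 <- Hr %*% p[[sprintf("L%d_W2", l)]] +
      rep(p[[sprintf("L%d_b2", l)]], each = v)
    R2 <- Y + F2
    ln2 <- lnForward(R2, p[[sprintf("L%d_ln2_g", l)]],
                     p[[sprintf("L%d_ln2_b", l)]])
    lay$Y <- Y
    lay$ln2 <- ln2[c("xhat", "istd")]
    X <- ln2$y
    cache$layers[[l]] <- lay
  }

  Hfull <- matrix(0, n, d)
  Hfull[seq_len(v), ] <- X
  list(hidden = Hfull, hidden_valid = X, attention = attn,
       cache = if (keep_cache) cache else NULL)
}

# Backward through the encoder stack given dX (v x d) at the top. Returns
# named gradient list covering every parameter touched.
encBackward <- function(state, cache, dX) {
  cfg <- state@config
  p <- state@params
  H <- cfg@n_heads; dk <- cfg@d_k; dv <- cfg@d_v
  v <- cache$v
  desc <- cache$desc
  gr <- list()
  add <- function(name, val) {
    gr[[name]] <<- if (is.null(gr[[name]])) val else gr[[name]] + val
  }
  for (l in rev(seq_len(cfg@n_layers))) {
    lay <- cache$layers[[l]]
    ln2 <- lnBackward(dX, lay$ln2, p[[sprintf("L%d_ln2_g", l)]])
    add(sprintf("L%d_ln2_g", l), ln2$dg)
    add(sprintf("L%d_ln2_b", l), ln2$db)
    dR2 <- ln2$dx
    dY <- dR2
    dF2 <- dR2
    add(sprintf("L%d_W2", l), crossprod(lay$Hr, dF2))
    add(sprintf("L%d_b2", l), colSums(dF2))
    dHr <- tcrossprod(dF2, p[[sprintf("L%d_W2", l)]])
    if (!is.null(lay$mH)) dHr <- dHr * lay$mH
    dF1 <- dHr * lay$relu_mask
    add(sprintf("L%d_W1", l), crossprod(lay$Yf, dF1))
    add(sprintf("L%d_b1", l), colSums(dF1))
    dY <- dY + tcrossprod(dF1, p[[sprintf("L%d_W1", l)]])
    ln1 <- lnBackward(dY, lay$ln1, p[[sprintf("L%d_ln1_g", l)]])
    add(sprintf("L%d_ln1_g", l), ln1$dg)
    add(sprintf("L%d_ln1_b", l), ln1$db)
    dR1 <- ln1$dx
    dXl <- dR1                       # residual into the block input
    dO <- dR1
    if (!is.null(lay$mO)) dO <- dO * lay$mO
    add(sprintf("L%d_Wo", l), crossprod(lay$C, dO))
    dC <- tcrossprod(dO, p[[sprintf("L%d_Wo", l)]])
    dQall <- matrix(0, v, H * dk)
    dKall <- matrix(0, v, H * dk)
    dVall <- matrix(0, v, H * dv)
    for (h in seq_len(H)) {
      qi <- ((h - 1L) * dk + 1L):(h * dk)
      vi <- ((h - 1L) * dv + 1L):(h * dv)
      dHh <- dC[, vi, drop = FALSE]
      Atil <- lay$Atil[[h]]
      A <- lay$A[[h]]
      dAtil <- tcrossprod(dHh, lay$Vall[, vi, drop = FALSE])
      dVall[, vi] <- crossprod(Atil, dHh)
      # ANAA: differentiate the smoothing exactly; the additive noise /
      # expected-value term and its (mu, sigma) statistics are treated as
      # constants w.r.t. A.
      dA <- if (desc$family == "core" && desc$cfg@mode == "ANAA")
        smoothBackward(dAtil, desc$kern, v) else dAtil
      dS <- A * (dA - rowSums(dA * A))
      dQall[, qi] <- dS %*% lay$Kall[, qi, drop = FALSE] / sqrt(dk)
      dKall[, qi] <- crossprod(dS, lay$Qall[, qi, drop = FALSE]) / sqrt(dk)
    }
    add(sprintf("L%d_Wq", l), crossprod(lay$Xin, dQall))
    add(sprintf("L%d_Wk", l), crossprod(lay$Xin, dKall))
    add(sprintf("L%d_Wv", l), crossprod(lay$Xin, dVall))
    dXl <- dXl + tcrossprod(dQall, p[[sprintf("L%d_Wq", l)]]) +
      tcrossprod(dKall, p[[sprintf("L%d_Wk", l)]]) +
      tcrossprod(dVall, p[[sprintf("L%d_Wv", l)]])
    dX <- dXl
  }
  # embedding gradients: scatter rows
  dTok <- matrix(0, cfg@vocab_size, cfg@d_model)
  for (i in seq_len(v))
    dTok[cache$ids[i], ] <- dTok[cache$ids[i], ] + dX[i, ]
  gr$tok_emb <- dTok
  dPos <- matrix(0, cfg@max_len, cfg@d_model)
  dPos[seq_len(v), ] <- dX
  gr$pos_emb <- dPos
  gr
}

#' Encode a token sequence
#'
#' Runs the full encoder stack and optionally retains every per-layer,
#' per-head attention matrix (n x n, padded positions zero).
#'
#' @param state an \linkS4class{EncoderState}.
#' @param tokens integer vector of 0-based token ids (PAD = 0 only as a
#'   suffix).
#' @param aug NULL, an \linkS4class{AugmentationConfig} or a
#'   \linkS4class{BaselineConfig}.
#' @param training logical; training path draws noise/masks, eval path is
#'   deterministic.
#' @param collect_attention retain attention matrices for diagnostics.
#' @return list with \code{hidden} (n x d_model) and \code{attention}
#'   (named list of matrices, or NULL).
#' @export
encode <- function(state, tokens, aug = NULL, training = FALSE,
                   collect_attention = FALSE) {
  out <- encForward(state, as.integer(tokens), aug = aug,
                    training = training, collect = collect_attention)
  list(hidden = out$hidden, attention = out$attention)
}

#' Masked-language-model forward pass
#'
#' Cross-entropy averaged over the masked positions only; positions are
#' 1-based indices into the sequence.
#'
#' @param state an \linkS4class{EncoderState}.
#' @param tokens corrupted token sequence (0-based ids).
#' @param mask_positions 1-based positions whose original tokens are
#'   predicted.
#' @param targets original 0-based token ids at those positions.
#' @param aug optional augmentation (training path).
#' @param training logical.
#' @return list with \code{loss} and \code{log_scores} (masked positions x
#'   vocab matrix of log-probabilities).
#' @export
mlmForward <- function(state, tokens, mask_positions, targets, aug = NULL,
                       training = FALSE) {
  if (length(mask_positions) == 0L) {
    warning("no masked positions: MLM loss is 0 by convention")
    return(list(loss = 0, log_scores = NULL))
  }
  out <- encForward(state, as.integer(tokens), aug = aug,
                    training = training)
  Hm <- out$hidden_valid[mask_positions, , drop = FALSE]
  logits <- Hm %*% state@params$mlm_W +
    rep(state@params$mlm_b, each = nrow(Hm))
  lse <- apply(logits, 1L, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  lp <- logits - lse
  idx <- cbind(seq_along(targets), as.integer(targets) + 1L)
  list(loss = -mean(lp[idx]), log_scores = lp)
}

#' Classification forward pass
#'
#' Sigmoid score of the positive outcome from the [CLS] position
#' representation. With the core augmentation's eval path this is
#' deterministic.
#'
#' @inheritParams mlmForward
#' @return probability in (0, 1).
#' @export
classifyForward <- function(state, tokens, aug = NULL, training = FALSE) {
  out <- encForward(state, as.integer(tokens), aug = aug,
                    training = training)
  z <- sum(out$hidden_valid[1L, ] * state@params$cls_w) + state@params$cls_b
  plogis(z)
}

#' Save / load an encoder checkpoint
#'
#' The checkpoint container holds the configuration, all parameters, the
#' mode, the vocabulary hash and training history; numeric values
#' round-trip bit-exactly.
#'
#' @param state an \linkS4class{EncoderState}.
#' @param path file path.
#' @return \code{saveEncoder}: the path, invisibly. \code{loadEncoder}: the
#'   restored \linkS4class{EncoderState}.
#' @export
saveEncoder <- function(state, path) {
  saveRDS(list(config = state@config, params = state@params,
               mode = state@mode, vocab_hash = state@vocab_hash,
               history = state@history, package_version = "0.1.0"),
          path)
  invisible(path)
}

#' @rdname saveEncoder
#' @export
loadEncoder <- function(path) {
  x <- readRDS(path)
  new("EncoderState", config = x$config, params = x$params, mode = x$mode,
      vocab_hash = x$vocab_hash, history = x$history)
}
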