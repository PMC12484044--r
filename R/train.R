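# End-to-end training protocol: MLM pre-training, fine-tuning with early
# stopping on validation AUC, 5-fold repeated fine-tuning scored on a
# held-out test set, and the data-insufficiency subsampling sweep.

#' Training configuration
#'
#' @slot lr learning rate (Adam).
#' @slot batch_size samples per optimizer step.
#' @slot max_epochs maximum training epochs.
#' @slot patience early-stopping patience in epochs (validation AUC).
#' @slot mlm_prob MLM corruption probability.
#' @slot seed training-run seed.
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", batch_size = "integer",
                 max_epochs = "integer", patience = "integer",
                 mlm_prob = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@patience < 1L) return("patience must be >= 1")
    if (object@mlm_prob <= 0 || object@mlm_prob >= 1)
      return("mlm_prob must be in (0, 1)")
    TRUE
  })

#' Construct a TrainConfig
#'
#' Defaults: Adam with learning rate 5e-4 (use 1e-3 for pre-training),
#' batch 32, patience 5 epochs on validation AUC, 15\% MLM corruption.
#'
#' @param lr learning rate.
#' @param batch_size batch size.
#' @param max_epochs epoch cap.
#' @param patience early-stopping patience.
#' @param mlm_prob MLM corruption probability.
#' @param seed run seed.
#' @return a \code{TrainConfig}.
#' @export
trainConfig <- function(lr = 5e-4, batch_size = 32L, max_epochs = 20L,
                        patience = 5L, mlm_prob = 0.15, seed = 1L) {
  new("TrainConfig", lr = lr, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      mlm_prob = mlm_prob, seed = as.integer(seed))
}

#' Derive a named sub-seed from a global seed
#'
#' Deterministic FNV-1a-style mix of the stream name into the global seed,
#' reduced below 2^31, so each module (data, noise, subsampling, ...) gets
#' an independent reproducible stream.
#'
#' @param seed integer global seed.
#' @param name stream name.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, name) {
  h <- 2166136261
  for (b in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# ---- Adam -------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- MLM corruption ---------------------------------------------------------

# BERT convention: select non-special tokens with probability mlm_prob;
# of the selected, 80% -> [MASK], 10% -> random code id, 10% kept.
corruptTokens <- function(tokens, vocab_size, mlm_prob = 0.15) {
  eligible <- which(tokens >= 5L)
  if (length(eligible) == 0L)
    return(list(tokens = tokens, positions = integer(0),
                targets = integer(0)))
  sel <- eligible[runif(length(eligible)) < mlm_prob]
  if (length(sel) == 0L) sel <- eligible[sample.int(length(eligible), 1L)]
  targets <- tokens[sel]
  u <- runif(length(sel))
  out <- tokens
  out[sel[u < 0.8]] <- SPECIAL_TOKENS[["MASK"]]
  rnd <- sel[u >= 0.8 & u < 0.9]
  if (length(rnd))
    out[rnd] <- 4L + sample.int(vocab_size - 5L, length(rnd), replace = TRUE)
  list(tokens = out, positions = sel, targets = targets)
}

# ---- gradient steps ---------------------------------------------------------

mlmGrads <- function(state, tokens, mlm_prob) {
  cor <- corruptTokens(tokens, state@config@vocab_size, mlm_prob)
  if (length(cor$positions) == 0L) return(NULL)
  fwd <- encForward(state, cor$tokens, training = TRUE, keep_cache = TRUE)
  Hm <- fwd$hidden_valid[cor$positions, , drop = FALSE]
  logits <- Hm %*% state@params$mlm_W +
    rep(state@params$mlm_b, each = nrow(Hm))
  m <- apply(logits, 1L, max)
  P <- exp(logits - m)
  P <- P / rowSums(P)
  k <- length(cor$positions)
  idx <- cbind(seq_len(k), cor$targets + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dlog <- P
  dlog[idx] <- dlog[idx] - 1
  dlog <- dlog / k
  dH <- matrix(0, fwd$cache$v, state@config@d_model)
  dH[cor$positions, ] <- tcrossprod(dlog, state@params$mlm_W)
  gr <- encBackward(state, fwd$cache, dH)
  gr$mlm_W <- crossprod(Hm, dlog)
  gr$mlm_b <- colSums(dlog)
  list(loss = loss, grads = gr)
}

clsGrads <- function(state, tokens, label, aug) {
  fwd <- encForward(state, tokens, aug = aug, training = TRUE,
                    keep_cache = TRUE)
  h1 <- fwd$hidden_valid[1L, ]
  z <- sum(h1 * state@params$cls_w) + state@params$cls_b
  p <- plogis(z)
  loss <- -(label * log(max(p, 1e-12)) + (1 - label) * log(max(1 - p, 1e-12)))
  dz <- p - label
  dH <- matrix(0, fwd$cache$v, state@config@d_model)
  dH[1L, ] <- dz * state@params$cls_w
  gr <- encBackward(state, fwd$cache, dH)
  gr$cls_w <- dz * h1
  gr$cls_b <- dz
  list(loss = loss, grads = gr)
}

accumulateGrads <- function(acc, gr) {
  if (is.null(acc)) return(gr)
  for (nm in names(gr))
    acc[[nm]] <- if (is.null(acc[[nm]])) gr[[nm]] else acc[[nm]] + gr[[nm]]
  acc
}

runEpoch <- function(state, opt, order, step_fn, batch_size, lr) {
  losses <- numeric(0)
  i <- 1L
  while (i <= length(order)) {
    batch <- order[i:min(length(order), i + batch_size - 1L)]
    acc <- NULL
    nb <- 0L
    for (s in batch) {
      res <- step_fn(state, s)
      if (is.null(res)) next
      acc <- accumulateGrads(acc, res$grads)
      losses <- c(losses, res$loss)
      nb <- nb + 1L
    }
    if (nb > 0L) {
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
      upd <- adamStep(state@params, acc, opt, lr)
      state@params <- upd$params
      opt <- upd$opt
    }
    i <- i + batch_size
  }
  list(state = state, opt = opt, loss = mean(losses))
}

# ---- pre-training -----------------------------------------------------------

#' MLM pre-training
#'
#' Trains the encoder on masked-token reconstruction over the pre-training
#' split. No augmentation is applied during pre-training; the run is fully
#' determined by \code{cfg@seed}.
#'
#' @param state an \linkS4class{EncoderState}.
#' @param sequences list of token-id vectors.
#' @param cfg a \linkS4class{TrainConfig} (use \code{lr = 1e-3}).
#' @return the trained \linkS4class{EncoderState}; per-epoch losses are
#'   recorded in \code{state@history$pretrain_loss}.
#' @export
pretrain <- function(state, sequences, cfg = trainConfig(lr = 1e-3)) {
  set.seed(deriveSeed(cfg@seed, "pretrain"))
  opt <- adamInit(state@params)
  losses <- numeric(cfg@max_epochs)
  step_fn <- function(st, i) mlmGrads(st, sequences[[i]], cfg@mlm_prob)
  for (ep in seq_len(cfg@max_epochs)) {
    order <- sample.int(length(sequences))
    res <- runEpoch(state, opt, order, step_fn, cfg@batch_size, cfg@lr)
    state <- res$state
    opt <- res$opt
    losses[ep] <- res$loss
  }
  state@history$pretrain_loss <- losses
  state@mode <- "finetuning"
  state
}

# ---- fine-tuning ------------------------------------------------------------

# Eval-path version of an augmentation: core configs flip to the
# deterministic expected-value path; baselines are identity at eval.
evalAug <- function(aug) {
  if (is.null(aug) || is(aug, "BaselineConfig")) return(aug)
  aug@training <- FALSE
  aug
}

#' Score a set of sequences
#'
#' Deterministic eval-path classification scores.
#'
#' @param state an \linkS4class{EncoderState}.
#' @param sequences list of token-id vectors.
#' @param aug optional augmentation (its eval path is used).
#' @return numeric vector of positive-class probabilities.
#' @export
scoreSequences <- function(state, sequences, aug = NULL) {
  aug <- evalAug(aug)
  vapply(sequences, function(s)
    classifyForward(state, s, aug = aug, training = FALSE), numeric(1))
}

#' Fine-tune with early stopping on validation AUC
#'
#' @param state pre-trained (or fresh) \linkS4class{EncoderState}.
#' @param train_seqs,train_labels training sequences and 0/1 labels.
#' @param val_seqs,val_labels validation fold used for early stopping.
#' @param aug augmentation applied on the training path (NULL, an
#'   \linkS4class{AugmentationConfig} or a \linkS4class{BaselineConfig}).
#' @param cfg a \linkS4class{TrainConfig}.
#' @return list with \code{state} (best-validation parameters) and
#'   \code{curve} (per-epoch validation AUC).
#' @export
finetune <- function(state, train_seqs, train_labels, val_seqs, val_labels,
                     aug = NULL, cfg = trainConfig()) {
  set.seed(deriveSeed(cfg@seed, "finetune"))
  if (is(aug, "AugmentationConfig")) aug@training <- TRUE
  opt <- adamInit(state@params)
  best_auc <- -Inf
  best_params <- state@params
  curve <- numeric(0)
  bad <- 0L
  step_fn <- function(st, i)
    clsGrads(st, train_seqs[[i]], train_labels[i], aug)
  for (ep in seq_len(cfg@max_epochs)) {
    order <- sample.int(length(train_seqs))
    res <- runEpoch(state, opt, order, step_fn, cfg@batch_size, cfg@lr)
    state <- res$state
    opt <- res$opt
    val_auc <- tryCatch(
      aucScore(val_labels, scoreSequences(state, val_seqs, aug)),
      error = function(e) NA_real_)
    curve <- c(curve, val_auc)
    if (!is.na(val_auc) && val_auc > best_auc + 1e-9) {
      best_auc <- val_auc
      best_params <- state@params
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg@patience) break
    }
  }
  state@params <- best_params
  state@mode <- "inference"
  list(state = state, curve = curve, best_val_auc = best_auc)
}

#' Rank-based AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counted half (midrank formula, identical to the Wilcoxon statistic).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: labels contain a single class")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' 5-fold repeated fine-tuning scored on a held-out test set
#'
#' Each fold run starts from the identical initial state, trains on the
#' other k-1 folds with early stopping on the held-out fold, and is scored
#' on the untouched test set. Per-fold data order is re-seeded
#' (\code{cfg@seed} + fold index).
#'
#' @param state initial (typically pre-trained) \linkS4class{EncoderState}.
#' @param sequences,labels the fine-tuning pool.
#' @param folds list of index vectors into the pool, one per fold.
#' @param test_seqs,test_labels held-out test set.
#' @param aug augmentation for the training path.
#' @param cfg a \linkS4class{TrainConfig}.
#' @param fraction subsample-fraction tag recorded on the report.
#' @return an \linkS4class{EvalReport}.
#' @export
finetuneCV <- function(state, sequences, labels, folds, test_seqs,
                       test_labels, aug = NULL, cfg = trainConfig(),
                       fraction = 1.0) {
  fold_auc <- numeric(length(folds))
  curves <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    val_idx <- folds[[k]]
    tr_idx <- setdiff(unlist(folds), val_idx)
    kcfg <- cfg
    kcfg@seed <- cfg@seed + k
    ft <- finetune(state, sequences[tr_idx], labels[tr_idx],
                   sequences[val_idx], labels[val_idx], aug, kcfg)
    fold_auc[k] <- aucScore(test_labels,
                            scoreSequences(ft$state, test_seqs, aug))
    curves[[k]] <- ft$curve
  }
  mode_label <- if (is.null(aug)) "none"
    else if (is(aug, "AugmentationConfig")) aug@mode else aug@kind
  new("EvalReport", fold_auc = fold_auc, mean_auc = mean(fold_auc),
      sd_auc = sd(fold_auc), curves = curves, mode = mode_label,
      fraction = fraction)
}

# Label-stratified subsample: per class, shuffled take of round(fraction *
# class size). fraction = 1 returns every index (in shuffled order).
strataSubsample <- function(labels, fraction, seed) {
  set.seed(seed)
  idx <- integer(0)
  for (cl in unique(labels)) {
    cls <- which(labels == cl)
    cls <- cls[sample.int(length(cls))]
    idx <- c(idx, cls[seq_len(round(fraction * length(cls)))])
  }
  idx
}

#' Data-insufficiency sweep
#'
#' For each fraction, draws a label-stratified subsample of the
#' fine-tuning pool, re-folds it, and runs \code{\link{finetuneCV}} for
#' every augmentation mode. Fraction 1.0 with the same seed reproduces a
#' direct \code{finetuneCV} call on folds built by the same stratified
#' procedure.
#'
#' @inheritParams finetuneCV
#' @param augs named list of augmentations (e.g. \code{list(none = NULL,
#'   ANAA = augConfig("ANAA"))}).
#' @param fractions subsample fractions in (0, 1].
#' @param k_folds folds per run.
#' @return list of \linkS4class{EvalReport}, one per (fraction, mode),
#'   named "mode@fraction".
#' @export
subsampleExperiment <- function(state, sequences, labels, test_seqs,
                                test_labels, augs, fractions = c(1, 0.5,
                                0.2, 0.1), cfg = trainConfig(),
                                k_folds = 5L) {
  reports <- list()
  for (fr in fractions) {
    idx <- strataSubsample(labels, fr, deriveSeed(cfg@seed, "subsample"))
    folds <- makeFolds(idx, k_folds, labels[idx])
    for (nm in names(augs)) {
      rep_ <- finetuneCV(state, sequences, labels, folds, test_seqs,
                         test_labels, augs[[nm]], cfg, fraction = fr)
      reports[[sprintf("%s@%g", nm, fr)]] <- rep_
    }
  }
  reports
}
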