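# AUC, MLM pre-training on a planted deterministic rule, cross-validated
# fine-tuning bookkeeping, and the subsampling sweep.

test_that("rank-based AUC matches the all-pairs counting oracle", {
  expect_identical(aucScore(c(1, 0), c(0.9, 0.1)), 1)
  expect_identical(aucScore(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "single class")

  set.seed(61)
  for (r in 1:10) {
    labels <- rbinom(50, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(round(runif(50), 2))  # rounding forces ties
    expect_identical(aucScore(labels, scores), allPairsAUC(labels, scores))
  }
})

# Planted deterministic co-occurrence rule: the code universe is pairs
# (a_k, b_k) that only ever occur together in a visit, so a masked member
# is exactly recoverable from its partner.
pairedCorpus <- function(n_seq = 200L, n_pairs = 8L, seed = 50L) {
  set.seed(seed)
  replicate(n_seq, {
    ks <- sample(n_pairs, 3, replace = TRUE)
    out <- 1L
    for (k in ks) out <- c(out, 3L + 2L * k, 4L + 2L * k, 2L)
    out
  }, simplify = FALSE)
}

test_that("MLM pre-training learns the planted co-occurrence rule", {
  n_pairs <- 8L
  seqs <- pairedCorpus(200L, n_pairs)
  enc <- initEncoder(encoderConfig(5L + 2L * n_pairs, d_model = 16L,
                                   n_heads = 2L, n_layers = 1L,
                                   max_len = 16L), seed = 51)
  enc2 <- pretrain(enc, seqs, trainConfig(lr = 2e-3, batch_size = 16L,
                                          max_epochs = 60L, mlm_prob = 0.3,
                                          seed = 52L))
  loss <- enc2@history$pretrain_loss
  # loss decreases in epoch-averaged trend
  expect_lt(mean(tail(loss, 5)), mean(head(loss, 5)))
  expect_lt(tail(loss, 1), head(loss, 1) * 0.5)

  # masked-token top-1 recovery on the deterministic rule
  set.seed(53)
  correct <- 0L
  for (r in 1:100) {
    k <- sample(n_pairs, 1)
    toks <- c(1L, 3L + 2L * k, 4L + 2L * k, 2L)
    masked <- toks
    masked[3] <- SPECIAL_TOKENS[["MASK"]]
    res <- mlmForward(enc2, masked, 3L, toks[3])
    correct <- correct + (which.max(res$log_scores[1, ]) - 1L == toks[3])
  }
  expect_gt(correct / 100, 0.9)

  # checkpoint reload gives identical scores on a fixed input
  p <- tempfile(fileext = ".rds")
  saveEncoder(enc2, p)
  enc3 <- loadEncoder(p)
  fixed <- seqs[[1]]
  expect_identical(mlmForward(enc3, fixed, 2L, fixed[2])$loss,
                   mlmForward(enc2, fixed, 2L, fixed[2])$loss)
  unlink(p)
})

test_that("finetuneCV produces exactly k folds with recomputable summaries", {
  set.seed(62)
  # tiny separable task: label = presence of token 5
  n <- 60L
  seqs <- lapply(1:n, function(i) {
    body <- sample(6:14, 4, replace = TRUE)
    if (i %% 2 == 0) body[2] <- 5L
    c(1L, body, 2L)
  })
  labels <- as.integer(seq_len(n) %% 2 == 0)
  enc <- initEncoder(encoderConfig(20L, d_model = 8L, n_heads = 2L,
                                   n_layers = 1L, max_len = 16L), seed = 63)
  folds <- anaa:::makeFolds(1:40, 5L, labels[1:40])
  rep_ <- finetuneCV(enc, seqs, labels, folds, seqs[41:60], labels[41:60],
                     NULL, trainConfig(lr = 2e-3, batch_size = 8L,
                                       max_epochs = 6L, patience = 2L,
                                       seed = 64L))
  expect_length(rep_@fold_auc, 5L)
  expect_equal(rep_@mean_auc, mean(rep_@fold_auc))
  expect_equal(rep_@sd_auc, sd(rep_@fold_auc))
  expect_identical(rep_@mode, "none")
  expect_true(all(rep_@fold_auc >= 0 & rep_@fold_auc <= 1))
})

test_that("fine-tuned inference is deterministic for every augmentation mode", {
  enc <- initEncoder(encoderConfig(20L, d_model = 8L, n_heads = 2L,
                                   n_layers = 1L, max_len = 16L), seed = 65)
  seqs <- lapply(1:10, function(i) c(1L, sample(5:14, 4, TRUE), 2L))
  for (aug in list(NULL, augConfig("RNA"), augConfig("ANAA", sigma_eh = 0.33),
                   baselineConfig("naive_mask"))) {
    s1 <- scoreSequences(enc, seqs, aug)
    s2 <- scoreSequences(enc, seqs, aug)
    expect_identical(s1, s2)
  }
  # and across save/load
  p <- tempfile(fileext = ".rds")
  saveEncoder(enc, p)
  enc2 <- loadEncoder(p)
  aug <- augConfig("ANAA", sigma_eh = 1.0)
  expect_identical(scoreSequences(enc2, seqs, aug),
                   scoreSequences(enc, seqs, aug))
  unlink(p)
})

test_that("stratified subsampling has the right sizes and tags", {
  set.seed(66)
  labels <- rep(c(0L, 1L), c(60, 20))
  for (fr in c(1, 0.5, 0.2)) {
    idx <- anaa:::strataSubsample(labels, fr, seed = 67L)
    expect_length(idx, round(fr * 60) + round(fr * 20))
    expect_identical(sum(labels[idx]), as.integer(round(fr * 20)))
  }
  # fraction 1.0 keeps every sample
  expect_setequal(anaa:::strataSubsample(labels, 1, 67L), 1:80)

  # one report per (fraction, mode), tagged
  enc <- initEncoder(encoderConfig(20L, d_model = 8L, n_heads = 2L,
                                   n_layers = 1L, max_len = 16L), seed = 68)
  seqs <- lapply(1:50, function(i) c(1L, sample(5:14, 3, TRUE), 2L))
  labels <- rep(c(0L, 1L), 25)
  reports <- subsampleExperiment(
    enc, seqs[1:40], labels[1:40], seqs[41:50], labels[41:50],
    augs = list(none = NULL, RNA = augConfig("RNA")),
    fractions = c(1, 0.5),
    cfg = trainConfig(max_epochs = 2L, batch_size = 8L, seed = 69L),
    k_folds = 2L)
  expect_length(reports, 4L)
  expect_identical(reports[["RNA@0.5"]]@fraction, 0.5)
  expect_identical(reports[["none@1"]]@mode, "none")
})
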