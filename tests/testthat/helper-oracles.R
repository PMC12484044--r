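# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: the convolution oracle is a literal
# nested sum over kernel cells, and the AUC oracle counts all
# positive/negative pairs.

# Brute-force zero-padded 2D convolution of the leading v x v block:
# out[i,j] = sum over kernel offsets (u,s) of w[u,s] * M[i-u, j-s].
bruteSmooth <- function(M, kern, v = nrow(M)) {
  k <- kernelSize(kern)
  off <- (-(k %/% 2)):(ceiling(k / 2) - 1L)
  w <- kernelWeights(kern)
  out <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(v)) for (j in seq_len(v)) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) {
      si <- i - off[a]
      sj <- j - off[b]
      if (si >= 1 && si <= v && sj >= 1 && sj <= v)
        acc <- acc + w[a, b] * M[si, sj]
    }
    out[i, j] <- acc
  }
  out
}

# All-pairs counting AUC with half-credit for ties.
allPairsAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Direct double-sum noise statistics over every entry of the valid block.
bruteNoiseParams <- function(M, v = nrow(M), denom = c("m2", "n")) {
  denom <- match.arg(denom)
  blk <- M[seq_len(v), seq_len(v), drop = FALSE]
  tot <- 0
  for (i in seq_len(v)) for (j in seq_len(v)) tot <- tot + blk[i, j]
  mu <- tot / (v * v)
  ss <- 0
  for (i in seq_len(v)) for (j in seq_len(v)) ss <- ss + (blk[i, j] - mu)^2
  D <- if (denom == "m2") v^2 - 1 else v - 1
  list(mu = mu, sigma = sqrt(ss / D))
}

# Random row-stochastic attention matrix (softmax of random logits).
randomAttention <- function(n) {
  S <- matrix(rnorm(n * n), n, n)
  E <- exp(S - apply(S, 1, max))
  AttentionMatrix(E / rowSums(E))
}

# Tiny deterministic trajectory fixture used by several tokenization tests.
toyTrajectory <- function() {
  list(patient_id = "toy1",
       visits = list(c("I10.1", "E11.9"), c("C09AA05")))
}

# Five-patient cohort with visit counts 3, 9, 10, 12, 40.
visitCountCohort <- function() {
  mk <- function(id, n) list(patient_id = id,
                             visits = replicate(n, "A001", simplify = FALSE))
  list(mk("p3", 3), mk("p9", 9), mk("p10", 10), mk("p12", 12), mk("p40", 40))
}

# Small reduced-scale benchmark world shared by the smoke training tests
# and the directional acceptance benchmark.
benchSpec <- function(seed) {
  cohortPreset("mdc_like", n_patients = 600L, n_diag = 150L, n_med = 30L,
               codes_per_visit = 3, seed = seed)
}

benchPrepare <- function(seed, max_len = 128L) {
  coh <- generateCohort(benchSpec(seed))
  vocab <- buildVocabulary(coh@patients, min_count = 3L)
  tok <- tokenizeCohort(coh@patients, vocab, target_codes = "I500",
                        min_visits = 1L, max_len = max_len)
  sp <- splitCohort(tok$tokens, splitSpec(seed = seed), tok$labels)
  list(coh = coh, vocab = vocab, tok = tok, sp = sp)
}
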