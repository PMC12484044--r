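# Adaptive noise statistics, kernel construction, smoothing, and the
# train/eval augmentation paths.

test_that("adaptive noise statistics match the direct double-sum oracle", {
  # row-stochastic mass forces mu = 1/n
  A4 <- randomAttention(4)
  expect_equal(computeNoiseParams(A4)@mu, 0.25, tolerance = 1e-12)

  # 4x4 identity: sum of squared deviations 3.0, / 15 = 0.2
  Aid <- AttentionMatrix(diag(4))
  np <- computeNoiseParams(Aid)
  oracle <- bruteNoiseParams(diag(4))
  expect_equal(np@mu, 0.25)
  expect_equal(np@sigma_gn, oracle$sigma)
  expect_equal(np@sigma_gn, sqrt(0.2), tolerance = 1e-9)

  # uniform matrix: zero deviations
  Au <- AttentionMatrix(matrix(1 / 6, 6, 6))
  expect_identical(computeNoiseParams(Au)@sigma_gn, 0)

  # as-printed denominator divides the same sum by (n - 1)
  cfg_p <- augConfig("RNA", variance_denominator = "as_printed")
  expect_equal(computeNoiseParams(Aid, cfg_p)@sigma_gn,
               bruteNoiseParams(diag(4), denom = "n")$sigma)

  # degenerate input
  expect_error(computeNoiseParams(AttentionMatrix(matrix(1, 1, 1))),
               "valid_len")
})

test_that("mu = 1/valid_len for every row-stochastic matrix", {
  set.seed(101)
  for (n in c(3, 5, 9, 16)) {
    for (r in 1:5) {
      A <- randomAttention(n)
      expect_equal(computeNoiseParams(A)@mu, 1 / n, tolerance = 1e-9)
    }
  }
})

test_that("two-point on/off matrices give mu = alpha and variance alpha(1-alpha)m/(m-1)", {
  set.seed(102)
  for (n in c(4, 8, 16)) {
    for (alpha in c(1 / n, 0.25, 0.5)) {
      m <- n * n
      k_on <- round(alpha * m)
      vals <- sample(c(rep(1, k_on), rep(0, m - k_on)))
      A <- AttentionMatrix(matrix(vals, n, n), check_stochastic = FALSE)
      np <- computeNoiseParams(A)
      a_real <- k_on / m
      expect_equal(np@mu, a_real)
      expect_equal(np@sigma_gn^2, a_real * (1 - a_real) * m / (m - 1),
                   tolerance = 1e-12)
    }
  }
})

test_that("kernel-size rule and kernel invariants hold", {
  expect_identical(kernelSize(buildKernel(1.0)), 6L)
  expect_identical(kernelSize(buildKernel(0.33)), 2L)

  k1 <- buildKernel(0.1, normalized = TRUE)
  expect_identical(kernelSize(k1), 1L)
  expect_equal(kernelWeights(k1), matrix(1, 1, 1))

  # normalized weights sum to 1; all weights positive
  for (s in c(0.33, 0.5, 1.0)) {
    kn <- buildKernel(s)
    expect_true(all(kernelWeights(kn) > 0))
    expect_equal(sum(kernelWeights(kn)), 1, tolerance = 1e-12)
  }

  # odd kernels are reflection-symmetric about the center
  k3 <- buildKernel(0.5)  # k = round(pi) = 3
  expect_identical(kernelSize(k3), 3L)
  w <- kernelWeights(k3)
  expect_equal(w, w[3:1, 3:1])

  # raw (unnormalized) weights follow the Gaussian density formula
  kr <- buildKernel(0.5, normalized = FALSE)
  wr <- kernelWeights(kr)
  expect_equal(wr[2, 2], 1 / (2 * pi * 0.25))
  expect_equal(wr[1, 2], exp(-0.5 * 1 / 0.25) / (2 * pi * 0.25))

  expect_error(buildKernel(0), "positive")
  expect_error(buildKernel(-1), "positive")
})

test_that("smoothing matches the brute-force nested-sum oracle", {
  set.seed(103)
  # delta at the center reproduces the kernel
  M <- matrix(0, 7, 7); M[4, 4] <- 1
  k3 <- buildKernel(0.5)
  out <- smoothAttention(M, k3)
  expect_equal(out[3:5, 3:5], kernelWeights(k3), ignore_attr = TRUE)

  # identity kernel
  kid <- buildKernel(0.1)
  R <- matrix(rnorm(36), 6, 6)
  expect_equal(smoothAttention(R, kid), R)

  # random instances incl. even kernels and valid_len < n
  for (r in 1:40) {
    n <- sample(3:12, 1)
    v <- sample(2:n, 1)
    kern <- buildKernel(runif(1, 0.05, 1.1),
                        normalized = sample(c(TRUE, FALSE), 1))
    M <- matrix(rnorm(n * n), n, n)
    M[seq_len(n) > v, ] <- 0; M[, seq_len(n) > v] <- 0
    got <- suppressWarnings(smoothAttention(M, kern, v))
    expect_lt(max(abs(got - bruteSmooth(M, kern, v))), 1e-10)
    # padding stays exactly zero
    if (v < n) expect_true(all(got[(v + 1):n, ] == 0))
  }

  # oversized kernel warns but proceeds
  expect_warning(smoothAttention(matrix(1 / 2, 2, 2), buildKernel(1.0)),
                 "heavy smoothing")
})

test_that("smoothing is a constant-preserving low-pass filter", {
  set.seed(104)
  # constant matrix: interior positions keep the constant
  kern <- buildKernel(0.5)  # size 3
  C <- matrix(0.37, 12, 12)
  out <- smoothAttention(C, kern)
  interior <- 4:9  # farther than size_k from every boundary
  expect_equal(out[interior, interior], C[interior, interior],
               tolerance = 1e-12)

  # max absolute second difference along rows never increases
  for (r in 1:20) {
    n <- sample(6:12, 1)
    M <- matrix(rnorm(n * n), n, n)
    kern <- buildKernel(runif(1, 0.4, 1.0))  # normalized, size >= 3
    S <- smoothAttention(M, kern)
    d2 <- function(X) max(abs(X[, -c(1, 2)] - 2 * X[, -c(1, n)] +
                                X[, -c(n - 1, n)]))
    expect_lte(d2(S), d2(M) + 1e-12)
  }
})

test_that("training path: mode algebra and seeded reproducibility", {
  set.seed(105)
  A <- randomAttention(6)

  # mode none is a bit-exact identity
  cfg0 <- augConfig("none")
  expect_identical(augmentTrain(A, cfg0), scores(A))

  # RNA with sigma forced to 0 (uniform matrix) collapses to A + mu
  Au <- AttentionMatrix(matrix(1 / 5, 5, 5))
  got <- augmentTrain(Au, augConfig("RNA"))
  expect_equal(got, matrix(1 / 5 + 1 / 5, 5, 5), tolerance = 1e-12)

  # ANAA under a fixed seed equals an independent replay of the sampling
  # procedure: draw the same normal matrix, add, convolve via the oracle
  cfg <- augConfig("ANAA", sigma_eh = 0.5)
  set.seed(42)
  got <- augmentTrain(A, cfg)
  np <- computeNoiseParams(A)
  set.seed(42)
  G <- matrix(rnorm(36, np@mu, np@sigma_gn), 6, 6)
  kern <- buildKernel(0.5)
  expect_lt(max(abs(got - bruteSmooth(scores(A) + G, kern, 6))), 1e-10)

  # fresh noise on every call
  set.seed(43)
  expect_false(identical(augmentTrain(A, cfg), augmentTrain(A, cfg)))

  # noise only touches the valid region
  Ap <- AttentionMatrix(rbind(cbind(scores(randomAttention(4)),
                                    matrix(0, 4, 2)), matrix(0, 2, 6)),
                        valid_len = 4)
  outp <- augmentTrain(Ap, augConfig("RNA"))
  expect_true(all(outp[5:6, ] == 0) && all(outp[, 5:6] == 0))
})

test_that("eval path is deterministic and reduces correctly", {
  A <- randomAttention(7)
  cfg <- augConfig("ANAA", sigma_eh = 1.0, training = FALSE)

  # repeated calls bit-identical (no random draw)
  expect_identical(augmentEval(A, cfg), augmentEval(A, cfg))

  # size-1 kernel reduces ANAA to the constant shift A + mu
  cfg1 <- augConfig("ANAA", sigma_eh = 0.1, training = FALSE)
  expect_equal(augmentEval(A, cfg1), scores(A) + 1 / 7, tolerance = 1e-12)

  # RNA eval path: A + mu, no smoothing
  cfgr <- augConfig("RNA", training = FALSE)
  expect_equal(augmentEval(A, cfgr), scores(A) + 1 / 7, tolerance = 1e-12)

  # 4x4 identity against the composed oracles
  Aid <- AttentionMatrix(diag(4))
  cfg2 <- augConfig("ANAA", sigma_eh = 0.33, training = FALSE)
  got <- augmentEval(Aid, cfg2)
  expect_lt(max(abs(got - bruteSmooth(diag(4) + 0.25, buildKernel(0.33), 4))),
            1e-10)

  # mode none identity on the eval path too
  expect_identical(augmentEval(A, augConfig("none", training = FALSE)),
                   scores(A))

  # wrong-path guards
  expect_error(augmentTrain(A, cfg), "training")
  expect_error(augmentEval(A, augConfig("ANAA")), "training")
})

test_that("AttentionMatrix validity enforces the pre-augmentation contract", {
  expect_error(AttentionMatrix(matrix(2, 3, 3)), "sum to 1|\\[0, 1\\]")
  bad <- matrix(0, 4, 4); bad[1:3, 1:3] <- diag(3); bad[4, 4] <- 0.5
  expect_error(AttentionMatrix(bad, valid_len = 3), "padded")
  ok <- matrix(0, 4, 4); ok[1:3, 1:3] <- diag(3)
  expect_s4_class(AttentionMatrix(ok, valid_len = 3), "AttentionMatrix")
})

test_that("kernel weights export as a readable plain-text matrix", {
  kern <- buildKernel(0.33)
  p <- tempfile(fileext = ".txt")
  exportKernel(kern, p)
  back <- as.matrix(read.table(p))
  expect_equal(unname(back), unname(kernelWeights(kern)), tolerance = 1e-12)
})
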