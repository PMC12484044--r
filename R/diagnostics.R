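# Attention-behavior diagnostics: per-head [0,1]-scaled score histograms,
# a polarization summary of the near-binary pattern, offset-vs-median
# receptive-field curves, and heatmap export.

#' Collect attention matrices from a model
#'
#' Runs the eval-path forward over a set of sequences and retains every
#' per-layer, per-head attention matrix together with its valid length.
#'
#' @param state an \linkS4class{EncoderState}.
#' @param sequences list of token-id vectors.
#' @param aug NULL for the raw attention, or an augmentation whose
#'   deterministic eval path is applied.
#' @return an attention sample: list with \code{matrices} (list of lists,
#'   one per sequence, named "layerL_headH"), \code{valid_len} (integer
#'   vector), and \code{augmented} flag.
#' @export
collectAttention <- function(state, sequences, aug = NULL) {
  aug <- evalAug(aug)
  mats <- vector("list", length(sequences))
  vl <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    out <- encForward(state, as.integer(sequences[[i]]), aug = aug,
                      training = FALSE, collect = TRUE)
    mats[[i]] <- out$attention
    vl[i] <- sum(sequences[[i]] != 0L)
  }
  list(matrices = mats, valid_len = vl, augmented = !is.null(aug))
}

poolHead <- function(sample, key) {
  unlist(lapply(seq_along(sample$matrices), function(i) {
    M <- sample$matrices[[i]][[key]]
    v <- sample$valid_len[i]
    as.vector(M[seq_len(v), seq_len(v)])
  }), use.names = FALSE)
}

#' Per-head scaled histograms and polarization index
#'
#' For each (layer, head), pools the valid attention scores across all
#' sequences, min-max scales them to [0, 1], and computes a fixed-bin
#' histogram plus the polarization index: the fraction of scaled scores
#' within \code{eps} of 0 or 1. Heads whose pooled scores are constant
#' (min = max) are flagged degenerate and their scaled value defined as 0.
#' The on-mass estimate \code{on_mass_alpha} is the fraction of scaled
#' scores >= 0.5.
#'
#' @param sample an attention sample from \code{\link{collectAttention}}.
#' @param bins number of histogram bins on [0, 1].
#' @param eps polarization tolerance around the extremes.
#' @return list with per-head \code{histograms} (masses summing to 1),
#'   \code{breaks}, \code{polarization}, \code{on_mass_alpha} and
#'   \code{degenerate} flags.
#' @export
scaledHistogram <- function(sample, bins = 50L, eps = 0.05) {
  if (length(sample$matrices) == 0L) stop("empty attention sample")
  keys <- names(sample$matrices[[1]])
  breaks <- seq(0, 1, length.out = bins + 1L)
  hists <- list(); pol <- numeric(0); alpha <- numeric(0); degen <- logical(0)
  for (key in keys) {
    x <- poolHead(sample, key)
    rng <- range(x)
    if (rng[1] == rng[2]) {
      sc <- rep(0, length(x))
      degen[key] <- TRUE
    } else {
      sc <- (x - rng[1]) / (rng[2] - rng[1])
      degen[key] <- FALSE
    }
    cnt <- hist(sc, breaks = breaks, plot = FALSE)$counts
    hists[[key]] <- cnt / sum(cnt)
    pol[key] <- mean(sc <= eps | sc >= 1 - eps)
    alpha[key] <- mean(sc >= 0.5)
  }
  list(histograms = hists, breaks = breaks, polarization = pol,
       on_mass_alpha = alpha, degenerate = degen, eps = eps)
}

#' Receptive-field curve: median attention by token offset
#'
#' Buckets every valid score A[i, j] by the offset i - j (positive =
#' attention to previous events, negative = subsequent) and returns the
#' median per bucket, pooled over heads and layers by default.
#'
#' @param sample an attention sample from \code{\link{collectAttention}}.
#' @param per_head also return a per-head table.
#' @return data.frame(offset, median, n); with \code{per_head}, a list
#'   with \code{pooled} and \code{per_head} tables.
#' @export
receptiveField <- function(sample, per_head = FALSE) {
  keys <- names(sample$matrices[[1]])
  gather <- function(keyset) {
    offs <- list(); vals <- list()
    for (i in seq_along(sample$matrices)) {
      v <- sample$valid_len[i]
      om <- outer(seq_len(v), seq_len(v), `-`)
      for (key in keyset) {
        M <- sample$matrices[[i]][[key]]
        offs[[length(offs) + 1L]] <- as.vector(om)
        vals[[length(vals) + 1L]] <- as.vector(M[seq_len(v), seq_len(v)])
      }
    }
    off <- unlist(offs); val <- unlist(vals)
    agg <- tapply(val, off, median)
    data.frame(offset = as.integer(names(agg)), median = as.numeric(agg),
               n = as.integer(table(off)), row.names = NULL)
  }
  pooled <- gather(keys)
  if (!per_head) return(pooled)
  list(pooled = pooled,
       per_head = lapply(setNames(keys, keys), function(k) gather(k)))
}

#' Export an attention heatmap
#'
#' Writes a min-max scaled heatmap of one matrix to a PNG, plus a JSON
#' sidecar (same path with ".json") recording the dimensions and the
#' scaling (matrix min -> 0, max -> 1).
#'
#' @param sample an attention sample from \code{\link{collectAttention}}.
#' @param index sequence index.
#' @param layer,head which matrix.
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
exportHeatmap <- function(sample, index, layer, head, path) {
  key <- sprintf("layer%d_head%d", layer, head)
  M <- sample$matrices[[index]][[key]]
  v <- sample$valid_len[index]
  M <- M[seq_len(v), seq_len(v), drop = FALSE]
  rng <- range(M)
  S <- if (rng[1] == rng[2]) M * 0 else (M - rng[1]) / (rng[2] - rng[1])
  grDevices::png(path, width = 480, height = 480)
  op <- graphics::par(mar = c(2, 2, 2, 1))
  # flip rows so row 1 is at the top, matching matrix orientation
  graphics::image(t(S[rev(seq_len(v)), , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), zlim = c(0, 1),
                  axes = FALSE, main = key)
  graphics::par(op)
  grDevices::dev.off()
  jsonlite::write_json(
    list(rows = v, cols = v, layer = layer, head = head,
         scale = list(min_maps_to = 0, max_maps_to = 1,
                      matrix_min = rng[1], matrix_max = rng[2])),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
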