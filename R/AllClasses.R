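#' @import methods
#' @importFrom stats rnorm rbinom rpois rnbinom runif median sd qlogis plogis setNames
#' @importFrom graphics hist
#' @importFrom utils head tail write.table
NULL

# ---- attention augmentation core -------------------------------------------

#' Per-head attention score matrix
#'
#' Holds one head's n x n post-softmax attention score matrix for one
#' sample, together with the number of non-padding positions. Before
#' augmentation each valid row is a probability distribution over the valid
#' columns; augmented matrices are returned as plain base matrices because
#' they are deliberately no longer row-stochastic.
#'
#' @slot scores numeric n x n matrix; entries outside the leading
#'   \code{valid_len} x \code{valid_len} block must be exactly zero.
#' @slot valid_len integer count of non-padding positions.
#' @export
setClass("AttentionMatrix",
  representation(scores = "matrix", valid_len = "integer"),
  validity = function(object) {
    s <- object@scores
    v <- object@valid_len
    if (nrow(s) != ncol(s)) return("scores must be square")
    if (length(v) != 1L || is.na(v) || v < 0L || v > nrow(s))
      return("valid_len must be a single integer in [0, n]")
    if (v < nrow(s)) {
      pad <- s
      if (v > 0L) pad[seq_len(v), seq_len(v)] <- 0
      if (any(pad != 0)) return("padded rows/columns must be exactly 0")
    }
    TRUE
  })

#' Construct an AttentionMatrix
#'
#' @param scores square numeric matrix of attention scores.
#' @param valid_len number of non-padding positions (defaults to n).
#' @param check_stochastic if TRUE (default), require the valid block to be
#'   row-stochastic within 1e-6 with entries in [0, 1] -- the contract for a
#'   softmax output. Set FALSE to wrap already-augmented scores.
#' @return an \code{AttentionMatrix}.
#' @export
AttentionMatrix <- function(scores, valid_len = nrow(scores),
                            check_stochastic = TRUE) {
  scores <- as.matrix(scores)
  valid_len <- as.integer(valid_len)
  obj <- new("AttentionMatrix", scores = scores, valid_len = valid_len)
  if (check_stochastic && valid_len > 0L) {
    blk <- scores[seq_len(valid_len), seq_len(valid_len), drop = FALSE]
    if (any(blk < 0) || any(blk > 1))
      stop("pre-augmentation attention scores must lie in [0, 1]")
    if (any(abs(rowSums(blk) - 1) > 1e-6))
      stop("pre-augmentation attention rows must sum to 1 within 1e-6")
  }
  obj
}

#' @describeIn AttentionMatrix-class the raw score matrix
#' @param x an AttentionMatrix
#' @export
scores <- function(x) x@scores

#' @describeIn AttentionMatrix-class number of valid (non-padding) positions
#' @export
validLen <- function(x) x@valid_len

setMethod("show", "AttentionMatrix", function(object) {
  cat(sprintf("AttentionMatrix: %d x %d (valid_len = %d)\n",
              nrow(object@scores), ncol(object@scores), object@valid_len))
})

#' Adaptive noise parameters for one (sample, head) attention matrix
#'
#' @slot mu mean attention score over the valid block.
#' @slot sigma_gn standard deviation of the valid scores (>= 0).
#' @slot scope identifier of the (sample, head) the statistics came from.
#' @export
setClass("NoiseParams",
  representation(mu = "numeric", sigma_gn = "numeric", scope = "character"),
  validity = function(object) {
    if (length(object@mu) != 1L || length(object@sigma_gn) != 1L)
      return("mu and sigma_gn must be scalars")
    if (object@sigma_gn < 0) return("sigma_gn must be >= 0")
    TRUE
  })

setMethod("show", "NoiseParams", function(object) {
  cat(sprintf("NoiseParams [%s]: mu = %.6g, sigma_gn = %.6g\n",
              object@scope, object@mu, object@sigma_gn))
})

#' Discrete 2D Gaussian smoothing kernel
#'
#' The side length follows the event-horizon rule k = round(2*pi*sigma_eh),
#' clamped to >= 1. Kernel support is centered: offsets run from
#' -floor(k/2) to ceil(k/2)-1, so even kernels anchor one cell up-left of
#' center rather than translating the map.
#'
#' @slot sigma_eh event-horizon width of the Gaussian (> 0).
#' @slot size_k integer side length.
#' @slot weights size_k x size_k positive weight matrix.
#' @slot normalized TRUE when the weights sum to 1.
#' @export
setClass("SmoothingKernel",
  representation(sigma_eh = "numeric", size_k = "integer",
                 weights = "matrix", normalized = "logical"),
  validity = function(object) {
    if (object@sigma_eh <= 0) return("sigma_eh must be > 0")
    if (object@size_k < 1L) return("size_k must be >= 1")
    if (any(object@weights <= 0)) return("all kernel weights must be > 0")
    if (object@normalized && abs(sum(object@weights) - 1) > 1e-12)
      return("normalized kernel must sum to 1 within 1e-12")
    TRUE
  })

#' @describeIn SmoothingKernel-class kernel side length
#' @param x a SmoothingKernel
#' @export
kernelSize <- function(x) x@size_k

#' @describeIn SmoothingKernel-class weight matrix
#' @export
kernelWeights <- function(x) x@weights

setMethod("show", "SmoothingKernel", function(object) {
  cat(sprintf("SmoothingKernel: sigma_eh = %g, size %d x %d, %s\n",
              object@sigma_eh, object@size_k, object@size_k,
              if (object@normalized) "normalized" else "raw"))
})

#' Augmentation configuration for the attention core
#'
#' @slot mode one of "none", "RNA", "ANAA".
#' @slot sigma_eh event-horizon width of the smoothing kernel.
#' @slot kernel_normalized whether the kernel is scaled to sum 1.
#' @slot variance_denominator "elements_minus_one" (default: divide the sum
#'   of squared deviations over the n^2 valid entries by n^2 - 1) or
#'   "as_printed" (divide by n - 1, the literal printed formula).
#' @slot training TRUE selects the stochastic path, FALSE the deterministic
#'   expected-value path.
#' @slot rng_seed integer seed for the noise stream.
#' @export
setClass("AugmentationConfig",
  representation(mode = "character", sigma_eh = "numeric",
                 kernel_normalized = "logical",
                 variance_denominator = "character",
                 training = "logical", rng_seed = "integer"),
  validity = function(object) {
    if (!object@mode %in% c("none", "RNA", "ANAA"))
      return("mode must be one of none, RNA, ANAA")
    if (!object@variance_denominator %in% c("elements_minus_one", "as_printed"))
      return("variance_denominator must be elements_minus_one or as_printed")
    if (object@mode == "ANAA" && object@sigma_eh <= 0)
      return("sigma_eh must be > 0 for ANAA")
    TRUE
  })

#' Construct an AugmentationConfig
#'
#' @param mode "none", "RNA" or "ANAA".
#' @param sigma_eh event-horizon width (used by ANAA).
#' @param kernel_normalized normalize kernel weights to sum 1.
#' @param variance_denominator see \linkS4class{AugmentationConfig}.
#' @param training stochastic training path vs deterministic eval path.
#' @param rng_seed seed for the noise stream.
#' @return an \code{AugmentationConfig}.
#' @export
augConfig <- function(mode = c("none", "RNA", "ANAA"), sigma_eh = 1.0,
                      kernel_normalized = TRUE,
                      variance_denominator = c("elements_minus_one",
                                               "as_printed"),
                      training = TRUE, rng_seed = 1L) {
  new("AugmentationConfig", mode = match.arg(mode), sigma_eh = sigma_eh,
      kernel_normalized = kernel_normalized,
      variance_denominator = match.arg(variance_denominator),
      training = training, rng_seed = as.integer(rng_seed))
}

setMethod("show", "AugmentationConfig", function(object) {
  cat(sprintf("AugmentationConfig: mode = %s, sigma_eh = %g, %s path\n",
              object@mode, object@sigma_eh,
              if (object@training) "training" else "eval"))
})

# ---- baseline augmentations -------------------------------------------------

#' Baseline augmentation configuration
#'
#' @slot kind one of "naive_mask", "drop_attention", "embed_noise",
#'   "ffn_noise".
#' @slot p masking probability in [0, 1].
#' @slot omega span length for DropAttention (>= 1).
#' @slot alpha_scale magnitude of calibrated uniform noise (>= 0).
#' @slot seed integer seed for the masking/noise stream.
#' @export
setClass("BaselineConfig",
  representation(kind = "character", p = "numeric", omega = "integer",
                 alpha_scale = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("naive_mask", "drop_attention",
                            "embed_noise", "ffn_noise"))
      return("unknown baseline kind")
    if (object@p < 0 || object@p > 1) return("p must be in [0, 1]")
    if (object@omega < 1L) return("omega must be >= 1")
    if (object@alpha_scale < 0) return("alpha_scale must be >= 0")
    TRUE
  })

#' Construct a BaselineConfig
#'
#' @param kind baseline family.
#' @param p masking probability (attention masking baselines).
#' @param omega DropAttention span length.
#' @param alpha_scale uniform-noise magnitude (embedding / feed-forward).
#' @param seed stream seed.
#' @return a \code{BaselineConfig}.
#' @export
baselineConfig <- function(kind = c("naive_mask", "drop_attention",
                                    "embed_noise", "ffn_noise"),
                           p = 0.2, omega = 1L, alpha_scale = 5,
                           seed = 1L) {
  new("BaselineConfig", kind = match.arg(kind), p = p,
      omega = as.integer(omega), alpha_scale = alpha_scale,
      seed = as.integer(seed))
}

# ---- encoder ----------------------------------------------------------------

#' Transformer encoder configuration
#'
#' @slot vocab_size number of token ids (including the 5 special tokens).
#' @slot d_model embedding width; must equal n_heads * d_v.
#' @slot n_heads number of attention heads.
#' @slot d_k,d_v per-head key/value widths.
#' @slot n_layers number of encoder blocks.
#' @slot max_len maximum tokenized sequence length.
#' @slot dropout dropout probability on sublayer outputs during training.
#' @export
setClass("EncoderConfig",
  representation(vocab_size = "integer", d_model = "integer",
                 n_heads = "integer", d_k = "integer", d_v = "integer",
                 n_layers = "integer", max_len = "integer",
                 dropout = "numeric"),
  validity = function(object) {
    if (object@d_model != object@n_heads * object@d_v)
      return("d_model must equal n_heads * d_v")
    if (object@vocab_size < 6L) return("vocab_size must cover special tokens")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must be in [0, 1)")
    TRUE
  })

#' Construct an EncoderConfig
#'
#' @param vocab_size vocabulary size including special tokens.
#' @param d_model model width (= n_heads * d_v).
#' @param n_heads attention heads per layer.
#' @param d_k,d_v key/value width per head (default d_model / n_heads).
#' @param n_layers encoder blocks.
#' @param max_len maximum sequence length.
#' @param dropout dropout probability.
#' @return an \code{EncoderConfig}.
#' @export
encoderConfig <- function(vocab_size, d_model = 64L, n_heads = 4L,
                          d_k = d_model %/% n_heads,
                          d_v = d_model %/% n_heads,
                          n_layers = 2L, max_len = 256L, dropout = 0) {
  new("EncoderConfig", vocab_size = as.integer(vocab_size),
      d_model = as.integer(d_model), n_heads = as.integer(n_heads),
      d_k = as.integer(d_k), d_v = as.integer(d_v),
      n_layers = as.integer(n_layers), max_len = as.integer(max_len),
      dropout = dropout)
}

setMethod("show", "EncoderConfig", function(object) {
  cat(sprintf(
    "EncoderConfig: vocab %d, d_model %d, %d heads x %d layers, max_len %d\n",
    object@vocab_size, object@d_model, object@n_heads, object@n_layers,
    object@max_len))
})

#' Encoder state: parameters plus bookkeeping
#'
#' @slot config the \linkS4class{EncoderConfig}.
#' @slot params named list of parameter matrices/vectors.
#' @slot mode "pretraining", "finetuning" or "inference".
#' @slot vocab_hash hash of the vocabulary the state was trained against.
#' @slot history named list of training logs.
#' @export
setClass("EncoderState",
  representation(config = "EncoderConfig", params = "list",
                 mode = "character", vocab_hash = "character",
                 history = "list"),
  validity = function(object) {
    if (!object@mode %in% c("pretraining", "finetuning", "inference"))
      return("mode must be pretraining, finetuning or inference")
    TRUE
  })

setMethod("show", "EncoderState", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("EncoderState (%s): %d parameters, vocab %d\n",
              object@mode, np, object@config@vocab_size))
})

#' @describeIn EncoderState-class total learnable parameter count
#' @param x an EncoderState
#' @export
parameterCount <- function(x) sum(vapply(x@params, length, integer(1)))

# ---- tokenization -----------------------------------------------------------

#' Code vocabulary with reserved special tokens
#'
#' Token ids are 0-based: [PAD]=0, [CLS]=1, [SEP]=2, [MASK]=3, [UNK]=4,
#' observed codes from 5 upward, ordered by (frequency desc, code asc).
#'
#' @slot index named integer vector mapping code -> id (codes only).
#' @slot freq named integer vector of code frequencies (all observed codes).
#' @slot min_count threshold used when the vocabulary was built.
#' @export
setClass("Vocabulary",
  representation(index = "integer", freq = "integer", min_count = "integer"),
  validity = function(object) {
    if (length(object@index) &&
        !identical(sort(unname(object@index)),
                   seq(5L, length.out = length(object@index))))
      return("code ids must be contiguous from 5")
    TRUE
  })

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d codes (+5 special tokens), min_count = %d\n",
              length(object@index), object@min_count))
})

#' @describeIn Vocabulary-class total number of token ids (codes + specials)
#' @param x a Vocabulary
#' @export
vocabSize <- function(x) length(x@index) + 5L

#' Train/finetune/test split specification
#'
#' @slot fractions numeric length 3 (pretrain, finetune, test), summing to 1.
#' @slot k_folds number of cross-validation folds over the fine-tuning set.
#' @slot seed split seed.
#' @export
setClass("SplitSpec",
  representation(fractions = "numeric", k_folds = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@fractions) != 3L ||
        abs(sum(object@fractions) - 1) > 1e-9)
      return("fractions must be length 3 and sum to 1")
    if (object@k_folds < 2L) return("k_folds must be >= 2")
    TRUE
  })

#' Construct a SplitSpec
#' @param fractions (pretrain, finetune, test) fractions.
#' @param k_folds number of folds over the fine-tuning set.
#' @param seed split seed.
#' @return a \code{SplitSpec}.
#' @export
splitSpec <- function(fractions = c(0.7, 0.2, 0.1), k_folds = 5L, seed = 1L) {
  new("SplitSpec", fractions = fractions, k_folds = as.integer(k_folds),
      seed = as.integer(seed))
}

# ---- synthetic cohorts ------------------------------------------------------

#' Synthetic cohort specification
#'
#' Motifs are ordered code pairs: a motif fires for a patient when code_a
#' occurs in some visit i and code_b in a later visit j with j - i >=
#' min_offset, contributing log_odds to the outcome logit.
#'
#' @slot n_patients cohort size.
#' @slot n_diag,n_med sizes of the diagnosis and medication code universes.
#' @slot visit_mean,visit_dispersion negative-binomial visit-count parameters.
#' @slot codes_per_visit mean codes per visit (>= 1).
#' @slot popularity_exponent power-law exponent of code popularity.
#' @slot motifs data.frame with columns code_a, code_b, min_offset,
#'   log_odds, plant_prob.
#' @slot base_rate baseline outcome probability in (0, 1).
#' @slot target_code outcome code appended after the history of positives.
#' @slot seed generation seed.
#' @export
setClass("CohortSpec",
  representation(n_patients = "integer", n_diag = "integer", n_med = "integer",
                 visit_mean = "numeric", visit_dispersion = "numeric",
                 codes_per_visit = "numeric", popularity_exponent = "numeric",
                 motifs = "data.frame", base_rate = "numeric",
                 target_code = "character", seed = "integer"),
  validity = function(object) {
    if (object@base_rate <= 0 || object@base_rate >= 1)
      return("base_rate must be in (0, 1)")
    if (object@codes_per_visit < 1)
      return("codes_per_visit must be >= 1")
    if (object@codes_per_visit > object@n_diag + object@n_med)
      return("codes_per_visit exceeds the code universe")
    if (nrow(object@motifs) &&
        !all(c("code_a", "code_b", "min_offset", "log_odds",
               "plant_prob") %in% names(object@motifs)))
      return("motifs must have code_a, code_b, min_offset, log_odds, plant_prob")
    if (nrow(object@motifs) && any(object@motifs$min_offset < 0))
      return("motif offsets must be >= 0")
    TRUE
  })

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d patients, vocab %d+%d, ~%.1f visits x ~%.1f codes, %d motif(s)\n",
    object@n_patients, object@n_diag, object@n_med, object@visit_mean,
    object@codes_per_visit, nrow(object@motifs)))
})

# ---- evaluation -------------------------------------------------------------

#' Cross-validated evaluation report
#'
#' @slot fold_auc per-fold test AUC.
#' @slot mean_auc,sd_auc summary over folds.
#' @slot curves per-fold validation AUC curves.
#' @slot mode augmentation mode label.
#' @slot fraction fine-tuning subsample fraction.
#' @export
setClass("EvalReport",
  representation(fold_auc = "numeric", mean_auc = "numeric",
                 sd_auc = "numeric", curves = "list", mode = "character",
                 fraction = "numeric"),
  validity = function(object) {
    ok <- object@fold_auc[!is.na(object@fold_auc)]
    if (length(ok) && (any(ok < 0) || any(ok > 1)))
      return("AUC values must lie in [0, 1]")
    TRUE
  })

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s, fraction %.2f]: AUC %.3f (sd %.3f) over %d folds\n",
              object@mode, object@fraction, object@mean_auc, object@sd_auc,
              length(object@fold_auc)))
})
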