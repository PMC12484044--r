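# Tokenization pipeline: code normalization, rare-code filtering,
# [CLS]/[SEP] sequence assembly, outcome labels with positive-case
# truncation, minimum-visit filtering and patient-level splitting.
#
# A patient trajectory is a plain list: list(patient_id = "p1",
# visits = list(c("I501", ...), ...)) with visits in temporal order; each
# visit is a character vector treated as a set of diagnosis/medication
# codes.

#' Special token ids (0-based)
#'
#' Fixed ordering for reproducibility: [PAD]=0, [CLS]=1, [SEP]=2, [MASK]=3,
#' [UNK]=4.
#' @export
SPECIAL_TOKENS <- c(PAD = 0L, CLS = 1L, SEP = 2L, MASK = 3L, UNK = 4L)

#' Normalize a medical code
#'
#' Removes dots, then keeps the first 4 characters ("I50.1" -> "I501",
#' "C09AA05" -> "C09A"); shorter codes are unchanged. Vectorized.
#'
#' @param code character vector of non-empty code strings.
#' @return normalized character vector.
#' @export
normalizeCode <- function(code) {
  if (!is.character(code) || any(is.na(code)) || any(!nzchar(code)))
    stop("codes must be non-empty strings")
  substr(gsub(".", "", code, fixed = TRUE), 1L, 4L)
}

#' Build a code vocabulary
#'
#' Counts normalized codes across all visits; codes seen fewer than
#' min_count times are left out of the index (they tokenize to [UNK]).
#' Index assignment is deterministic: frequency descending, then code
#' ascending, starting at id 5 after the reserved special tokens.
#'
#' @param cohort list of patient trajectories.
#' @param min_count minimum code frequency to enter the vocabulary.
#' @return a \linkS4class{Vocabulary}.
#' @export
buildVocabulary <- function(cohort, min_count = 5L) {
  codes <- normalizeCode(unlist(lapply(cohort, function(p)
    unlist(p$visits, use.names = FALSE)), use.names = FALSE))
  tab <- table(codes)
  freq <- as.integer(tab)
  names(freq) <- names(tab)
  keep <- freq[freq >= min_count]
  ord <- order(-keep, names(keep), method = "radix")
  kept <- keep[ord]
  idx <- seq(5L, length.out = length(kept))
  names(idx) <- names(kept)
  new("Vocabulary", index = idx, freq = freq,
      min_count = as.integer(min_count))
}

#' Tokenize one trajectory
#'
#' Emits [CLS], then each visit's normalized codes in lexicographic order
#' followed by [SEP]. Codes missing from the vocabulary map to [UNK]; an
#' empty visit emits a bare [SEP]. When the full sequence exceeds max_len
#' the most recent whole visits that fit are kept (always retaining
#' [CLS]); if even the most recent visit overflows, its most recent codes
#' are kept.
#'
#' @param traj a patient trajectory.
#' @param vocab a \linkS4class{Vocabulary}.
#' @param max_len maximum token count.
#' @return integer vector of 0-based token ids.
#' @export
buildSequence <- function(traj, vocab, max_len = 256L) {
  chunks <- lapply(traj$visits, function(vis) {
    if (length(vis) == 0L) return(SPECIAL_TOKENS[["SEP"]])
    codes <- sort(unique(normalizeCode(vis)), method = "radix")
    ids <- unname(vocab@index[codes])
    ids[is.na(ids)] <- SPECIAL_TOKENS[["UNK"]]
    c(as.integer(ids), SPECIAL_TOKENS[["SEP"]])
  })
  lens <- vapply(chunks, length, integer(1))
  total <- 1L + sum(lens)
  if (total > max_len) {
    budget <- max_len - 1L
    keep <- integer(0)
    for (j in rev(seq_along(chunks))) {
      if (lens[j] <= budget) {
        keep <- c(j, keep)
        budget <- budget - lens[j]
      } else {
        if (length(keep) == 0L) {
          # single over-long visit: keep its tail (most recent codes + SEP)
          chunks[[j]] <- tail(chunks[[j]], budget)
          keep <- j
        }
        break
      }
    }
    chunks <- chunks[keep]
  }
  c(SPECIAL_TOKENS[["CLS"]], unlist(chunks, use.names = FALSE))
}

#' Construct the outcome label with positive-case truncation
#'
#' Excluded codes (e.g. medications that treat the target condition) are
#' removed from every visit first. Then, if any visit contains a target
#' code, the trajectory is cut strictly before that first target visit and
#' labeled 1; otherwise the full trajectory is kept with label 0. Positives
#' whose very first visit carries the target have no usable history and
#' yield NULL (callers drop and count them).
#'
#' @param traj a patient trajectory.
#' @param target_codes non-empty character vector of normalized target
#'   codes.
#' @param excluded_codes normalized codes removed everywhere before target
#'   detection.
#' @return list(traj = truncated trajectory, label = 0/1), or NULL for a
#'   dropped zero-history positive.
#' @export
makeLabel <- function(traj, target_codes, excluded_codes = character()) {
  if (length(target_codes) == 0L) stop("target_codes must be non-empty")
  target_codes <- normalizeCode(target_codes)
  visits <- lapply(traj$visits, function(vis) {
    if (length(vis) == 0L) return(vis)
    vis[!(normalizeCode(vis) %in% excluded_codes)]
  })
  hit <- which(vapply(visits, function(vis)
    length(vis) > 0L && any(normalizeCode(vis) %in% target_codes),
    logical(1)))
  if (length(hit) == 0L) {
    traj$visits <- visits
    return(list(traj = traj, label = 0L))
  }
  first <- hit[1L]
  if (first == 1L) return(NULL)
  traj$visits <- visits[seq_len(first - 1L)]
  list(traj = traj, label = 1L)
}

#' Filter a cohort by minimum visit count
#'
#' Keeps patients whose (already label-truncated) trajectory has at least
#' \code{threshold} visits; "fewer than threshold" are excluded, so the
#' boundary is inclusive.
#'
#' @param cohort list of trajectories (or of makeLabel results).
#' @param threshold minimum number of visits.
#' @return the surviving subset of the cohort.
#' @export
filterMinVisits <- function(cohort, threshold) {
  nv <- vapply(cohort, function(p) {
    tr <- if (!is.null(p$traj)) p$traj else p
    length(tr$visits)
  }, integer(1))
  cohort[nv >= threshold]
}

#' Patient-level pretrain / finetune / test split with stratified folds
#'
#' Patients are shuffled with the split seed, partitioned into disjoint
#' pretrain / fine-tune / test sets by the given fractions, and the
#' fine-tune set is divided into label-stratified cross-validation folds.
#'
#' @param cohort list of patients.
#' @param spec a \linkS4class{SplitSpec}.
#' @param labels integer 0/1 vector (one per patient) used for fold
#'   stratification; without labels folds are unstratified.
#' @return list with integer index vectors \code{pretrain}, \code{finetune},
#'   \code{test}, and \code{folds} (list of k index vectors partitioning
#'   \code{finetune}).
#' @export
splitCohort <- function(cohort, spec = splitSpec(), labels = NULL) {
  n <- length(cohort)
  set.seed(spec@seed)
  perm <- sample.int(n)
  n_pre <- round(spec@fractions[1] * n)
  n_fin <- round(spec@fractions[2] * n)
  pretrain <- perm[seq_len(n_pre)]
  finetune <- perm[n_pre + seq_len(n_fin)]
  test <- perm[setdiff(seq_len(n), seq_len(n_pre + n_fin))]
  folds <- makeFolds(finetune, spec@k_folds,
                     if (is.null(labels)) NULL else labels[finetune])
  list(pretrain = pretrain, finetune = finetune, test = test, folds = folds)
}

# Round-robin fold assignment, stratified by label when given. Assumes the
# caller has already randomized patient order.
makeFolds <- function(idx, k, labels = NULL) {
  folds <- vector("list", k)
  assign_rr <- function(items) {
    for (i in seq_along(items)) {
      f <- ((i - 1L) %% k) + 1L
      folds[[f]] <<- c(folds[[f]], items[i])
    }
  }
  if (is.null(labels)) {
    assign_rr(idx)
  } else {
    assign_rr(idx[labels == 1L])
    assign_rr(idx[labels != 1L])
  }
  folds
}

#' Read / write cohorts as line-delimited JSON
#'
#' One patient per line: \code{{"patient_id": str, "visits": [{"codes":
#' [str, ...]}, ...], "label": 0/1}} (label optional).
#'
#' @param path file path.
#' @return \code{readCohortJSONL}: list of trajectories (with \code{label}
#'   fields when present). \code{writeCohortJSONL}: the path, invisibly.
#' @export
readCohortJSONL <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    p <- list(patient_id = x$patient_id,
              visits = lapply(x$visits, function(v)
                as.character(unlist(v$codes))))
    if (!is.null(x$label)) p$label <- as.integer(x$label)
    p
  })
}

#' @rdname readCohortJSONL
#' @param cohort list of trajectories; an optional \code{label} element per
#'   patient is carried through.
#' @export
writeCohortJSONL <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in cohort) {
    rec <- list(patient_id = p$patient_id,
                visits = lapply(p$visits, function(v) list(codes = as.list(v))))
    if (!is.null(p$label)) rec$label <- p$label
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Label and tokenize a cohort end-to-end
#'
#' Applies \code{\link{makeLabel}} (dropping zero-history positives), the
#' minimum-visit filter on the truncated trajectories, and
#' \code{\link{buildSequence}} against the vocabulary.
#'
#' @param cohort list of trajectories.
#' @param vocab a \linkS4class{Vocabulary}.
#' @param target_codes,excluded_codes passed to \code{\link{makeLabel}}.
#' @param min_visits minimum-visit threshold (applied post-truncation).
#' @param max_len maximum tokenized length.
#' @return list with \code{tokens} (list of id vectors), \code{labels}
#'   (integer vector), \code{patient_id} (character), and \code{n_dropped}
#'   (zero-history positives).
#' @export
tokenizeCohort <- function(cohort, vocab, target_codes,
                           excluded_codes = character(), min_visits = 1L,
                           max_len = 256L) {
  labeled <- lapply(cohort, makeLabel, target_codes = target_codes,
                    excluded_codes = excluded_codes)
  dropped <- sum(vapply(labeled, is.null, logical(1)))
  labeled <- Filter(Negate(is.null), labeled)
  labeled <- filterMinVisits(labeled, min_visits)
  list(tokens = lapply(labeled, function(x)
         buildSequence(x$traj, vocab, max_len)),
       labels = vapply(labeled, function(x) x$label, integer(1)),
       patient_id = vapply(labeled, function(x)
         as.character(x$traj$patient_id), character(1)),
       n_dropped = dropped)
}
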