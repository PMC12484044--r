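# Code normalization, vocabulary, sequence assembly, labels, filters,
# splits.

test_that("code normalization strips dots and keeps the first 4 characters", {
  expect_identical(normalizeCode("I50.1"), "I501")
  expect_identical(normalizeCode("A01"), "A01")
  expect_identical(normalizeCode("C09AA05"), "C09A")
  expect_identical(normalizeCode(c("E11.9", "N18")), c("E119", "N18"))
  expect_error(normalizeCode(""), "non-empty")
})

test_that("vocabulary building respects the frequency threshold and is deterministic", {
  coh <- list(
    list(patient_id = "a", visits = list(c("A001", "B002"), c("A001"))),
    list(patient_id = "b", visits = list(c("A001", "X999"), c("X999", "B002"))))
  v1 <- buildVocabulary(coh, min_count = 1L)
  expect_true(all(c("A001", "B002", "X999") %in% names(v1@index)))
  # contiguous ids from 5, frequency-desc then code-asc
  expect_identical(unname(v1@index[order(v1@index)][1]), 5L)
  expect_identical(names(which(v1@index == 5L)), "A001")  # freq 3

  v3 <- buildVocabulary(coh, min_count = 3L)
  expect_false("X999" %in% names(v3@index))  # freq 2 < 3 -> [UNK]
  expect_true("A001" %in% names(v3@index))

  v2 <- buildVocabulary(coh, min_count = 1L)
  expect_identical(v1@index, v2@index)
})

test_that("sequence assembly follows the [CLS] V1 [SEP] V2 [SEP] pattern", {
  coh <- list(list(patient_id = "a",
                   visits = list(c("A001", "B002"), "C003")))
  vocab <- buildVocabulary(coh, min_count = 1L)
  traj <- list(patient_id = "a", visits = list(c("B002", "A001"), "C003"))
  toks <- buildSequence(traj, vocab)
  ia <- vocab@index[["A001"]]; ib <- vocab@index[["B002"]]
  ic <- vocab@index[["C003"]]
  expect_identical(toks, c(1L, ia, ib, 2L, ic, 2L))  # within-visit sorted

  # empty visit emits a bare [SEP]
  traj2 <- list(patient_id = "a", visits = list(character(0), "C003"))
  expect_identical(buildSequence(traj2, vocab), c(1L, 2L, ic, 2L))

  # unknown codes map to [UNK]; count = 1 + sum(|V|) + O
  traj3 <- list(patient_id = "a", visits = list(c("ZZZZ", "A001"), "C003"))
  t3 <- buildSequence(traj3, vocab)
  expect_identical(length(t3), 1L + 3L + 2L)
  expect_true(4L %in% t3)

  # over-length keeps the most recent visits, retaining [CLS]
  long <- list(patient_id = "a",
               visits = rep(list(c("A001", "B002")), 10))
  tl <- buildSequence(long, vocab, max_len = 10L)
  expect_lte(length(tl), 10L)
  expect_identical(tl[1], 1L)
  expect_identical(tl[-1], rep(c(ia, ib, 2L), 3))
})

test_that("labels truncate strictly before the first target visit", {
  mk <- function(visits) list(patient_id = "p", visits = visits)
  # target in visit 5 of 8 -> label 1, visits 1-4 kept
  vis <- rep(list("A001"), 8); vis[[5]] <- c("A001", "I501")
  res <- makeLabel(mk(vis), "I501")
  expect_identical(res$label, 1L)
  expect_length(res$traj$visits, 4L)

  # no target -> label 0, everything kept
  res0 <- makeLabel(mk(rep(list("A001"), 8)), "I501")
  expect_identical(res0$label, 0L)
  expect_length(res0$traj$visits, 8L)

  # target in visit 1 -> dropped
  vis1 <- rep(list("A001"), 3); vis1[[1]] <- "I501"
  expect_null(makeLabel(mk(vis1), "I501"))

  # exclusion precedes detection: a target visible only through an
  # excluded code is removed first, leaving a negative
  vis2 <- list("A001", c("A001", "C09A"), "B002")
  res2 <- makeLabel(mk(vis2), target_codes = "C09A",
                    excluded_codes = "C09A")
  expect_identical(res2$label, 0L)
  expect_length(res2$traj$visits, 3L)
  expect_false(any(vapply(res2$traj$visits, function(v) "C09A" %in% v,
                          logical(1))))

  # dotted raw codes are normalized before matching
  vis3 <- list("A001", "I50.1")
  res3 <- makeLabel(mk(vis3), "I501")
  expect_identical(res3$label, 1L)
  expect_length(res3$traj$visits, 1L)
})

test_that("minimum-visit filter keeps >= threshold (boundary inclusive)", {
  coh <- visitCountCohort()  # visit counts 3, 9, 10, 12, 40
  kept <- filterMinVisits(coh, 10L)
  expect_length(kept, 3L)
  expect_identical(vapply(kept, function(p) p$patient_id, character(1)),
                   c("p10", "p12", "p40"))
})

test_that("patient-level splits are disjoint, sized and reproducible", {
  coh <- replicate(100, list(patient_id = "x", visits = list("A001")),
                   simplify = FALSE)
  labels <- rep(c(0L, 1L), 50)
  sp <- splitCohort(coh, splitSpec(seed = 3L), labels)
  expect_length(sp$pretrain, 70L)
  expect_length(sp$finetune, 20L)
  expect_length(sp$test, 10L)
  expect_length(intersect(sp$pretrain, sp$finetune), 0L)
  expect_length(intersect(sp$pretrain, sp$test), 0L)
  expect_length(intersect(sp$finetune, sp$test), 0L)
  # folds partition the finetune set
  expect_setequal(unlist(sp$folds), sp$finetune)
  expect_identical(anyDuplicated(unlist(sp$folds)), 0L)
  # label stratification spreads positives across folds
  per_fold_pos <- vapply(sp$folds, function(f) sum(labels[f]), integer(1))
  expect_lte(max(per_fold_pos) - min(per_fold_pos), 1L)
  # same seed twice -> identical assignment
  sp2 <- splitCohort(coh, splitSpec(seed = 3L), labels)
  expect_identical(sp, sp2)
})

test_that("cohorts round-trip through line-delimited JSON", {
  coh <- list(list(patient_id = "p1",
                   visits = list(c("I50.1", "A01"), "B002"), label = 1L),
              list(patient_id = "p2", visits = list("C09AA05")))
  p <- tempfile(fileext = ".jsonl")
  writeCohortJSONL(coh, p)
  back <- readCohortJSONL(p)
  expect_identical(back[[1]]$visits, coh[[1]]$visits)
  expect_identical(back[[1]]$label, 1L)
  expect_null(back[[2]]$label)
  unlink(p)
})

test_that("tokenizeCohort composes labeling, filtering and assembly; positives carry no target tokens", {
  set.seed(14)
  coh <- generateCohort(cohortSpec(n_patients = 120L, n_diag = 40L,
                                   n_med = 10L, visit_mean = 6,
                                   codes_per_visit = 2, seed = 21L))
  vocab <- buildVocabulary(coh@patients, min_count = 1L)
  tok <- tokenizeCohort(coh@patients, vocab, target_codes = "I500")
  tid <- vocab@index["I500"]
  for (i in which(tok$labels == 1L))
    expect_false(!is.na(tid) && tid %in% tok$tokens[[i]])
  # tokenization is a pure function
  tok2 <- tokenizeCohort(coh@patients, vocab, target_codes = "I500")
  expect_identical(tok$tokens, tok2$tokens)
})
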