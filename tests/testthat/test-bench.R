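# Benchmark scoring: decoys, TP-vs-EPQ curves, minimum error rate, and
# the bootstrap comparison of two methods.

toy_result <- function(hits, n_queries = 2, total_true = NULL) {
  if (is.null(total_true)) total_true <- sum(hits$label == "true_homolog")
  benchmark_result(hits, n_queries = n_queries,
                   total_true_pairs = total_true)
}

test_that("decoy construction counts, composition, and determinism", {
  db <- dplyr::bind_rows(lapply(1:10, function(i)
    aa_seqs(paste0("s", i), rand_residues(40, seed = i))))
  d1 <- make_decoys(db, copies = 5, seed = 2)
  expect_equal(nrow(d1), 50L)
  expect_identical(d1, make_decoys(db, copies = 5, seed = 2))
  src <- sub("_shuf[0-9]+$", "", d1$id)
  for (i in seq_len(nrow(d1))) {
    expect_equal(sort(strsplit(d1$seq[i], "")[[1]]),
                 sort(strsplit(db$seq[db$id == src[i]], "")[[1]]))
  }
})

test_that("EPQ values reproduce the false-positive arithmetic", {
  # 25 pooled false positives over 2521 queries is an EPQ of ~0.01
  hits <- tibble::tibble(query = "q1",
                         target = paste0("d", 1:25),
                         evalue = seq(1e-5, 1e-3, length.out = 25),
                         label = "false_hit")
  r <- benchmark_result(hits, n_queries = 2521, total_true_pairs = 0)
  curve <- tp_vs_epq(r)
  expect_equal(max(curve$epq), 25 / 2521)
  expect_equal(round(max(curve$epq), 4), 0.0099)
})

test_that("the ROC curve matches a hand threshold sweep on a toy pool", {
  hits <- tibble::tibble(
    query = "q",
    target = paste0("t", 1:6),
    evalue = c(1e-9, 1e-7, 1e-5, 1e-5, 1e-3, 1e-1),
    label = c("true_homolog", "false_hit", "true_homolog", "false_hit",
              "ambiguous", "true_homolog"))
  r <- toy_result(hits, n_queries = 2)
  curve <- tp_vs_epq(r)
  # hand enumeration over thresholds (ties at 1e-5 are one step):
  #  t<=1e-9: tp 1 fp 0 | 1e-7: tp 1 fp 1 | 1e-5: tp 2 fp 2 |
  #  1e-1: tp 3 fp 2 (ambiguous skipped)
  expect_equal(curve$fp, c(0L, 1L, 2L))
  expect_equal(curve$tp, c(1L, 1L, 3L))
  expect_equal(curve$epq, c(0, 0.5, 1))
  # tp is non-decreasing in epq
  expect_true(all(diff(curve$tp) >= 0))
  # grid read-off
  grid <- tp_vs_epq(r, epq_grid = c(0, 0.5, 1))
  expect_equal(grid$tp, c(1L, 1L, 3L))
})

test_that("all-true pools put every hit at EPQ zero", {
  hits <- tibble::tibble(query = "q", target = paste0("t", 1:4),
                         evalue = c(1e-8, 1e-6, 1e-4, 1e-2),
                         label = "true_homolog")
  curve <- tp_vs_epq(toy_result(hits))
  expect_equal(curve$epq, 0)
  expect_equal(curve$tp, 4L)
})

test_that("minimum error rate handles separation, crossing, and absence", {
  sep <- tibble::tibble(query = "q", target = paste0("t", 1:4),
                        evalue = c(1e-9, 1e-8, 1e-2, 1e-1),
                        label = c("true_homolog", "true_homolog",
                                  "false_hit", "false_hit"))
  expect_equal(min_error_rate(toy_result(sep)), 0L)

  crossed <- tibble::tibble(
    query = "q", target = paste0("t", 1:5),
    evalue = c(1e-10, 1e-8, 0.5, 1e-6, 1.0),
    label = c("true_homolog", "true_homolog", "true_homolog",
              "false_hit", "false_hit"))
  expect_equal(min_error_rate(toy_result(crossed, total_true = 3)), 1L)

  none <- benchmark_result(
    tibble::tibble(query = character(), target = character(),
                   evalue = numeric(), label = character()),
    n_queries = 5, total_true_pairs = 7)
  expect_equal(min_error_rate(none), 7L)

  # MER never exceeds the number of true pairs and ignores row order
  shuf <- crossed[sample(1:5), ]
  expect_equal(min_error_rate(toy_result(shuf, total_true = 3)), 1L)
  expect_lte(min_error_rate(toy_result(crossed, total_true = 3)), 3L)
})

test_that("bootstrap of identical results is a null interval", {
  hits <- tibble::tibble(
    query = rep(c("q1", "q2"), each = 3),
    target = paste0("t", 1:6),
    evalue = c(1e-8, 1e-6, 1e-2, 1e-7, 1e-5, 1e-1),
    label = rep(c("true_homolog", "true_homolog", "false_hit"), 2))
  a <- toy_result(hits, n_queries = 2)
  ci <- bootstrap_diff(a, a, reps = 200, epq = 0.5, seed = 5)
  expect_equal(ci$ci_low, 0)
  expect_equal(ci$ci_high, 0)
  expect_error(bootstrap_diff(a, a, reps = 50), "at least 100")
})

test_that("bootstrap keeps the middle conf*reps order statistics and
           detects strict domination", {
  set.seed(31)
  qs <- paste0("q", 1:12)
  mk <- function(tp_per_q) {
    rows <- lapply(qs, function(q) tibble::tibble(
      query = q,
      target = paste0(q, "_t", seq_len(tp_per_q)),
      evalue = 10^-(8:(9 - tp_per_q)),
      label = "true_homolog"))
    benchmark_result(dplyr::bind_rows(rows), n_queries = 12,
                     total_true_pairs = 12 * tp_per_q)
  }
  a <- mk(3); b <- mk(1)
  ci <- bootstrap_diff(a, b, reps = 1000, conf = 0.95, epq = 0.01,
                       seed = 7)
  # every query contributes +2, so every replicate differs by 24 exactly
  expect_equal(ci$ci_low, 24)
  expect_equal(ci$ci_high, 24)

  # a noisier domination: A adds one extra true hit on half the queries
  rows_b <- dplyr::bind_rows(lapply(qs, function(q) tibble::tibble(
    query = q, target = paste0(q, "_x"), evalue = 1e-8,
    label = "true_homolog")))
  extra <- dplyr::bind_rows(lapply(qs[1:6], function(q) tibble::tibble(
    query = q, target = paste0(q, "_y"), evalue = 1e-7,
    label = "true_homolog")))
  b2 <- benchmark_result(rows_b, 12, 24)
  a2 <- benchmark_result(dplyr::bind_rows(rows_b, extra), 12, 24)
  ci2 <- bootstrap_diff(a2, b2, reps = 500, conf = 0.95, epq = 0.01,
                        seed = 8)
  expect_gt(ci2$ci_low, 0)
  # widening the confidence cannot narrow the interval
  ci3 <- bootstrap_diff(a2, b2, reps = 500, conf = 0.5, epq = 0.01,
                        seed = 8)
  expect_gte(ci3$ci_low, ci2$ci_low)
  expect_lte(ci3$ci_high, ci2$ci_high)
})

test_that("label_hits marks unknown pairs ambiguous and autoplot works", {
  truth <- tibble::tibble(query = "q", target = "t1",
                          label = "true_homolog")
  hits <- tibble::tibble(query = "q", target = c("t1", "zzz"),
                         evalue = c(1e-8, 1e-2))
  lab <- label_hits(hits, truth)
  expect_equal(lab$label, c("true_homolog", "ambiguous"))
  curve <- tp_vs_epq(toy_result(lab))
  expect_s3_class(autoplot(curve), "ggplot")
})
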