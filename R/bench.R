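# Shuffled-decoy benchmark scoring: labeled hit pools, true positives
# versus errors per query, minimum error rate, and bootstrap comparison
# of two methods.  E-value thresholds are pooled (global) across queries;
# hits with equal E-values are processed as one threshold step; ambiguous
# pairs count toward neither truth class.

#' Make shuffled decoys for a database
#'
#' `copies` composition-preserving shuffles of each sequence, ids
#' suffixed `_shuf<k>`, grouped per source in input order; deterministic
#' under the seed.
#'
#' @param db Sequence tibble.
#' @param copies Shuffled copies per sequence (default 5).
#' @param seed Integer seed.
#' @return A tibble of `copies * nrow(db)` decoys.
#' @export
make_decoys <- function(db, copies = 5L, seed = 1) {
  stopifnot(copies >= 1)
  shuffle_sequences(db, seed = seed, copies = copies)
}

#' Pooled, labeled benchmark result
#'
#' @param hits Tibble with columns `query`, `target`, `evalue`, `label`
#'   (`true_homolog`, `false_hit`, or `ambiguous`); one best hit per
#'   (query, target) pair.
#' @param n_queries Number of search queries (EPQ denominator).
#' @param total_true_pairs Total annotated true homologous pairs.
#' @param queries Optional full query universe (defaults to the distinct
#'   queries among the hits); used by the bootstrap.
#' @return An object of class `bench_result`.
#' @export
benchmark_result <- function(hits, n_queries, total_true_pairs,
                             queries = NULL) {
  stopifnot(n_queries >= 1, total_true_pairs >= 0)
  bad <- setdiff(unique(hits$label),
                 c("true_homolog", "false_hit", "ambiguous"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  hits <- hits[!duplicated(hits[c("query", "target")]), , drop = FALSE]
  structure(list(hits = tibble::as_tibble(hits),
                 n_queries = as.integer(n_queries),
                 total_true_pairs = as.integer(total_true_pairs),
                 queries = queries %||% sort(unique(hits$query))),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat("<bench_result> ", nrow(x$hits), " labeled hits, ", x$n_queries,
      " queries, ", x$total_true_pairs, " true pairs\n", sep = "")
  invisible(x)
}

#' Label hits against a truth table
#'
#' @param hits Hit tibble with `query` and `target` columns.
#' @param truth Tibble `query`, `target`, `label`.
#' @return `hits` with a `label` column; pairs absent from the truth
#'   table are labeled `ambiguous`.
#' @export
label_hits <- function(hits, truth) {
  out <- dplyr::left_join(hits, truth, by = c("query", "target"))
  out$label[is.na(out$label)] <- "ambiguous"
  out
}

# Cumulative (fp, tp) counts over ascending pooled E-value thresholds,
# ambiguous hits skipped, ties collapsed to one step.
cum_counts <- function(hits) {
  h <- hits[hits$label != "ambiguous", , drop = FALSE]
  if (nrow(h) == 0)
    return(tibble::tibble(threshold = numeric(), fp = integer(),
                          tp = integer()))
  h |>
    dplyr::arrange(.data$evalue) |>
    dplyr::group_by(threshold = .data$evalue) |>
    dplyr::summarise(dfp = sum(.data$label == "false_hit"),
                     dtp = sum(.data$label == "true_homolog")) |>
    dplyr::mutate(fp = cumsum(.data$dfp), tp = cumsum(.data$dtp)) |>
    dplyr::select("threshold", "fp", "tp")
}

#' True positives versus errors per query
#'
#' Pools all labeled hits, sweeps the global E-value threshold, and
#' reports, for each false-positive count reached, the true-positive
#' count at the most permissive threshold attaining it.  EPQ is
#' `fp / n_queries`.
#'
#' @param result A `bench_result`.
#' @param epq_grid Optional EPQ values at which to read the curve; when
#'   given, returns one row per grid point with the TP count at a
#'   false-positive budget of `floor(epq * n_queries)`.
#' @return A tibble of ROC points: `epq`, `fp`, `tp` (class `roc_points`).
#' @export
tp_vs_epq <- function(result, epq_grid = NULL) {
  cc <- cum_counts(result$hits)
  curve <- cc |>
    dplyr::group_by(.data$fp) |>
    dplyr::summarise(tp = max(.data$tp)) |>
    dplyr::mutate(epq = .data$fp / result$n_queries) |>
    dplyr::select("epq", "fp", "tp")
  if (!is.null(epq_grid)) {
    curve <- tibble::tibble(
      epq = epq_grid,
      fp = vapply(epq_grid, function(g)
        as.integer(floor(g * result$n_queries + 1e-9)), 1L))
    curve$tp <- vapply(curve$fp, function(b) tp_at_budget(cc, b), 1L)
  }
  class(curve) <- c("roc_points", class(curve))
  curve
}

tp_at_budget <- function(cc, fp_budget) {
  ok <- cc$fp <= fp_budget
  if (!any(ok)) 0L else as.integer(max(cc$tp[ok]))
}

#' Minimum error rate
#'
#' Minimum, over all pooled E-value thresholds, of false positives plus
#' false negatives (`total_true_pairs - TP`).
#'
#' @param result A `bench_result`.
#' @return Integer error count; at most `total_true_pairs`.
#' @export
min_error_rate <- function(result) {
  cc <- cum_counts(result$hits)
  errs <- c(result$total_true_pairs,           # threshold below every hit
            cc$fp + (result$total_true_pairs - cc$tp))
  as.integer(min(errs))
}

#' Bootstrap comparison of two methods
#'
#' Resamples the query set with replacement `reps` times; each replicate
#' recomputes the TP count at the given EPQ for both results and records
#' the difference `TP_A - TP_B`.  The confidence interval is the middle
#' `conf * reps` order statistics.
#'
#' @param result_a,result_b `bench_result` objects sharing a query
#'   universe.
#' @param reps Number of bootstrap replicates (at least 100).
#' @param conf Confidence level.
#' @param epq Errors-per-query operating point.
#' @param seed Integer seed.
#' @return A one-row tibble: `ci_low`, `ci_high`, `mean_diff`, `epq`,
#'   `reps`, `conf`.
#' @export
bootstrap_diff <- function(result_a, result_b, reps = 1000, conf = 0.95,
                           epq = 0.01, seed = 1) {
  if (reps < 100) stop("need at least 100 bootstrap replicates")
  queries <- sort(unique(c(result_a$queries, result_b$queries)))
  nq <- max(result_a$n_queries, result_b$n_queries, length(queries))
  ha <- result_a$hits[result_a$hits$label != "ambiguous", , drop = FALSE]
  hb <- result_b$hits[result_b$hits$label != "ambiguous", , drop = FALSE]
  diffs <- with_seed(seed, vapply(seq_len(reps), function(r) {
    take <- table(sample(queries, nq, replace = TRUE))
    tp_boot(ha, take, epq, nq) - tp_boot(hb, take, epq, nq)
  }, 0))
  s <- sort(diffs)
  drop <- floor((reps - conf * reps) / 2)
  tibble::tibble(ci_low = s[drop + 1L], ci_high = s[reps - drop],
                 mean_diff = mean(diffs), epq = epq,
                 reps = as.integer(reps), conf = conf)
}

tp_boot <- function(hits, take, epq, nq) {
  mult <- as.integer(take[hits$query])
  mult[is.na(mult)] <- 0L
  h <- hits[rep(seq_len(nrow(hits)), mult), , drop = FALSE]
  cc <- cum_counts(h)
  tp_at_budget(cc, floor(epq * nq + 1e-9))
}

#' Plot a TP-versus-EPQ curve
#'
#' @param object A `roc_points` tibble from [tp_vs_epq()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_points <- function(object, ...) {
  d <- object[object$epq > 0, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epq, y = .data$tp)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "errors per query", y = "true positives",
                  title = "True positives vs errors per query") +
    ggplot2::theme_minimal()
}
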