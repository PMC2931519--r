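# The four-stage acceleration sieve applied per database sequence before
# full scoring: (1) significant 4-residue word scan via a table-driven
# DFA, (2) ungapped diagonal extension with the delta/2 drop-off rule and
# the mu qualification threshold, (3) the two-hit rule, (4) a windowed
# Viterbi gate at eta.  Thresholds are in bits; strict inequalities at
# theta, mu, and eta; -Inf disables a stage.

#' Filter parameters
#'
#' Control surface of the acceleration sieve.  Defaults are the tuned
#' operating point theta = 6, delta = 2, mu = 7, eta = 20 (bits).
#'
#' @param theta Word-score threshold, bits (words must score strictly
#'   above it).
#' @param delta Extension drop-off parameter, bits; extension stops once
#'   the running score falls `delta/2` below the best observed.
#' @param mu Extended-hit qualification threshold, bits (strict).
#' @param eta Windowed-Viterbi gate threshold, bits (strict); `-Inf`
#'   always passes.
#' @param word_len Word length; fixed at 4.
#' @param merge_overlaps Merge overlapping same-diagonal extended hits
#'   before the two-hit count?
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(theta = 6, delta = 2, mu = 7, eta = 20,
                          word_len = 4L, merge_overlaps = TRUE) {
  if (word_len != 4L) stop("word length is fixed at 4")
  structure(list(theta = theta, delta = delta, mu = mu, eta = eta,
                 word_len = 4L, merge_overlaps = merge_overlaps),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat("<filter_params> theta =", x$theta, "| delta =", x$delta,
      "| mu =", x$mu, "| eta =", x$eta, "bits\n")
  invisible(x)
}

#' Enumerate significant words of a model
#'
#' All (model position, 4-mer) pairs whose summed match emission bit
#' score is strictly above `theta`.  Words are anchored: the same string
#' at a different model start is a distinct word.
#'
#' @param model A `profile_hmm` with at least 4 match states.
#' @param theta Word-score threshold in bits; `-Inf` enumerates all
#'   `(M-3) * 20^4` words.
#' @return A tibble with `model_start` (0-based), `word`, `score`.
#' @export
enumerate_words <- function(model, theta = 6) {
  if (model$M < 4) stop("model has fewer than 4 match states")
  r <- cpp_enum_words(model$msc, theta)
  word <- if (length(r$model_start)) {
    m <- matrix(AA[r$codes + 1L], ncol = 4)
    paste0(m[, 1], m[, 2], m[, 3], m[, 4])
  } else character()
  tibble::tibble(model_start = as.integer(r$model_start), word = word,
                 score = as.numeric(r$score))
}

#' Compile words into a scanning automaton
#'
#' Builds the table-driven deterministic finite automaton that reports
#' every occurrence of every word (with its model anchor) in one
#' left-to-right pass over a sequence.
#'
#' @param words Word tibble from [enumerate_words()].
#' @return An object of class `word_automaton`.
#' @export
word_automaton <- function(words) {
  codes <- if (nrow(words)) {
    m <- do.call(rbind, strsplit(words$word, ""))
    matrix(match(m, AA) - 1L, ncol = 4)
  } else matrix(integer(), 0, 4)
  ptr <- cpp_build_automaton(as.integer(words$model_start), codes)
  structure(list(ptr = ptr, n_words = nrow(words)),
            class = "word_automaton")
}

#' @export
print.word_automaton <- function(x, ...) {
  cat("<word_automaton>", x$n_words, "anchored 4-mers\n")
  invisible(x)
}

#' Scan a sequence for word occurrences
#'
#' @param automaton A `word_automaton`.
#' @param seq Residue string or one-row sequence tibble.
#' @return A tibble of word hits: `seq_start`, `model_start` (0-based),
#'   `diagonal = seq_start - model_start`, sorted by `seq_start` then
#'   `model_start`.
#' @export
scan_words <- function(automaton, seq) {
  codes <- encode_seq(as_residues(seq))
  m <- cpp_scan(automaton$ptr, codes)
  out <- tibble::tibble(seq_start = m[, 1], model_start = m[, 2])
  out$diagonal <- out$seq_start - out$model_start
  dplyr::arrange(out, .data$seq_start, .data$model_start)
}

#' Extend a word hit along its diagonal
#'
#' Ungapped extension of the 4-residue seed: leftward one (residue, match
#' state) pair at a time, accumulating match emission scores, stopping
#' when the running score drops `delta/2` below the best observed or a
#' boundary is reached, keeping the best endpoint; then rightward.
#'
#' @param model A `profile_hmm`.
#' @param seq Residue string or one-row sequence tibble.
#' @param hit One word hit (list or one-row tibble with `seq_start`,
#'   `model_start`).
#' @param delta Drop-off parameter in bits.
#' @return A one-row tibble: `seq_start`, `seq_end`, `model_start`,
#'   `model_end` (half-open), `score`, and the seed coordinates.
#' @export
extend_word_hit <- function(model, seq, hit, delta = 2) {
  codes <- encode_seq(as_residues(seq))
  v <- cpp_extend(model$msc, codes, as.integer(hit$seq_start[1]),
                  as.integer(hit$model_start[1]), delta)
  tibble::tibble(seq_start = as.integer(v[1]), seq_end = as.integer(v[2]),
                 model_start = as.integer(v[3]), model_end = as.integer(v[4]),
                 score = v[5],
                 seed_seq_start = as.integer(hit$seq_start[1]),
                 seed_model_start = as.integer(hit$model_start[1]))
}

#' Qualify extended hits at the mu threshold
#'
#' Keeps hits scoring strictly above `mu`, then (by default) merges
#' duplicates that share a diagonal and overlap in sequence interval,
#' keeping the highest-scoring representative — adjacent overlapping
#' words from one ungapped segment should not satisfy the two-hit rule on
#' their own.
#'
#' @param hits Extended-hit tibble (from [extend_word_hit()]).
#' @param mu Qualification threshold, bits.
#' @param merge_overlaps Merge overlapping same-diagonal hits?
#' @return The qualified hit tibble.
#' @export
qualify_hits <- function(hits, mu = 7, merge_overlaps = TRUE) {
  keep <- hits[hits$score > mu, , drop = FALSE]
  if (!merge_overlaps || nrow(keep) < 2) return(keep)
  keep$diagonal <- keep$seq_start - keep$model_start
  out <- keep |>
    dplyr::group_by(.data$diagonal) |>
    dplyr::arrange(.data$seq_start, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(
      .data$seq_start >= dplyr::lag(cummax(.data$seq_end),
                                    default = -1L))) |>
    dplyr::group_by(.data$diagonal, .data$cluster) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$seq_start, .data$model_start)
  out$diagonal <- NULL
  out$cluster <- NULL
  out
}

#' Two-hit rule
#'
#' @param qualified Qualified extended-hit tibble (post-merge).
#' @return `TRUE` iff at least two hits remain.
#' @export
two_hit <- function(qualified) nrow(qualified) >= 2

#' Windowed Viterbi gate
#'
#' Gapped Viterbi alignment restricted to the region spanned by the
#' qualified extended hits (inclusive span in both sequence and model
#' coordinates); the sequence advances iff the windowed score is strictly
#' greater than `eta`.
#'
#' @param model A `profile_hmm`.
#' @param seq Residue string or one-row sequence tibble.
#' @param qualified Qualified extended-hit tibble with at least two rows.
#' @param eta Gate threshold, bits; `-Inf` always passes.
#' @return A list with `pass` (logical) and `score` (bits).
#' @export
window_gate <- function(model, seq, qualified, eta = 20) {
  stopifnot(nrow(qualified) >= 2)
  sw <- c(min(qualified$seq_start), max(qualified$seq_end))
  mw <- c(min(qualified$model_start), max(qualified$model_end))
  score <- viterbi_window(model, seq, sw, mw)
  list(pass = is.infinite(eta) && eta < 0 || score > eta, score = score)
}

#' Run the full filter cascade on one sequence
#'
#' Stages are applied in order — word scan, extension and qualification,
#' two-hit rule, windowed Viterbi gate — short-circuiting at the first
#' failure.  Models with fewer than 4 match states bypass the filter
#' (outcome `"passed"`, no window score): no 4-residue words exist, so
#' the filter must never discard for them.
#'
#' @param model A `profile_hmm`.
#' @param seq Residue string or one-row sequence tibble.
#' @param params A `filter_params` object.
#' @param automaton Optional precompiled `word_automaton` for
#'   `params$theta` (built on the fly otherwise).
#' @return A list of class `filter_outcome`: `stage_reached` in
#'   `no_words`, `one_hit`, `window_fail`, `passed`; `qualified_hits`;
#'   `window_score` (NA unless the gate ran).
#' @export
filter_sequence <- function(model, seq, params = filter_params(),
                            automaton = NULL) {
  if (model$M < 4)
    return(new_filter_outcome("passed", empty_exthits(), NA_real_))
  if (is.null(automaton))
    automaton <- word_automaton(enumerate_words(model, params$theta))
  codes <- encode_seq(as_residues(seq))
  p <- model_parts(model)
  r <- cpp_filter_cascade(p$msc, p$isc, p$tsc, p$entry, p$exit,
                          automaton$ptr, codes, params$delta, params$mu,
                          params$eta, params$merge_overlaps)
  stage <- c("no_words", "one_hit", "window_fail", "passed")[r$stage + 1L]
  hits <- if (is.null(r$hits)) empty_exthits() else
    tibble::tibble(seq_start = as.integer(r$hits[, 1]),
                   seq_end = as.integer(r$hits[, 2]),
                   model_start = as.integer(r$hits[, 3]),
                   model_end = as.integer(r$hits[, 4]),
                   score = r$hits[, 5])
  new_filter_outcome(stage, hits, r$window_score)
}

new_filter_outcome <- function(stage, hits, ws) {
  structure(list(stage_reached = stage, qualified_hits = hits,
                 window_score = ws), class = "filter_outcome")
}

empty_exthits <- function() {
  tibble::tibble(seq_start = integer(), seq_end = integer(),
                 model_start = integer(), model_end = integer(),
                 score = numeric(), seed_seq_start = integer(),
                 seed_model_start = integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Search a sequence database with a profile HMM
#'
#' Applies the acceleration sieve per sequence (unless `filter = FALSE`),
#' fully scores survivors with the chosen final algorithm, and converts
#' scores to E-values with the model's calibration.  The filter only
#' selects — it never rescores — so every filtered-in sequence carries
#' exactly the score and E-value an unfiltered run would report.
#'
#' @param db Sequence tibble (the database).
#' @param model A calibrated `profile_hmm`.
#' @param params A `filter_params` object.
#' @param final Final scoring algorithm, `"viterbi"` or `"forward"`.
#' @param e_cutoff Report hits with E-value at or below this.
#' @param filter Apply the sieve?  `FALSE` fully scores every sequence.
#' @return A tibble of hits (class `hmm_hits`) sorted by E-value:
#'   `query`, `target`, `bits`, `evalue`, `seq_start`, `seq_end`,
#'   `model_start`, `model_end` (alignment envelope, 0-based half-open).
#'   Filter-stage counts are attached as the `"stats"` attribute (see
#'   [filter_stats()]).
#' @export
hmm_search <- function(db, model, params = filter_params(),
                       final = c("viterbi", "forward"), e_cutoff = 10,
                       filter = TRUE) {
  final <- match.arg(final)
  evd <- model_evd(model, final)
  n <- nrow(db)
  use_filter <- filter && model$M >= 4
  automaton <- if (use_filter)
    word_automaton(enumerate_words(model, params$theta))
  p <- model_parts(model)
  codes <- lapply(db$seq, encode_seq)
  stages <- rep("passed", n)
  if (use_filter) {
    stage_names <- c("no_words", "one_hit", "window_fail", "passed")
    for (i in seq_len(n)) {
      r <- cpp_filter_cascade(p$msc, p$isc, p$tsc, p$entry, p$exit,
                              automaton$ptr, codes[[i]], params$delta,
                              params$mu, params$eta, params$merge_overlaps)
      stages[i] <- stage_names[r$stage + 1L]
    }
  }
  scored <- which(stages == "passed")
  bits <- cpp_score_many(p$msc, p$isc, p$tsc, p$entry, p$exit,
                         codes[scored], if (final == "viterbi") 0L else 1L)
  ev <- evalue(bits, evd, n)
  keep <- which(ev <= e_cutoff)
  rows <- lapply(keep, function(j) {
    i <- scored[j]
    vt <- cpp_viterbi(p$msc, p$isc, p$tsc, p$entry, p$exit, codes[[i]],
                      0L, length(codes[[i]]), 0L, model$M, TRUE)
    tr <- vt$trace
    consumed <- tr[, 1] %in% c(1L, 2L)   # M and I rows consume residues
    mrows <- tr[, 1] == 1L
    tibble::tibble(
      query = model$name, target = db$id[i], bits = bits[j],
      evalue = ev[j],
      seq_start = min(tr[consumed, 3]),
      seq_end = max(tr[consumed, 3]) + 1L,
      model_start = min(tr[mrows, 2]),
      model_end = max(tr[mrows, 2]) + 1L)
  })
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits)) hits <- dplyr::arrange(hits, .data$evalue)
  else hits <- tibble::tibble(query = character(), target = character(),
                              bits = numeric(), evalue = numeric(),
                              seq_start = integer(), seq_end = integer(),
                              model_start = integer(), model_end = integer())
  stats <- tibble::tibble(
    sequences_total = n,
    with_word_hits = if (use_filter) sum(stages != "no_words") else n,
    with_two_hits = if (use_filter)
      sum(stages %in% c("window_fail", "passed")) else n,
    passed_window = sum(stages == "passed"),
    fully_scored = sum(stages == "passed"))
  attr(hits, "stats") <- stats
  attr(hits, "model_name") <- model$name
  attr(hits, "final") <- final
  class(hits) <- c("hmm_hits", class(hits))
  hits
}

#' Filter cascade statistics of a search
#'
#' @param hits An `hmm_hits` tibble from [hmm_search()].
#' @return A one-row tibble: `sequences_total`, `with_word_hits`,
#'   `with_two_hits`, `passed_window`, `fully_scored`.
#' @export
filter_stats <- function(hits) attr(hits, "stats")

#' @rdname tidy
#' @description `glance.hmm_hits()` summarises a search: hit count and
#'   the filter cascade counts.
#' @export
glance.hmm_hits <- function(x, ...) {
  dplyr::mutate(filter_stats(x), n_hits = nrow(x), .before = 1)
}

#' Plot the filter cascade of a search
#'
#' Bar chart of sequence counts surviving each filter stage.
#'
#' @param object An `hmm_hits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hmm_hits <- function(object, ...) {
  s <- filter_stats(object)
  d <- tibble::tibble(
    stage = factor(c("database", "word hits", "two hits", "window pass",
                     "fully scored"),
                   levels = c("database", "word hits", "two hits",
                              "window pass", "fully scored")),
    n = c(s$sequences_total, s$with_word_hits, s$with_two_hits,
          s$passed_window, s$fully_scored))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "sequences (log scale)",
                  title = "Acceleration filter cascade") +
    ggplot2::theme_minimal()
}
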