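# The four-stage acceleration sieve: word enumeration, DFA scan,
# diagonal extension, qualification/merging, two-hit rule, window gate,
# and the search driver's score-identity contract.

test_that("word enumeration matches 20^4 brute force on a small model", {
  m <- rand_profile(6, seed = 41)
  got <- enumerate_words(m, theta = 6)
  # brute force: all 160k words at each of the 3 anchors via outer sums
  want <- list()
  for (k in 1:3) {
    sc <- outer(outer(outer(m$msc[k, ], m$msc[k + 1, ], "+"),
                      m$msc[k + 2, ], "+"), m$msc[k + 3, ], "+")
    idx <- which(sc > 6, arr.ind = TRUE)
    if (nrow(idx)) {
      want[[k]] <- data.frame(
        model_start = k - 1L,
        word = paste0(AA20[idx[, 1]], AA20[idx[, 2]],
                      AA20[idx[, 3]], AA20[idx[, 4]]),
        score = sc[idx])
    }
  }
  want <- do.call(rbind, want)
  want <- want[order(want$model_start, want$word), ]
  got <- got[order(got$model_start, got$word), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$model_start, want$model_start)
  expect_equal(got$word, want$word)
  expect_equal(got$score, want$score, tolerance = 1e-9)
})

test_that("word enumeration boundary cases", {
  # all match scores zero: no word can clear a positive threshold
  bg <- amino_background()
  flat <- matrix(rep(bg$freq, each = 6), 6, 20,
                 dimnames = list(NULL, AA20))
  m <- rand_profile(6, seed = 42)
  m$mat_emis <- flat
  m$msc <- log2(sweep(flat, 2, bg$freq, "/"))   # all zeros
  expect_equal(nrow(enumerate_words(m, 6)), 0L)
  # theta = -Inf enumerates (M-3) * 20^4 words
  m5 <- rand_profile(5, seed = 43)
  expect_equal(nrow(enumerate_words(m5, -Inf)), 2L * 20^4)
  expect_error(enumerate_words(rand_profile(3, seed = 1), 6), "fewer than 4")
})

test_that("automaton scan equals the naive multi-word scan", {
  # hand case: overlapping words both reported
  words <- tibble::tibble(model_start = c(0L, 1L),
                          word = c("ACDE", "CDEF"), score = c(9, 9))
  aut <- word_automaton(words)
  hits <- scan_words(aut, "ACDEF")
  expect_equal(hits$seq_start, c(0L, 1L))
  expect_equal(hits$model_start, c(0L, 1L))
  expect_equal(hits$diagonal, c(0L, 0L))

  # random 50-word set on a random 10kb text
  set.seed(44)
  words <- tibble::tibble(
    model_start = sample(0:30, 50, replace = TRUE),
    word = vapply(1:50, function(i)
      paste(sample(AA20[1:6], 4, replace = TRUE), collapse = ""), ""),
    score = 8)
  words <- words[!duplicated(words[c("model_start", "word")]), ]
  txt <- rand_residues(10000, seed = 45, letters = AA20[1:6])
  got <- scan_words(word_automaton(words), txt)
  want <- naive_scan(words, txt)
  expect_gt(nrow(want), 0)
  expect_equal(as.data.frame(got[c("seq_start", "model_start")]), want)

  # empty word list matches nothing
  none <- word_automaton(words[0, ])
  expect_equal(nrow(scan_words(none, txt)), 0L)
})

test_that("extension stops on drop-off and at boundaries", {
  m <- rand_profile(12, seed = 46)
  # flanks all strongly negative: the hit is the word itself
  m$msc[, ] <- -10
  m$msc[5:8, "A"] <- 3
  s <- paste(rep("A", 20), collapse = "")
  h <- extend_word_hit(m, s, list(seq_start = 8, model_start = 4), delta = 2)
  expect_equal(h$seq_start, 8L)
  expect_equal(h$seq_end, 12L)
  expect_equal(h$score, 12, tolerance = 1e-9)

  # flanks all positive: extension runs to the nearer boundary
  m$msc[, "A"] <- 1
  h2 <- extend_word_hit(m, s, list(seq_start = 8, model_start = 4), delta = 2)
  expect_equal(h2$model_start, 0L)   # model start is the nearer left bound
  expect_equal(h2$seq_start, 4L)
  expect_equal(h2$model_end, 12L)
  expect_equal(h2$seq_end, 16L)
  expect_equal(h2$score, 12, tolerance = 1e-9)
})

test_that("extension equals direct simulation of the drop-off rule", {
  for (i in 1:60) {
    m <- rand_profile(12, seed = 4000 + i)
    s <- rand_residues(30, seed = 5000 + i)
    seq_start <- sample(0:26, 1)
    model_start <- sample(0:8, 1)
    delta <- sample(c(1, 2, 4), 1)
    got <- extend_word_hit(m, s, list(seq_start = seq_start,
                                      model_start = model_start), delta)
    want <- oracle_extend(m, s, seq_start, model_start, delta)
    expect_equal(got$seq_start, want$seq_start)
    expect_equal(got$seq_end, want$seq_end)
    expect_equal(got$model_start, want$model_start)
    expect_equal(got$model_end, want$model_end)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

ext_hits <- function(ss, se, ks, ke, score) {
  tibble::tibble(seq_start = as.integer(ss), seq_end = as.integer(se),
                 model_start = as.integer(ks), model_end = as.integer(ke),
                 score = score)
}

test_that("qualification is strict and merges overlapping same-diagonal
           hits", {
  h <- ext_hits(c(0, 10, 20), c(8, 18, 28), c(0, 10, 20), c(8, 18, 28),
                c(6.9, 7.0, 7.1))
  expect_equal(qualify_hits(h, mu = 7)$score, 7.1)   # strictly above

  # overlapping, same diagonal: one survivor with the higher score
  h2 <- ext_hits(c(0, 4), c(8, 12), c(0, 4), c(8, 12), c(8, 9))
  q2 <- qualify_hits(h2, mu = 7)
  expect_equal(nrow(q2), 1L)
  expect_equal(q2$score, 9)

  # same diagonal but disjoint: both retained
  h3 <- ext_hits(c(0, 9), c(8, 17), c(0, 9), c(8, 17), c(8, 9))
  expect_equal(nrow(qualify_hits(h3, mu = 7)), 2L)

  # different diagonals, overlapping in sequence: both retained
  h4 <- ext_hits(c(0, 2), c(8, 10), c(0, 4), c(8, 12), c(8, 9))
  expect_equal(nrow(qualify_hits(h4, mu = 7)), 2L)

  # merging can be disabled
  expect_equal(nrow(qualify_hits(h2, mu = 7, merge_overlaps = FALSE)), 2L)
})

test_that("two-hit rule counts post-merge hits", {
  expect_false(two_hit(ext_hits(integer(), integer(), integer(),
                                integer(), numeric())))
  one <- ext_hits(0, 8, 0, 8, 9)
  expect_false(two_hit(one))
  h2 <- ext_hits(c(0, 4), c(8, 12), c(0, 4), c(8, 12), c(8, 9))
  expect_false(two_hit(qualify_hits(h2, mu = 7)))   # merged into one
  five <- ext_hits(seq(0, 40, 10), seq(8, 48, 10), seq(0, 40, 10),
                   seq(8, 48, 10), rep(9, 5))
  expect_true(two_hit(five))
})

test_that("window gate spans the qualified hits and applies eta strictly", {
  fx <- fixture_family()
  s <- fx$fam$members$seq[1]
  L <- nchar(s); M <- fx$model$M
  q <- ext_hits(c(0, L - 8), c(8, L), c(0, M - 8), c(8, M), c(9, 9))
  g <- window_gate(fx$model, s, q, eta = 20)
  expect_equal(g$score, viterbi_score(fx$model, s))   # full span
  expect_true(window_gate(fx$model, s, q, eta = -Inf)$pass)
  expect_identical(window_gate(fx$model, s, q, eta = g$score)$pass, FALSE)
  expect_true(window_gate(fx$model, s, q, eta = g$score - 0.01)$pass)
})

test_that("window gate on planted domains tracks the full score", {
  # members carry the domain inside random flanks; the hit-spanning
  # window must capture essentially the full viterbi score
  fx <- fixture_family()
  aut <- word_automaton(enumerate_words(fx$model, 6))
  n_checked <- 0
  for (i in seq_len(nrow(fx$fam$members))) {
    out <- filter_sequence(fx$model, fx$fam$members$seq[i],
                           automaton = aut)
    if (out$stage_reached %in% c("window_fail", "passed")) {
      full <- viterbi_score(fx$model, fx$fam$members$seq[i])
      expect_lte(abs(out$window_score - full), 0.5)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("cascade short-circuits with consistent stages and matches the
           staged pipeline", {
  fx <- fixture_family()
  params <- filter_params()
  aut <- word_automaton(enumerate_words(fx$model, params$theta))
  seqs <- c(fx$fam$members$seq[1:4],
            shuffle_sequences(fx$fam$members[1:4, ], seed = 3)$seq,
            random_sequences(4, seed = 4)$seq)
  for (s in seqs) {
    out <- filter_sequence(fx$model, s, params, aut)
    wh <- scan_words(aut, s)
    if (nrow(wh) == 0) {
      expect_equal(out$stage_reached, "no_words")
      next
    }
    ext <- dplyr::bind_rows(lapply(seq_len(nrow(wh)), function(r)
      extend_word_hit(fx$model, s, wh[r, ], params$delta)))
    qual <- qualify_hits(ext, params$mu, params$merge_overlaps)
    expect_equal(as.data.frame(out$qualified_hits),
                 as.data.frame(qual[names(out$qualified_hits)]))
    if (!two_hit(qual)) {
      expect_equal(out$stage_reached, "one_hit")
      next
    }
    gate <- window_gate(fx$model, s, qual, params$eta)
    expect_equal(out$window_score, gate$score, tolerance = 1e-9)
    expect_equal(out$stage_reached,
                 if (gate$pass) "passed" else "window_fail")
  }
})

test_that("sentinel thresholds disable stages", {
  m <- rand_profile(7, seed = 61)
  s <- rand_residues(30, seed = 62)
  params <- filter_params(theta = -Inf, delta = 2, mu = -Inf, eta = -Inf)
  out <- filter_sequence(m, s, params)
  expect_equal(out$stage_reached, "passed")
})

test_that("models with fewer than 4 match states bypass the filter", {
  m <- calibrate_profile(seq_profile("ACD"), "viterbi", n = 200, seed = 1)
  out <- filter_sequence(m, "ACDACD")
  expect_equal(out$stage_reached, "passed")
  db <- aa_seqs(c("t1", "t2"), c("ACDW", "WWWWACD"))
  hits <- hmm_search(db, m, e_cutoff = Inf)
  expect_equal(filter_stats(hits)$fully_scored, 2L)
})

test_that("search reports identical scores with and without the filter", {
  fx <- fixture_family()
  db <- dplyr::bind_rows(fx$fam$members,
                         make_decoys(fx$fam$members, copies = 3, seed = 8))
  hf <- hmm_search(db, fx$model, e_cutoff = Inf)
  hu <- hmm_search(db, fx$model, e_cutoff = Inf, filter = FALSE)
  expect_equal(filter_stats(hu)$fully_scored, nrow(db))
  expect_true(all(hf$target %in% hu$target))
  j <- match(hf$target, hu$target)
  expect_equal(hf$bits, hu$bits[j], tolerance = 1e-12)
  expect_equal(hf$evalue, hu$evalue[j], tolerance = 1e-12)
  expect_equal(hf$seq_start, hu$seq_start[j])
  expect_equal(hf$model_end, hu$model_end[j])
  # hits come back sorted by E-value
  expect_true(!is.unsorted(hf$evalue))
  # filter-stage counts are monotone along the cascade
  st <- filter_stats(hf)
  expect_true(st$sequences_total >= st$with_word_hits &&
              st$with_word_hits >= st$with_two_hits &&
              st$with_two_hits >= st$passed_window &&
              st$passed_window == st$fully_scored)
})

test_that("the model's own consensus outranks decoys", {
  fx <- fixture_family()
  consensus <- paste(AA20[apply(fx$model$mat_emis, 1, which.max)],
                     collapse = "")
  db <- dplyr::bind_rows(
    aa_seqs("consensus", consensus),
    shuffle_sequences(aa_seqs("c2", consensus), seed = 12, copies = 50))
  hits <- hmm_search(db, fx$model, e_cutoff = Inf, filter = FALSE)
  expect_equal(hits$target[1], "consensus")
  expect_lt(hits$evalue[1], 1e-10)
})

test_that("raising theta, mu, or eta never grows the passed set;
           raising delta never shrinks it", {
  fx <- fixture_family()
  db <- dplyr::bind_rows(fx$fam$members,
                         make_decoys(fx$fam$members, copies = 2, seed = 13))
  passed_set <- function(theta, delta, mu, eta) {
    aut <- word_automaton(enumerate_words(fx$model, theta))
    p <- filter_params(theta, delta, mu, eta)
    which(vapply(db$seq, function(s)
      filter_sequence(fx$model, s, p, aut)$stage_reached == "passed", TRUE))
  }
  base <- passed_set(6, 2, 7, 20)
  expect_true(all(passed_set(8, 2, 7, 20) %in% base))
  expect_true(all(passed_set(6, 2, 9, 20) %in% base))
  expect_true(all(passed_set(6, 2, 7, 25) %in% base))
  expect_true(all(base %in% passed_set(6, 3, 7, 20)))
})

test_that("glance and autoplot summarise a search", {
  fx <- fixture_family()
  hits <- hmm_search(fx$fam$members, fx$model, e_cutoff = Inf)
  g <- glance(hits)
  expect_equal(g$n_hits, nrow(hits))
  p <- autoplot(hits)
  expect_s3_class(p, "ggplot")
})
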