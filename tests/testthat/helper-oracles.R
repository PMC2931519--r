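# Independent oracles and fixture builders shared across the suite.
# The oracles re-derive expected values from first principles (path
# enumeration, naive scans, direct simulation of stated rules) and never
# call the kernels they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rdirichlet1 <- function(n, alpha) {
  x <- rgamma(n, alpha)
  x / sum(x)
}

# Random valid profile HMM built directly from probabilities.  With
# `hot = k` letters, emission mass concentrates on the first k alphabet
# letters (a reduced-alphabet model for exhaustive path tests).
rand_profile <- function(M, seed, hot = 20, conc = 0.5) {
  set.seed(seed)
  emis <- t(vapply(seq_len(M), function(k) {
    p <- rep(1e-4, 20)
    p[seq_len(hot)] <- rdirichlet1(hot, conc) + 1e-3
    p / sum(p)
  }, numeric(20)))
  colnames(emis) <- AA20
  trans <- matrix(0, M, 7,
                  dimnames = list(NULL, c("mm", "mi", "md", "im", "ii",
                                          "dm", "dd")))
  for (k in seq_len(M)) {
    if (k < M) {
      trans[k, 1:3] <- rdirichlet1(3, c(8, 1, 1))
      trans[k, 4:5] <- rdirichlet1(2, c(1, 1))
      trans[k, 6:7] <- rdirichlet1(2, c(1, 1))
    } else {
      trans[k, ] <- c(1, 0, 0, 1, 0, 1, 0)
    }
  }
  bg <- amino_background()
  ins <- matrix(rep(bg$freq, each = M), M, 20, dimnames = list(NULL, AA20))
  m <- hmmsieve:::new_profile(paste0("toy", M), emis, ins, trans,
                              c(1, rep(0, M - 1)), c(rep(0, M - 1), 1), bg)
  configure_local(m)
}

# Exhaustive enumeration of every legal local state path and its bit
# score.  Returns the vector of complete-path scores (entry ... exit).
enum_path_scores <- function(model, residues) {
  codes <- match(strsplit(residues, "")[[1]], AA20)
  L <- length(codes)
  M <- model$M
  msc <- model$msc; isc <- model$isc; tsc <- model$tsc
  en <- model$entry_sc; ex <- model$exit_sc
  scores <- numeric(0)
  rec_m <- function(k, i, sc) {
    scores <<- c(scores, sc + ex[k])           # exit after this match
    if (i < L) {
      rec_i(k, i + 1, sc + tsc[k, "mi"] + isc[k, codes[i + 1]])
      if (k < M)
        rec_m(k + 1, i + 1, sc + tsc[k, "mm"] + msc[k + 1, codes[i + 1]])
    }
    if (k < M) rec_d(k + 1, i, sc + tsc[k, "md"])
  }
  rec_i <- function(k, i, sc) {
    if (i < L) {
      rec_i(k, i + 1, sc + tsc[k, "ii"] + isc[k, codes[i + 1]])
      if (k < M)
        rec_m(k + 1, i + 1, sc + tsc[k, "im"] + msc[k + 1, codes[i + 1]])
    }
  }
  rec_d <- function(k, i, sc) {
    if (i < L && k < M)
      rec_m(k + 1, i + 1, sc + tsc[k, "dm"] + msc[k + 1, codes[i + 1]])
    if (k < M) rec_d(k + 1, i, sc + tsc[k, "dd"])
  }
  for (i in seq_len(L))
    for (k in seq_len(M))
      rec_m(k, i, en[k] + msc[k, codes[i]])
  scores[is.finite(scores)]
}

oracle_viterbi <- function(model, residues) max(enum_path_scores(model, residues))
oracle_forward <- function(model, residues) {
  s <- enum_path_scores(model, residues)
  m <- max(s)
  m + log2(sum(2^(s - m)))
}

# All sequences of a given length over a reduced alphabet.
all_seqs <- function(len, letters = AA20[1:4]) {
  apply(do.call(expand.grid, rep(list(letters), len)), 1, paste,
        collapse = "")
}

# Naive multi-word scan: substring comparison at every offset.
naive_scan <- function(words, residues) {
  L <- nchar(residues)
  out <- list()
  for (r in seq_len(nrow(words))) {
    w <- words$word[r]
    for (s in seq_len(L - 3)) {
      if (substr(residues, s, s + 3) == w)
        out[[length(out) + 1]] <- data.frame(seq_start = s - 1L,
                                             model_start = words$model_start[r])
    }
  }
  d <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_start = integer(), model_start = integer())
  d <- d[order(d$seq_start, d$model_start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Direct simulation of the stated drop-off extension rule, independent
# of the kernel: walk outward, track running and best scores, stop once
# running <= best - delta/2 or a boundary, keep the best endpoint.
oracle_extend <- function(model, residues, seq_start, model_start, delta) {
  codes <- match(strsplit(residues, "")[[1]], AA20)
  word <- sum(vapply(0:3, function(j)
    model$msc[model_start + j + 1, codes[seq_start + j + 1]], 0))
  walk <- function(dirn) {
    run <- 0; best <- 0; best_off <- 0; off <- 0
    repeat {
      if (dirn < 0) {
        si <- seq_start - off - 1; ki <- model_start - off - 1
        if (si < 0 || ki < 0) break
      } else {
        si <- seq_start + 4 + off; ki <- model_start + 4 + off
        if (si >= length(codes) || ki >= model$M) break
      }
      run <- run + model$msc[ki + 1, codes[si + 1]]
      off <- off + 1
      if (run > best) { best <- run; best_off <- off }
      if (run <= best - delta / 2) break
    }
    list(best = best, off = best_off)
  }
  lt <- walk(-1); rt <- walk(+1)
  list(seq_start = seq_start - lt$off, seq_end = seq_start + 4 + rt$off,
       model_start = model_start - lt$off,
       model_end = model_start + 4 + rt$off,
       score = as.numeric(word + lt$best + rt$best))
}

rand_residues <- function(n, seed, letters = AA20) {
  set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Shared calibrated family fixture (built once per test run).
.fixture_env <- new.env()
fixture_family <- function() {
  if (is.null(.fixture_env$fam)) {
    fam <- generate_family(family_spec(length = 80, n_members = 12,
                                       mutation_rate = 0.2,
                                       indel_rate = 0.01, seed = 31),
                           id = "fixfam")
    model <- build_profile(fam$msa, name = "fixfam")
    model <- calibrate_profile(model, "viterbi", n = 1000, seed = 32)
    .fixture_env$fam <- list(fam = fam, model = model)
  }
  .fixture_env$fam
}
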