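# Construction of local/local profile HMMs from alignments or single
# sequences.  Emissions are stored both as probabilities and as log-odds
# bit scores against the background; transitions as probabilities and
# log2 values.  Match emission scores are what the word filter reads.

.hmmsieve_cache <- new.env(parent = emptyenv())

# Conditional substitution mixture q(a | b) derived from BLOSUM62
# (half-bit convention): q(a|b) proportional to f(a) * 2^(S_ab / 2).
blosum_conditional <- function(bg = amino_background()) {
  key <- paste0("blosum_q_", digest_freq(bg))
  if (!is.null(.hmmsieve_cache[[key]])) return(.hmmsieve_cache[[key]])
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62[AA, AA]
  q <- bg$freq * 2^(S / 2)          # recycles f(a) down columns b
  q <- sweep(q, 2, colSums(q), "/") # q[a, b] = q(a | b)
  .hmmsieve_cache[[key]] <- q
  q
}

digest_freq <- function(bg) paste(signif(bg$freq[1:3], 6), collapse = "_")

# Henikoff position-based sequence weights over an alignment character
# matrix ("-" marks gaps); normalised to sum to 1.
henikoff_weights <- function(chm) {
  n <- nrow(chm)
  w <- numeric(n)
  for (c in seq_len(ncol(chm))) {
    col <- chm[, c]
    res <- col != "-"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    w[res] <- w[res] + 1 / (r * as.numeric(tab[col[res]]))
  }
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

msa_char_matrix <- function(msa, bg) {
  rows <- toupper(msa$aln)
  rows <- resolve_degenerate(rows, bg)
  rows <- gsub("[.]", "-", rows)
  do.call(rbind, strsplit(rows, ""))
}

new_profile <- function(name, mat_emis, ins_emis, trans, entry, exitp, bg,
                        calibration = list()) {
  M <- nrow(mat_emis)
  f <- bg$freq
  model <- structure(list(
    name = name, M = M, bg = bg,
    mat_emis = mat_emis, ins_emis = ins_emis, trans = trans,
    entry = entry, exit = exitp,
    msc = log2(sweep(mat_emis, 2, f, "/")),
    isc = log2(sweep(ins_emis, 2, f, "/")),
    tsc = log2(trans),
    entry_sc = log2(entry), exit_sc = log2(exitp),
    calibration = calibration
  ), class = "profile_hmm")
  model
}

#' Validate profile-HMM invariants
#'
#' Checks that per-position emission and transition probabilities are
#' proper distributions, that entry/exit mass does not exceed 1, and that
#' match scores equal `log2(p / f)`.
#'
#' @param model A `profile_hmm`.
#' @param tol Numeric tolerance on probability sums.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_profile <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "profile_hmm"), model$M >= 1)
  if (any(abs(rowSums(model$mat_emis) - 1) > 1e-6))
    stop("match emission rows do not sum to 1")
  if (any(abs(rowSums(model$ins_emis) - 1) > 1e-6))
    stop("insert emission rows do not sum to 1")
  tr <- model$trans
  M <- model$M
  if (M > 1) {
    k <- seq_len(M - 1)
    if (any(abs(rowSums(tr[k, 1:3, drop = FALSE]) - 1) > tol) ||
        any(abs(rowSums(tr[k, 4:5, drop = FALSE]) - 1) > tol) ||
        any(abs(rowSums(tr[k, 6:7, drop = FALSE]) - 1) > tol))
      stop("per-position transition distributions do not sum to 1")
  }
  if (sum(model$entry) > 1 + tol || sum(model$exit) > 1 + tol)
    stop("entry/exit mass exceeds 1")
  recon <- log2(sweep(model$mat_emis, 2, model$bg$freq, "/"))
  if (max(abs(recon - model$msc)) > 1e-9)
    stop("match scores inconsistent with stored probabilities")
  invisible(model)
}

# Mean per-match-state relative entropy (bits) of emissions vs background.
mean_relative_entropy <- function(mat_emis, f) {
  re <- rowSums(mat_emis * log2(sweep(mat_emis, 2, f, "/")))
  mean(re)
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Columns with at least `occupancy` weighted residue fraction become match
#' states; Henikoff position-based weights are rescaled so that the mean
#' match-state relative entropy approaches `relent_target` bits (the
#' information-content analogue of entropy weighting); emissions receive a
#' substitution-mixture pseudocount of total weight `pseudocount`.
#'
#' @param msa An `aa_msa` tibble (see [read_alignment()]).
#' @param bg Background model.
#' @param name Model name; defaults to `"model"`.
#' @param relent_target Target mean match relative entropy, bits.
#' @param pseudocount Total pseudocount weight added per column.
#' @param occupancy Weighted-residue fraction required for a match column.
#' @param local Configure uniform local entry/exit (see
#'   [configure_local()]); on by default.
#' @return A `profile_hmm` object.
#' @export
build_profile <- function(msa, bg = amino_background(), name = "model",
                          relent_target = 1.3, pseudocount = 5,
                          occupancy = 0.5, local = TRUE) {
  stopifnot(nrow(msa) >= 1)
  chm <- msa_char_matrix(msa, bg)
  w <- henikoff_weights(chm)
  f <- bg$freq
  q <- blosum_conditional(bg)
  resmask <- chm != "-"
  occ <- as.numeric(crossprod(resmask, w))       # weighted occupancy per col
  match_cols <- which(occ >= occupancy)
  M <- length(match_cols)
  if (M == 0L) stop("alignment has zero match columns under occupancy rule")

  # weighted residue fractions per match column (sum to occ_k)
  cnt <- matrix(0, M, 20, dimnames = list(NULL, AA))
  for (j in seq_len(M)) {
    col <- chm[, match_cols[j]]
    res <- col != "-"
    if (any(res))
      cnt[j, ] <- vapply(AA, function(a) sum(w[res & col == a]), 0)
  }
  occk <- rowSums(cnt)
  pc <- t(apply(cnt, 1, function(ck) {
    if (sum(ck) == 0) return(f)
    as.numeric(q %*% (ck / sum(ck)))
  }))

  emis_at <- function(W) {
    p <- (W * cnt + pseudocount * pc) / (W * occk + pseudocount)
    p / rowSums(p)
  }
  # rescale total sequence weight to meet the relative-entropy target
  lo <- 1e-4; hi <- 1e6
  re_hi <- mean_relative_entropy(emis_at(hi), f)
  re_lo <- mean_relative_entropy(emis_at(lo), f)
  if (re_hi <= relent_target) {
    W <- hi
  } else if (re_lo >= relent_target) {
    W <- lo
  } else {
    for (it in 1:60) {
      W <- sqrt(lo * hi)
      if (mean_relative_entropy(emis_at(W), f) > relent_target) hi <- W
      else lo <- W
    }
    W <- sqrt(lo * hi)
  }
  mat_emis <- emis_at(W)

  # transition counts along each row's implied state path, Henikoff-weighted
  # and scaled by the same effective weight W
  cMM <- cMI <- cMD <- cIM <- cII <- cDM <- cDD <- numeric(M)
  is_match <- logical(ncol(chm)); is_match[match_cols] <- TRUE
  colk <- cumsum(is_match)                       # model position per column
  for (i in seq_len(nrow(chm))) {
    prev <- "B"; prevk <- 0
    for (c in seq_len(ncol(chm))) {
      ch <- chm[i, c]
      if (is_match[c]) {
        cur <- if (ch == "-") "D" else "M"
        k <- colk[c]
        if (prevk >= 1) {
          key <- paste0(prev, cur)
          if (key == "MM") cMM[prevk] <- cMM[prevk] + w[i]
          else if (key == "MD") cMD[prevk] <- cMD[prevk] + w[i]
          else if (key == "IM") cIM[prevk] <- cIM[prevk] + w[i]
          else if (key == "DM") cDM[prevk] <- cDM[prevk] + w[i]
          else if (key == "DD") cDD[prevk] <- cDD[prevk] + w[i]
        }
        prev <- cur; prevk <- k
      } else if (ch != "-") {
        if (prevk >= 1 && prevk < M) {
          if (prev == "M") cMI[prevk] <- cMI[prevk] + w[i]
          else if (prev == "I") cII[prevk] <- cII[prevk] + w[i]
          # inserts after a delete are rare; fold into the insert track
          else cII[prevk] <- cII[prevk] + w[i]
        }
        if (prevk >= 1) prev <- "I"
      }
    }
  }
  aM <- c(1.0, 0.1, 0.1); aI <- c(0.5, 0.5); aD <- c(0.5, 0.5)
  trans <- matrix(0, M, 7,
                  dimnames = list(NULL, c("mm", "mi", "md", "im", "ii",
                                          "dm", "dd")))
  for (k in seq_len(M)) {
    if (k < M) {
      m3 <- W * c(cMM[k], cMI[k], cMD[k]) + aM
      i2 <- W * c(cIM[k], cII[k]) + aI
      d2 <- W * c(cDM[k], cDD[k]) + aD
      trans[k, 1:3] <- m3 / sum(m3)
      trans[k, 4:5] <- i2 / sum(i2)
      trans[k, 6:7] <- d2 / sum(d2)
    } else {
      trans[k, ] <- c(1, 0, 0, 1, 0, 1, 0)  # terminal: all mass onward
    }
  }
  ins_emis <- matrix(rep(f, each = M), M, 20, dimnames = list(NULL, AA))
  entry <- c(1, rep(0, M - 1))
  exitp <- c(rep(0, M - 1), 1)
  model <- new_profile(name, mat_emis, ins_emis, trans, entry, exitp, bg)
  if (local) model <- configure_local(model) else model
}

#' Build a profile HMM from a single sequence
#'
#' Position emissions are a substitution-mixture around the query residue:
#' one observed count plus `pseudocount` counts of the BLOSUM62-conditional
#' profile of that residue.  Transition probabilities are fixed, mildly
#' gap-averse defaults.
#'
#' @param seqs A one-row sequence tibble, or a residue string.
#' @param bg Background model.
#' @param pseudocount Pseudocount weight.
#' @param local Configure uniform local entry/exit; on by default.
#' @return A `profile_hmm` with `M == nchar(sequence)`.
#' @export
seq_profile <- function(seqs, bg = amino_background(), pseudocount = 5,
                        local = TRUE) {
  if (is.character(seqs)) seqs <- aa_seqs("query", seqs)
  stopifnot(nrow(seqs) == 1)
  codes <- encode_seq(seqs$seq[1]) + 1L
  M <- length(codes)
  q <- blosum_conditional(bg)
  mat_emis <- matrix(0, M, 20, dimnames = list(NULL, AA))
  for (k in seq_len(M)) {
    p <- pseudocount * q[, codes[k]]
    p[codes[k]] <- p[codes[k]] + 1
    mat_emis[k, ] <- p / sum(p)
  }
  trans <- matrix(rep(c(0.975, 0.0125, 0.0125, 0.5, 0.5, 0.5, 0.5), each = M),
                  M, 7, dimnames = list(NULL, c("mm", "mi", "md", "im", "ii",
                                                "dm", "dd")))
  if (M >= 1) trans[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  ins_emis <- matrix(rep(bg$freq, each = M), M, 20,
                     dimnames = list(NULL, AA))
  model <- new_profile(seqs$id[1], mat_emis, ins_emis, trans,
                       c(1, rep(0, M - 1)), c(rep(0, M - 1), 1), bg)
  if (local) configure_local(model) else model
}

#' Configure uniform local entry and exit
#'
#' Local/local alignment semantics: an alignment may begin at any match
#' state (uniform entry probability 1/M) and end at any match state
#' (uniform exit 1/M); flanking unmatched residues score net zero bits.
#'
#' @param model A `profile_hmm`.
#' @return The model with uniform entry/exit.
#' @export
configure_local <- function(model) {
  M <- model$M
  model$entry <- rep(1 / M, M)
  model$exit <- rep(1 / M, M)
  model$entry_sc <- log2(model$entry)
  model$exit_sc <- log2(model$exit)
  model
}

#' @export
print.profile_hmm <- function(x, ...) {
  cal <- names(x$calibration)
  cat("<profile_hmm> '", x$name, "': M = ", x$M,
      ", mean relative entropy = ",
      round(mean_relative_entropy(x$mat_emis, x$bg$freq), 3), " bits",
      if (length(cal)) paste0(", calibrated: ", paste(cal, collapse = "+"))
      else ", uncalibrated",
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy
#' @description `tidy.profile_hmm()` returns one row per (match position,
#'   residue) with the emission probability and bit score.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.profile_hmm <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$M) - 1L, each = 20L),
    residue = rep(AA, x$M),
    prob = as.numeric(t(x$mat_emis)),
    score = as.numeric(t(x$msc)))
}

#' Broom-style summaries
#'
#' @name tidy
NULL

#' @rdname tidy
#' @description `glance.profile_hmm()` returns a one-row model summary.
#' @export
glance.profile_hmm <- function(x, ...) {
  tibble::tibble(
    name = x$name, M = x$M,
    mean_relent = mean_relative_entropy(x$mat_emis, x$bg$freq),
    calibrated_viterbi = "viterbi" %in% names(x$calibration),
    calibrated_forward = "forward" %in% names(x$calibration))
}

fmt_sc <- function(x) {
  ifelse(is.finite(x), formatC(x, digits = 5, format = "f"), "-inf")
}
parse_sc <- function(s) {
  x <- suppressWarnings(as.numeric(s))
  x[s == "-inf"] <- -Inf
  x
}

#' Write a profile HMM to a plain-text model file
#'
#' Key/value block format: background frequencies, per-position match and
#' insert log2-odds emission scores and log2 transition probabilities at 5
#' decimal places, entry/exit scores, and any calibration blocks.
#'
#' @param model A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl("HMMSIEVE", "1")
  wl("NAME", model$name)
  wl("M", model$M)
  wl("ALPH", paste(AA, collapse = ""))
  wl("BG", paste(formatC(model$bg$freq, digits = 6, format = "f"),
                 collapse = " "))
  wl("P1", formatC(model$bg$p1, digits = 6, format = "f"))
  for (k in seq_len(model$M)) {
    wl("MAT", k - 1, paste(fmt_sc(model$msc[k, ]), collapse = " "))
    wl("INS", k - 1, paste(fmt_sc(model$isc[k, ]), collapse = " "))
    wl("TRN", k - 1, paste(fmt_sc(model$tsc[k, ]), collapse = " "))
  }
  wl("ENTRY", paste(fmt_sc(model$entry_sc), collapse = " "))
  wl("EXIT", paste(fmt_sc(model$exit_sc), collapse = " "))
  for (alg in names(model$calibration)) {
    evd <- model$calibration[[alg]]
    wl("CAL", alg, formatC(evd$evd_mu, digits = 6, format = "f"),
       formatC(evd$evd_lambda, digits = 6, format = "f"), evd$n_samples)
  }
  wl("END")
  invisible(path)
}

#' Read a profile HMM model file
#'
#' @param path Path to a file written by [write_profile()].
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  tok <- strsplit(lines, "\\s+")
  if (tok[[1]][1] != "HMMSIEVE") stop("not a hmmsieve model file: ", path)
  kv <- function(key) {
    i <- which(vapply(tok, function(t) t[1] == key, TRUE))[1]
    tok[[i]][-1]
  }
  name <- kv("NAME")[1]
  M <- as.integer(kv("M")[1])
  f <- as.numeric(kv("BG"))
  names(f) <- AA
  bg <- amino_background(f, p1 = as.numeric(kv("P1")[1]))
  msc <- isc <- matrix(0, M, 20, dimnames = list(NULL, AA))
  tsc <- matrix(0, M, 7)
  for (t in tok) {
    if (t[1] %in% c("MAT", "INS", "TRN")) {
      k <- as.integer(t[2]) + 1L
      v <- parse_sc(t[-(1:2)])
      if (t[1] == "MAT") msc[k, ] <- v
      else if (t[1] == "INS") isc[k, ] <- v
      else tsc[k, ] <- v
    }
  }
  entry_sc <- parse_sc(kv("ENTRY"))
  exit_sc <- parse_sc(kv("EXIT"))
  mat_emis <- sweep(2^msc, 2, bg$freq, "*")
  mat_emis <- mat_emis / rowSums(mat_emis)
  ins_emis <- sweep(2^isc, 2, bg$freq, "*")
  ins_emis <- ins_emis / rowSums(ins_emis)
  calibration <- list()
  for (t in tok) {
    if (t[1] == "CAL") {
      calibration[[t[2]]] <- evd_params(
        evd_mu = as.numeric(t[3]), evd_lambda = as.numeric(t[4]),
        n_samples = as.integer(t[5]), algorithm = t[2])
    }
  }
  new_profile(name, mat_emis, ins_emis, 2^tsc, 2^entry_sc, 2^exit_sc, bg,
              calibration = calibration)
}
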