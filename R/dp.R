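# Exact local/local Viterbi and Forward scoring in bits, with traceback
# and window-restricted variants.  All heavy lifting is in the compiled
# kernels; these wrappers handle encoding, windows, and trace tibbles.

model_parts <- function(model) {
  list(msc = model$msc, isc = model$isc, tsc = model$tsc,
       entry = model$entry_sc, exit = model$exit_sc)
}

as_residues <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq$seq[1]
  } else {
    as.character(seq)
  }
}

trace_tibble <- function(tr) {
  if (is.null(tr)) return(NULL)
  states <- c("B", "M", "I", "D", "E")
  tibble::tibble(state = states[tr[, 1] + 1L],
                 model_pos = tr[, 2],
                 seq_pos = tr[, 3])
}

#' Viterbi score and optimal alignment
#'
#' Best local state path score in bits (log2-odds of the path versus the
#' null model); flanking unmatched residues contribute net zero bits.
#' Traceback ties are broken deterministically with state priority
#' M > D > I.
#'
#' @param model A `profile_hmm`.
#' @param seq A residue string or one-row sequence tibble.
#' @param trace Return the optimal trace as well?
#' @return If `trace`, a list with `score` (bits) and `trace` (a tibble of
#'   `state`, `model_pos`, `seq_pos`, 0-based); otherwise the score.
#' @export
viterbi_score <- function(model, seq, trace = FALSE) {
  codes <- encode_seq(as_residues(seq))
  p <- model_parts(model)
  r <- cpp_viterbi(p$msc, p$isc, p$tsc, p$entry, p$exit, codes,
                   0L, length(codes), 0L, model$M, trace)
  if (!trace) return(r$score)
  list(score = r$score, trace = trace_tibble(r$trace))
}

#' Forward score
#'
#' log2 of the summed probability over all local state paths, relative to
#' the null model; computed in log2 space with stable accumulation.
#' Always at least the Viterbi score.
#'
#' @inheritParams viterbi_score
#' @return Score in bits.
#' @export
forward_score <- function(model, seq) {
  codes <- encode_seq(as_residues(seq))
  p <- model_parts(model)
  cpp_forward(p$msc, p$isc, p$tsc, p$entry, p$exit, codes,
              0L, length(codes), 0L, model$M)
}

#' Window-restricted Viterbi score
#'
#' Best local Viterbi score where matched/inserted residues lie inside
#' `seq_window` and matched model states lie inside `model_window` (both
#' 0-based half-open).  Narrowing a window can never increase the score.
#'
#' @inheritParams viterbi_score
#' @param seq_window Integer pair `c(start, end)`, half-open, on the
#'   sequence.
#' @param model_window Integer pair, half-open, on match states.
#' @return Score in bits.
#' @export
viterbi_window <- function(model, seq, seq_window, model_window) {
  codes <- encode_seq(as_residues(seq))
  L <- length(codes)
  sw <- as.integer(seq_window); mw <- as.integer(model_window)
  if (sw[2] <= sw[1] || mw[2] <= mw[1]) stop("empty window")
  if (sw[1] < 0 || sw[2] > L || mw[1] < 0 || mw[2] > model$M)
    stop("window out of bounds")
  p <- model_parts(model)
  cpp_viterbi(p$msc, p$isc, p$tsc, p$entry, p$exit, codes,
              sw[1], sw[2], mw[1], mw[2], FALSE)$score
}

#' Score many sequences at once
#'
#' @param model A `profile_hmm`.
#' @param seqs Sequence tibble.
#' @param algorithm `"viterbi"` or `"forward"`.
#' @return The input tibble with a `bits` column appended.
#' @export
score_sequences <- function(seqs, model, algorithm = c("viterbi", "forward")) {
  algorithm <- match.arg(algorithm)
  p <- model_parts(model)
  codes <- lapply(seqs$seq, encode_seq)
  bits <- cpp_score_many(p$msc, p$isc, p$tsc, p$entry, p$exit, codes,
                         if (algorithm == "viterbi") 0L else 1L)
  dplyr::mutate(seqs, bits = bits)
}
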