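# The 20-letter amino-acid alphabet, background model, and residue coding.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson amino-acid frequencies, the standard null for
# protein log-odds scoring; renormalised to sum exactly to 1.
RR_FREQ <- c(
  A = 0.078794, C = 0.015160, D = 0.053522, E = 0.066830, F = 0.039706,
  G = 0.069507, H = 0.022920, I = 0.059009, K = 0.059442, L = 0.096372,
  M = 0.023772, N = 0.041439, P = 0.048462, Q = 0.039564, R = 0.051206,
  S = 0.068230, T = 0.054161, V = 0.064705, W = 0.014335, Y = 0.030234
)
RR_FREQ <- RR_FREQ / sum(RR_FREQ)

#' Background residue model
#'
#' The null model against which all bit scores are computed: i.i.d. residue
#' frequencies plus a geometric length model with self-transition
#' probability `p1`.  Defaults to the Robinson & Robinson frequencies used
#' by classic profile-HMM software.
#'
#' @param freq Named numeric vector of 20 residue frequencies (names must be
#'   the amino-acid one-letter codes).  Renormalised to sum to 1.
#' @param p1 Null-model self-transition probability (controls expected
#'   length; only stored, flanking residues score net zero bits).
#' @return An object of class `aa_background` with elements `freq` and `p1`.
#' @export
#' @examples
#' bg <- amino_background()
#' sum(bg$freq)
amino_background <- function(freq = RR_FREQ, p1 = 350 / 351) {
  stopifnot(length(freq) == 20L, !is.null(names(freq)))
  freq <- freq[AA]
  if (anyNA(freq) || any(freq <= 0))
    stop("background frequencies must be positive and named by amino acid")
  freq <- freq / sum(freq)
  structure(list(freq = freq, p1 = p1), class = "aa_background")
}

#' @export
print.aa_background <- function(x, ...) {
  cat("<aa_background> 20 residue frequencies, p1 =",
      format(x$p1, digits = 4), "\n")
  invisible(x)
}

# Resolve degenerate one-letter codes onto the 20-letter alphabet:
# B->D, Z->E, U->C, O->K, and X -> the most frequent background residue.
# Deterministic so that parsing is reproducible.
resolve_degenerate <- function(residues, bg = amino_background()) {
  xsub <- names(which.max(bg$freq))
  from <- paste0("BZUOX", "bzuox")
  to <- paste0("DECK", xsub, "deck", tolower(xsub))
  chartr(from, to, residues)
}

# Encode residue string to 0-based integer codes for the C++ kernels.
encode_seq <- function(residues) {
  codes <- match(strsplit(toupper(residues), "")[[1]], AA) - 1L
  if (anyNA(codes))
    stop("sequence contains characters outside the amino-acid alphabet")
  codes
}

decode_seq <- function(codes) paste(AA[codes + 1L], collapse = "")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
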