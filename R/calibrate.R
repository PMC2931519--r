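# E-value calibration: score a sample of random background sequences,
# fit a Gumbel (extreme value) distribution by maximum likelihood, and
# convert bit scores to E-values.

#' Extreme-value distribution parameters
#'
#' @param evd_mu Location, bits.
#' @param evd_lambda Scale, per bit; must be positive.
#' @param n_samples Number of scores used in the fit (at least 100).
#' @param algorithm Scoring algorithm the fit applies to.
#' @return An object of class `evd_params`.
#' @export
evd_params <- function(evd_mu, evd_lambda, n_samples,
                       algorithm = c("viterbi", "forward")) {
  algorithm <- match.arg(algorithm)
  stopifnot(evd_lambda > 0, n_samples >= 100)
  structure(list(evd_mu = evd_mu, evd_lambda = evd_lambda,
                 n_samples = as.integer(n_samples), algorithm = algorithm),
            class = "evd_params")
}

#' @export
print.evd_params <- function(x, ...) {
  cat("<evd_params> ", x$algorithm, ": mu = ", round(x$evd_mu, 3),
      " bits, lambda = ", round(x$evd_lambda, 4), " (n = ", x$n_samples,
      ")\n", sep = "")
  invisible(x)
}

#' Generate random background sequences
#'
#' Residues are drawn i.i.d. from the background; lengths are normal
#' (mean 325, sd 200), rounded, and clamped below at 50 — the classic
#' calibration length model for protein search.
#'
#' @param n Number of sequences.
#' @param bg Background model.
#' @param seed Integer seed (reproducible).
#' @param len_mean,len_sd,len_min Length distribution controls.
#' @return A sequence tibble with ids `rnd1..rndn`.
#' @export
random_sequences <- function(n, bg = amino_background(), seed = 1,
                             len_mean = 325, len_sd = 200, len_min = 50) {
  stopifnot(n >= 1)
  with_seed(seed, {
    lens <- pmax(len_min, round(rnorm(n, len_mean, len_sd)))
    seqs <- vapply(lens, function(L) {
      paste(sample(AA, L, replace = TRUE, prob = bg$freq), collapse = "")
    }, "")
    tibble::tibble(id = paste0("rnd", seq_len(n)), desc = "random",
                   seq = seqs)
  })
}

#' Maximum-likelihood Gumbel fit to a score sample
#'
#' Fits a Gumbel by maximum likelihood with optional left-censoring:
#' scores at or below the `censor_frac` sample quantile enter the
#' likelihood only through the censoring mass.  Censoring at the median
#' (the default) anchors the fit on the high-score tail — which is what
#' E-values are computed from — rather than on the bulk, where local
#' alignment score distributions deviate from the Gumbel.  The profile
#' likelihood equation for lambda is solved by Newton iteration
#' (tolerance 1e-6); mu then has a closed form.
#'
#' @param scores Numeric vector of at least 100 finite bit scores.
#' @param algorithm Label stored on the result.
#' @param censor_frac Fraction of the sample to left-censor; 0 gives the
#'   plain (uncensored) fit.
#' @return An `evd_params` object.
#' @export
fit_evd <- function(scores, algorithm = c("viterbi", "forward"),
                    censor_frac = 0.5) {
  algorithm <- match.arg(algorithm)
  x <- scores[is.finite(scores)]
  if (length(x) < 100) stop("need at least 100 finite scores to fit an EVD")
  if (sd(x) == 0) stop("degenerate score sample: all scores equal")
  stopifnot(censor_frac >= 0, censor_frac < 1)
  if (censor_frac > 0) {
    c0 <- quantile(x, censor_frac, names = FALSE)
    tail_x <- x[x > c0]
    nc <- sum(x <= c0)
  } else {
    c0 <- -Inf
    tail_x <- x
    nc <- 0L
  }
  if (length(tail_x) < 10) stop("censoring leaves too few tail scores")
  xbar <- mean(tail_x)
  xmax <- max(tail_x)
  lam <- pi / (sqrt(6) * sd(x))     # method-of-moments start
  for (it in 1:200) {
    et <- exp(-lam * (tail_x - xmax))   # shifted for numerical stability
    ec <- if (nc > 0) nc * exp(-lam * (c0 - xmax)) else 0
    a0 <- sum(et) + ec
    a1 <- sum(tail_x * et) + if (nc > 0) c0 * ec else 0
    a2 <- sum(tail_x^2 * et) + if (nc > 0) c0^2 * ec else 0
    fval <- 1 / lam - xbar + a1 / a0
    fp <- -1 / lam^2 + (a1^2 - a2 * a0) / a0^2
    lam_new <- lam - fval / fp
    if (lam_new <= 0) lam_new <- lam / 2
    if (abs(lam_new - lam) < 1e-6 * lam) { lam <- lam_new; break }
    lam <- lam_new
  }
  et <- exp(-lam * (tail_x - xmax))
  ec <- if (nc > 0) nc * exp(-lam * (c0 - xmax)) else 0
  mu <- xmax - log((sum(et) + ec) / length(tail_x)) / lam
  evd_params(evd_mu = mu, evd_lambda = lam, n_samples = length(x),
             algorithm = algorithm)
}

#' Convert a bit score to an E-value
#'
#' `E = db_size * P(score' >= score)` under the fitted Gumbel:
#' `P = 1 - exp(-exp(-lambda * (score - mu)))`.  Strictly decreasing in
#' the score and linear in the database size.
#'
#' @param score Bit score (vectorised).
#' @param evd An `evd_params` object.
#' @param db_size Number of sequences searched.
#' @return E-value(s).
#' @export
evalue <- function(score, evd, db_size) {
  stopifnot(db_size >= 1)
  y <- evd$evd_lambda * (score - evd$evd_mu)
  db_size * (-expm1(-exp(-y)))
}

#' Calibrate a profile HMM
#'
#' Scores `n` random background sequences with the chosen algorithm
#' (per-sequence maximum bit score), fits a Gumbel by maximum likelihood,
#' and stores the parameters on the model.
#'
#' @param model A `profile_hmm`.
#' @param algorithm `"viterbi"` or `"forward"`.
#' @param n Number of random sequences (default 2000).
#' @param seed Integer seed.
#' @param bg Background used to draw random sequences; defaults to the
#'   model's own.
#' @param ... Passed to [random_sequences()].
#' @return The model with a `calibration[[algorithm]]` entry.
#' @export
calibrate_profile <- function(model, algorithm = c("viterbi", "forward"),
                              n = 2000, seed = 1, bg = model$bg, ...) {
  algorithm <- match.arg(algorithm)
  rnd <- random_sequences(n, bg = bg, seed = seed, ...)
  scored <- score_sequences(rnd, model, algorithm = algorithm)
  model$calibration[[algorithm]] <-
    fit_evd(scored$bits, algorithm = algorithm)
  model
}

model_evd <- function(model, algorithm) {
  evd <- model$calibration[[algorithm]]
  if (is.null(evd))
    stop("model '", model$name, "' is not calibrated for ", algorithm,
         " scoring; run calibrate_profile(model, \"", algorithm, "\")")
  evd
}
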