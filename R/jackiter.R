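# Iterative profile search over a full database: find initial homologs
# with a single-sequence model, align members to the model by Viterbi
# traceback, rebuild, recalibrate, and re-search under a per-iteration
# E-value schedule until the member set stops growing.

#' Iteration parameters
#'
#' @param e_schedule E-value admission cutoffs per iteration (strict `<`);
#'   extended by repeating the last value.
#' @param max_iter Maximum number of search iterations (default 7).
#' @param final_calibration Algorithm the final model is calibrated for.
#' @return An object of class `iteration_params`.
#' @export
iteration_params <- function(e_schedule = c(1e-5, 1e-5, 1e-4, 3e-4, 3e-4),
                             max_iter = 7L,
                             final_calibration = c("forward", "viterbi")) {
  stopifnot(max_iter >= 1)
  structure(list(e_schedule = e_schedule, max_iter = as.integer(max_iter),
                 final_calibration = match.arg(final_calibration)),
            class = "iteration_params")
}

schedule_at <- function(params, i) {
  s <- params$e_schedule
  if (i <= length(s)) s[i] else s[length(s)]
}

#' Find initial homologs of a single query
#'
#' Builds a substitution-mixture model of the query ([seq_profile()]),
#' calibrates it, and runs a filtered Viterbi search; database
#' subsequences (alignment envelopes) with E-value strictly below
#' `e_cutoff` become the initial member set, always including the query
#' itself.
#'
#' @param query One-row sequence tibble (or residue string).
#' @param db Sequence tibble.
#' @param e_cutoff Initial admission E-value (default 1e-3).
#' @param filter_params Sieve parameters for the search.
#' @param calib_n,seed Calibration sample size and seed.
#' @return A member tibble: `target`, `seq_start`, `seq_end`, `residues`.
#' @export
initial_members <- function(query, db, e_cutoff = 1e-3,
                            filter_params = hmmsieve::filter_params(),
                            calib_n = 2000, seed = 1) {
  if (is.character(query)) query <- aa_seqs("query", query)
  model <- seq_profile(query)
  model <- calibrate_profile(model, "viterbi", n = calib_n, seed = seed)
  hits <- hmm_search(db, model, filter_params, final = "viterbi",
                     e_cutoff = e_cutoff, filter = TRUE)
  hits <- hits[hits$evalue < e_cutoff & hits$target != query$id[1], ,
               drop = FALSE]
  members <- tibble::tibble(
    target = query$id[1], seq_start = 0L, seq_end = nchar(query$seq[1]),
    residues = query$seq[1])
  if (nrow(hits)) {
    ext <- tibble::tibble(
      target = hits$target, seq_start = hits$seq_start,
      seq_end = hits$seq_end,
      residues = substr(db$seq[match(hits$target, db$id)],
                        hits$seq_start + 1L, hits$seq_end))
    ext <- ext[!duplicated(ext$target), , drop = FALSE]
    members <- dplyr::bind_rows(members, ext)
  }
  members
}

#' Align member subsequences to a model
#'
#' Each member is aligned by Viterbi traceback; match states define the
#' uppercase columns, insertions go to lowercase columns padded with `.`
#' (one column block per insert locus, width = longest insertion).
#'
#' @param model A `profile_hmm`.
#' @param members Member tibble (see [initial_members()]).
#' @return An `aa_msa` tibble whose RF line marks match columns with `x`.
#' @export
align_members <- function(model, members) {
  stopifnot(nrow(members) >= 1)
  M <- model$M
  n <- nrow(members)
  mrow <- matrix("-", n, M)
  inserts <- vector("list", n)  # per member: named list slot -> string
  for (i in seq_len(n)) {
    vt <- viterbi_score(model, members$residues[i], trace = TRUE)
    tr <- vt$trace
    chars <- strsplit(members$residues[i], "")[[1]]
    ins_i <- list()
    for (r in seq_len(nrow(tr))) {
      st <- tr$state[r]
      if (st == "M") {
        mrow[i, tr$model_pos[r] + 1L] <- chars[tr$seq_pos[r] + 1L]
      } else if (st == "I") {
        key <- as.character(tr$model_pos[r] + 1L)  # insert after match k
        ins_i[[key]] <- paste0(ins_i[[key]] %||% "",
                               tolower(chars[tr$seq_pos[r] + 1L]))
      }
    }
    inserts[[i]] <- ins_i
  }
  widths <- integer(M)  # insert block width after match k (1-based)
  for (i in seq_len(n)) {
    for (key in names(inserts[[i]])) {
      k <- as.integer(key)
      widths[k] <- max(widths[k], nchar(inserts[[i]][[key]]))
    }
  }
  aln <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (k in seq_len(M)) {
      parts <- c(parts, mrow[i, k])
      if (widths[k] > 0) {
        ins <- inserts[[i]][[as.character(k)]] %||% ""
        parts <- c(parts,
                   paste0(ins, strrep(".", widths[k] - nchar(ins))))
      }
    }
    paste(parts, collapse = "")
  }, "")
  rf <- paste(vapply(seq_len(M), function(k)
    paste0("x", strrep(".", widths[k])), ""), collapse = "")
  new_msa(members$target, aln, rf = rf)
}

#' Iterative profile-HMM search
#'
#' Starting from a single query: find initial homologs, then repeatedly
#' build a model from the current member alignment, calibrate it, run a
#' filtered Viterbi search of the whole database, and admit new targets
#' whose E-value falls strictly below the iteration's scheduled cutoff.
#' Stops when no new member is admitted or after `params$max_iter`
#' iterations.  Members are never dropped, and a target keeps the
#' envelope from the iteration that first admitted it.  The final model
#' is rebuilt from the final alignment and calibrated for
#' `params$final_calibration` scoring.
#'
#' @param query One-row sequence tibble or residue string.
#' @param db Sequence tibble.
#' @param params An `iteration_params` object.
#' @param filter_params Sieve parameters used in every search.
#' @param e_init Initial-homolog admission cutoff.
#' @param calib_n Calibration sample size per iteration.
#' @param seed Integer seed; iteration i calibrates with `seed + i`.
#' @return A list of class `jackhmmer_result`: `model` (final, calibrated),
#'   `alignment`, `members`, `log` (per-iteration tibble), `iterations`,
#'   `converged`.
#' @export
jackhmmer <- function(query, db, params = iteration_params(),
                      filter_params = hmmsieve::filter_params(),
                      e_init = 1e-3, calib_n = 2000, seed = 1) {
  stopifnot(nrow(db) >= 1)
  if (is.character(query)) query <- aa_seqs("query", query)
  members <- initial_members(query, db, e_cutoff = e_init,
                             filter_params = filter_params,
                             calib_n = calib_n, seed = seed)
  msa <- align_members(seq_profile(query), members)
  log <- list(tibble::tibble(iteration = 0L, e_cutoff = e_init,
                             n_hits = NA_integer_,
                             n_new = nrow(members) - 1L,
                             n_members = nrow(members)))
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    e_cut <- schedule_at(params, iter)
    model <- build_profile(msa, bg = model_bg(query), name = query$id[1])
    model <- calibrate_profile(model, "viterbi", n = calib_n,
                               seed = seed + iter)
    hits <- hmm_search(db, model, filter_params, final = "viterbi",
                       e_cutoff = e_cut, filter = TRUE)
    hits <- hits[hits$evalue < e_cut, , drop = FALSE]
    new <- hits[!(hits$target %in% members$target), , drop = FALSE]
    new <- new[!duplicated(new$target), , drop = FALSE]
    log[[iter + 1L]] <- tibble::tibble(
      iteration = iter, e_cutoff = e_cut, n_hits = nrow(hits),
      n_new = nrow(new), n_members = nrow(members) + nrow(new))
    if (nrow(new) == 0) { converged <- TRUE; break }
    members <- dplyr::bind_rows(members, tibble::tibble(
      target = new$target, seq_start = new$seq_start,
      seq_end = new$seq_end,
      residues = substr(db$seq[match(new$target, db$id)],
                        new$seq_start + 1L, new$seq_end)))
    msa <- align_members(model, members)
  }
  final <- build_profile(msa, bg = model_bg(query), name = query$id[1])
  final <- calibrate_profile(final, params$final_calibration, n = calib_n,
                             seed = seed + iter + 1L)
  if (params$final_calibration != "viterbi")
    final <- calibrate_profile(final, "viterbi", n = calib_n,
                               seed = seed + iter + 2L)
  structure(list(model = final, alignment = msa, members = members,
                 log = dplyr::bind_rows(log), iterations = iter,
                 converged = converged),
            class = "jackhmmer_result")
}

model_bg <- function(query) amino_background()

#' @export
print.jackhmmer_result <- function(x, ...) {
  cat("<jackhmmer_result> ", nrow(x$members), " members after ",
      x$iterations, " iteration(s)",
      if (x$converged) " (converged)" else " (max iterations)", "\n",
      sep = "")
  invisible(x)
}

#' @rdname tidy
#' @description `glance.jackhmmer_result()` returns a one-row summary of
#'   an iterative search.
#' @export
glance.jackhmmer_result <- function(x, ...) {
  tibble::tibble(n_members = nrow(x$members), iterations = x$iterations,
                 converged = x$converged, model_M = x$model$M)
}

#' @rdname tidy
#' @description `tidy.jackhmmer_result()` returns the per-iteration log.
#' @export
tidy.jackhmmer_result <- function(x, ...) x$log
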