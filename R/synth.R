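# Synthetic protein families: an i.i.d. background ancestor, members
# derived by per-site substitution and geometric indels, embedded in
# random background flanks, with the true alignment recorded.  Together
# with shuffled decoys this emulates a remote-homology benchmark at desk
# scale.

#' Specification of a synthetic family
#'
#' @param length Ancestor length in residues (at least 10).
#' @param n_members Number of derived member sequences.
#' @param mutation_rate Per-site substitution probability; replacements
#'   are drawn from the background and may resample the same residue, so
#'   expected identity to the ancestor is `1 - mutation_rate * (1 - f)`
#'   averaged over the background.
#' @param indel_rate Per-site indel probability (half deletions, half
#'   insertions; insertion lengths geometric with mean 1.5, capped at 10).
#' @param flank_len Integer range `c(min, max)` of random background
#'   flanks added to each side of a member.
#' @param seed Integer seed.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(length = 120L, n_members = 20L,
                        mutation_rate = 0.15, indel_rate = 0.01,
                        flank_len = c(0L, 30L), seed = 1L) {
  stopifnot(length >= 10, n_members >= 1,
            mutation_rate >= 0, mutation_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  structure(list(length = as.integer(length),
                 n_members = as.integer(n_members),
                 mutation_rate = mutation_rate, indel_rate = indel_rate,
                 flank_len = as.integer(flank_len),
                 seed = as.integer(seed)),
            class = "family_spec")
}

draw_bg <- function(n, bg) sample(AA, n, replace = TRUE, prob = bg$freq)

#' Generate a synthetic protein family
#'
#' @param spec A `family_spec`.
#' @param bg Background model.
#' @param id Family identifier; member ids are `<id>_m<j>`.
#' @param ancestor Optional ancestor residue string of length
#'   `spec$length`; drawn from the background when `NULL`.  Passing the
#'   (possibly mutated) ancestor of another family builds nested
#'   subfamilies at controlled divergence.
#' @return A list with `msa` (the true core alignment, insert columns in
#'   lowercase), `members` (sequence tibble, flanks included),
#'   `ancestor` (residue string), and `spec`.
#' @export
generate_family <- function(spec, bg = amino_background(), id = "fam1",
                            ancestor = NULL) {
  with_seed(spec$seed, {
    L <- spec$length
    anc <- if (is.null(ancestor)) draw_bg(L, bg) else {
      stopifnot(nchar(ancestor) == L)
      strsplit(ancestor, "")[[1]]
    }
    half <- spec$indel_rate / 2
    core <- vector("list", spec$n_members)   # matrix rows over anc sites
    inserts <- vector("list", spec$n_members)
    seqs <- character(spec$n_members)
    for (i in seq_len(spec$n_members)) {
      row <- anc
      mut <- runif(L) < spec$mutation_rate
      row[mut] <- draw_bg(sum(mut), bg)
      del <- runif(L) < half
      row[del] <- "-"
      ins <- which(runif(L) < half)
      ins_i <- list()
      for (j in ins) {
        len <- min(10L, rgeom(1, 1 / 1.5) + 1L)
        ins_i[[as.character(j)]] <- paste(draw_bg(len, bg), collapse = "")
      }
      core[[i]] <- row
      inserts[[i]] <- ins_i
      body <- character(0)
      for (j in seq_len(L)) {
        if (row[j] != "-") body <- c(body, row[j])
        insj <- ins_i[[as.character(j)]]
        if (!is.null(insj)) body <- c(body, insj)
      }
      fl <- sample(seq(spec$flank_len[1], spec$flank_len[2]), 2,
                   replace = TRUE)
      seqs[i] <- paste0(paste(draw_bg(fl[1], bg), collapse = ""),
                        paste(body, collapse = ""),
                        paste(draw_bg(fl[2], bg), collapse = ""))
    }
    widths <- integer(L)
    for (i in seq_len(spec$n_members)) {
      for (key in names(inserts[[i]]))
        widths[as.integer(key)] <- max(widths[as.integer(key)],
                                       nchar(inserts[[i]][[key]]))
    }
    aln <- vapply(seq_len(spec$n_members), function(i) {
      parts <- character(0)
      for (j in seq_len(L)) {
        parts <- c(parts, core[[i]][j])
        if (widths[j] > 0) {
          insj <- tolower(inserts[[i]][[as.character(j)]] %||% "")
          parts <- c(parts, paste0(insj, strrep(".", widths[j] - nchar(insj))))
        }
      }
      paste(parts, collapse = "")
    }, "")
    ids <- paste0(id, "_m", seq_len(spec$n_members))
    rf <- paste(vapply(seq_len(L), function(j)
      paste0("x", strrep(".", widths[j])), ""), collapse = "")
    list(msa = new_msa(ids, aln, rf = rf),
         members = aa_seqs(ids, seqs, desc = paste("member of", id),
                           bg = bg),
         ancestor = paste(anc, collapse = ""),
         spec = spec)
  })
}

#' Assemble a benchmark database from synthetic families
#'
#' The database holds every family member plus `decoys_per_seq` shuffled
#' copies of each; the truth table labels ordered (query, target) pairs:
#' same family `true_homolog`, decoy `false_hit`, different family
#' `ambiguous`.  Self pairs are excluded.
#'
#' @param families List of [generate_family()] results.
#' @param decoys_per_seq Shuffled copies per member (default 5).
#' @param seed Integer seed for the shuffles.
#' @return A list with `db` (sequence tibble), `truth` (tibble `query`,
#'   `target`, `label`), and `family` (tibble `id`, `family`).
#' @export
make_test_db <- function(families, decoys_per_seq = 5L, seed = 1) {
  stopifnot(length(families) >= 1)
  mem <- dplyr::bind_rows(lapply(seq_along(families), function(i) {
    dplyr::mutate(families[[i]]$members,
                  family = sub("_m[0-9]+$", "", .data$id[1]))
  }))
  reals <- mem[c("id", "desc", "seq")]
  decoys <- make_decoys(reals, copies = decoys_per_seq, seed = seed)
  db <- dplyr::bind_rows(reals, decoys)
  fam_of <- setNames(mem$family, mem$id)
  truth <- tidyr::expand_grid(query = mem$id, target = db$id) |>
    dplyr::filter(.data$query != .data$target) |>
    dplyr::mutate(label = dplyr::case_when(
      is.na(fam_of[.data$target]) ~ "false_hit",
      fam_of[.data$target] == fam_of[.data$query] ~ "true_homolog",
      TRUE ~ "ambiguous"))
  list(db = db, truth = truth,
       family = tibble::tibble(id = mem$id, family = mem$family))
}
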