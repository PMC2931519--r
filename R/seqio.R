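# Sequence and alignment I/O, plus composition-preserving shuffling.
#
# A sequence database is an ordinary tibble with columns `id`, `desc`,
# `seq`; an alignment is a tibble with columns `id`, `aln` (equal-width
# gapped strings) carrying class "aa_msa" and an optional "rf" attribute.

#' Construct a sequence tibble
#'
#' @param id Character vector of unique, whitespace-free identifiers.
#' @param seq Character vector of residue strings (degenerate codes are
#'   resolved onto the 20-letter alphabet).
#' @param desc Optional descriptions.
#' @param bg Background used to resolve the degenerate code `X`.
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @export
aa_seqs <- function(id, seq, desc = "", bg = amino_background()) {
  id <- as.character(id)
  if (any(grepl("\\s", id))) stop("sequence ids must not contain whitespace")
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  seq <- resolve_degenerate(toupper(as.character(seq)), bg)
  if (any(nchar(seq) == 0L)) stop("empty sequence record")
  tibble::tibble(id = id, desc = rep_len(as.character(desc), length(id)),
                 seq = seq)
}

#' Read a protein FASTA file
#'
#' One row per record, order preserved.  Degenerate residue codes are
#' resolved deterministically (B to D, Z to E, U to C, O to K, X to the
#' most frequent background residue) so that downstream scoring sees only
#' the 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param bg Background used for degenerate-code resolution.
#' @return A tibble with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, bg = amino_background()) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA parse error: no records in '", path, "'")
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  res <- as.character(set)
  empty <- which(nchar(res) == 0L)
  if (length(empty))
    stop("FASTA parse error: empty record '", id[empty[1]],
         "' (record ", empty[1], ")")
  res <- gsub("[*]", "", res)
  aa_seqs(id = id, seq = res, desc = desc, bg = bg)
}

#' Write sequences to FASTA
#'
#' @param seqs Sequence tibble (columns `id`, `seq`, optional `desc`).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  desc <- if ("desc" %in% names(seqs)) seqs$desc else ""
  nm <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::AAStringSet(setNames(seqs$seq, nm))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

new_msa <- function(id, aln, rf = NULL) {
  w <- unique(nchar(aln))
  if (length(w) != 1L) {
    bad <- id[nchar(aln) != nchar(aln)[1]]
    stop("alignment rows have unequal lengths (offending ids: ",
         paste(bad, collapse = ", "), ")")
  }
  if (!is.null(rf) && nchar(rf) != w)
    stop("RF annotation length does not match alignment columns")
  out <- tibble::tibble(id = id, aln = aln)
  attr(out, "rf") <- rf
  class(out) <- c("aa_msa", class(out))
  out
}

#' Number of columns in an alignment
#' @param msa An `aa_msa` tibble.
#' @return Integer column count.
#' @export
msa_columns <- function(msa) nchar(msa$aln[1])

#' Read a multiple sequence alignment
#'
#' Supports Stockholm (single- or multi-block; a `#=GC RF` line is retained
#' as the `rf` attribute) and aligned FASTA.  Gap characters are `-` and
#' `.`; rows must have equal length.
#'
#' @param path Path to the alignment file.
#' @param format `"stockholm"` or `"afa"`.
#' @return An `aa_msa` tibble with columns `id` and `aln`.
#' @export
read_alignment <- function(path, format = c("stockholm", "afa")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "afa") {
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0L) stop("alignment parse error: no records")
    return(new_msa(sub("\\s.*$", "", names(set)),
                   unname(as.character(set))))
  }
  lines <- readLines(path)
  rows <- list()
  rf <- NULL
  order <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "//" ) break
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      if (grepl("^#=GC\\s+RF\\s+", ln)) {
        piece <- sub("^#=GC\\s+RF\\s+", "", ln)
        rf <- paste0(if (is.null(rf)) "" else rf, gsub("\\s", "", piece))
      }
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("Stockholm parse error at line ", i, ": expected 'name sequence'")
    nm <- parts[1]
    if (!nm %in% order) order <- c(order, nm)
    rows[[nm]] <- paste0(if (is.null(rows[[nm]])) "" else rows[[nm]], parts[2])
  }
  if (length(rows) == 0L) stop("Stockholm parse error: no sequence rows")
  aln <- unlist(rows[order], use.names = FALSE)
  w <- nchar(aln)
  if (length(unique(w)) != 1L)
    stop("alignment rows have unequal lengths (offending ids: ",
         paste(order[w != w[1]], collapse = ", "), ")")
  new_msa(order, aln, rf = rf)
}

#' Write an alignment in Stockholm format
#'
#' @param msa An `aa_msa` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(msa, path) {
  pad <- max(nchar(msa$id), 9L) + 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(sprintf("%-*s%s", pad, msa$id, msa$aln), con)
  rf <- attr(msa, "rf")
  if (!is.null(rf)) writeLines(sprintf("%-*s%s", pad, "#=GC RF", rf), con)
  writeLines("//", con)
  invisible(path)
}

#' Strip gaps from alignment rows
#' @param msa An `aa_msa` tibble.
#' @return A sequence tibble of the ungapped rows.
#' @export
msa_to_seqs <- function(msa) {
  aa_seqs(id = msa$id, seq = toupper(gsub("[-.]", "", msa$aln)))
}

#' Shuffle sequences residue-by-residue
#'
#' Produces composition-preserving decoys: each output is a uniformly
#' random permutation (Fisher-Yates, via R's `sample`) of its source
#' residues.  Deterministic for a given seed; copies are grouped per source
#' sequence, in input order, with ids suffixed `_shuf<k>`.
#'
#' @param seqs Sequence tibble.
#' @param seed Integer seed.
#' @param copies Number of shuffled copies per input sequence.
#' @return A tibble of `copies * nrow(seqs)` shuffled sequences.
#' @export
#' @examples
#' s <- aa_seqs("q", "ACDEFGHIK")
#' shuffle_sequences(s, seed = 1, copies = 2)
shuffle_sequences <- function(seqs, seed, copies = 1L) {
  stopifnot(copies >= 1L)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(seqs)), function(i) {
      r <- strsplit(seqs$seq[i], "")[[1]]
      tibble::tibble(
        id = paste0(seqs$id[i], "_shuf", seq_len(copies)),
        desc = paste("shuffle of", seqs$id[i]),
        seq = vapply(seq_len(copies),
                     function(k) paste(sample(r), collapse = ""), ""))
    })
    dplyr::bind_rows(out)
  })
}
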