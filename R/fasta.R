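#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a tibble with one row per entry.
#' Sequences are uppercased; record order is preserved. The record id is the
#' first whitespace-delimited token of the header, the rest is kept as the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description` and `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "MKLV", ">p2", "acdef"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "acr_input_error")
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    abort(paste0("FASTA file contains no records: ", path), class = "acr_input_error")
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")),
          class = "acr_input_error")
  }
  sequence <- toupper(as.character(seqs))
  if (any(!nzchar(sequence))) {
    bad <- ids[!nzchar(sequence)]
    abort(paste0("empty sequence for record(s): ", paste(bad, collapse = ", ")),
          class = "acr_input_error")
  }
  tibble(id = ids, description = unname(desc), sequence = unname(sequence))
}

#' Write a protein tibble to FASTA
#'
#' @param proteins A tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  check_protein_tbl(proteins)
  hdr <- proteins$id
  if (!is.null(proteins$description)) {
    has_desc <- nzchar(proteins$description)
    hdr[has_desc] <- paste(proteins$id[has_desc], proteins$description[has_desc])
  }
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

check_protein_tbl <- function(proteins) {
  if (!is.data.frame(proteins) || !all(c("id", "sequence") %in% names(proteins))) {
    abort("`proteins` must be a data frame with columns `id` and `sequence`",
          class = "acr_input_error")
  }
  invisible(proteins)
}

#' Validate protein sequences against the standard amino-acid alphabet
#'
#' Uppercases every sequence and checks that it only contains the 20 standard
#' amino-acid letters. Under `policy = "reject"` (default) any other letter is
#' an error naming the record, position and offending character. Under
#' `policy = "mask"` nonstandard letters (including B, Z, U, O and existing X)
#' are replaced by `"X"`; the composition descriptors and the PSSM row
#' selector treat `X` as a 21st residue type that contributes to no feature,
#' while the sequence length keeps its full value.
#'
#' @param proteins A protein tibble (see [read_fasta()]).
#' @param policy Either `"reject"` or `"mask"`.
#' @return The validated protein tibble.
#' @export
validate_proteins <- function(proteins, policy = c("reject", "mask")) {
  policy <- match.arg(policy)
  check_protein_tbl(proteins)
  seqs <- toupper(proteins$sequence)
  if (any(!nzchar(seqs))) {
    abort("empty sequence(s) present", class = "acr_input_error")
  }
  ok <- paste(acr_residues(), collapse = "")
  bad_re <- paste0("[^", ok, "]")
  hit <- regexpr(bad_re, seqs)
  if (policy == "reject") {
    if (any(hit > 0L)) {
      i <- which(hit > 0L)[1L]
      letter <- substr(seqs[i], hit[i], hit[i])
      abort(
        paste0("nonstandard residue '", letter, "' at position ", hit[i],
               " in record '", proteins$id[i], "'"),
        class = "acr_input_error"
      )
    }
  } else {
    seqs <- gsub(bad_re, "X", seqs)
  }
  proteins$sequence <- seqs
  proteins
}

#' Keep proteins whose length falls in a closed interval
#'
#' Anti-CRISPRs are small proteins; the training-data convention keeps
#' sequences of 50 to 350 residues, boundaries included. The filter is
#' order-preserving and idempotent.
#'
#' @param proteins A protein tibble.
#' @param min_len,max_len Inclusive length bounds (defaults 50 and 350).
#' @return The filtered tibble.
#' @export
filter_by_length <- function(proteins, min_len = 50L, max_len = 350L) {
  check_protein_tbl(proteins)
  if (min_len > max_len) {
    abort("`min_len` must not exceed `max_len`", class = "acr_input_error")
  }
  len <- nchar(proteins$sequence)
  proteins[len >= min_len & len <= max_len, , drop = FALSE]
}
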