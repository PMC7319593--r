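# PSI-BLAST ASCII PSSM handling.
#
# A PSSM produced with `psiblast -out_ascii_pssm` holds, per query position,
# two 20-column blocks: integer log-odds scores and weighted observed
# percentages, followed by two per-position statistics. Only the first block
# (the log-odds P_{i,j}) feeds the descriptors; the parser targets the BLAST+
# layout and takes the first 20 integer columns of each row.

#' Construct a PSSM object
#'
#' @param protein_id Identifier matching a protein record.
#' @param scores Numeric L x 20 matrix of integer log-odds; columns in
#'   PSI-BLAST order ([acr_pssm_columns()]).
#' @param row_residues Character scalar (length-L string) or vector of the
#'   query residues, one per row.
#' @return An object of class `acr_pssm`: a list with elements `protein_id`,
#'   `scores` (with column names set) and `row_residues` (single string).
#' @export
new_pssm <- function(protein_id, scores, row_residues) {
  scores <- as.matrix(scores)
  if (length(row_residues) > 1L) row_residues <- paste(row_residues, collapse = "")
  if (ncol(scores) != 20L) {
    abort("PSSM must have exactly 20 score columns", class = "acr_input_error")
  }
  if (nrow(scores) != nchar(row_residues)) {
    abort("PSSM row count must equal the number of row residues",
          class = "acr_input_error")
  }
  if (nrow(scores) == 0L) {
    abort("PSSM has no rows", class = "acr_input_error")
  }
  storage.mode(scores) <- "double"
  dimnames(scores) <- list(NULL, acr_pssm_columns())
  structure(
    list(protein_id = protein_id, scores = scores, row_residues = row_residues),
    class = "acr_pssm"
  )
}

#' @export
print.acr_pssm <- function(x, ...) {
  cat("<acr_pssm> ", x$protein_id, ": ", nrow(x$scores), " x 20\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Parses the text of a `psiblast -out_ascii_pssm` file, keeping the first
#' block of 20 integer (log-odds) columns. Trailing statistics lines are
#' ignored.
#'
#' @param text Character vector of file lines, or a single string.
#' @param protein_id Identifier to attach to the matrix.
#' @return An `acr_pssm` object.
#' @export
parse_pssm <- function(text, protein_id = NA_character_) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  std <- acr_pssm_columns()
  toks <- strsplit(trimws(text), "\\s+")
  header_at <- NA_integer_
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) %in% c(20L, 40L) && all(tk %in% std) &&
        setequal(tk[1:20], std)) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at)) {
    abort("no PSSM header line (20 or 40 residue columns) found",
          class = "acr_parse_error")
  }
  col_order <- toks[[header_at]][1:20]
  residues <- character(0)
  rows <- list()
  for (i in seq(header_at + 1L, length(toks))) {
    tk <- toks[[i]]
    if (length(tk) == 0L || all(tk == "")) break
    # data rows start with a 1-based position index and the query residue
    if (!grepl("^[0-9]+$", tk[1L])) break
    if (length(tk) < 22L) {
      abort(paste0("truncated PSSM row at line ", i, ": expected at least 22 ",
                   "fields, found ", length(tk)),
            class = "acr_parse_error")
    }
    vals <- suppressWarnings(as.integer(tk[3:22]))
    if (anyNA(vals)) {
      abort(paste0("non-integer score token at line ", i),
            class = "acr_parse_error")
    }
    residues[length(residues) + 1L] <- tk[2L]
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) {
    abort("PSSM contains no score rows", class = "acr_parse_error")
  }
  scores <- do.call(rbind, rows)
  # reorder columns if the file uses a nonstandard permutation
  if (!identical(col_order, std)) scores <- scores[, match(std, col_order), drop = FALSE]
  new_pssm(protein_id, scores, residues)
}

#' Read one PSSM file
#'
#' @param path Path to an ASCII PSSM file; the protein id defaults to the file
#'   name without its `.pssm` extension.
#' @param protein_id Optional explicit id.
#' @return An `acr_pssm` object.
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("PSSM file not found: ", path), class = "acr_input_error")
  }
  if (is.null(protein_id)) {
    protein_id <- sub("\\.pssm$", "", basename(path))
  }
  parse_pssm(readLines(path, warn = FALSE), protein_id)
}

#' Write a PSSM in the ASCII dialect the parser reads
#'
#' Emits the BLAST+-style layout (position, residue, 20 integer log-odds,
#' a zero-filled percentage block and two trailing statistics columns), so
#' that `parse_pssm(write_pssm(x))` round-trips exactly.
#'
#' @param pssm An `acr_pssm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "acr_pssm"))
  std <- acr_pssm_columns()
  res <- strsplit(pssm$row_residues, "")[[1L]]
  header <- paste0("            ", paste(sprintf("%3s", c(std, std)), collapse = " "))
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    header
  )
  for (i in seq_len(nrow(pssm$scores))) {
    lines[length(lines) + 1L] <- paste0(
      sprintf("%5d %s ", i, res[i]),
      paste(sprintf("%3d", as.integer(pssm$scores[i, ])), collapse = " "),
      "  ",
      paste(sprintf("%3d", integer(20L)), collapse = " "),
      "  0.00 0.00"
    )
  }
  lines <- c(lines, "", "                      K         Lambda",
             "Standard Ungapped    0.1347     0.3176")
  writeLines(lines, path)
  invisible(path)
}

#' Read a directory of per-protein PSSM files
#'
#' Follows the `<dir>/<protein_id>.pssm` convention.
#'
#' @param dir Directory containing the `.pssm` files.
#' @param ids Protein ids to load.
#' @return A named list of `acr_pssm` objects, one per id.
#' @export
read_pssm_dir <- function(dir, ids) {
  paths <- file.path(dir, paste0(ids, ".pssm"))
  missing <- ids[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(paste0("missing PSSM file(s) for: ", paste(missing, collapse = ", ")),
          class = "acr_input_error")
  }
  setNames(lapply(seq_along(ids), function(i) read_pssm(paths[i], ids[i])), ids)
}

#' Check that proteins and PSSMs pair up
#'
#' Asserts that every protein has a PSSM whose row residues equal its
#' sequence. Run at pipeline entry before any encoding.
#'
#' @param proteins A protein tibble.
#' @param pssms A named list of `acr_pssm` objects.
#' @return Invisibly, the protein tibble.
#' @export
check_pssm_pairing <- function(proteins, pssms) {
  check_protein_tbl(proteins)
  missing <- setdiff(proteins$id, names(pssms))
  if (length(missing) > 0L) {
    abort(paste0("no PSSM for protein(s): ", paste(missing, collapse = ", ")),
          class = "acr_input_error")
  }
  for (i in seq_len(nrow(proteins))) {
    p <- pssms[[proteins$id[i]]]
    if (!identical(p$row_residues, proteins$sequence[i])) {
      abort(paste0("PSSM row residues disagree with sequence for '",
                   proteins$id[i], "'"),
            class = "acr_input_error")
    }
  }
  invisible(proteins)
}

#' PSI-BLAST configuration
#'
#' Settings for generating PSSMs with an external BLAST+ `psiblast` binary:
#' iterative search of each query against a protein database, keeping hits
#' above the e-value cut-off. Defaults follow the conventional profile-search
#' protocol (3 iterations, e-value 0.001) used to build anti-CRISPR
#' descriptors; the database (e.g. UniRef50) is supplied by the user and
#' never bundled.
#'
#' @param database Path to a formatted BLAST protein database.
#' @param binary Name or path of the `psiblast` executable.
#' @param iterations Number of PSI-BLAST iterations (>= 1; default 3).
#' @param evalue Inclusion e-value threshold (> 0; default 0.001).
#' @param on_no_hits What to do when the search produces no PSSM: `"error"`
#'   (default) or `"blosum"`, which substitutes a pseudo-PSSM whose row for
#'   residue r is the BLOSUM62 row of r (flagged via the `fallback`
#'   attribute).
#' @return A list of class `acr_psiblast_config`.
#' @export
psiblast_config <- function(database, binary = "psiblast", iterations = 3L,
                            evalue = 0.001, on_no_hits = c("error", "blosum")) {
  if (iterations < 1L) abort("`iterations` must be >= 1", class = "acr_input_error")
  if (evalue <= 0) abort("`evalue` must be positive", class = "acr_input_error")
  structure(
    list(database = database, binary = binary, iterations = as.integer(iterations),
         evalue = evalue, on_no_hits = match.arg(on_no_hits)),
    class = "acr_psiblast_config"
  )
}

blosum_pseudo_pssm <- function(protein_id, sequence) {
  b62 <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  res <- strsplit(sequence, "")[[1L]]
  scores <- b62[res, acr_pssm_columns(), drop = FALSE]
  out <- new_pssm(protein_id, scores, sequence)
  attr(out, "fallback") <- "blosum62"
  out
}

#' Generate PSSMs with an external PSI-BLAST binary
#'
#' Runs `psiblast` for every protein in `proteins` against the configured
#' database, writes `<out_dir>/<id>.pssm`, and parses the results. Queries
#' for which PSI-BLAST emits no matrix (no hits above the e-value cut-off)
#' are handled according to `config$on_no_hits`.
#'
#' @param proteins A protein tibble.
#' @param config An [psiblast_config()] object.
#' @param out_dir Directory receiving the ASCII PSSM files.
#' @return A named list of `acr_pssm` objects.
#' @export
run_psiblast <- function(proteins, config, out_dir) {
  check_protein_tbl(proteins)
  stopifnot(inherits(config, "acr_psiblast_config"))
  if (Sys.which(config$binary) == "" && !file.exists(config$binary)) {
    abort(paste0("psiblast binary not found: ", config$binary),
          class = "acr_external_error")
  }
  db_check <- paste0(config$database, c(".pin", ".pdb", ""))
  if (!any(file.exists(db_check))) {
    abort(paste0("BLAST database not found: ", config$database),
          class = "acr_external_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    qf <- tempfile(fileext = ".fasta")
    writeLines(c(paste0(">", id), proteins$sequence[i]), qf)
    pf <- file.path(out_dir, paste0(id, ".pssm"))
    status <- system2(
      config$binary,
      c("-query", qf, "-db", config$database,
        "-num_iterations", config$iterations,
        "-evalue", format(config$evalue, scientific = FALSE),
        "-out_ascii_pssm", pf, "-out", tempfile()),
      stdout = FALSE, stderr = FALSE
    )
    unlink(qf)
    if (status != 0L || !file.exists(pf)) {
      if (config$on_no_hits == "blosum") {
        p <- blosum_pseudo_pssm(id, proteins$sequence[i])
        write_pssm(p, pf)
        out[[id]] <- p
        next
      }
      abort(paste0("PSI-BLAST produced no PSSM for '", id,
                   "' (no hits above the e-value cut-off?)"),
            class = "acr_external_error")
    }
    out[[id]] <- read_pssm(pf, id)
  }
  out
}
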