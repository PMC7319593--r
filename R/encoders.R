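# Feature encoders.
#
# Six descriptors map a protein (sequence + L x 20 PSSM) to a fixed-length
# vector:
#   AAC        20   residue frequencies
#   DPC        400  dipeptide frequencies
#   PSSM_COMP  400  PSSM rows summed and L-averaged per residue type,
#                   20 x 20 flattened row-by-row
#   DPC_PSSM   400  adjacent-row column cross-products,
#                   y_{i,j} = 1/(L-1) * sum_k p_{k,i} p_{k+1,j}
#   PSSM_AC    20*LG column-wise autocovariance at lags 1..LG (default 200)
#   RPSSM      110  on the 10-column reduced PSSM: 100 adjacent-row squared
#                   half-differences D_{s,t} then 10 column variances D_s
#
# All computation is in double precision; element orderings are fixed (see
# each function) because they are part of the persisted model format.

seq_chars <- function(sequence) strsplit(sequence, "")[[1L]]

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 standard residues, in alphabetical order.
#' Nonstandard letters (policy `"mask"`) count toward the length L but toward
#' no residue frequency.
#'
#' @param sequence A protein sequence string.
#' @return Named numeric vector of length 20.
#' @export
aac_vector <- function(sequence) {
  ch <- seq_chars(sequence)
  L <- length(ch)
  if (L < 1L) abort("empty sequence", class = "acr_input_error")
  res <- acr_residues()
  counts <- table(factor(ch, levels = res))
  setNames(as.numeric(counts) / L, res)
}

#' Dipeptide composition (DPC)
#'
#' Frequency of each of the 400 ordered dipeptides among the L-1 adjacent
#' pairs, in alphabetical row-major order (AA, AC, ..., YY).
#'
#' @param sequence A protein sequence string (length >= 2).
#' @return Named numeric vector of length 400.
#' @export
dpc_vector <- function(sequence) {
  ch <- seq_chars(sequence)
  L <- length(ch)
  if (L < 2L) abort("sequence must have length >= 2 for DPC", class = "acr_input_error")
  res <- acr_residues()
  lv <- as.vector(t(outer(res, res, paste0)))
  dip <- paste0(ch[-L], ch[-1L])
  counts <- table(factor(dip, levels = lv))
  setNames(as.numeric(counts) / (L - 1L), lv)
}

#' PSSM-composition descriptor
#'
#' For each residue type a_i, sums the PSSM rows at positions where the query
#' residue equals a_i and divides by the full length L, giving a 20 x 20
#' matrix flattened row-by-row (row = residue type, column = PSSM column).
#' Rows of residue types absent from the sequence (and rows at masked `X`
#' positions) contribute zeros; L always remains the full sequence length.
#'
#' @param pssm An `acr_pssm` object.
#' @return Named numeric vector of length 400.
#' @export
pssm_composition_vector <- function(pssm) {
  stopifnot(inherits(pssm, "acr_pssm"))
  P <- pssm$scores
  L <- nrow(P)
  res <- strsplit(pssm$row_residues, "")[[1L]]
  cols <- acr_pssm_columns()
  f <- factor(res, levels = cols)
  M <- matrix(0, 20L, 20L, dimnames = list(cols, cols))
  keep <- !is.na(f)
  if (any(keep)) {
    sums <- rowsum(P[keep, , drop = FALSE], f[keep])
    M[rownames(sums), ] <- sums / L
  }
  v <- as.vector(t(M))
  names(v) <- as.vector(t(outer(cols, cols, function(a, b) paste0(a, "_", b))))
  v
}

#' DPC-PSSM descriptor
#'
#' Adjacent-row cross-products of PSSM columns:
#' `y[i, j] = sum_k P[k, i] * P[k + 1, j] / (L - 1)`, emitted in the order
#' (y_{1,1}, ..., y_{1,20}, y_{2,1}, ..., y_{20,20}).
#'
#' @param pssm An `acr_pssm` object with at least 2 rows.
#' @return Named numeric vector of length 400.
#' @export
dpc_pssm_vector <- function(pssm) {
  stopifnot(inherits(pssm, "acr_pssm"))
  P <- pssm$scores
  L <- nrow(P)
  if (L < 2L) abort("PSSM must have >= 2 rows for DPC-PSSM", class = "acr_input_error")
  Y <- crossprod(P[-L, , drop = FALSE], P[-1L, , drop = FALSE]) / (L - 1L)
  cols <- acr_pssm_columns()
  v <- as.vector(t(Y))
  names(v) <- as.vector(t(outer(cols, cols, function(a, b) paste0(a, "_", b))))
  v
}

#' PSSM autocovariance (PSSM-AC) descriptor
#'
#' For each PSSM column j, the autocovariance
#' `AC(j, lg) = sum_i (P[i,j] - mean_j)(P[i+lg, j] - mean_j) / (L - lg)` at
#' lags `lg = 1..lag`. Output is ordered column-by-column: all lags of column
#' 1, then all lags of column 2, and so on (20 * lag values).
#'
#' @param pssm An `acr_pssm` object.
#' @param lag Maximum lag LG (default 10); requires `L > lag`.
#' @return Named numeric vector of length `20 * lag`.
#' @export
pssm_ac_vector <- function(pssm, lag = 10L) {
  stopifnot(inherits(pssm, "acr_pssm"))
  lag <- as.integer(lag)
  if (lag < 1L) abort("`lag` must be >= 1", class = "acr_input_error")
  P <- pssm$scores
  L <- nrow(P)
  if (L <= lag) {
    abort(paste0("sequence length (", L, ") must exceed the PSSM-AC lag (",
                 lag, ")"),
          class = "acr_input_error")
  }
  C <- sweep(P, 2L, colMeans(P))
  cols <- acr_pssm_columns()
  out <- numeric(20L * lag)
  nm <- character(20L * lag)
  k <- 0L
  for (j in seq_len(20L)) {
    x <- C[, j]
    for (lg in seq_len(lag)) {
      k <- k + 1L
      out[k] <- sum(x[seq_len(L - lg)] * x[seq(lg + 1L, L)]) / (L - lg)
      nm[k] <- paste0(cols[j], "_lag", lg)
    }
  }
  setNames(out, nm)
}

#' Reduce a PSSM to 10 physicochemical group columns
#'
#' Averages PSSM columns within the fixed residue groups FYW, ML, IV, ATS,
#' NH, QED, RK, C, G, P (in that order), giving an L x 10 matrix.
#'
#' @param pssm An `acr_pssm` object.
#' @return Numeric L x 10 matrix with group names as column names.
#' @export
reduce_pssm <- function(pssm) {
  stopifnot(inherits(pssm, "acr_pssm"))
  groups <- rpssm_groups()
  P <- pssm$scores
  out <- vapply(groups, function(g) rowMeans(P[, g, drop = FALSE]),
                numeric(nrow(P)))
  if (nrow(P) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- vapply(groups, paste, "", collapse = "")
  out
}

#' RPSSM descriptor
#'
#' On the reduced L x 10 PSSM, computes the 100 adjacent-row half squared
#' differences `D[s, t] = 1/(L-1) * sum_i (p[i, s] - p[i+1, t])^2 / 2` and
#' the 10 column variances `D[s] = sum_i (p[i, s] - mean_s)^2 / L`, emitted
#' as (D_{1,1}, D_{1,2}, ..., D_{10,10}, D_1, ..., D_10).
#'
#' @param pssm An `acr_pssm` object with at least 2 rows.
#' @return Named numeric vector of length 110; all entries are >= 0.
#' @export
rpssm_vector <- function(pssm) {
  R <- reduce_pssm(pssm)
  L <- nrow(R)
  if (L < 2L) abort("PSSM must have >= 2 rows for RPSSM", class = "acr_input_error")
  A <- R[-L, , drop = FALSE]
  B <- R[-1L, , drop = FALSE]
  # (a - b)^2 expanded so one crossprod serves all (s, t) pairs
  Dst <- (outer(colSums(A^2), colSums(B^2), "+") - 2 * crossprod(A, B)) /
    (2 * (L - 1L))
  Dst[Dst < 0] <- 0  # guard against tiny negative round-off
  Ds <- colSums(sweep(R, 2L, colMeans(R))^2) / L
  gn <- colnames(R)
  v <- c(as.vector(t(Dst)), Ds)
  names(v) <- c(
    as.vector(t(outer(gn, gn, function(a, b) paste0("D_", a, ".", b)))),
    paste0("D_", gn)
  )
  v
}

encode_one <- function(encoder, sequence, pssm, lag) {
  switch(encoder,
    AAC = aac_vector(sequence),
    DPC = dpc_vector(sequence),
    PSSM_COMP = pssm_composition_vector(pssm),
    DPC_PSSM = dpc_pssm_vector(pssm),
    PSSM_AC = pssm_ac_vector(pssm, lag),
    RPSSM = rpssm_vector(pssm),
    abort(paste0("unknown encoder tag: ", encoder), class = "acr_input_error")
  )
}

#' Encode proteins with the selected descriptors
#'
#' Computes feature vectors for every protein; by default the four
#' evolutionary (PSSM-derived) descriptors used by the ensemble model.
#' Protein/PSSM pairing is checked first (`row_residues` must equal the
#' sequence).
#'
#' @param proteins A protein tibble.
#' @param pssms Named list of `acr_pssm` objects (required unless only AAC
#'   and/or DPC are requested).
#' @param encoders Character vector of encoder tags among
#'   `r paste(acr_encoders(), collapse = ", ")`.
#' @param lag PSSM-AC maximum lag (default 10).
#' @return A tibble with columns `protein_id`, `encoder`, `dimension` and a
#'   list-column `values` of named numeric vectors.
#' @export
encode_features <- function(proteins, pssms = NULL,
                            encoders = acr_evolutionary_encoders(),
                            lag = 10L) {
  check_protein_tbl(proteins)
  bad <- setdiff(encoders, acr_encoders())
  if (length(bad) > 0L) {
    abort(paste0("unknown encoder tag(s): ", paste(bad, collapse = ", ")),
          class = "acr_input_error")
  }
  needs_pssm <- any(encoders %in% acr_evolutionary_encoders())
  if (needs_pssm) {
    if (is.null(pssms)) {
      abort("PSSM-derived encoders requested but `pssms` is NULL",
            class = "acr_input_error")
    }
    check_pssm_pairing(proteins, pssms)
  }
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    id <- proteins$id[i]
    purrr::map(encoders, function(enc) {
      v <- encode_one(enc, proteins$sequence[i], pssms[[id]], lag)
      tibble(protein_id = id, encoder = enc, dimension = length(v),
             values = list(v))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Extract a feature matrix for one encoder
#'
#' @param features A feature tibble from [encode_features()].
#' @param encoder A single encoder tag.
#' @return Numeric matrix with one row per protein (row names = protein ids).
#' @export
feature_matrix <- function(features, encoder) {
  rows <- features[features$encoder == encoder, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort(paste0("no features for encoder '", encoder, "'"),
          class = "acr_input_error")
  }
  m <- do.call(rbind, rows$values)
  rownames(m) <- rows$protein_id
  m
}

#' Write / read a tab-separated feature table
#'
#' One row per (protein, encoder): `protein_id`, `encoder`, then the feature
#' values with their element names as column headers are not practical across
#' encoders of different dimensions, so values are serialized as
#' tab-separated numbers after the two key columns. `read_feature_table()`
#' restores the tibble bit-identically (full double precision).
#'
#' @param features A feature tibble from [encode_features()].
#' @param path Output path.
#' @return `path` (writer) or the restored feature tibble (reader).
#' @export
write_feature_table <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(features))) {
    cat(features$protein_id[i], features$encoder[i],
        sprintf("%.17g", features$values[[i]]),
        file = con, sep = "\t")
    cat("\n", file = con)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @param lag PSSM-AC lag used when the table was written (restores element
#'   names).
#' @export
read_feature_table <- function(path, lag = 10L) {
  if (!file.exists(path)) {
    abort(paste0("feature table not found: ", path), class = "acr_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map(parts, function(tk) {
    enc <- tk[2L]
    v <- as.numeric(tk[-(1:2)])
    names(v) <- feature_names(enc, length(v), lag)
    tibble(protein_id = tk[1L], encoder = enc, dimension = length(v),
           values = list(v))
  })
  dplyr::bind_rows(rows)
}

feature_names <- function(encoder, n, lag) {
  res <- acr_residues()
  cols <- acr_pssm_columns()
  gn <- vapply(rpssm_groups(), paste, "", collapse = "")
  switch(encoder,
    AAC = res,
    DPC = as.vector(t(outer(res, res, paste0))),
    PSSM_COMP = ,
    DPC_PSSM = as.vector(t(outer(cols, cols, function(a, b) paste0(a, "_", b)))),
    PSSM_AC = as.vector(vapply(cols, function(cc) paste0(cc, "_lag", seq_len(n / 20L)),
                               character(n / 20L))),
    RPSSM = c(as.vector(t(outer(gn, gn, function(a, b) paste0("D_", a, ".", b)))),
              paste0("D_", gn)),
    NULL
  )
}
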