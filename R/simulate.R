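# Seeded synthetic-data generators.
#
# These emulate the *shape* of an anti-CRISPR training problem — a small
# positive class against a ~10x larger negative pool, protein lengths in the
# 50-350 residue band, integer PSSM scores — without any claim of realism
# about PSI-BLAST score distributions or phylogenetic structure. The class
# signal is injected in PSSM space (a constant shift on a fixed set of
# columns for positives) so that every PSSM-derived descriptor can see it.

local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a random protein record
#'
#' Uniform-random sequence over the 20 standard residues; deterministic for a
#' given seed.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @param id Record id (default derived from the seed).
#' @return A one-row protein tibble.
#' @export
sim_protein <- function(length, seed, id = paste0("sim", seed)) {
  if (length < 1L) abort("`length` must be >= 1", class = "acr_input_error")
  local_seed(seed, {
    s <- paste(sample(acr_residues(), length, replace = TRUE), collapse = "")
    tibble(id = id, description = "synthetic protein", sequence = s)
  })
}

#' Generate a random PSSM for a protein
#'
#' Integer scores uniform over `score_range`; optionally a constant
#' `shift` (rounded to integer) is added to the columns named in
#' `shift_columns`, emulating class-specific conservation.
#'
#' @param protein A one-row protein tibble.
#' @param seed Integer seed.
#' @param score_range Length-2 integer range (default `c(-10, 10)`).
#' @param shift Non-negative shift added to `shift_columns` (default 0).
#' @param shift_columns Residue letters naming the shifted PSSM columns.
#' @return An `acr_pssm` object.
#' @export
sim_pssm <- function(protein, seed, score_range = c(-10L, 10L), shift = 0,
                     shift_columns = c("F", "L", "I", "A", "R")) {
  check_protein_tbl(protein)
  if (score_range[1L] > score_range[2L]) {
    abort("empty score range", class = "acr_input_error")
  }
  L <- nchar(protein$sequence[1L])
  local_seed(seed, {
    scores <- matrix(
      sample(seq(score_range[1L], score_range[2L]), L * 20L, replace = TRUE),
      nrow = L, ncol = 20L
    )
    colnames(scores) <- acr_pssm_columns()
    if (shift != 0) {
      scores[, shift_columns] <- scores[, shift_columns] + round(shift)
    }
    new_pssm(protein$id[1L], scores, protein$sequence[1L])
  })
}

#' Assemble a labelled dataset container
#'
#' @param ids Protein ids (unique, ordered).
#' @param labels Integer 0/1 labels aligned to `ids` (1 = anti-CRISPR).
#' @param features Named list mapping encoder tag to a feature matrix whose
#'   rows align with `ids`.
#' @return A list of class `acr_dataset` with elements `ids`, `labels`,
#'   `features`.
#' @export
acr_dataset <- function(ids, labels, features) {
  if (anyDuplicated(ids)) abort("duplicate ids in dataset", class = "acr_input_error")
  if (length(labels) != length(ids)) {
    abort("`labels` must align with `ids`", class = "acr_input_error")
  }
  if (!all(labels %in% c(0L, 1L))) {
    abort("labels must be 0/1", class = "acr_input_error")
  }
  for (enc in names(features)) {
    m <- features[[enc]]
    if (nrow(m) != length(ids) || !identical(rownames(m), as.character(ids))) {
      abort(paste0("feature matrix '", enc, "' does not align with ids"),
            class = "acr_input_error")
    }
  }
  structure(list(ids = as.character(ids), labels = as.integer(labels),
                 features = features),
            class = "acr_dataset")
}

#' @export
print.acr_dataset <- function(x, ...) {
  cat("<acr_dataset> ", length(x$ids), " proteins (",
      sum(x$labels == 1L), " positive / ", sum(x$labels == 0L),
      " negative); encoders: ", paste(names(x$features), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Subset a dataset by position or id, preserving alignment.
dataset_slice <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$ids)
  acr_dataset(
    dataset$ids[idx],
    dataset$labels[idx],
    lapply(dataset$features, function(m) m[idx, , drop = FALSE])
  )
}

#' Generate a labelled synthetic anti-CRISPR dataset
#'
#' Draws `n_pos` positive and `n_neg` negative proteins with lengths uniform
#' in `length_range` and per-protein random PSSMs; positives receive
#' `class_shift` on the fixed `shift_columns` before encoding, so class
#' separability grows with the shift and is visible to all four evolutionary
#' descriptors. At `class_shift = 0` the two classes are exchangeable.
#'
#' @param n_pos,n_neg Class sizes.
#' @param class_shift Non-negative PSSM column shift for positives.
#' @param seed Integer seed; every record's sequence and PSSM derive from it.
#' @param length_range,score_range Integer ranges (defaults `c(50, 350)` and
#'   `c(-10, 10)`).
#' @param shift_columns Residue letters naming the shifted columns.
#' @param encoders Encoders to compute (default the four evolutionary ones).
#' @param lag PSSM-AC lag.
#' @param write_dir Optional directory; when given, the FASTA
#'   (`proteins.fasta`) and per-id `.pssm` files are also written there.
#' @param id_prefix Prefix for generated ids.
#' @return A list with `proteins` (tibble), `pssms` (named list) and
#'   `dataset` (`acr_dataset`).
#' @export
sim_acr_dataset <- function(n_pos, n_neg, class_shift = 0, seed = 1L,
                            length_range = c(50L, 350L),
                            score_range = c(-10L, 10L),
                            shift_columns = c("F", "L", "I", "A", "R"),
                            encoders = acr_evolutionary_encoders(),
                            lag = 10L, write_dir = NULL, id_prefix = "sim") {
  if (n_pos < 0L || n_neg < 0L) abort("negative class size", class = "acr_input_error")
  if (class_shift < 0) abort("`class_shift` must be >= 0", class = "acr_input_error")
  if (length_range[1L] < 2L || length_range[2L] > 10000L ||
      length_range[1L] > length_range[2L]) {
    abort("`length_range` must lie within [2, 10000]", class = "acr_input_error")
  }
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  lens <- local_seed(seed, sample(seq(length_range[1L], length_range[2L]),
                                  n, replace = TRUE))
  ids <- sprintf("%s_%s%03d", id_prefix,
                 ifelse(labels == 1L, "pos", "neg"),
                 c(seq_len(n_pos), seq_len(n_neg)))
  proteins <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
    sim_protein(lens[i], seed = (seed %% 1000000L) * 1000L + i, id = ids[i])
  }))
  proteins$description <- ifelse(labels == 1L, "synthetic positive",
                                 "synthetic negative")
  pssms <- setNames(purrr::map(seq_len(n), function(i) {
    sim_pssm(proteins[i, ], seed = (seed %% 1000000L) * 1000L + 500000000L + i,
             score_range = score_range,
             shift = if (labels[i] == 1L) class_shift else 0,
             shift_columns = shift_columns)
  }), ids)
  feats <- encode_features(proteins, pssms, encoders = encoders, lag = lag)
  fmats <- setNames(lapply(encoders, function(e) feature_matrix(feats, e)),
                    encoders)
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteins, file.path(write_dir, "proteins.fasta"))
    for (id in ids) write_pssm(pssms[[id]], file.path(write_dir, paste0(id, ".pssm")))
  }
  list(proteins = proteins, pssms = pssms,
       dataset = acr_dataset(ids, labels, fmats))
}
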