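# Evaluation protocols.
#
# Two repeated, balanced protocols mirror how small-positive-class protein
# predictors are benchmarked:
#  * repeated balanced cross-validation: N times, draw all positives plus an
#    equal-size random negative draw, run stratified k-fold CV in which the
#    *entire* ensemble (undersampling subsets + grid search) is retrained on
#    the training folds, score the held-out folds, and average the N reports;
#  * repeated balanced independent test: a fixed trained model is scored N
#    times against all independent positives plus equal-size random negative
#    draws.
# Nothing is ever tuned on a held-out fold; subset construction and grid
# search only see training-fold ids.

eval_config <- function(n_repeats, k_folds, seed, threshold, n_subsets,
                        exponents, folds) {
  list(n_repeats = as.integer(n_repeats), k_folds = as.integer(k_folds),
       seed = as.integer(seed), threshold = threshold,
       n_subsets = as.integer(n_subsets), exponents = exponents,
       folds = as.integer(folds))
}

metrics_row <- function(truth, estimate, scores) {
  m <- classification_metrics(confusion_counts(truth, estimate))
  m$auc <- roc_auc(scores, truth)
  m
}

average_row <- function(per_repeat) {
  avg <- dplyr::summarise(per_repeat,
                          dplyr::across(dplyr::where(is.numeric), mean))
  avg$repeat_id <- "average"
  avg
}

#' Repeated balanced cross-validation
#'
#' For each of `n_repeats` repeats, draws a balanced dataset (all positives
#' plus an equal-size seeded random draw of negatives), assigns stratified
#' `k_folds` folds, and for every fold trains a full ensemble (balanced
#' subsets, grid search, Platt calibration) on the training folds and scores
#' the held-out fold. Per-repeat metrics are computed on the pooled held-out
#' scores at `threshold`; the averaged report is their arithmetic mean.
#'
#' @param dataset An `acr_dataset` with the four evolutionary encoders (an
#'   imbalanced pool: at least as many negatives as positives).
#' @param n_repeats Number of balanced repeats N (default 10).
#' @param k_folds CV folds (default 5).
#' @param seed Master seed; repeat r derives its own seed `seed + 1000 * r`.
#' @param threshold Decision threshold (default 0.5).
#' @param n_subsets,exponents,folds Passed to [train_acr_ensemble()].
#' @return An object of class `acr_eval`: list with `per_repeat` (tibble, one
#'   row per repeat), `average` (one-row tibble), `config`, and `scores`
#'   (held-out scores per repeat, for ROC plotting).
#' @export
cv_balanced_repeats <- function(dataset, n_repeats = 10L, k_folds = 5L,
                                seed = 1L, threshold = 0.5, n_subsets = 10L,
                                exponents = -10:10, folds = 5L) {
  stopifnot(inherits(dataset, "acr_dataset"))
  if (n_repeats < 1L) abort("`n_repeats` must be >= 1", class = "acr_input_error")
  if (k_folds < 2L) abort("`k_folds` must be >= 2", class = "acr_input_error")
  pos_ids <- dataset$ids[dataset$labels == 1L]
  neg_ids <- dataset$ids[dataset$labels == 0L]
  if (length(neg_ids) < length(pos_ids)) {
    abort("fewer negatives than positives in the pool", class = "acr_input_error")
  }
  reports <- list()
  all_scores <- list()
  for (r in seq_len(n_repeats)) {
    seed_r <- seed + 1000L * r
    bal_neg <- local_seed(seed_r, sample(neg_ids, length(pos_ids)))
    bal <- dataset_slice(dataset, c(pos_ids, bal_neg))
    fold_id <- make_folds(bal$labels, k_folds, seed_r + 1L)
    truth <- integer(0); est <- integer(0); sc <- numeric(0)
    for (f in seq_len(k_folds)) {
      tr_idx <- which(fold_id != f)
      te_idx <- which(fold_id == f)
      if (length(unique(bal$labels[tr_idx])) < 2L) {
        abort("a training fold lost one class; use more samples or fewer folds",
              class = "acr_input_error")
      }
      train_ds <- dataset_slice(bal, tr_idx)
      test_ds <- dataset_slice(bal, te_idx)
      fit <- train_acr_ensemble(train_ds, n_subsets = n_subsets,
                                seed = seed_r + 10L * f,
                                exponents = exponents, folds = folds,
                                threshold = threshold)
      pr <- predict_dataset(fit, test_ds)
      truth <- c(truth, test_ds$labels)
      est <- c(est, pr$label)
      sc <- c(sc, pr$final_score)
    }
    rep_row <- metrics_row(truth, est, sc)
    rep_row$repeat_id <- as.character(r)
    reports[[r]] <- rep_row
    all_scores[[r]] <- tibble(repeat_id = as.character(r), truth = truth,
                              score = sc)
  }
  per_repeat <- dplyr::bind_rows(reports)
  per_repeat <- dplyr::relocate(per_repeat, "repeat_id")
  structure(
    list(per_repeat = per_repeat,
         average = dplyr::relocate(average_row(per_repeat), "repeat_id"),
         config = eval_config(n_repeats, k_folds, seed, threshold, n_subsets,
                              exponents, folds),
         scores = dplyr::bind_rows(all_scores),
         protocol = "repeated_balanced_cv"),
    class = "acr_eval"
  )
}

#' Repeated balanced independent test
#'
#' Scores a fixed trained model `n_repeats` times, each time on all
#' independent positives plus an equal-size seeded random draw from the
#' negative pool, and averages the per-repeat metric reports.
#'
#' @param model A trained `acr_ensemble`.
#' @param positives An `acr_dataset` of independent positive samples (labels
#'   all 1).
#' @param negative_pool An `acr_dataset` negative pool (labels all 0), at
#'   least as large as `positives`.
#' @param n_repeats Number of repeats (default 10).
#' @param seed Master seed.
#' @param threshold Decision threshold (default 0.5).
#' @return An `acr_eval` object (see [cv_balanced_repeats()]).
#' @export
independent_test_repeats <- function(model, positives, negative_pool,
                                     n_repeats = 10L, seed = 1L,
                                     threshold = 0.5) {
  stopifnot(inherits(model, "acr_ensemble"),
            inherits(positives, "acr_dataset"),
            inherits(negative_pool, "acr_dataset"))
  np <- length(positives$ids)
  if (np == 0L) abort("no positive samples", class = "acr_input_error")
  if (length(negative_pool$ids) < np) {
    abort("negative pool smaller than the positive set", class = "acr_input_error")
  }
  # score everything once; repeats only re-select negatives
  pos_scores <- predict_dataset(model, positives)$final_score
  neg_scores <- predict_dataset(model, negative_pool)$final_score
  names(neg_scores) <- negative_pool$ids
  reports <- list()
  all_scores <- list()
  for (r in seq_len(n_repeats)) {
    seed_r <- seed + 1000L * r
    drawn <- local_seed(seed_r, sample(negative_pool$ids, np))
    sc <- c(pos_scores, neg_scores[drawn])
    truth <- c(rep(1L, np), rep(0L, np))
    est <- label_from_score(sc, threshold)
    rep_row <- metrics_row(truth, est, sc)
    rep_row$repeat_id <- as.character(r)
    reports[[r]] <- rep_row
    all_scores[[r]] <- tibble(repeat_id = as.character(r), truth = truth,
                              score = unname(sc))
  }
  per_repeat <- dplyr::relocate(dplyr::bind_rows(reports), "repeat_id")
  structure(
    list(per_repeat = per_repeat,
         average = dplyr::relocate(average_row(per_repeat), "repeat_id"),
         config = list(n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                       threshold = threshold, n_positives = np),
         scores = dplyr::bind_rows(all_scores),
         protocol = "repeated_independent_test"),
    class = "acr_eval"
  )
}

#' @export
print.acr_eval <- function(x, ...) {
  cat("<acr_eval> ", x$protocol, ", ", nrow(x$per_repeat), " repeats\n", sep = "")
  print(x$average)
  invisible(x)
}

#' Tidy / glance methods for evaluation reports
#'
#' `tidy()` returns the per-repeat rows plus the AVERAGE row; `glance()`
#' returns the averaged metrics with the protocol configuration.
#'
#' @param x An `acr_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy acr_eval
#' @export
tidy.acr_eval <- function(x, ...) {
  dplyr::bind_rows(x$per_repeat, x$average)
}

#' @rdname tidy.acr_eval
#' @method glance acr_eval
#' @export
glance.acr_eval <- function(x, ...) {
  out <- x$average
  out$repeat_id <- NULL
  out$protocol <- x$protocol
  out$n_repeats <- x$config$n_repeats
  out$seed <- x$config$seed
  out
}

#' Write an evaluation report as TSV
#'
#' Writes the per-repeat rows plus an `average` row, preceded by `#` header
#' lines echoing the tool version and full protocol configuration (so two
#' runs with identical configs produce identical files).
#'
#' @param x An `acr_eval` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "acr_eval"))
  cfg <- vapply(names(x$config), function(k) {
    paste0(k, "=", paste(x$config[[k]], collapse = ","))
  }, "")
  header <- c(
    paste0("# acrscreen ", packageVersion("acrscreen"), " ", x$protocol),
    paste0("# ", paste(cfg, collapse = "; "))
  )
  tab <- tidy(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROC points as a two-column TSV
#'
#' @param scores,labels Vectors as in [roc_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(scores, labels, path) {
  rc <- roc_curve(scores, labels)
  write.table(rc[, c("fpr", "tpr")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Rank predictions and report marker retrieval
#'
#' Sorts scored proteins by final score (descending; ties broken by protein
#' id so ranking is reproducible) and reports, for each ranking cutoff, how
#' many marker proteins (known anti-CRISPRs) fall within the top ranks —
#' the screening view used when scanning a genome or contig for candidates.
#'
#' @param predictions A tibble with `protein_id` and `final_score` (e.g. from
#'   [predict.acr_ensemble()]); unscored known-list rows are dropped.
#' @param markers Character vector of marker protein ids.
#' @param cutoff_step Ranking-range step (default 10).
#' @return A list of class `acr_ranking`: `ranked` (tibble with `rank`,
#'   `protein_id`, `final_score`, `is_marker`), `retrieval` (tibble of class
#'   `acr_retrieval` with `cutoff`, `retrieved`) and `lowest_marker_rank`.
#' @export
rank_predictions <- function(predictions, markers, cutoff_step = 10L) {
  if (!all(c("protein_id", "final_score") %in% names(predictions))) {
    abort("`predictions` needs columns `protein_id` and `final_score`",
          class = "acr_input_error")
  }
  scored <- predictions[!is.na(predictions$final_score), , drop = FALSE]
  unknown <- setdiff(markers, scored$protein_id)
  if (length(unknown) > 0L) {
    abort(paste0("marker id(s) not among scored predictions: ",
                 paste(unknown, collapse = ", ")),
          class = "acr_input_error")
  }
  o <- order(-scored$final_score, scored$protein_id)
  ranked <- tibble(
    rank = seq_len(nrow(scored)),
    protein_id = scored$protein_id[o],
    final_score = scored$final_score[o],
    is_marker = scored$protein_id[o] %in% markers
  )
  n <- nrow(ranked)
  cutoffs <- unique(c(seq(cutoff_step, n, by = cutoff_step), n))
  retrieval <- tibble(
    cutoff = cutoffs,
    retrieved = vapply(cutoffs, function(ct) sum(ranked$is_marker[seq_len(ct)]),
                       integer(1))
  )
  class(retrieval) <- c("acr_retrieval", class(retrieval))
  structure(
    list(ranked = ranked, retrieval = retrieval,
         lowest_marker_rank = if (any(ranked$is_marker)) {
           max(ranked$rank[ranked$is_marker])
         } else NA_integer_),
    class = "acr_ranking"
  )
}

#' @export
print.acr_ranking <- function(x, ...) {
  cat("<acr_ranking> ", nrow(x$ranked), " proteins, ",
      sum(x$ranked$is_marker), " markers; lowest marker rank ",
      x$lowest_marker_rank, "\n", sep = "")
  invisible(x)
}

#' Plot a marker retrieval curve
#'
#' Number of marker anti-CRISPRs retrieved within each ranking range.
#'
#' @param object An `acr_retrieval` tibble from [rank_predictions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acr_retrieval
#' @export
autoplot.acr_retrieval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff, y = .data$retrieved)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Ranking range (top N)", y = "Anti-CRISPRs retrieved") +
    ggplot2::theme_minimal()
}

#' Plot per-repeat evaluation metrics
#'
#' Dot plot of SN, SP, ACC, F-value, MCC and AUC across repeats, with the
#' averaged value marked.
#'
#' @param object An `acr_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acr_eval
#' @export
autoplot.acr_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_repeat,
    cols = c("sn", "sp", "acc", "f_value", "mcc", "auc"),
    names_to = "metric", values_to = "value"
  )
  avg <- tidyr::pivot_longer(
    object$average,
    cols = c("sn", "sp", "acc", "f_value", "mcc", "auc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.5) +
    ggplot2::geom_point(data = avg, colour = "red", size = 3, shape = 18) +
    ggplot2::labs(x = NULL, y = "Value",
                  title = paste0(object$protocol, " (red = average)")) +
    ggplot2::theme_minimal()
}
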