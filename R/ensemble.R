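# Multiple-undersampling SVM ensemble.
#
# Training data for anti-CRISPR prediction are heavily imbalanced (about one
# known Acr per ten negatives). For each feature type, the minority class is
# kept whole and paired with an equal-size random draw of negatives,
# `n_subsets` times; one RBF-kernel SVM is grid-searched and fitted per
# balanced subset and their positive-class probabilities are averaged into a
# single-feature score. The final ensemble score is the unweighted mean of
# the four single-feature scores, thresholded at 0.5 (score >= threshold is
# called anti-CRISPR).
#
# Implementation notes:
#  * SVMs are fitted with kernlab::ksvm on precomputed kernel matrices: one
#    squared-distance matrix per subset serves the whole Cost x Gamma grid.
#  * Probabilities come from Platt sigmoid calibration (smoothed targets)
#    fitted on the training decision values — fully deterministic, unlike
#    libsvm's internal cross-validated calibration.

sqdist <- function(A, B) {
  D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

# Stratified fold assignment, seeded; guarantees both classes in every fold
# whenever each class has >= k members.
make_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Balanced undersampling subsets
#'
#' Builds `n_subsets` class-balanced subsets, each containing every positive
#' sample plus an equal-size draw (without replacement) from the negative
#' pool. Draws are independent across subsets and fully reproducible: subset
#' k uses derived seed `seed + k`. Positives are never resampled, so changing
#' the seed only changes negative memberships.
#'
#' @param dataset An `acr_dataset`.
#' @param n_subsets Number of subsets (default 10).
#' @param seed Integer master seed.
#' @return A tibble with columns `subset`, `seed`, and list-columns
#'   `positive_ids`, `negative_ids`.
#' @export
balanced_subsets <- function(dataset, n_subsets = 10L, seed = 1L) {
  stopifnot(inherits(dataset, "acr_dataset"))
  if (n_subsets < 1L) abort("`n_subsets` must be >= 1", class = "acr_input_error")
  pos <- dataset$ids[dataset$labels == 1L]
  neg <- dataset$ids[dataset$labels == 0L]
  if (length(pos) == 0L) abort("no positive samples", class = "acr_input_error")
  if (length(neg) < length(pos)) {
    abort("fewer negatives than positives: cannot balance by undersampling",
          class = "acr_input_error")
  }
  rows <- purrr::map(seq_len(n_subsets), function(k) {
    sk <- seed + k
    drawn <- local_seed(sk, sample(neg, length(pos)))
    tibble(subset = k, seed = sk,
           positive_ids = list(pos), negative_ids = list(drawn))
  })
  dplyr::bind_rows(rows)
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Evaluates every (Cost, Gamma) pair on the power-of-two grid
#' `2^exponents x 2^exponents` by seeded stratified k-fold cross-validated
#' accuracy and returns the best cell. Ties are broken toward the smallest
#' cost, then the smallest gamma (the smoother model).
#'
#' @param x Numeric feature matrix.
#' @param y 0/1 labels (both classes required).
#' @param exponents Integer exponents of the grid (default `-10:10`).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A one-row tibble: `cost`, `gamma`, `cost_exp`, `gamma_exp`,
#'   `cv_accuracy`.
#' @export
svm_grid_search <- function(x, y, exponents = -10:10, folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    abort("grid search needs both classes present", class = "acr_input_error")
  }
  n <- nrow(x)
  fold_id <- make_folds(y, folds, seed)
  yf <- factor(y, levels = c(0L, 1L))
  D <- sqdist(x, x)
  acc <- matrix(0, length(exponents), length(exponents),
                dimnames = list(gamma = exponents, cost = exponents))
  for (gi in seq_along(exponents)) {
    K <- exp(-(2^exponents[gi]) * D)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      if (length(te) == 0L) next
      Ktr <- kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE])
      for (ci in seq_along(exponents)) {
        m <- kernlab::ksvm(Ktr, yf[tr], type = "C-svc", C = 2^exponents[ci],
                           shrinking = FALSE)
        Kte <- kernlab::as.kernelMatrix(
          K[te, tr, drop = FALSE][, kernlab::SVindex(m), drop = FALSE]
        )
        pr <- kernlab::predict(m, Kte)
        acc[gi, ci] <- acc[gi, ci] + sum(pr == yf[te])
      }
    }
  }
  acc <- acc / n
  # best accuracy; ties -> smallest cost, then smallest gamma
  cand <- which(acc == max(acc), arr.ind = TRUE)
  cand <- cand[order(cand[, 2L], cand[, 1L]), , drop = FALSE]
  gi <- cand[1L, 1L]; ci <- cand[1L, 2L]
  tibble(
    cost = 2^exponents[ci], gamma = 2^exponents[gi],
    cost_exp = exponents[ci], gamma_exp = exponents[gi],
    cv_accuracy = acc[gi, ci]
  )
}

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

# Platt sigmoid calibration with smoothed targets: P(y=1 | f) =
# 1 / (1 + exp(A*f + B)), (A, B) by penalised MLE on the training decision
# values. Deterministic; absorbs the sign convention of the decision values.
fit_platt <- function(f, y) {
  np <- sum(y == 1L); nn <- sum(y == 0L)
  t <- ifelse(y == 1L, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(ab) {
    z <- ab[1L] * f + ab[2L]
    sum(t * log1pexp(z) + (1 - t) * log1pexp(-z))
  }
  init <- c(A = 0, B = log((nn + 1) / (np + 1)))
  fit <- optim(init, nll, method = "BFGS", control = list(maxit = 200L))
  c(A = unname(fit$par[1L]), B = unname(fit$par[2L]))
}

platt_prob <- function(f, platt) {
  1 / (1 + exp(pmin(pmax(platt["A"] * f + platt["B"], -700), 700)))
}

# Fit one RBF-SVM classifier with fixed (cost, gamma) and attach Platt
# calibration fitted on the training decision values.
fit_rbf_classifier <- function(x, y, cost, gamma) {
  yf <- factor(as.integer(y), levels = c(0L, 1L))
  K <- exp(-gamma * sqdist(x, x))
  # shrinking is disabled: kernlab's shrinking heuristic returns a
  # non-optimal solution on the precomputed-kernel code path (verified
  # against the vector interface and e1071 on identical problems)
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc", C = cost,
                     shrinking = FALSE)
  svi <- kernlab::SVindex(m)
  co <- unlist(kernlab::coef(m))
  b <- kernlab::b(m)
  f_train <- as.numeric(K[, svi, drop = FALSE] %*% co - b)
  list(
    sv = x[svi, , drop = FALSE],
    coef = co,
    b = b,
    cost = cost,
    gamma = gamma,
    platt = fit_platt(f_train, as.integer(y))
  )
}

decision_values <- function(clf, x) {
  if (!is.null(clf$center)) {
    x <- sweep(sweep(x, 2L, clf$center), 2L, clf$scale, "/")
  }
  Kn <- exp(-clf$gamma * sqdist(x, clf$sv))
  as.numeric(Kn %*% clf$coef - clf$b)
}

classifier_prob <- function(clf, x) {
  platt_prob(decision_values(clf, x), clf$platt)
}

#' Train a single-feature undersampling ensemble
#'
#' Draws balanced subsets, grid-searches (Cost, Gamma) within each subset by
#' stratified CV, fits one RBF-SVM per subset and calibrates its score to a
#' positive-class probability. Fully reproducible from `seed`.
#'
#' @param dataset An `acr_dataset` carrying features for `encoder`.
#' @param encoder One encoder tag.
#' @param n_subsets Number of undersampling subsets (default 10).
#' @param seed Integer seed.
#' @param exponents Grid-search exponent range (default `-10:10`).
#' @param folds Inner CV folds for the grid search (default 5).
#' @return An object of class `acr_feature_model`.
#' @export
train_feature_model <- function(dataset, encoder, n_subsets = 10L, seed = 1L,
                                exponents = -10:10, folds = 5L) {
  stopifnot(inherits(dataset, "acr_dataset"))
  if (!encoder %in% names(dataset$features)) {
    abort(paste0("dataset has no features for encoder '", encoder, "'"),
          class = "acr_input_error")
  }
  subsets <- balanced_subsets(dataset, n_subsets, seed)
  X <- dataset$features[[encoder]]
  classifiers <- purrr::map(seq_len(n_subsets), function(k) {
    ids <- c(subsets$positive_ids[[k]], subsets$negative_ids[[k]])
    idx <- match(ids, dataset$ids)
    Xk <- X[idx, , drop = FALSE]
    yk <- dataset$labels[idx]
    # per-subset feature standardization (the e1071 default SVM convention):
    # puts all descriptors on comparable scales so the power-of-two gamma
    # grid spans meaningful kernel widths; constant columns stay at zero
    ctr <- colMeans(Xk)
    scl <- apply(Xk, 2L, stats::sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(Xk, 2L, ctr), 2L, scl, "/")
    spec <- svm_grid_search(Xs, yk, exponents = exponents, folds = folds,
                            seed = subsets$seed[k] + 1L)
    clf <- fit_rbf_classifier(Xs, yk, spec$cost, spec$gamma)
    clf$center <- ctr
    clf$scale <- scl
    clf$subset <- k
    clf$subset_seed <- subsets$seed[k]
    clf$cv_accuracy <- spec$cv_accuracy
    clf$subset_ids <- ids
    clf
  })
  structure(
    list(encoder = encoder, classifiers = classifiers,
         n_subsets = as.integer(n_subsets), seed = seed,
         dimension = ncol(X)),
    class = "acr_feature_model"
  )
}

#' Score proteins with a single-feature model
#'
#' Arithmetic mean of the member classifiers' calibrated positive-class
#' probabilities; always in `[0, 1]`.
#'
#' @param model An `acr_feature_model`.
#' @param x Feature matrix (columns matching the model's encoder dimension).
#' @return Numeric vector of scores, one per row of `x`.
#' @export
predict_feature_model <- function(model, x) {
  stopifnot(inherits(model, "acr_feature_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$dimension) {
    abort(paste0("feature dimension mismatch: model expects ", model$dimension,
                 ", got ", ncol(x)),
          class = "acr_input_error")
  }
  probs <- vapply(model$classifiers, classifier_prob, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1L)
  rowMeans(probs)
}

#' Train the four-feature anti-CRISPR ensemble
#'
#' Trains one single-feature undersampling ensemble per evolutionary
#' descriptor (PSSM_COMP, DPC_PSSM, PSSM_AC, RPSSM) with per-feature seeds
#' derived from the master seed by fixed offsets, and combines them by score
#' averaging at a 0.5 decision threshold.
#'
#' @inheritParams train_feature_model
#' @param threshold Decision threshold in (0, 1); a final score `>=`
#'   threshold is called anti-CRISPR.
#' @return An object of class `acr_ensemble`.
#' @export
train_acr_ensemble <- function(dataset, n_subsets = 10L, seed = 1L,
                               exponents = -10:10, folds = 5L,
                               threshold = 0.5) {
  stopifnot(inherits(dataset, "acr_dataset"))
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1", class = "acr_input_error")
  }
  encs <- acr_evolutionary_encoders()
  missing <- setdiff(encs, names(dataset$features))
  if (length(missing) > 0L) {
    abort(paste0("dataset is missing features for encoder(s): ",
                 paste(missing, collapse = ", ")),
          class = "acr_input_error")
  }
  feature_seeds <- setNames(seed + 100000L * seq_along(encs), encs)
  models <- purrr::map(encs, function(enc) {
    train_feature_model(dataset, enc, n_subsets = n_subsets,
                        seed = feature_seeds[[enc]],
                        exponents = exponents, folds = folds)
  })
  names(models) <- encs
  lag <- ncol(dataset$features[["PSSM_AC"]]) %/% 20L
  structure(
    list(
      feature_models = models,
      threshold = threshold,
      metadata = list(
        seed = seed, feature_seeds = feature_seeds,
        n_subsets = as.integer(n_subsets), exponents = exponents,
        folds = as.integer(folds), lag = lag,
        n_train = length(dataset$ids),
        n_positive = sum(dataset$labels == 1L),
        package_version = as.character(packageVersion("acrscreen"))
      )
    ),
    class = "acr_ensemble"
  )
}

#' @export
print.acr_ensemble <- function(x, ...) {
  cat("<acr_ensemble> ", length(x$feature_models), " feature models x ",
      x$metadata$n_subsets, " classifiers; threshold ", x$threshold,
      "; trained on ", x$metadata$n_positive, "+/",
      x$metadata$n_train - x$metadata$n_positive, "- samples\n", sep = "")
  invisible(x)
}

#' Decision rule of the ensemble
#'
#' A final score greater than or equal to the threshold is labelled
#' anti-CRISPR (so a score of exactly 0.5 is positive at the default
#' threshold).
#'
#' @param score Numeric final score(s) in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 labels.
#' @export
label_from_score <- function(score, threshold = 0.5) {
  as.integer(score >= threshold)
}

#' Score an encoded dataset with a trained ensemble
#'
#' Applies the four single-feature models to the dataset's feature matrices
#' and averages their scores. This is the fast path used by the evaluation
#' protocols, where features are already encoded.
#'
#' @param model An `acr_ensemble`.
#' @param dataset An `acr_dataset` with the four evolutionary encoders.
#' @return A tibble: `protein_id`, one score column per encoder
#'   (`score_<ENCODER>`), `final_score`, `label`.
#' @export
predict_dataset <- function(model, dataset) {
  stopifnot(inherits(model, "acr_ensemble"), inherits(dataset, "acr_dataset"))
  encs <- names(model$feature_models)
  per <- vapply(encs, function(enc) {
    X <- dataset$features[[enc]]
    if (is.null(X)) {
      abort(paste0("dataset is missing features for encoder '", enc, "'"),
            class = "acr_input_error")
    }
    predict_feature_model(model$feature_models[[enc]], X)
  }, numeric(length(dataset$ids)))
  if (length(dataset$ids) == 1L) per <- matrix(per, nrow = 1L,
                                               dimnames = list(NULL, encs))
  final <- rowMeans(per)
  out <- tibble(protein_id = dataset$ids)
  for (enc in encs) out[[paste0("score_", enc)]] <- per[, enc]
  out$final_score <- final
  out$label <- label_from_score(final, model$threshold)
  out
}

#' Built-in list of experimentally validated anti-CRISPRs
#'
#' Returns the known-anti-CRISPR reference list used by [predict.acr_ensemble()]
#' to flag exact sequence matches instead of scoring them. The copy shipped
#' with the package (`known_acr_synthetic.fasta`) is a clearly-labelled
#' synthetic stand-in so the mechanism is testable offline; point `path` at a
#' FASTA of real validated anti-CRISPRs for production screening.
#'
#' @param path Optional FASTA path overriding the packaged synthetic list.
#' @return A protein tibble.
#' @export
acr_known_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "known_acr_synthetic.fasta",
                        package = "acrscreen")
  }
  read_fasta(path)
}

#' Predict anti-CRISPR activity for proteins
#'
#' Encodes each protein with the four evolutionary descriptors, scores every
#' single-feature model and averages into the final score. In normal mode,
#' proteins whose sequence exactly matches the known-anti-CRISPR list are
#' flagged `known_acr = TRUE` and returned without a score; in benchmarking
#' mode the list is bypassed and every protein is scored.
#'
#' @param object A trained `acr_ensemble`.
#' @param proteins A protein tibble.
#' @param pssms Named list of `acr_pssm` objects paired with `proteins`.
#' @param benchmarking Bypass the known-list filter (default `FALSE`).
#' @param known_acrs Optional protein tibble of validated anti-CRISPRs
#'   (defaults to [acr_known_list()]).
#' @param ... Unused.
#' @return A tibble: `protein_id`, per-feature scores, `final_score`,
#'   `label`, `known_acr`.
#' @export
predict.acr_ensemble <- function(object, proteins, pssms,
                                 benchmarking = FALSE, known_acrs = NULL,
                                 ...) {
  check_protein_tbl(proteins)
  if (nrow(proteins) == 0L) {
    return(tibble(protein_id = character(0), final_score = numeric(0),
                  label = integer(0), known_acr = logical(0)))
  }
  if (is.null(known_acrs)) known_acrs <- acr_known_list()
  known <- rep(FALSE, nrow(proteins))
  if (!benchmarking) {
    known <- proteins$sequence %in% known_acrs$sequence
  }
  to_score <- proteins[!known, , drop = FALSE]
  encs <- names(object$feature_models)
  out <- tibble(protein_id = proteins$id)
  for (enc in encs) out[[paste0("score_", enc)]] <- NA_real_
  out$final_score <- NA_real_
  out$label <- NA_integer_
  out$known_acr <- known
  if (nrow(to_score) > 0L) {
    feats <- encode_features(to_score, pssms, encoders = encs,
                             lag = object$metadata$lag)
    fmats <- setNames(lapply(encs, function(e) feature_matrix(feats, e)), encs)
    ds <- acr_dataset(to_score$id, rep(0L, nrow(to_score)), fmats)
    sc <- predict_dataset(object, ds)
    idx <- match(sc$protein_id, out$protein_id)
    for (enc in encs) out[[paste0("score_", enc)]][idx] <- sc[[paste0("score_", enc)]]
    out$final_score[idx] <- sc$final_score
    out$label[idx] <- sc$label
  }
  out
}

#' Save / load a trained ensemble
#'
#' The model is persisted as a versioned archive (format tag, format version,
#' metadata, serialized classifiers). Loading validates the format and the
#' encoder set, so a truncated or foreign file fails loudly.
#'
#' @param model An `acr_ensemble`.
#' @param path File path (conventionally `.rds`).
#' @return `save_acr_model()`: `path`, invisibly. `load_acr_model()`: the
#'   restored `acr_ensemble`.
#' @export
save_acr_model <- function(model, path) {
  stopifnot(inherits(model, "acr_ensemble"))
  saveRDS(list(format = "acrscreen_model", format_version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_acr_model
#' @export
load_acr_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("model file not found: ", path), class = "acr_input_error")
  }
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("cannot read model file (corrupt?): ", conditionMessage(e)),
          class = "acr_input_error")
  })
  if (!is.list(obj) || !identical(obj$format, "acrscreen_model")) {
    abort("not an acrscreen model file", class = "acr_input_error")
  }
  if (!identical(obj$format_version, 1L)) {
    abort(paste0("unsupported model format version: ", obj$format_version),
          class = "acr_input_error")
  }
  model <- obj$model
  if (!inherits(model, "acr_ensemble") ||
      !setequal(names(model$feature_models), acr_evolutionary_encoders())) {
    abort("model file fails validation: expected four evolutionary feature models",
          class = "acr_input_error")
  }
  model
}

#' Tidy a trained ensemble
#'
#' One row per member classifier with its subset, selected hyperparameters
#' and inner-CV accuracy.
#'
#' @param x An `acr_ensemble`.
#' @param ... Unused.
#' @return A tibble: `encoder`, `subset`, `subset_seed`, `cost`, `gamma`,
#'   `cv_accuracy`, `n_sv`.
#' @method tidy acr_ensemble
#' @export
tidy.acr_ensemble <- function(x, ...) {
  rows <- purrr::map(x$feature_models, function(fm) {
    dplyr::bind_rows(purrr::map(fm$classifiers, function(clf) {
      tibble(encoder = fm$encoder, subset = clf$subset,
             subset_seed = clf$subset_seed, cost = clf$cost,
             gamma = clf$gamma, cv_accuracy = clf$cv_accuracy,
             n_sv = nrow(clf$sv))
    }))
  })
  dplyr::bind_rows(rows)
}

#' Glance at a trained ensemble
#'
#' @param x An `acr_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble of ensemble-level facts.
#' @method glance acr_ensemble
#' @export
glance.acr_ensemble <- function(x, ...) {
  tibble(
    n_feature_models = length(x$feature_models),
    n_subsets = x$metadata$n_subsets,
    n_classifiers = length(x$feature_models) * x$metadata$n_subsets,
    threshold = x$threshold,
    seed = x$metadata$seed,
    grid_min_exp = min(x$metadata$exponents),
    grid_max_exp = max(x$metadata$exponents),
    n_train = x$metadata$n_train,
    n_positive = x$metadata$n_positive
  )
}
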