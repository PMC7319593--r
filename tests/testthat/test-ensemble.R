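make_blobs <- function(n_per_class, p = 5, shift = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per_class * p), ncol = p),
    matrix(rnorm(n_per_class * p, mean = shift), ncol = p)
  )
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

test_that("balanced subsets are 1:1, reproducible, and keep all positives", {
  ds <- golden_pool()$dataset
  subs <- balanced_subsets(ds, n_subsets = 10, seed = 3)
  expect_equal(nrow(subs), 10L)
  pos <- ds$ids[ds$labels == 1L]
  for (k in 1:10) {
    expect_identical(subs$positive_ids[[k]], pos)
    expect_length(subs$negative_ids[[k]], length(pos))
    expect_length(intersect(subs$negative_ids[[k]], pos), 0L)
    expect_false(anyDuplicated(subs$negative_ids[[k]]) > 0)
  }
  again <- balanced_subsets(ds, n_subsets = 10, seed = 3)
  expect_identical(subs, again)
  other <- balanced_subsets(ds, n_subsets = 10, seed = 4)
  expect_identical(other$positive_ids, subs$positive_ids)
  expect_false(identical(other$negative_ids, subs$negative_ids))
})

test_that("balanced subsets reject impossible requests", {
  few_neg <- sim_acr_dataset(n_pos = 5, n_neg = 3, seed = 2,
                             length_range = c(50, 60))$dataset
  expect_error(balanced_subsets(few_neg, 2, seed = 1), class = "acr_input_error")
  ds <- golden_pool()$dataset
  expect_error(balanced_subsets(ds, 0, seed = 1), class = "acr_input_error")
})

test_that("grid search separates Gaussian blobs and respects restrictions", {
  bl <- make_blobs(20, seed = 5)
  spec <- svm_grid_search(bl$X, bl$y, exponents = seq(-10, 10, 5), seed = 1)
  expect_equal(spec$cv_accuracy, 1)
  one <- svm_grid_search(bl$X, bl$y, exponents = 0L, seed = 1)
  expect_equal(one$cost, 1)
  expect_equal(one$gamma, 1)
  expect_error(svm_grid_search(bl$X, rep(1L, nrow(bl$X)), exponents = 0L),
               class = "acr_input_error")
})

test_that("grid search is deterministic and breaks ties toward smaller cost", {
  bl <- make_blobs(15, seed = 6)
  s1 <- svm_grid_search(bl$X, bl$y, exponents = c(-2, 0, 2), seed = 9)
  s2 <- svm_grid_search(bl$X, bl$y, exponents = c(-2, 0, 2), seed = 9)
  expect_identical(s1, s2)
  expect_true(s1$cv_accuracy == 1)
  # constant features make every grid cell equally (un)informative, so the
  # tie-break must surface: smallest cost first, then smallest gamma
  Xc <- matrix(1, 20, 3)
  yc <- rep(c(0L, 1L), 10)
  tie <- svm_grid_search(Xc, yc, exponents = c(-3, 0, 3), seed = 2)
  expect_equal(tie$cost_exp, -3)
  expect_equal(tie$gamma_exp, -3)
})

test_that("single-feature models score separably and average member outputs", {
  ds <- golden_pool()$dataset
  m <- train_feature_model(ds, "PSSM_COMP", n_subsets = 2, seed = 1,
                           exponents = test_grid)
  expect_s3_class(m, "acr_feature_model")
  expect_length(m$classifiers, 2L)
  sc <- predict_feature_model(m, ds$features$PSSM_COMP)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(mean((sc >= 0.5) == (ds$labels == 1L)), 1)
  # the ensemble score is the arithmetic mean of member probabilities
  member <- vapply(m$classifiers, acrscreen:::classifier_prob,
                   numeric(nrow(ds$features$PSSM_COMP)),
                   x = ds$features$PSSM_COMP)
  expect_equal(sc, rowMeans(member), tolerance = 1e-12)
  expect_true(all(sc >= apply(member, 1, min) - 1e-12))
  expect_true(all(sc <= apply(member, 1, max) + 1e-12))
  one <- train_feature_model(ds, "RPSSM", n_subsets = 1, seed = 1,
                             exponents = 0L)
  expect_length(one$classifiers, 1L)
  expect_error(train_feature_model(ds, "AAC", n_subsets = 1, seed = 1),
               class = "acr_input_error")
})

test_that("ensemble training produces 4 x n_subsets classifiers, deterministically", {
  ds <- golden_pool()$dataset
  m1 <- train_acr_ensemble(ds, n_subsets = 2, seed = 11, exponents = test_grid)
  expect_named(m1$feature_models, c("PSSM_COMP", "DPC_PSSM", "PSSM_AC", "RPSSM"))
  td <- tidy(m1)
  expect_equal(nrow(td), 8L)
  expect_true(all(td$cost %in% 2^test_grid))
  expect_true(all(td$gamma %in% 2^test_grid))
  g <- glance(m1)
  expect_equal(g$n_feature_models, 4L)
  expect_equal(g$n_classifiers, 8L)
  expect_equal(g$threshold, 0.5)

  m2 <- train_acr_ensemble(ds, n_subsets = 2, seed = 11, exponents = test_grid)
  f1 <- withr::local_tempfile(fileext = ".rds")
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_acr_model(m1, f1)
  save_acr_model(m2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  dropped <- ds
  dropped$features$RPSSM <- NULL
  err <- expect_error(train_acr_ensemble(dropped, n_subsets = 1, seed = 1,
                                         exponents = 0L),
                      class = "acr_input_error")
  expect_match(conditionMessage(err), "RPSSM")
})

test_that("final score is the unweighted mean of the four feature scores", {
  sim <- golden_pool()
  m <- train_acr_ensemble(sim$dataset, n_subsets = 1, seed = 3,
                          exponents = c(-4L, 0L))
  pr <- predict_dataset(m, sim$dataset)
  per <- as.matrix(pr[, paste0("score_", names(m$feature_models))])
  expect_equal(pr$final_score, unname(rowMeans(per)), tolerance = 1e-12)
  expect_true(all(per >= 0 & per <= 1))
  expect_equal(pr$label, label_from_score(pr$final_score, 0.5))
})

test_that("threshold rule is >=: a 0.503 score and an exact 0.5 are positive", {
  expect_equal(label_from_score(0.503), 1L)
  expect_equal(label_from_score(0.5), 1L)
  expect_equal(label_from_score(0.4999999), 0L)
  expect_equal(label_from_score(c(0.2, 0.4, 0.6, 0.8)), c(0L, 0L, 1L, 1L))
  expect_equal(label_from_score(mean(c(0.2, 0.4, 0.6, 0.8))), 1L)
})

test_that("model persistence round-trips predictions exactly", {
  sim <- golden_pool()
  m <- train_acr_ensemble(sim$dataset, n_subsets = 1, seed = 5,
                          exponents = c(-4L, 0L))
  f <- withr::local_tempfile(fileext = ".rds")
  save_acr_model(m, f)
  back <- load_acr_model(f)
  p1 <- predict_dataset(m, sim$dataset)
  p2 <- predict_dataset(back, sim$dataset)
  expect_equal(p1$final_score, p2$final_score, tolerance = 1e-12)

  raw <- readBin(f, "raw", n = 50)
  writeBin(raw, f)
  expect_error(load_acr_model(f), class = "acr_input_error")
  saveRDS(list(format = "something_else"), f)
  expect_error(load_acr_model(f), class = "acr_input_error")
  bad <- m
  bad$feature_models <- bad$feature_models[1:2]
  saveRDS(list(format = "acrscreen_model", format_version = 1L, model = bad), f)
  expect_error(load_acr_model(f), "four evolutionary", class = "acr_input_error")
})

test_that("the known-list filter skips scoring unless benchmarking", {
  sim <- golden_pool()
  m <- train_acr_ensemble(sim$dataset, n_subsets = 1, seed = 7,
                          exponents = c(-4L, 0L))
  known <- acr_known_list()
  expect_gt(nrow(known), 0L)
  prot <- dplyr::bind_rows(sim$proteins[1, ], known[1, ])
  pssms <- sim$pssms[prot$id[1]]
  pssms[[known$id[1]]] <- sim_pssm(known[1, ], seed = 100)
  normal <- predict(m, prot, pssms)
  expect_false(normal$known_acr[1])
  expect_true(normal$known_acr[2])
  expect_true(is.na(normal$final_score[2]))
  expect_false(is.na(normal$final_score[1]))
  bench <- predict(m, prot, pssms, benchmarking = TRUE)
  expect_false(any(bench$known_acr))
  expect_true(all(!is.na(bench$final_score)))
  # benchmarking scores a superset of the normally scored proteins
  expect_true(all(normal$protein_id[!normal$known_acr] %in%
                  bench$protein_id[!is.na(bench$final_score)]))
  expect_equal(bench$final_score[1], normal$final_score[1], tolerance = 1e-12)
})

test_that("the kernlab-based classifier agrees with an e1071 fit of the same spec", {
  bl <- make_blobs(25, p = 8, shift = 3, seed = 12)
  clf <- acrscreen:::fit_rbf_classifier(bl$X, bl$y, cost = 2, gamma = 2^-3)
  dec <- acrscreen:::decision_values(clf, bl$X)
  ref <- e1071::svm(bl$X, factor(bl$y, levels = c(0L, 1L)), kernel = "radial",
                    cost = 2, gamma = 2^-3, scale = FALSE)
  ref_lab <- as.integer(as.character(predict(ref, bl$X)))
  # two independent SMO implementations of the same model must make the same
  # training-set calls; decision magnitudes may differ slightly
  my_lab <- as.integer(acrscreen:::classifier_prob(clf, bl$X) >= 0.5)
  expect_equal(my_lab, ref_lab)
  ref_dec <- as.numeric(attr(predict(ref, bl$X, decision.values = TRUE),
                             "decision.values"))
  expect_gt(abs(stats::cor(dec, ref_dec)), 0.999)
})
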