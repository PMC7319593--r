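test_that("repeated balanced CV reaches perfect accuracy on separable data", {
  # pool large enough that fold-level Platt calibration resolves the 0.5
  # threshold, not just the ranking
  sim <- sim_acr_dataset(n_pos = 24, n_neg = 120, class_shift = 5, seed = 42,
                         length_range = c(50, 80), id_prefix = "cvp")
  res <- cv_balanced_repeats(sim$dataset, n_repeats = 2, k_folds = 5,
                             seed = 21, n_subsets = 2, exponents = test_grid)
  expect_s3_class(res, "acr_eval")
  expect_equal(nrow(res$per_repeat), 2L)
  expect_equal(res$average$acc, 1)
  expect_equal(res$average$auc, 1)
  # every repeat scores each balanced sample exactly once as held-out
  expect_equal(unname(table(res$scores$repeat_id)), rep(48L, 2),
               ignore_attr = TRUE)
})

test_that("the average row is the component-wise mean of the repeats", {
  ds <- golden_pool()$dataset
  res <- cv_balanced_repeats(ds, n_repeats = 3, k_folds = 3, seed = 4,
                             n_subsets = 1, exponents = c(-4L, 0L))
  for (col in c("sn", "sp", "acc", "f_value", "mcc", "auc")) {
    expect_equal(res$average[[col]], mean(res$per_repeat[[col]]))
  }
  one <- cv_balanced_repeats(ds, n_repeats = 1, k_folds = 3, seed = 4,
                             n_subsets = 1, exponents = c(-4L, 0L))
  expect_equal(one$average[names(one$average) != "repeat_id"],
               one$per_repeat[names(one$per_repeat) != "repeat_id"],
               ignore_attr = TRUE)
})

test_that("repeated balanced CV is deterministic under a fixed seed", {
  ds <- golden_pool()$dataset
  r1 <- cv_balanced_repeats(ds, n_repeats = 2, k_folds = 3, seed = 8,
                            n_subsets = 1, exponents = c(-4L, 0L))
  r2 <- cv_balanced_repeats(ds, n_repeats = 2, k_folds = 3, seed = 8,
                            n_subsets = 1, exponents = c(-4L, 0L))
  expect_identical(r1$per_repeat, r2$per_repeat)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(r1, f1)
  write_eval_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("stratified folds partition samples and keep both classes", {
  y <- rep(c(0L, 1L), c(40, 10))
  folds <- acrscreen:::make_folds(y, 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(folds == f & y == 1L), 2L)
    expect_equal(sum(folds == f & y == 0L), 8L)
  }
})

test_that("independent test repeats draw balanced sets and average metrics", {
  sim <- golden_pool()
  model <- train_acr_ensemble(sim$dataset, n_subsets = 2, seed = 31,
                              exponents = test_grid)
  test_pos <- sim_acr_dataset(n_pos = 8, n_neg = 0, class_shift = 5, seed = 99,
                              length_range = c(50, 80), id_prefix = "ipos")
  test_neg <- sim_acr_dataset(n_pos = 0, n_neg = 40, class_shift = 5, seed = 98,
                              length_range = c(50, 80), id_prefix = "ineg")
  pos_ds <- test_pos$dataset
  neg_ds <- test_neg$dataset
  res <- independent_test_repeats(model, pos_ds, neg_ds, n_repeats = 3,
                                  seed = 17)
  expect_equal(nrow(res$per_repeat), 3L)
  # each repeat evaluates all positives plus an equal negative draw
  expect_true(all(table(res$scores$repeat_id) == 16L))
  expect_equal(res$average$mcc, 1)  # fully separable
  again <- independent_test_repeats(model, pos_ds, neg_ds, n_repeats = 3,
                                    seed = 17)
  expect_identical(res$per_repeat, again$per_repeat)
  small_pool <- dataset_subset_for_tests(neg_ds, 4)
  expect_error(independent_test_repeats(model, pos_ds, small_pool, 2, seed = 1),
               class = "acr_input_error")
})

test_that("ranked screening reports marker retrieval per cutoff", {
  pred <- tibble::tibble(
    protein_id = paste0("p", 1:5),
    final_score = c(0.9, 0.8, 0.6, 0.4, 0.2)
  )
  rk <- rank_predictions(pred, markers = c("p1", "p2"), cutoff_step = 2)
  expect_equal(rk$ranked$protein_id[1:2], c("p1", "p2"))
  expect_equal(rk$retrieval$retrieved[rk$retrieval$cutoff == 2], 2L)
  expect_equal(rk$lowest_marker_rank, 2L)

  tied <- tibble::tibble(protein_id = c("b", "a", "c"),
                         final_score = rep(0.5, 3))
  rk2 <- rank_predictions(tied, markers = "a", cutoff_step = 1)
  expect_equal(rk2$ranked$protein_id, c("a", "b", "c"))  # id tie-break
  expect_equal(rk2$lowest_marker_rank, 1L)

  expect_error(rank_predictions(pred, markers = "ghost"),
               class = "acr_input_error")

  # genome-screening shape: 125 proteins, 33 markers, cutoffs every 10
  set.seed(1)
  big <- tibble::tibble(protein_id = sprintf("g%03d", 1:125),
                        final_score = runif(125))
  marks <- sample(big$protein_id, 33)
  rk3 <- rank_predictions(big, markers = marks, cutoff_step = 10)
  expect_equal(nrow(rk3$retrieval), 13L)
  expect_equal(max(rk3$retrieval$cutoff), 125L)
  expect_equal(rk3$retrieval$retrieved[13], 33L)
  expect_s3_class(autoplot(rk3$retrieval), "ggplot")
})

test_that("evaluation reports serialize with config headers", {
  ds <- golden_pool()$dataset
  res <- cv_balanced_repeats(ds, n_repeats = 1, k_folds = 3, seed = 2,
                             n_subsets = 1, exponents = 0L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(res, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# acrscreen")
  expect_match(lines[2], "seed=2")
  body <- read.delim(f, comment.char = "#")
  expect_equal(nrow(body), 2L)  # one repeat + average
  expect_equal(body$repeat_id, c("1", "average"))
  roc_f <- withr::local_tempfile(fileext = ".tsv")
  write_roc_points(res$scores$score, res$scores$truth, roc_f)
  pts <- read.delim(roc_f)
  expect_named(pts, c("fpr", "tpr"))
  expect_s3_class(autoplot(res), "ggplot")
})
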