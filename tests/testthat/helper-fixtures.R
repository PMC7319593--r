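# Shared fixtures built in code at test time.

# Small separable "golden" pool reused across ensemble/evaluation tests:
# 12 positives vs 60 negatives, strong PSSM column shift, short sequences so
# grid searches stay fast.
golden_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- acrscreen::sim_acr_dataset(
        n_pos = 12, n_neg = 60, class_shift = 5, seed = 42,
        length_range = c(50, 80)
      )
    }
    cache
  }
})

# Coarse grid used wherever a test trains a full ensemble: the separable
# fixture is classified perfectly across wide neighbourhoods of the grid, so
# the fine default grid only adds wall-clock time.
test_grid <- c(-8L, -4L, 0L, 4L, 8L)

# A hand-written three-row ASCII PSSM in the psiblast dialect.
tiny_pssm_text <- function() {
  c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", rep(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V"), 2)), collapse = " ")),
    paste0("    1 M  ", paste(sprintf("%3d", c(-1, -2, -2, -3, -1, 0, -2, -3, -2, 1, 2, -1, 8, 0, -2, -1, -1, -1, -1, 1)), collapse = " "),
           "  ", paste(sprintf("%3d", rep(0, 20)), collapse = " "), "  0.36 0.12"),
    paste0("    2 K  ", paste(sprintf("%3d", c(-1, 2, 0, -1, -3, 1, 1, -2, -1, -3, -2, 5, -1, -3, -1, 0, -1, -3, -2, -2)), collapse = " "),
           "  ", paste(sprintf("%3d", rep(0, 20)), collapse = " "), "  0.41 0.10"),
    paste0("    3 L  ", paste(sprintf("%3d", c(-1, -2, -3, -4, -1, -2, -3, -4, -3, 2, 4, -2, 2, 0, -3, -2, -1, -2, -1, 1)), collapse = " "),
           "  ", paste(sprintf("%3d", rep(0, 20)), collapse = " "), "  0.30 0.15"),
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1347     0.3176"
  )
}

dataset_subset_for_tests <- function(ds, n) {
  acrscreen:::dataset_slice(ds, seq_len(n))
}

expect_exit_status <- function(status, expected) {
  testthat::expect_identical(as.integer(status), as.integer(expected))
}
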