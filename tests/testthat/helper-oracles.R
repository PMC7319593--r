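# Independent brute-force oracles: literal loop transcriptions of the
# descriptor and metric definitions, kept free of the package's vectorized
# code paths so the two routes can disagree.

bf_cols <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
bf_res_alpha <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                       "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))

bf_aac <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  out <- numeric(20)
  for (i in 1:20) {
    n <- 0
    for (k in 1:L) if (ch[k] == bf_res_alpha[i]) n <- n + 1
    out[i] <- n / L
  }
  out
}

bf_dpc <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  out <- numeric(400)
  idx <- 0
  for (i in 1:20) for (j in 1:20) {
    idx <- idx + 1
    n <- 0
    for (k in 1:(L - 1)) {
      if (ch[k] == bf_res_alpha[i] && ch[k + 1] == bf_res_alpha[j]) n <- n + 1
    }
    out[idx] <- n / (L - 1)
  }
  out
}

bf_pssm_comp <- function(P, residues) {
  L <- nrow(P)
  R <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (k in 1:L) {
      delta <- if (residues[k] == bf_cols[i]) 1 else 0
      R[i, ] <- R[i, ] + P[k, ] * delta
    }
    R[i, ] <- R[i, ] / L
  }
  out <- numeric(400)
  idx <- 0
  for (i in 1:20) for (j in 1:20) { idx <- idx + 1; out[idx] <- R[i, j] }
  out
}

bf_dpc_pssm <- function(P) {
  L <- nrow(P)
  out <- numeric(400)
  idx <- 0
  for (i in 1:20) for (j in 1:20) {
    idx <- idx + 1
    s <- 0
    for (k in 1:(L - 1)) s <- s + P[k, i] * P[k + 1, j]
    out[idx] <- s / (L - 1)
  }
  out
}

bf_pssm_ac <- function(P, LG) {
  L <- nrow(P)
  out <- numeric(20 * LG)
  idx <- 0
  for (j in 1:20) {
    pbar <- 0
    for (i in 1:L) pbar <- pbar + P[i, j] / L
    for (lg in 1:LG) {
      idx <- idx + 1
      s <- 0
      for (i in 1:(L - lg)) {
        s <- s + (P[i, j] - pbar) * (P[i + lg, j] - pbar) / (L - lg)
      }
      out[idx] <- s
    }
  }
  out
}

bf_reduce <- function(P) {
  cl <- function(r) P[, which(bf_cols == r), drop = TRUE]
  cbind(
    (cl("F") + cl("Y") + cl("W")) / 3,
    (cl("M") + cl("L")) / 2,
    (cl("I") + cl("V")) / 2,
    (cl("A") + cl("T") + cl("S")) / 3,
    (cl("N") + cl("H")) / 2,
    (cl("Q") + cl("E") + cl("D")) / 3,
    (cl("R") + cl("K")) / 2,
    cl("C"),
    cl("G"),
    cl("P")
  )
}

bf_rpssm <- function(P) {
  R <- bf_reduce(P)
  if (is.null(dim(R))) R <- matrix(R, nrow = 1)
  L <- nrow(R)
  Dst <- numeric(100)
  idx <- 0
  for (s in 1:10) for (t in 1:10) {
    idx <- idx + 1
    acc <- 0
    for (i in 1:(L - 1)) acc <- acc + (R[i, s] - R[i + 1, t])^2 / 2
    Dst[idx] <- acc / (L - 1)
  }
  Ds <- numeric(10)
  for (s in 1:10) {
    pbar <- 0
    for (i in 1:L) pbar <- pbar + R[i, s] / L
    acc <- 0
    for (i in 1:L) acc <- acc + (R[i, s] - pbar)^2
    Ds[s] <- acc / L
  }
  c(Dst, Ds)
}

# Metric formulas re-derived independently: MCC via the Pearson correlation
# of the two binary vectors (an algebraic identity), the others from basic
# arithmetic written separately from the package code.
bf_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  p <- tp + fn
  n <- tn + fp
  sn <- if (p == 0) 0 else tp / p
  sp <- if (n == 0) 0 else tn / n
  acc <- (tp + tn) / total
  f <- if (2 * tp + fp + fn == 0) 0 else (2 * tp) / (2 * tp + fp + fn)
  truth <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  mcc <- suppressWarnings(stats::cor(truth, pred))
  if (!is.finite(mcc)) mcc <- 0
  list(sn = sn, sp = sp, acc = acc, f_value = f, mcc = mcc)
}

# AUC as the probability a random positive outscores a random negative,
# ties counted one half.
bf_auc_pairwise <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# A random PSSM for oracle sweeps, built without package generators.
bf_random_pssm <- function(L, seed, lo = -10, hi = 10) {
  set.seed(seed)
  residues <- sample(bf_cols, L, replace = TRUE)
  P <- matrix(sample(lo:hi, L * 20, replace = TRUE), nrow = L)
  list(P = P, residues = residues,
       pssm = acrscreen::new_pssm(paste0("bf", seed), P, residues))
}
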