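# Independent oracles used across test files. All are deliberately naive
# (double loops, exhaustive enumeration) so they stay independent of the
# package's vectorized / compiled implementations.

# Naive O(N^2) template-counting sample entropy, self-matches excluded,
# templates restricted to the first N - m positions at both lengths.
naive_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  count_pairs <- function(mm) {
    nt <- n - m
    cnt <- 0L
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1L
      }
    }
    cnt
  }
  b <- count_pairs(m)
  a <- count_pairs(m + 1)
  if (a == 0 || b == 0) return(Inf)
  -log(a / b)
}

# Naive approximate entropy, self-matches included.
naive_apen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in 1:nt) {
      cnt <- 0L
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1L
      }
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Brute-force LOOCV 1-NN predictions with per-fold standardization and
# lowest-index tie-breaking, written as plain loops.
brute_knn1_loocv <- function(x, y) {
  n <- nrow(x)
  pred <- character(n)
  for (i in 1:n) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0] <- 1
    best_d <- Inf; best_j <- NA
    xi <- (x[i, ] - mu) / sdv
    for (j in 1:(n - 1)) {
      xj <- (xtr[j, ] - mu) / sdv
      d <- sum((xi - xj)^2)
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    pred[i] <- as.character(ytr[best_j])
  }
  factor(pred, levels = levels(y))
}

# Exhaustive best subset of size <= k by a given evaluator (maximize).
exhaustive_best_subset <- function(evaluator, candidates, k) {
  best_m <- -Inf; best_s <- NULL
  for (size in 1:k) {
    combs <- combn(candidates, size, simplify = FALSE)
    for (s in combs) {
      m <- evaluator(s)$metric
      if (m > best_m) { best_m <- m; best_s <- s }
    }
  }
  list(subset = best_s, metric = best_m)
}

# Small cohort (few subjects) with features extracted, cached per session to
# keep the suite fast; seed fixed so every test sees the same cohort.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(synth_config(), 3, seed = 20260923)
      fm <- suppressMessages(extract_cohort_features(co))
      cache <<- list(cohort = co, features = fm)
    }
    cache
  }
})
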