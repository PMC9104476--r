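test_that("confusion metrics reproduce hand-computed values", {
  perfect <- confusion_metrics(16, 0, 16, 0)
  expect_equal(unname(perfect), rep(100, 5))
  m <- confusion_metrics(14, 2, 15, 1)
  expect_equal(m[["accuracy"]], 90.625, tolerance = 1e-9)
  expect_equal(m[["sensitivity"]], 87.5, tolerance = 1e-9)
  expect_equal(m[["specificity"]], 93.75, tolerance = 1e-9)
  expect_equal(m[["precision"]], 100 * 14 / 15, tolerance = 1e-9)
  expect_equal(m[["f_score"]], 100 * 2 * (14 / 15) * 0.875 / (14 / 15 + 0.875),
               tolerance = 1e-9)
  degen <- confusion_metrics(0, 16, 16, 0)
  expect_equal(degen[["accuracy"]], 50)
  expect_true(is.na(degen[["precision"]]))
  expect_true(is.na(degen[["f_score"]]))
  expect_error(confusion_metrics(0, 0, 0, 0), "not all zero")
})

test_that("reported F-score is consistent with precision and sensitivity", {
  set.seed(20)
  for (i in 1:20) {
    cm <- as.list(sample(0:16, 4, replace = TRUE))
    if (sum(unlist(cm)) == 0 || (cm[[1]] + cm[[4]]) == 0) next
    m <- confusion_metrics(cm[[1]], cm[[2]], cm[[3]], cm[[4]])
    if (is.na(m[["f_score"]])) next
    expect_equal(m[["f_score"]],
                 2 * m[["precision"]] * m[["sensitivity"]] /
                   (m[["precision"]] + m[["sensitivity"]]),
                 tolerance = 1e-9)
  }
})

test_that("subject datasets have the 16/16 class composition", {
  fm <- shared_cohort()$features
  ds <- assemble_subject_dataset(fm, "S01")
  expect_length(ds$label, 32)
  expect_identical(as.integer(table(ds$label)), c(16L, 16L))
  # non-liquid class: 5 saliva bursts + 11 baseline windows
  expect_identical(sum(ds$volume_mL > 0), 16L)
  ds2 <- assemble_subject_dataset(fm, "S01")
  expect_identical(ds$x, ds2$x)            # deterministic assembly
  expect_error(assemble_subject_dataset(fm[fm$task != "straw", ], "S01"),
               "straw")
})

test_that("LOOCV 1-NN matches the XOR construction and the brute-force oracle", {
  xor_x <- matrix(c(0, 1, 0, 1, 0, 1, 1, 0), ncol = 2)  # (0,0)A (1,1)A (0,1)B (1,0)B
  xor_y <- factor(c("A", "A", "B", "B"))
  ds <- list(x = xor_x, label = xor_y)
  colnames(ds$x) <- c("f1", "f2")
  class(ds) <- "subject_dataset"
  levels(ds$label) <- c("liquid", "nonliquid")
  res <- loocv_evaluate(ds, c("f1", "f2"), "KNN1", standardize = FALSE)
  expect_equal(res$metrics[["accuracy"]], 0)   # each NN is opposite-class
  expect_equal(sum(res$confusion), 4)

  set.seed(21)
  for (i in 1:25) {
    n <- sample(10:20, 1)
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(sample(c("liquid", "nonliquid"), n, replace = TRUE),
                levels = c("liquid", "nonliquid"))
    if (length(unique(y)) < 2) next
    ds <- structure(list(x = x, label = y), class = "subject_dataset")
    got <- loocv_evaluate(ds, c("a", "b", "c"), "KNN1")$predictions
    expect_identical(got, brute_knn1_loocv(x, y))
  }
})

test_that("both classifiers separate well-separated Gaussian clouds", {
  set.seed(22)
  for (i in 1:10) {
    x <- rbind(matrix(rnorm(32, 0, 0.5), 16, 2),
               matrix(rnorm(32, 6, 0.5), 16, 2))
    colnames(x) <- c("f1", "f2")
    y <- factor(rep(c("liquid", "nonliquid"), each = 16),
                levels = c("liquid", "nonliquid"))
    ds <- structure(list(x = x, label = y), class = "subject_dataset")
    for (model in c("KNN1", "LDA")) {
      acc <- loocv_evaluate(ds, c("f1", "f2"), model)$metrics[["accuracy"]]
      expect_gte(acc, 95)
      # single-feature fits must work too (1-column design)
      acc1 <- loocv_evaluate(ds, "f1", model)$metrics[["accuracy"]]
      expect_gte(acc1, 95)
    }
  }
})

test_that("LDA agrees with an established reference on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(23)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 2), 30, 2))
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("liquid", "nonliquid"), each = 30))
  fit <- swallowEMG:::lda_fit(x, y)
  mine <- swallowEMG:::lda_predict(fit, x)
  ref <- predict(MASS::lda(x, grouping = y), x)$class
  expect_identical(as.character(mine), as.character(ref))
})

test_that("singular covariance falls back to shrinkage instead of crashing", {
  x <- cbind(f1 = c(0, 0, 0, 1, 1, 1), f2 = c(0, 0, 0, 1, 1, 1))  # collinear
  y <- factor(rep(c("liquid", "nonliquid"), each = 3),
              levels = c("liquid", "nonliquid"))
  ds <- structure(list(x = x, label = y), class = "subject_dataset")
  res <- loocv_evaluate(ds, c("f1", "f2"), "LDA", standardize = FALSE)
  expect_true(is.finite(res$metrics[["accuracy"]]))
})

test_that("permuted labels give chance-level accuracy (no information leak)", {
  fm <- shared_cohort()$features
  subjects <- unique(fm$subject)
  set.seed(24)
  accs <- unlist(lapply(subjects, function(s) {
    ds <- assemble_subject_dataset(fm, s)
    replicate(4, {
      ds$label <- sample(ds$label)
      loocv_evaluate(ds, c("IEMG", "RMS"), "KNN1")$metrics[["accuracy"]]
    })
  }))
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})
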