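# Cheap deterministic evaluator used across selection tests: the metric is a
# known function of the subset, so the greedy path can be predicted or
# brute-forced.
make_quadratic_evaluator <- function(weights, interaction = 0) {
  function(subset) {
    m <- sum(weights[subset])
    if (interaction != 0 && all(c("f1", "f2") %in% subset))
      m <- m + interaction
    list(metric = m, per_subject = rep(m, 3))
  }
}

test_that("the single informative feature is selected first", {
  set.seed(30)
  n <- 40
  x <- data.frame(inf = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 4, 0.3)),
                  noise1 = rnorm(n), noise2 = rnorm(n))
  y <- factor(rep(c("liquid", "nonliquid"), each = n / 2),
              levels = c("liquid", "nonliquid"))
  ds <- structure(list(x = as.matrix(x), label = y),
                  class = "subject_dataset")
  ev <- function(subset)
    list(metric = loocv_evaluate(ds, subset, "KNN1")$metrics[["accuracy"]])
  trace <- forward_select(ev, c("noise1", "inf", "noise2"), "maximize",
                          max_features = 2)
  expect_identical(trace$steps$feature[1], "inf")
})

test_that("stopping rules behave as specified", {
  w <- c(f1 = 3, f2 = 2, f3 = 1)
  ev <- make_quadratic_evaluator(w)
  one <- forward_select(ev, names(w), "maximize", epsilon = Inf)
  expect_identical(nrow(one$steps), 1L)
  expect_identical(one$stopping, "plateau")
  capped <- forward_select(ev, names(w), "maximize", max_features = 2)
  expect_identical(capped$stopping, "max_features")
  expect_identical(capped$selected, c("f1", "f2"))
  all3 <- forward_select(ev, names(w), "maximize", max_features = 10)
  expect_identical(all3$stopping, "exhausted")
  expect_identical(all3$selected, c("f1", "f2", "f3"))
  # metric series is monotone non-decreasing up to the stop
  expect_true(all(diff(all3$steps$metric) >= 0))
})

test_that("ties break by candidate order and failures are skipped", {
  ev_tie <- make_quadratic_evaluator(c(a = 1, b = 1, c = 0))
  tr <- forward_select(ev_tie, c("b", "a", "c"), "maximize", max_features = 1)
  expect_identical(tr$selected, "b")       # first candidate wins the tie
  ev_fail <- function(subset) {
    if ("bad" %in% subset) stop("boom")
    list(metric = sum(subset == "good"))
  }
  expect_warning(
    tr2 <- forward_select(ev_fail, c("bad", "good"), "maximize",
                          max_features = 1),
    "boom")
  expect_identical(tr2$selected, "good")
})

test_that("greedy selection equals exhaustive search when gains are additive", {
  set.seed(31)
  w <- stats::setNames(c(runif(3, 1, 2), runif(7, 0, 0.1)),
                       paste0("f", 1:10))
  ev <- make_quadratic_evaluator(w)
  greedy <- forward_select(ev, names(w), "maximize", max_features = 3)
  brute <- exhaustive_best_subset(ev, names(w), 3)
  expect_setequal(greedy$selected, brute$subset)
  expect_equal(greedy$steps$metric[3], brute$metric)
})

test_that("with an interaction the brute-force subset bounds the greedy one", {
  # f3 alone beats f1/f2, but f1+f2 together beat any pair containing f3:
  # greedy is allowed to miss this; exhaustive search must find it.
  ev <- make_quadratic_evaluator(c(f1 = 0.4, f2 = 0.4, f3 = 1,
                                   f4 = 0, f5 = 0), interaction = 2)
  brute <- exhaustive_best_subset(ev, paste0("f", 1:5), 2)
  expect_setequal(brute$subset, c("f1", "f2"))
  greedy <- forward_select(ev, paste0("f", 1:5), "maximize", max_features = 2)
  expect_lte(greedy$steps$metric[2], brute$metric)
})

test_that("selection on pure noise stops early most of the time", {
  set.seed(32)
  stops <- replicate(50, {
    m0 <- runif(1)
    ev <- function(subset) list(metric = m0)   # no subset improves anything
    tr <- forward_select(ev, paste0("f", 1:5), "maximize", max_features = 5)
    tr$stopping == "plateau"
  })
  expect_gte(mean(stops), 0.8)
})

test_that("one-way ANOVA across steps matches hand computation", {
  identical_groups <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- anova_across_steps(identical_groups)
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)
  r2 <- anova_across_steps(list(g1 = c(1, 2, 3), g2 = c(101, 102, 103)))
  # SSB = 2 * 3 * 50^2, SSW = 4, df = (1, 4): F = 15000 / 1
  expect_equal(r2$f, 15000)
  expect_lt(r2$p, 0.001)
  expect_error(anova_across_steps(list(a = 1:3)), "two groups")
  expect_error(anova_across_steps(list(a = 1:3, b = 2)), "at least two values")
  degenerate <- anova_across_steps(list(a = c(1, 1), b = c(1, 1)))
  expect_true(is.na(degenerate$p))
  expect_equal(nrow(r2$pairwise), 1)
})
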