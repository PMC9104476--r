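#' Assemble one subject's two-class dataset from the cohort feature matrix
#'
#' Builds the 32-observation per-subject classification problem: the liquid
#' class holds the 16 burst windows of the liquid tasks (5 cup + 5 bottle +
#' 5 straw + 1 maximum-capacity swallow); the non-liquid class holds the 5
#' saliva burst windows plus 11 baseline-noise windows, chosen
#' deterministically as the baselines of the first 11 recordings in task
#' order (saliva, cup, bottle, straw, maxcap).
#'
#' @param features Feature matrix from [extract_cohort_features()].
#' @param subject Subject identifier to extract.
#' @return List of class `subject_dataset`: `x` (32 x p feature matrix),
#'   `label` (factor liquid/nonliquid), `volume_mL`, `subject`.
#' @export
assemble_subject_dataset <- function(features, subject) {
  df <- features[features$subject == subject, , drop = FALSE]
  task_order <- c("saliva", "cup", "bottle", "straw", "maxcap")
  if (!all(task_order %in% df$task))
    stop("subject ", subject, " is missing task(s): ",
         paste(setdiff(task_order, df$task), collapse = ", "))
  df <- df[order(match(df$task, task_order), df$recording), , drop = FALSE]
  bursts <- df[df$kind == "burst", , drop = FALSE]
  bases <- df[df$kind == "baseline", , drop = FALSE]
  n_rec <- nrow(bursts)
  if (n_rec != 21)
    stop("subject ", subject, " has ", n_rec, " recordings; expected 21")

  liquid <- bursts[bursts$task != "saliva", , drop = FALSE]
  saliva <- bursts[bursts$task == "saliva", , drop = FALSE]
  noise <- bases[1:11, , drop = FALSE]

  meta_cols <- c("recording", "subject", "task", "volume_mL", "kind")
  fcols <- setdiff(names(df), meta_cols)
  obs <- rbind(liquid, saliva, noise)
  x <- as.matrix(obs[, fcols, drop = FALSE])
  lab <- factor(rep(c("liquid", "nonliquid"), c(nrow(liquid),
                                                nrow(saliva) + nrow(noise))),
                levels = c("liquid", "nonliquid"))
  vol <- obs$volume_mL
  vol[lab == "nonliquid"] <- 0
  structure(list(x = x, label = lab, volume_mL = vol, subject = subject),
            class = "subject_dataset")
}

#' Classification performance metrics from a confusion table
#'
#' Treating liquid swallows as the positive class:
#' accuracy = (TP + TN) / all, sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), precision = TP / (TP + FP), and
#' F-score = 2 (precision x sensitivity) / (precision + sensitivity),
#' all as percentages. When no observation is predicted positive
#' (TP + FP = 0), precision and the F-score are reported as `NA`; an empty
#' true class likewise yields `NA` for the corresponding rate.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return Named numeric vector: accuracy, sensitivity, specificity,
#'   precision, f_score (percent).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || sum(counts) == 0)
    stop("confusion counts must be non-negative and not all zero")
  acc <- (tp + tn) / sum(counts)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  100 * c(accuracy = acc, sensitivity = sens, specificity = spec,
          precision = prec, f_score = f1)
}

# Pooled-covariance linear discriminant fit with a shrinkage fallback.
# With ~31 training points and up to a handful of features the pooled
# covariance can be near-singular; shrink toward its diagonal until the
# system solves.
lda_fit <- function(x, y) {
  classes <- levels(y)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  rownames(mu) <- classes
  n <- nrow(x)
  sw <- Reduce(`+`, lapply(classes, function(cl) {
    xc <- sweep(x[y == cl, , drop = FALSE], 2, mu[cl, ])
    crossprod(xc)
  })) / (n - length(classes))
  prior <- as.numeric(table(y)[classes]) / n
  # last resort: a pure ridge handles the all-zero-variance case
  ridge <- diag(mean(diag(sw)) + 1e-8, nrow(sw))
  for (lambda in c(0, 1e-4, 1e-2, 1e-1, 0.5, 1, 2)) {
    s <- if (lambda <= 1) (1 - lambda) * sw + lambda * diag(diag(sw), nrow(sw))
         else ridge
    w <- tryCatch(solve(s, t(mu)), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) {
      return(list(w = w, b = -0.5 * colSums(t(mu) * w) + log(prior),
                  classes = classes))
    }
  }
  stop("pooled covariance unusable even after full shrinkage")
}

lda_predict <- function(fit, x) {
  scores <- x %*% fit$w + rep(fit$b, each = nrow(x))
  factor(fit$classes[max.col(scores, ties.method = "first")],
         levels = fit$classes)
}

# 1-nearest-neighbour prediction; distance ties go to the lowest training
# index so results are deterministic.
knn1_predict <- function(train_x, train_y, test_x) {
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d2 <- colSums((t(train_x) - test_x[i, ])^2)
    pred[i] <- as.character(train_y[which.min(d2)])
  }
  factor(pred, levels = levels(train_y))
}

#' Leave-one-out cross-validated classification of one subject
#'
#' Each of the 32 observations is held out once; the classifier is fit on the
#' remaining 31 and predicts the held-out point. Features are standardized
#' inside each fold using training means/SDs only (no information leak);
#' zero-SD features within a fold are left unscaled. The confusion table is
#' aggregated over folds and scored with [confusion_metrics()].
#'
#' @param dataset A `subject_dataset` from [assemble_subject_dataset()].
#' @param feature_subset Character vector of feature names to use.
#' @param model `"KNN1"` (1-nearest neighbour) or `"LDA"`.
#' @param standardize Standardize per fold (default `TRUE`).
#' @return List: `metrics` (from [confusion_metrics()]), `confusion`
#'   (tp, fn, tn, fp), `predictions` (factor).
#' @export
loocv_evaluate <- function(dataset, feature_subset,
                           model = c("KNN1", "LDA"), standardize = TRUE) {
  model <- match.arg(model)
  if (length(feature_subset) == 0) stop("empty feature subset")
  missing_f <- setdiff(feature_subset, colnames(dataset$x))
  if (length(missing_f) > 0)
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  x <- dataset$x[, feature_subset, drop = FALSE]
  y <- dataset$label
  n <- nrow(x)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    xte <- x[i, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    pred[i] <- if (model == "KNN1") knn1_predict(xtr, ytr, xte)
               else lda_predict(lda_fit(xtr, ytr), xte)
  }
  tp <- sum(pred == "liquid" & y == "liquid")
  fn <- sum(pred == "nonliquid" & y == "liquid")
  tn <- sum(pred == "nonliquid" & y == "nonliquid")
  fp <- sum(pred == "liquid" & y == "nonliquid")
  list(metrics = confusion_metrics(tp, fn, tn, fp),
       confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
       predictions = pred)
}

#' Cohort-level LOOCV classification report
#'
#' Runs [loocv_evaluate()] for every subject and aggregates each metric as
#' mean and SD across subjects — the layout of the study-style performance
#' tables.
#'
#' @param datasets List of `subject_dataset` objects.
#' @inheritParams loocv_evaluate
#' @return List: `per_subject` (data.frame of per-subject metrics),
#'   `summary` (data.frame: metric, mean, sd).
#' @export
classify_cohort <- function(datasets, feature_subset, model = "KNN1",
                            standardize = TRUE) {
  per <- do.call(rbind, lapply(datasets, function(d) {
    m <- loocv_evaluate(d, feature_subset, model, standardize)$metrics
    data.frame(subject = d$subject, t(m))
  }))
  rownames(per) <- NULL
  metric_cols <- setdiff(names(per), "subject")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(per[metric_cols], mean, numeric(1)),
    sd = vapply(per[metric_cols], stats::sd, numeric(1)),
    row.names = NULL
  )
  list(per_subject = per, summary = summ)
}
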