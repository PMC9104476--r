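#' Mean absolute relative estimation error, in percent
#'
#' The volume-estimation error measure: the mean over sips of
#' `|predicted - actual| / actual x 100`.
#'
#' @param predicted,actual Equal-length numeric vectors; `actual` must be
#'   strictly positive.
#' @return Scalar percentage.
#' @export
mean_estimation_error <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (any(actual <= 0)) stop("actual volumes must be positive")
  mean(abs(predicted - actual) / actual) * 100
}

#' Mean-sip baseline volume estimator
#'
#' The naive predictor that always answers a subject's mean sip volume.
#' Per subject: mean and sample SD of the sip volumes, and the
#' mean-relative-error percentage of predicting every sip by the mean.
#' The across-all row aggregates the per-subject columns: mean of the means,
#' SD of the means, and mean of the per-subject errors.
#'
#' @param volumes Named list of numeric vectors (one per subject, each >= 2
#'   positive sip volumes in mL), or a data.frame with columns `subject` and
#'   `volume_mL`.
#' @return data.frame with columns subject, mean_mL, sd_mL, error_pct; the
#'   last row is `"Across All"`.
#' @export
mean_sip_baseline <- function(volumes) {
  if (is.data.frame(volumes))
    volumes <- split(volumes$volume_mL, volumes$subject)
  if (any(vapply(volumes, length, integer(1)) < 2))
    stop("each subject needs at least two sips")
  if (any(unlist(volumes) <= 0)) stop("sip volumes must be positive")
  per <- do.call(rbind, lapply(names(volumes), function(s) {
    v <- volumes[[s]]
    data.frame(subject = s, mean_mL = mean(v), sd_mL = stats::sd(v),
               error_pct = mean_estimation_error(rep(mean(v), length(v)), v))
  }))
  across <- data.frame(subject = "Across All",
                       mean_mL = mean(per$mean_mL),
                       sd_mL = stats::sd(per$mean_mL),
                       error_pct = mean(per$error_pct))
  rbind(per, across)
}

#' Aggregate a published per-subject sip summary
#'
#' Applies the across-all aggregation of [mean_sip_baseline()] to an already
#' summarized per-subject table (columns `mean_mL` and `error_pct`), as used
#' with the bundled reference summary in `inst/extdata`.
#'
#' @param per_subject data.frame with columns `mean_mL`, `error_pct`.
#' @return Named numeric vector: mean_mL (mean of per-subject means), sd_mL
#'   (SD of per-subject means), error_pct (mean of per-subject errors).
#' @export
aggregate_sip_summary <- function(per_subject) {
  stopifnot(all(c("mean_mL", "error_pct") %in% names(per_subject)))
  c(mean_mL = mean(per_subject$mean_mL),
    sd_mL = stats::sd(per_subject$mean_mL),
    error_pct = mean(per_subject$error_pct))
}

# Seeded k-fold assignment: shuffle indices, deal them round-robin.
kfold_assign <- function(n, k) {
  folds <- rep_len(seq_len(k), n)
  sample(folds)
}

#' Cross-validated linear-regression volume estimation for one subject
#'
#' Ordinary-least-squares regression of sip volume on the selected features
#' (intercept plus a linear term per predictor), evaluated by 5-fold
#' cross-validation with a seeded shuffle: each fold's sips are predicted by
#' a model fit on the remaining folds, and RMSE plus mean estimation error
#' are pooled over all held-out predictions. Rank-deficient designs fall
#' back to the minimum-norm least-squares solution with a warning.
#'
#' @param x Feature matrix (liquid sips only, rows = sips).
#' @param volume Positive sip volumes (mL), one per row of `x`.
#' @param feature_subset Character vector of feature columns.
#' @param k Number of folds (default 5).
#' @return List: `rmse_mL`, `ee_pct`, `predicted`, `actual`, `fold`.
#' @export
linear_regression_cv <- function(x, volume, feature_subset, k = 5) {
  if (length(volume) < 2 * k) k <- max(2, floor(length(volume) / 2))
  if (length(feature_subset) == 0) stop("empty feature subset")
  xm <- as.matrix(x[, feature_subset, drop = FALSE])
  n <- nrow(xm)
  fold <- kfold_assign(n, k)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    d <- cbind(1, xm[tr, , drop = FALSE])
    qr_d <- qr(d)
    if (qr_d$rank < ncol(d))
      warning("rank-deficient design; using minimum-norm solution")
    beta <- qr.coef(qr_d, volume[tr])
    beta[is.na(beta)] <- 0
    pred[!tr] <- cbind(1, xm[!tr, , drop = FALSE]) %*% beta
  }
  list(rmse_mL = sqrt(mean((pred - volume)^2)),
       ee_pct = mean_estimation_error(pred, volume),
       predicted = pred, actual = volume, fold = fold)
}

# ---- shallow tanh network trained by Levenberg-Marquardt ------------------

# Forward pass: f(x) = w2' [tanh(W1 [x; 1]); 1].
mlp_forward <- function(theta, x, n_hidden) {
  d <- ncol(x)
  w1 <- matrix(theta[seq_len(n_hidden * (d + 1))], n_hidden, d + 1)
  w2 <- theta[n_hidden * (d + 1) + seq_len(n_hidden + 1)]
  h <- tanh(w1 %*% t(cbind(x, 1)))                  # n_hidden x n
  as.numeric(w2[seq_len(n_hidden)] %*% h + w2[n_hidden + 1])
}

# Jacobian of predictions wrt theta (n x p), analytic.
mlp_jacobian <- function(theta, x, n_hidden) {
  d <- ncol(x)
  n <- nrow(x)
  w1 <- matrix(theta[seq_len(n_hidden * (d + 1))], n_hidden, d + 1)
  w2 <- theta[n_hidden * (d + 1) + seq_len(n_hidden + 1)]
  xb <- cbind(x, 1)                                  # n x (d+1)
  h <- tanh(w1 %*% t(xb))                            # n_hidden x n
  dh <- (1 - h^2) * w2[seq_len(n_hidden)]            # n_hidden x n
  jw1 <- matrix(0, n, n_hidden * (d + 1))
  for (j in seq_len(d + 1))
    jw1[, (j - 1) * n_hidden + seq_len(n_hidden)] <- t(dh) * xb[, j]
  cbind(jw1, t(h), 1)
}

# Levenberg-Marquardt with validation-based early stopping. Damping is
# multiplied/divided by 10 on rejected/accepted steps; training stops on
# gradient norm < tol, max_iter, lambda overflow, or max_val_fail
# consecutive validation failures; the weights with the best validation
# error are returned.
lm_train <- function(theta, xtr, ytr, xval, yval, n_hidden,
                     max_iter = 200, tol = 1e-7, max_val_fail = 6) {
  lambda <- 1e-3
  r <- ytr - mlp_forward(theta, xtr, n_hidden)
  sse <- sum(r^2)
  best_theta <- theta
  best_val <- mean((yval - mlp_forward(theta, xval, n_hidden))^2)
  val_fail <- 0
  for (it in seq_len(max_iter)) {
    jac <- mlp_jacobian(theta, xtr, n_hidden)
    g <- crossprod(jac, r)
    if (sqrt(sum(g^2)) < tol) break
    jtj <- crossprod(jac)
    repeat {
      step <- tryCatch(
        solve(jtj + lambda * diag(diag(jtj) + 1e-12), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.numeric(step)
        rc <- ytr - mlp_forward(cand, xtr, n_hidden)
        if (sum(rc^2) < sse) break
      }
      lambda <- lambda * 10
      if (lambda > 1e10) break
    }
    if (lambda > 1e10) break
    theta <- cand
    r <- rc
    sse <- sum(rc^2)
    lambda <- max(lambda / 10, 1e-12)
    val <- mean((yval - mlp_forward(theta, xval, n_hidden))^2)
    if (val < best_val) {
      best_val <- val
      best_theta <- theta
      val_fail <- 0
    } else {
      val_fail <- val_fail + 1
      if (val_fail >= max_val_fail) break
    }
  }
  list(theta = best_theta, val_mse = best_val)
}

#' Shallow-network volume estimation for one subject
#'
#' A single hidden layer of `n_hidden` tanh units with a linear output,
#' trained by Levenberg-Marquardt (damped Gauss-Newton on the squared error)
#' on a random 70/15/15 train/validation/test division with early stopping on
#' the validation error. Inputs and target are z-scored on the training split
#' for conditioning. The best of `restarts` random initializations (by
#' validation error) is kept, and errors are scored on the held-out test
#' sips (configurable to all sips).
#'
#' @inheritParams linear_regression_cv
#' @param n_hidden Hidden units (default 15).
#' @param restarts Random initializations (default 3).
#' @param score `"test"` (default) scores held-out sips; `"all"` scores every
#'   sip.
#' @return List: `rmse_mL`, `ee_pct`, `predicted`, `actual` (scored sips),
#'   `split` (train/val/test assignment).
#' @export
ann_estimator <- function(x, volume, feature_subset, n_hidden = 15,
                          restarts = 3, score = c("test", "all")) {
  score <- match.arg(score)
  if (length(volume) < 10) stop("need at least 10 observations")
  xm <- as.matrix(x[, feature_subset, drop = FALSE])
  n <- nrow(xm)
  idx <- sample(n)
  n_tr <- round(0.7 * n)
  n_val <- max(round(0.15 * n), 1)
  split <- rep("test", n)
  split[idx[seq_len(n_tr)]] <- "train"
  split[idx[n_tr + seq_len(n_val)]] <- "val"
  tr <- split == "train"; va <- split == "val"; te <- split == "test"

  mu <- colMeans(xm[tr, , drop = FALSE])
  sdv <- apply(xm[tr, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xs <- sweep(sweep(xm, 2, mu), 2, sdv, "/")
  ymu <- mean(volume[tr]); ysd <- stats::sd(volume[tr])
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (volume - ymu) / ysd

  p <- n_hidden * (ncol(xs) + 1) + n_hidden + 1
  best <- NULL
  for (k in seq_len(restarts)) {
    theta0 <- stats::rnorm(p, sd = 0.5)
    fit <- lm_train(theta0, xs[tr, , drop = FALSE], ys[tr],
                    xs[va, , drop = FALSE], ys[va], n_hidden)
    if (is.null(best) || fit$val_mse < best$val_mse) best <- fit
  }
  pred_all <- mlp_forward(best$theta, xs, n_hidden) * ysd + ymu
  keep <- if (score == "test") te else rep(TRUE, n)
  list(rmse_mL = sqrt(mean((pred_all[keep] - volume[keep])^2)),
       ee_pct = mean_estimation_error(pred_all[keep], volume[keep]),
       predicted = pred_all[keep], actual = volume[keep], split = split)
}

#' Cohort-level volume-estimation report
#'
#' Runs one estimator per subject on the liquid sips of the cohort feature
#' matrix and aggregates RMSE and mean estimation error as mean and SD
#' across subjects (plus the pooled values over all held-out predictions).
#'
#' @param features Feature matrix from [extract_cohort_features()].
#' @param feature_subset Character vector of feature columns.
#' @param method `"lr"` (cross-validated OLS), `"ann"`, or `"baseline"`.
#' @param ... Passed to [linear_regression_cv()] or [ann_estimator()].
#' @return List: `per_subject` (data.frame subject, rmse_mL, ee_pct),
#'   `summary` (mean/sd rows for both measures), `pooled`.
#' @export
estimate_cohort <- function(features, feature_subset,
                            method = c("lr", "ann", "baseline"), ...) {
  method <- match.arg(method)
  liquid <- features[features$kind == "burst" & features$volume_mL > 0, ,
                     drop = FALSE]
  subjects <- unique(liquid$subject)
  pred_all <- numeric(0); act_all <- numeric(0)
  per <- do.call(rbind, lapply(subjects, function(s) {
    d <- liquid[liquid$subject == s, , drop = FALSE]
    res <- switch(method,
      lr = linear_regression_cv(d, d$volume_mL, feature_subset, ...),
      ann = ann_estimator(d, d$volume_mL, feature_subset, ...),
      baseline = {
        m <- mean(d$volume_mL)
        pr <- rep(m, nrow(d))
        list(rmse_mL = sqrt(mean((pr - d$volume_mL)^2)),
             ee_pct = mean_estimation_error(pr, d$volume_mL),
             predicted = pr, actual = d$volume_mL)
      })
    pred_all <<- c(pred_all, res$predicted)
    act_all <<- c(act_all, res$actual)
    data.frame(subject = s, rmse_mL = res$rmse_mL, ee_pct = res$ee_pct)
  }))
  rownames(per) <- NULL
  list(per_subject = per,
       summary = data.frame(
         measure = c("rmse_mL", "ee_pct"),
         mean = c(mean(per$rmse_mL), mean(per$ee_pct)),
         sd = c(stats::sd(per$rmse_mL), stats::sd(per$ee_pct))),
       pooled = c(rmse_mL = sqrt(mean((pred_all - act_all)^2)),
                  ee_pct = mean_estimation_error(pred_all, act_all)))
}
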