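#' Stepwise forward feature selection
#'
#' Greedy wrapper selection around an arbitrary evaluator: at each step every
#' remaining candidate is evaluated together with the already-selected set,
#' the best one is kept, and the search stops when the improvement over the
#' previous step is `epsilon` or less, when `max_features` is reached, or
#' when candidates are exhausted. Ties are broken by candidate order (the
#' canonical [feature_names()] order in the standard pipeline).
#'
#' @param evaluator `function(feature_subset)` returning a list with `metric`
#'   (scalar driving the search) and optionally `per_subject` (numeric vector
#'   recorded in the trace, e.g. per-subject accuracies). An evaluator that
#'   errors on a subset causes that subset to be skipped with a warning.
#' @param candidates Character vector of candidate feature names.
#' @param direction `"maximize"` (e.g. accuracy) or `"minimize"` (e.g. RMSE).
#' @param max_features Maximum subset size (default 10).
#' @param epsilon Minimum improvement to continue (default 0).
#' @return List of class `selection_trace`: `steps` (data.frame: step,
#'   feature, metric), `per_subject` (list of per-step vectors), `selected`
#'   (character), `stopping` (one of plateau, max_features, exhausted).
#' @export
forward_select <- function(evaluator, candidates,
                           direction = c("maximize", "minimize"),
                           max_features = 10, epsilon = 0) {
  direction <- match.arg(direction)
  if (length(candidates) == 0) stop("no candidate features")
  sgn <- if (direction == "maximize") 1 else -1
  selected <- character(0)
  remaining <- candidates
  steps <- data.frame(step = integer(0), feature = character(0),
                      metric = numeric(0))
  per_subject <- list()
  best_prev <- -Inf
  stopping <- "exhausted"

  while (length(remaining) > 0 && length(selected) < max_features) {
    best_metric <- -Inf
    best_feat <- NA_character_
    best_ps <- NULL
    for (f in remaining) {              # candidate order breaks ties
      res <- tryCatch(evaluator(c(selected, f)), error = function(e) {
        warning("evaluator failed on {", paste(c(selected, f), collapse = ", "),
                "}: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      m <- sgn * res$metric
      if (is.finite(m) && m > best_metric) {
        best_metric <- m
        best_feat <- f
        best_ps <- res$per_subject
      }
    }
    if (is.na(best_feat)) stop("evaluator failed on every candidate subset")
    if (length(selected) > 0 && best_metric - best_prev <= epsilon) {
      stopping <- "plateau"
      break
    }
    selected <- c(selected, best_feat)
    remaining <- setdiff(remaining, best_feat)
    steps <- rbind(steps, data.frame(step = length(selected),
                                     feature = best_feat,
                                     metric = sgn * best_metric))
    per_subject[[length(selected)]] <- best_ps
    best_prev <- best_metric
    if (length(selected) >= max_features) stopping <- "max_features"
  }
  structure(list(steps = steps, per_subject = per_subject,
                 selected = selected, stopping = stopping),
            class = "selection_trace")
}

#' One-way ANOVA of a metric across feature-set sizes
#'
#' Tests whether the per-subject metric (accuracy, RMSE, ...) differs as
#' features are added: a standard one-way ANOVA over the groups (one group
#' per feature-set size), plus descriptive pairwise two-group ANOVAs.
#' If every group has zero within-group variance, the F statistic is
#' degenerate and p is reported as `NA`.
#'
#' @param groups Named list of numeric vectors, one per feature-set size,
#'   each of length >= 2 (e.g. `selection_trace$per_subject`).
#' @return List: `f` (F statistic), `p` (overall p-value), `pairwise`
#'   (data.frame: group1, group2, f, p).
#' @export
anova_across_steps <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least two values")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  one <- function(g) {
    df <- data.frame(y = unlist(g, use.names = FALSE),
                     grp = factor(rep(names(g), lengths(g))))
    tab <- stats::anova(stats::lm(y ~ grp, data = df))
    f <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
    if (!is.finite(f)) { f <- NA_real_; p <- NA_real_ }
    c(f = f, p = p)
  }
  overall <- one(groups)
  pairs <- utils::combn(names(groups), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    r <- one(groups[pairs[, k]])
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               f = r[["f"]], p = r[["p"]])
  }))
  list(f = overall[["f"]], p = overall[["p"]], pairwise = pw)
}
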