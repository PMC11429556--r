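#' Two-class Fisher score
#'
#' The univariate separability criterion
#' \deqn{F = (\mu_1 - \mu_2)^2 / (\sigma_1^2 + \sigma_2^2)}
#' with unbiased group variances. It is symmetric in group order, invariant to
#' adding a constant and to rescaling both groups. If both variances are zero
#' the score is `Inf` when the means differ and 0 when they are equal.
#'
#' @param values_group1,values_group2 Numeric vectors, each of length >= 2.
#' @param weighted If `TRUE`, use the class-size-weighted pooled denominator
#'   \eqn{(n_1 \sigma_1^2 + n_2 \sigma_2^2) / (n_1 + n_2)} instead of the plain
#'   sum of variances.
#' @return Non-negative score (possibly `Inf`).
#' @examples
#' fisher_score(c(1, 2, 3), c(3, 4, 5)) # (2 - 4)^2 / (1 + 1) = 2
#' @export
fisher_score <- function(values_group1, values_group2, weighted = FALSE) {
  if (length(values_group1) < 2 || length(values_group2) < 2) {
    stop("each group needs at least 2 values")
  }
  m1 <- mean(values_group1); m2 <- mean(values_group2)
  v1 <- var(values_group1); v2 <- var(values_group2)
  denom <- if (weighted) {
    n1 <- length(values_group1); n2 <- length(values_group2)
    (n1 * v1 + n2 * v2) / (n1 + n2)
  } else {
    v1 + v2
  }
  num <- (m1 - m2)^2
  if (denom == 0) {
    return(if (num == 0) 0 else Inf)
  }
  num / denom
}

#' Fisher scores for every region column
#'
#' Applies [fisher_score()] column-wise to a region feature matrix, contrasting
#' the two groups in `groups`.
#'
#' @param features A `ran_features` of kind `"region"`, or a plain numeric
#'   matrix (samples x regions).
#' @param groups Group label per row (two distinct values). Defaults to the
#'   feature matrix's own metadata.
#' @param weighted Passed to [fisher_score()].
#' @return Named numeric vector of scores, one per region column.
#' @export
score_regions <- function(features, groups = NULL, weighted = FALSE) {
  x <- if (inherits(features, "ran_features")) features$values else features
  if (is.null(groups) && inherits(features, "ran_features")) {
    groups <- features$meta$group
  }
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups are required, got: ",
                             paste(lev, collapse = ", "))
  if (min(table(groups)) < 2) stop("each group needs at least 2 samples")
  g1 <- groups == lev[1]
  apply(x, 2, function(col) fisher_score(col[g1], col[!g1], weighted = weighted))
}

#' Selection configuration
#'
#' @param thresholds Strictly increasing positive threshold grid. The default
#'   is the six values 0.16, 0.18, ..., 0.26.
#' @param rule Survival rule across visits; `"any_visit"` keeps a region whose
#'   score meets the threshold at one or more visits.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(thresholds = seq(0.16, 0.26, by = 0.02),
                             rule = "any_visit") {
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be positive and strictly increasing")
  }
  rule <- match.arg(rule, "any_visit")
  structure(list(thresholds = thresholds, rule = rule),
            class = "selection_config")
}

#' Regions surviving a Fisher threshold at least once across visits
#'
#' @param scores_by_visit Named list of per-visit score vectors (region label
#'   -> score), e.g. one [score_regions()] result per visit.
#' @param threshold Positive scalar.
#' @return Integer vector of region labels whose score meets or exceeds the
#'   threshold in any visit, in region order.
#' @export
select_surviving_regions <- function(scores_by_visit, threshold) {
  if (length(scores_by_visit) < 1) stop("need scores for at least one visit")
  hits <- lapply(scores_by_visit, function(s) {
    names(s)[!is.na(s) & s >= threshold]
  })
  labs <- unique(unlist(hits))
  sort(as.integer(labs))
}

#' Sweep the Fisher threshold grid and pick the accuracy-optimal one
#'
#' For every threshold in the grid, forms the surviving region set and asks
#' `evaluate` for the per-visit leave-one-out accuracy of an SVM restricted to
#' that set; the chosen threshold maximizes the mean accuracy across visits.
#' Ties go to the largest tied threshold (the most selective set), logged via
#' `message()`. Thresholds whose surviving set is empty are skipped with a
#' note. Identical region sets are evaluated once and cached.
#'
#' @param scores_by_visit As in [select_surviving_regions()].
#' @param evaluate Function taking an integer region-label vector and
#'   returning a numeric vector of per-visit LOO accuracies.
#' @param config A [selection_config()].
#' @return List of class `selection_result`: `table` (threshold, n_regions,
#'   mean_accuracy), `sets` (per-threshold region sets), `chosen_threshold`,
#'   `chosen_regions`.
#' @export
sweep_thresholds <- function(scores_by_visit, evaluate,
                             config = selection_config()) {
  stopifnot(inherits(config, "selection_config"), is.function(evaluate))
  thr <- config$thresholds
  sets <- lapply(thr, function(t) select_surviving_regions(scores_by_visit, t))
  names(sets) <- as.character(thr)
  cache <- new.env(parent = emptyenv())
  mean_acc <- vapply(seq_along(thr), function(k) {
    set <- sets[[k]]
    if (length(set) == 0) {
      message(sprintf("threshold %g: empty region set, skipped", thr[k]))
      return(NA_real_)
    }
    key <- paste(set, collapse = ",")
    if (is.null(cache[[key]])) cache[[key]] <- mean(evaluate(set))
    cache[[key]]
  }, numeric(1))
  if (all(is.na(mean_acc))) stop("every threshold yields an empty region set")
  best <- max(mean_acc, na.rm = TRUE)
  tied <- which(!is.na(mean_acc) & mean_acc == best)
  if (length(tied) > 1) {
    message(sprintf("thresholds tied at mean accuracy %.4f: %s; keeping %g",
                    best, paste(thr[tied], collapse = ", "), thr[max(tied)]))
  }
  pick <- max(tied)
  structure(list(
    table = data.frame(threshold = thr,
                       n_regions = vapply(sets, length, integer(1)),
                       mean_accuracy = mean_acc),
    sets = sets,
    chosen_threshold = thr[pick],
    chosen_regions = sets[[pick]]
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Fisher threshold sweep: chose %g (%d regions)\n",
              x$chosen_threshold, length(x$chosen_regions)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
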