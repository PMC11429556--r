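#' Linear SVM configuration
#'
#' The classifier throughout is a linear soft-margin support vector machine
#' with cost `C = 1`. Features are not standardized by default: weight-map
#' magnitude thresholds (see [threshold_clusters()]) operate on raw weights,
#' which are only comparable across runs when the feature scale is left alone.
#' `scale = "zscore"` standardizes within each training fold using that fold's
#' means and SDs.
#'
#' @param cost Soft-margin cost C (> 0).
#' @param scale `"none"` (default) or `"zscore"`.
#' @param eps SMO convergence tolerance on the KKT violation gap.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(cost = 1, scale = c("none", "zscore"), eps = 1e-3) {
  if (cost <= 0) stop("cost must be positive")
  structure(list(cost = cost, scale = match.arg(scale), eps = eps),
            class = "svm_config")
}

# canonical class ordering: factor levels if given, else sort order.
# The FIRST class in this ordering wins exact decision ties (logged).
class_levels <- function(labels) {
  if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
}

encode_labels <- function(labels, positive, lev) {
  labels <- as.character(labels)
  if (!positive %in% lev) stop("positive class '", positive, "' not among labels")
  if (length(lev) != 2) stop("exactly two classes are required, got: ",
                             paste(lev, collapse = ", "))
  ifelse(labels == positive, 1L, -1L)
}

decode_pred <- function(decision, positive, negative, tie_class) {
  out <- ifelse(decision > 0, positive, negative)
  ties <- decision == 0
  if (any(ties)) {
    message(sprintf("%d tied decision value(s) resolved to class '%s'",
                    sum(ties), tie_class))
    out[ties] <- tie_class
  }
  out
}

#' Fit a linear SVM on the full sample
#'
#' Solves the two-class C-SVC dual by sequential minimal optimization on a
#' precomputed Gram matrix and returns the primal weight vector. The decision
#' function is `f(x) = w . x + b`; `f > 0` predicts the positive class.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param labels Two-class label vector.
#' @param positive Name of the positive class (weights with positive sign are
#'   associated with it).
#' @param config An [svm_config()].
#' @return List of class `linear_svm`: `w`, `b`, `positive`, `negative`,
#'   `levels`, `alpha`.
#' @export
svm_fit <- function(x, labels, positive, config = svm_config()) {
  x <- as.matrix(x)
  lev <- class_levels(labels)
  y <- encode_labels(labels, positive, lev)
  if (min(table(y)) < 2) stop("each class needs at least 2 samples")
  if (config$scale == "zscore") {
    mu <- colMeans(x); sg <- apply(x, 2, sd); sg[sg == 0] <- 1
    x <- sweep(sweep(x, 2, mu, "-"), 2, sg, "/")
  }
  K <- tcrossprod(x)
  fit <- .svc_fit_kernel(K, y, config$cost, eps = config$eps)
  w <- drop(crossprod(x, fit$alpha * y))
  structure(list(w = w, b = fit$b, positive = positive,
                 negative = setdiff(lev, positive), levels = lev,
                 alpha = fit$alpha, config = config),
            class = "linear_svm")
}

#' Classification metrics from held-out predictions
#'
#' Accuracy, sensitivity (recall on the positive class), specificity, and
#' balanced accuracy (the arithmetic mean of sensitivity and specificity).
#' All are fractions in \[0, 1\]. A metric with a zero denominator (no samples
#' of that class) is `NA` with a warning.
#'
#' @param predictions,labels Aligned class vectors.
#' @param positive Name of the positive class.
#' @return List of class `classification_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, and the confusion counts `tp`, `tn`,
#'   `fp`, `fn`, `n_pos`, `n_neg`.
#' @export
classification_metrics <- function(predictions, labels, positive) {
  predictions <- as.character(predictions); labels <- as.character(labels)
  stopifnot(length(predictions) == length(labels))
  is_pos <- labels == positive
  tp <- sum(is_pos & predictions == positive)
  fn <- sum(is_pos & predictions != positive)
  tn <- sum(!is_pos & predictions != positive)
  fp <- sum(!is_pos & predictions == positive)
  n_pos <- tp + fn; n_neg <- tn + fp
  sens <- if (n_pos == 0) { warning("no positive samples; sensitivity is NA"); NA_real_ } else tp / n_pos
  spec <- if (n_neg == 0) { warning("no negative samples; specificity is NA"); NA_real_ } else tn / n_neg
  structure(list(
    accuracy = (tp + tn) / length(labels),
    sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    tp = tp, tn = tn, fp = fp, fn = fn, n_pos = n_pos, n_neg = n_neg
  ), class = "classification_metrics")
}

#' Leave-one-out cross-validated SVM classification
#'
#' n-fold cross-validation where fold i holds out exactly sample i, fits the
#' SVM on the remaining n - 1 samples, and records the held-out prediction.
#' All folds share one precomputed Gram matrix. A fold whose training set
#' degenerates to a single class (possible when a class has one sample)
#' predicts that majority class and is noted via `message()`. Exact decision
#' ties resolve to the first class in the canonical ordering (factor levels,
#' else sort order).
#'
#' @param x Numeric feature matrix (samples x features); row names are kept on
#'   the predictions.
#' @param labels Two-class label vector.
#' @param positive Positive class name.
#' @param config An [svm_config()].
#' @return List of class `cv_result`: `predictions` (held-out class per
#'   sample), `decision` (held-out decision values), `metrics`
#'   (a [classification_metrics()] result), `positive`, `n`.
#' @export
loo_cv <- function(x, labels, positive, config = svm_config()) {
  x <- as.matrix(x)
  lev <- class_levels(labels)
  y <- encode_labels(labels, positive, lev)
  if (min(table(y)) < 1 || length(unique(y)) != 2) {
    stop("both classes must be present")
  }
  if (sum(y == 1) == 1 || sum(y == -1) == 1) {
    message("a class has a single sample; its fold degenerates to a ",
            "majority-class prediction")
  }
  if (config$scale == "zscore") {
    dec <- vapply(seq_len(nrow(x)), function(i) {
      xi <- x[-i, , drop = FALSE]
      mu <- colMeans(xi); sg <- apply(xi, 2, sd); sg[sg == 0] <- 1
      Ki <- tcrossprod(sweep(sweep(x, 2, mu, "-"), 2, sg, "/"))
      drop(.svc_loo_decision_one(Ki, y, config, i))
    }, numeric(1))
  } else {
    K <- tcrossprod(x)
    dec <- .svc_loo_decision(K, y, config$cost, eps = config$eps)
  }
  negative <- setdiff(lev, positive)
  tie_class <- lev[1]
  pred <- decode_pred(dec, positive, negative, tie_class)
  names(pred) <- rownames(x)
  structure(list(predictions = pred, decision = dec,
                 metrics = classification_metrics(pred, as.character(labels), positive),
                 positive = positive, n = nrow(x)),
            class = "cv_result")
}

# single held-out fold on a fold-specific kernel (z-scored path)
.svc_loo_decision_one <- function(K, y, config, i) {
  fit <- .svc_fit_kernel(K[-i, -i, drop = FALSE], y[-i], config$cost,
                         eps = config$eps)
  if (isTRUE(fit$one_class)) return(y[-i][1])
  sum(fit$alpha * y[-i] * K[-i, i]) + fit$b
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "LOO-CV (n = %d, positive = '%s'): acc %.1f%%, sens %.1f%%, spec %.1f%%, bal %.1f%%\n",
    x$n, x$positive, 100 * m$accuracy, 100 * m$sensitivity,
    100 * m$specificity, 100 * m$balanced_accuracy))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p = %d/%d = %.4f\n",
                x$permutation$k, x$permutation$B, x$permutation$p))
  }
  invisible(x)
}

#' Monte Carlo permutation p-value for LOO accuracy
#'
#' Reruns the full leave-one-out classification on `B` random permutations of
#' the label vector (group sizes are preserved by construction) and counts how
#' often the shuffled accuracy is at least the observed one. The observed
#' labeling itself is not part of the count; `p = k / B` is reported along
#' with the bias-corrected `(k + 1) / (B + 1)` estimator.
#'
#' @inheritParams loo_cv
#' @param B Number of shuffles (>= 1).
#' @param seed Integer seed for the shuffles.
#' @return List of class `permutation_test`: `k`, `B`, `p`, `p_corrected`,
#'   `observed_accuracy`, `perm_accuracies`, `seed`.
#' @export
permutation_pvalue <- function(x, labels, positive, config = svm_config(),
                               B = 1000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  x <- as.matrix(x)
  lev <- class_levels(labels)
  y <- encode_labels(labels, positive, lev)
  observed <- loo_cv(x, labels, positive, config)
  obs_acc <- observed$metrics$accuracy
  tie <- if (lev[1] == positive) 1L else -1L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  Y <- vapply(seq_len(B), function(b) sample(y), integer(length(y)))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  if (config$scale == "zscore") {
    acc <- apply(Y, 2, function(yb) {
      lb <- ifelse(yb == 1L, positive, setdiff(lev, positive))
      loo_cv(x, factor(lb, levels = lev), positive, config)$metrics$accuracy
    })
  } else {
    K <- tcrossprod(x)
    acc <- .svc_loo_accuracy_many(K, Y, config$cost, tie, eps = config$eps)
  }
  k <- sum(acc >= obs_acc - 1e-12)
  structure(list(k = k, B = B, p = k / B, p_corrected = (k + 1) / (B + 1),
                 observed_accuracy = obs_acc, perm_accuracies = acc,
                 seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed accuracy %.3f, p = %d/%d = %.4f (corrected %.4f)\n",
              x$observed_accuracy, x$k, x$B, x$p, x$p_corrected))
  invisible(x)
}
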