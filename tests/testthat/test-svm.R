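test_that("LOO-CV separates a trivially separable problem", {
  x <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c("control", "control", "survivor", "survivor")
  res <- loo_cv(x, y, positive = "survivor")
  expect_equal(res$metrics$accuracy, 1)
  expect_equal(res$metrics$balanced_accuracy, 1)
  expect_error(loo_cv(x, rep("survivor", 4), positive = "survivor"),
               "two classes")
})

test_that("LOO predictions agree with an independent SVM implementation", {
  set.seed(10)
  n_checked <- 0; n_agree <- 0
  for (rep in 1:12) {
    n <- sample(c(10, 20, 41), 1)
    d <- sample(c(2, 5, 30), 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- rep(c("survivor", "control"), length.out = n)
    if (rep %% 2 == 0) x[y == "survivor", ] <- x[y == "survivor", ] + 0.8
    res <- loo_cv(x, y, positive = "survivor")
    ref <- oracle_loo_e1071(x, y, positive = "survivor")
    n_checked <- n_checked + n
    n_agree <- n_agree + sum(res$predictions == ref)
  }
  # both solvers stop at a small KKT tolerance; samples sitting on the
  # boundary may flip, everything else must agree
  expect_gte(n_agree / n_checked, 0.99)
})

test_that("full-sample weight vector matches the independent solver", {
  set.seed(11)
  for (rep in 1:6) {
    n <- 30; d <- sample(c(3, 12), 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- rep(c("survivor", "control"), each = n / 2)
    x[y == "survivor", ] <- x[y == "survivor", ] + 0.5
    fit <- svm_fit(x, y, positive = "survivor")
    ref <- e1071::svm(x, factor(y, levels = c("survivor", "control")),
                      kernel = "linear", cost = 1, scale = FALSE)
    w_ref <- drop(crossprod(ref$coefs, ref$SV))
    expect_equal(fit$w, w_ref, tolerance = 2e-2, ignore_attr = TRUE)
    expect_equal(fit$b, -ref$rho, tolerance = 2e-2)
  }
})

test_that("LOO-CV is deterministic and invariant to sample order", {
  set.seed(12)
  x <- matrix(rnorm(40 * 4), 40, 4)
  rownames(x) <- sprintf("S%02d", 1:40)
  y <- rep(c("survivor", "control"), 20)
  r1 <- loo_cv(x, y, positive = "survivor")
  r2 <- loo_cv(x, y, positive = "survivor")
  expect_identical(r1$predictions, r2$predictions)
  perm <- sample(40)
  r3 <- loo_cv(x[perm, ], y[perm], positive = "survivor")
  expect_identical(r3$predictions[rownames(x)], r1$predictions)
})

test_that("LOO accuracy is at chance for labels independent of features", {
  set.seed(13)
  accs <- vapply(1:60, function(s) {
    x <- matrix(rnorm(40 * 5), 40, 5)
    y <- rep(c("survivor", "control"), 20)
    loo_cv(x, y, positive = "survivor")$metrics$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)))
})

test_that("classification metrics reproduce their defining identities", {
  # reconstructed confusion counts: 30 of 50 survivors and 27 of 50 controls
  # correct gives accuracy 57%
  labels <- rep(c("survivor", "control"), each = 50)
  preds <- c(rep("survivor", 30), rep("control", 20),
             rep("control", 27), rep("survivor", 23))
  m <- classification_metrics(preds, labels, positive = "survivor")
  expect_equal(m$accuracy, 0.57)
  expect_equal(m$sensitivity, 0.60)
  expect_equal(m$specificity, 0.54)
  expect_equal(m$balanced_accuracy, (0.60 + 0.54) / 2)
  # balanced accuracy and accuracy-reconstruction identities on random draws
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(10:80, 1)
    labels <- sample(c("survivor", "control"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    preds <- sample(c("survivor", "control"), n, replace = TRUE)
    m <- classification_metrics(preds, labels, "survivor")
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    expect_equal(m$accuracy,
                 (m$sensitivity * m$n_pos + m$specificity * m$n_neg) /
                   (m$n_pos + m$n_neg),
                 tolerance = 1e-12)
  }
  # perfect predictions
  m <- classification_metrics(c("a", "b"), c("a", "b"), positive = "a")
  expect_equal(m$accuracy, 1); expect_equal(m$balanced_accuracy, 1)
  # zero-denominator metric is NA with a warning
  expect_warning(m0 <- classification_metrics(c("a", "a"), c("a", "a"), "b"),
                 "no positive")
  expect_true(is.na(m0$sensitivity))
})

test_that("permutation p-value follows the counting rule", {
  # constant features: every shuffle ties the observed accuracy, p = 1
  x <- matrix(1, 8, 2)
  y <- rep(c("survivor", "control"), 4)
  suppressMessages(pt <- permutation_pvalue(x, y, "survivor", B = 50, seed = 1))
  expect_equal(pt$p, 1)
  expect_equal(pt$p_corrected, 1)
  # strong planted effect: 2 pooled-SD separation at n = 40 is detected
  set.seed(15)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c("survivor", "control"), each = 20)
  x[y == "survivor", ] <- x[y == "survivor", ] + 2
  pt <- permutation_pvalue(x, y, "survivor", B = 200, seed = 2)
  expect_lte(pt$p, 0.05)
  expect_equal(pt$p, pt$k / pt$B)
  expect_equal(pt$p_corrected, (pt$k + 1) / (pt$B + 1))
  # invariant to relabeling the classes
  y2 <- ifelse(y == "survivor", "case", "ctrl")
  pt2 <- permutation_pvalue(x, y2, "case", B = 200, seed = 2)
  expect_equal(pt2$k, pt$k)
  expect_error(permutation_pvalue(x, y, "survivor", B = 0), "B must be")
})

test_that("a single-sample class degenerates to a majority-class fold", {
  set.seed(16)
  x <- matrix(rnorm(6 * 2), 6, 2)
  y <- c("survivor", rep("control", 5))
  expect_message(res <- loo_cv(x, y, positive = "survivor"), "single sample")
  # when the lone survivor is held out, training is all-control and the fold
  # must predict control
  expect_equal(unname(res$predictions[1]), "control")
})
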