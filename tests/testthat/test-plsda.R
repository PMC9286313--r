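# Small labeled matrix with two well-separated classes.
separated_classes <- function(n_per = 30, p = 40, gap = 10, seed = 20) {
  withr::with_seed(seed, {
    mu <- rnorm(p)
    delta <- rnorm(p); delta <- gap * delta / sqrt(sum(delta^2))
    X <- rbind(
      matrix(rnorm(n_per * p), n_per) + rep(mu, each = n_per),
      matrix(rnorm(n_per * p), n_per) + rep(mu + delta, each = n_per))
    list(X = X, y = rep(c("a", "b"), each = n_per))
  })
}

test_that("the first latent variable follows the class-covariant channel", {
  withr::with_seed(21, {
    n <- 60
    y <- rep(c("a", "b"), each = n / 2)
    ind <- as.numeric(y == "a")
    X <- matrix(rnorm(n * 20, sd = 0.05), n)
    X[, 7] <- ind + rnorm(n, sd = 0.01)
  })
  m <- fit_plsda(X, n_lv = 1, y = y)
  expect_equal(which.max(abs(m$loadings[, 1])), 7)
  # closed form: first LV weight proportional to cov(columns, indicator)
  Xc <- scale(X, scale = FALSE)
  cv <- as.vector(crossprod(Xc, ind - mean(ind)))
  w <- m$weights[, 1]
  expect_gt(abs(sum(cv * w)) / sqrt(sum(cv^2) * sum(w^2)), 0.9999)
})

test_that("duplicating all rows leaves the model unchanged up to scale conventions", {
  d <- separated_classes(15, 25, gap = 3)
  m1 <- fit_plsda(d$X, n_lv = 2, y = d$y)
  m2 <- fit_plsda(rbind(d$X, d$X), n_lv = 2, y = c(d$y, d$y))
  for (a in 1:2) {
    v1 <- m1$loadings[, a] / sqrt(sum(m1$loadings[, a]^2))
    v2 <- m2$loadings[, a] / sqrt(sum(m2$loadings[, a]^2))
    expect_gt(abs(sum(v1 * v2)), 1 - 1e-8)
  }
  expect_equal(m1$variance_captured, m2$variance_captured, tolerance = 1e-8)
})

test_that("well-separated classes are fit perfectly and errors are raised for bad inputs", {
  d <- separated_classes(30, 40, gap = 10)
  m <- fit_plsda(d$X, n_lv = 3, y = d$y)
  pr <- predict(m, d$X, y_true = d$y)
  expect_equal(pr$report$metrics$sensitivity, c(1, 1))
  expect_error(fit_plsda(d$X, n_lv = 100, y = d$y), "n_lv")
  expect_error(fit_plsda(d$X, n_lv = 2, y = rep("a", 60)), "2 classes")
})

test_that("venetian-blinds folds interleave by dataset order", {
  f <- venetian_blinds(25, 10)
  expect_equal(f, ((seq_len(25) - 1) %% 10) + 1L)
  for (i in 1:25) expect_equal(f[i], ((i - 1) %% 10) + 1)
})

test_that("cross-validation is perfect on separable data and errors when a fold loses a class", {
  d <- separated_classes(30, 40, gap = 10)
  cv <- cross_validate(d$X, n_lv = 2, splits = 10, y = d$y)
  expect_equal(cv$report$metrics$sensitivity, c(1, 1))
  expect_equal(cv$report$metrics$specificity, c(1, 1))
  # with alternating labels and 2 folds, each training half is
  # single-class: the fold check must refuse
  y_bad <- rep(c("a", "b"), 10)
  X_bad <- withr::with_seed(39, matrix(rnorm(20 * 10), 20))
  expect_error(cross_validate(X_bad, n_lv = 1, splits = 2, y = y_bad),
               "lost an entire class")
})

test_that("cross-validated metrics collapse to chance under label permutation", {
  d <- separated_classes(100, 30, gap = 8, seed = 30)
  y_perm <- withr::with_seed(31, sample(d$y))
  cv <- cross_validate(d$X, n_lv = 3, splits = 10, y = y_perm)
  expect_lt(abs(cv$report$metrics$sensitivity[1] - 0.5), 0.1)
  expect_lt(abs(cv$report$metrics$specificity[1] - 0.5), 0.1)
})

test_that("cross-validation is invariant to a consistent channel permutation", {
  d <- separated_classes(20, 30, gap = 2, seed = 32)
  perm <- withr::with_seed(33, sample(30))
  cv1 <- cross_validate(d$X, n_lv = 2, splits = 5, y = d$y)
  cv2 <- cross_validate(d$X[, perm], n_lv = 2, splits = 5, y = d$y)
  expect_identical(cv1$predictions$predicted, cv2$predictions$predicted)
})

test_that("X-variance captured decreases latent variable by latent variable", {
  d <- separated_classes(40, 50, gap = 5, seed = 34)
  m <- fit_plsda(d$X, n_lv = 4, y = d$y)
  expect_true(all(diff(m$variance_captured) <= 1e-8))
})

test_that("Q-residual and Hotelling T2 diagnostics retain inliers and flag gross outliers", {
  d <- separated_classes(50, 30, gap = 6, seed = 35)
  m <- fit_plsda(d$X, n_lv = 2, y = d$y)
  # a sample at the score centroid, inside the LV subspace: Q = 0, T2 = 0
  centroid <- matrix(m$x_mean, 1)
  Xc <- sweep(centroid, 2, m$x_mean)
  Tn <- Xc %*% m$weights
  Q <- rowSums((Xc - Tn %*% t(m$loadings))^2)
  expect_lt(Q, 1e-16)
  expect_lt(sum(Tn^2), 1e-16)

  # limits at infinity retain everything
  m_inf <- m
  m_inf$q_limit <- Inf; m_inf$t2_limit <- Inf
  res <- exclude_outliers(m_inf, d$X, y = d$y)
  expect_true(all(res$mask))

  # a trapping event that is both amplified and off-model in shape is
  # excluded; exclusion demands both statistics, so a purely rescaled
  # spectrum (which the refitted subspace absorbs) is retained
  d2 <- separated_classes(250, 100, gap = 6, seed = 35)
  v <- withr::with_seed(36, rnorm(100)); v <- v / sqrt(sum(v^2))
  X_out <- rbind(d2$X, 3 * d2$X[1, ] + 15 * v)
  y_out <- c(d2$y, "a")
  m2 <- fit_plsda(X_out, n_lv = 2, y = y_out)
  res2 <- exclude_outliers(m2, X_out, y = y_out)
  expect_true(res2$diagnostics$excluded[501])
  expect_lt(mean(res2$diagnostics$excluded), 0.2)
  X_scaled <- rbind(d2$X, 10 * d2$X[1, ])
  m3 <- fit_plsda(X_scaled, n_lv = 2, y = y_out)
  res3 <- exclude_outliers(m3, X_scaled, y = y_out)
  expect_gt(res3$diagnostics$T2[501], m3$t2_limit)
  expect_false(res3$diagnostics$excluded[501])
})

test_that("ROC analysis matches the pair-counting oracle and its analytic limits", {
  # perfectly separating scores
  r <- evraman:::roc_points(c(TRUE, TRUE, FALSE, FALSE), c(9, 8, 2, 1))
  expect_equal(r$auc, 1)
  # 4-point toy set vs the Mann-Whitney pair count
  truth <- c(TRUE, FALSE, TRUE, FALSE)
  score <- c(0.9, 0.8, 0.3, 0.2)
  r2 <- evraman:::roc_points(truth, score)
  pairs <- 0
  for (i in which(truth)) for (j in which(!truth)) {
    pairs <- pairs + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  expect_equal(r2$auc, pairs / (sum(truth) * sum(!truth)))
  # label-independent scores give AUC 1/2 (n = 2000 null simulation)
  withr::with_seed(36, {
    sc <- rnorm(2000)
    lab <- rep(c(TRUE, FALSE), 1000)
  })
  r3 <- evraman:::roc_points(lab, sc)
  expect_lt(abs(r3$auc - 0.5), 0.03)
  # cross-check against an independent ROC implementation
  # (direction pinned: higher scores predict the positive class)
  ref <- suppressMessages(pROC::roc(response = lab, predictor = sc,
                                    levels = c(FALSE, TRUE),
                                    direction = "<"))
  expect_equal(r3$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("roc_curves reports per-class and macro AUC on model indicators", {
  d <- separated_classes(25, 20, gap = 8, seed = 37)
  m <- fit_plsda(d$X, n_lv = 2, y = d$y)
  roc <- roc_curves(m, d$X, y = d$y)
  expect_equal(nrow(roc$auc), 2)
  expect_equal(roc$macro_auc, mean(roc$auc$auc))
  expect_gt(roc$macro_auc, 0.99)
})

test_that("prediction on the training set reproduces the training report", {
  d <- separated_classes(20, 25, gap = 3, seed = 38)
  m <- fit_plsda(d$X, n_lv = 2, y = d$y)
  pr1 <- predict(m, d$X, y_true = d$y)
  pr2 <- predict(m, d$X, y_true = d$y)
  expect_identical(pr1$report$metrics, pr2$report$metrics)
  # a spectrum equal to a class-mean training spectrum lands in that class
  mean_a <- colMeans(d$X[d$y == "a", , drop = FALSE])
  pr3 <- predict(m, matrix(mean_a, 1))
  expect_equal(pr3$predictions$predicted, "a")
  expect_error(predict(m, d$X[, 1:10]), "axis mismatch")
})

test_that("halving the noise never meaningfully degrades cross-validated performance", {
  axis <- wavenumber_axis(256)
  pbs <- generate_pbs_reference(axis, 60, seed = 41)
  curve <- synthetic_response_curve(axis$wavenumber)
  score <- function(snr) {
    profs <- default_class_profiles(snr = snr)
    d <- generate_dataset(sim_config(profs, axis, n_per_class = 60,
                                     seed = 42))
    p <- preprocess_pipeline(d, pbs, curve, pipeline_config())
    cv <- cross_validate(p, n_lv = 3, splits = 10)
    sum(cv$report$metrics[1, c("sensitivity", "specificity")])
  }
  expect_gte(score(120), score(60) - 0.02)
})

test_that("tidy and glance expose pseudospectra and fit summaries", {
  d <- separated_classes(15, 20, gap = 4, seed = 43)
  m <- fit_plsda(d$X, n_lv = 2, y = d$y)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 20)
  expect_named(td, c("lv", "wavenumber", "loading", "variance_captured"))
  gl <- glance(m)
  expect_equal(gl$n, 30)
  expect_equal(gl$n_lv, 2)
})
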