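#' Fit a PLS discriminant analysis model
#'
#' PLS2 regression of mean-centered spectra against mean-centered one-hot
#' class indicators, computed with the SIMPLS algorithm (de Jong 1993).
#' No variance scaling is applied to the channels. Latent-variable (LV)
#' scores condense the spectral variance relevant to class separation;
#' the LV loadings ("pseudospectra") show which wavenumbers drive the
#' classification. Class assignment is by argmax of the predicted
#' indicator variables.
#'
#' @param x A spectra tibble with a `class` metadata column, or a numeric
#'   matrix (rows = spectra) together with `y`.
#' @param n_lv Number of latent variables (default 3, the usual choice
#'   for a two-class EV model; 7 suits an 11-class panel).
#' @param y Class labels; ignored when `x` is a spectra tibble with a
#'   `class` column.
#' @return A `plsda_model` object with elements `weights` (projection
#'   vectors, channels x LV), `loadings` (pseudospectra), `scores`,
#'   `coef`, `x_mean`, `y_mean`, `variance_captured` (% of X variance per
#'   LV), `class_names`, `q_limit`, `t2_limit` (95% reference limits on
#'   the training Q residuals and Hotelling T2).
#' @export
fit_plsda <- function(x, n_lv = 3, y = NULL) {
  d <- plsda_xy(x, y)
  X <- d$X; y <- d$y
  classes <- unique(y)
  if (length(classes) < 2) abort("PLSDA needs at least 2 classes.")
  if (n_lv > min(ncol(X), nrow(X) - 1)) {
    abort("`n_lv` exceeds min(channels, samples - 1).")
  }
  Y <- indicator_matrix(y, classes)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  fit <- simpls(Xc, Yc, n_lv)
  ssx <- sum(Xc^2)
  var_cap <- 100 * colSums(fit$P^2) / ssx
  structure(list(
    n_lv = n_lv, x_mean = x_mean, y_mean = y_mean,
    weights = fit$R, loadings = fit$P, q = fit$Q,
    scores = fit$T, coef = fit$B,
    variance_captured = var_cap,
    class_names = classes, y_train = y, ids = d$ids,
    wavenumber = d$wavenumber,
    score_var = apply(fit$T, 2, stats::var),
    q_limit = q_residual_limit(Xc, fit, conf = 0.95),
    t2_limit = t2_limit(n_lv, nrow(X), conf = 0.95)
  ), class = "plsda_model")
}

# Accept either a spectra tibble (class column) or matrix + labels.
plsda_xy <- function(x, y = NULL, require_y = TRUE) {
  if (is.data.frame(x)) {
    u <- unstack_spectra(x)
    if (is.null(y) && "class" %in% names(u$meta)) y <- u$meta$class
    if (is.null(y) && require_y) abort("no `class` metadata column.")
    list(X = u$X, y = if (is.null(y)) NULL else as.character(y),
         ids = u$ids, wavenumber = u$wavenumber)
  } else {
    if (is.null(y) && require_y) abort("`y` required when `x` is a matrix.")
    if (!is.null(y)) stopifnot(nrow(x) == length(y))
    list(X = x, y = if (is.null(y)) NULL else as.character(y),
         ids = rownames(x) %||% as.character(seq_len(nrow(x))),
         wavenumber = seq_len(ncol(x)))
  }
}

indicator_matrix <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

# SIMPLS (de Jong 1993) on centered X (n x p) and Y (n x c).
simpls <- function(Xc, Yc, A) {
  n <- nrow(Xc); p <- ncol(Xc); cc <- ncol(Yc)
  R <- matrix(0, p, A); Tm <- matrix(0, n, A); P <- matrix(0, p, A)
  Q <- matrix(0, cc, A); V <- matrix(0, p, A)
  S <- crossprod(Xc, Yc)
  for (a in seq_len(A)) {
    q <- svd(S, nu = 0, nv = 1)$v[, 1]
    r <- S %*% q
    t <- Xc %*% r
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) abort("degenerate latent variable (zero score norm).")
    t <- t / nt; r <- r / nt
    pv <- crossprod(Xc, t)
    qv <- crossprod(Yc, t)
    v <- pv
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Tm[, a] <- t; P[, a] <- pv; Q[, a] <- qv; V[, a] <- v
  }
  list(R = R, T = Tm, P = P, Q = Q, B = R %*% t(Q))
}

# Jackson-Mudholkar upper control limit for Q residuals, with an
# empirical-quantile fallback when the moment approximation degenerates.
q_residual_limit <- function(Xc, fit, conf = 0.95) {
  E <- Xc - fit$T %*% t(fit$P)
  q_train <- rowSums(E^2)
  ev <- svd(E, nu = 0, nv = 0)$d^2 / max(1, nrow(Xc) - 1)
  ev <- ev[ev > 1e-12 * max(ev, 1e-300)]
  if (length(ev) < 2) return(max(q_train) * 1.0001)
  th1 <- sum(ev); th2 <- sum(ev^2); th3 <- sum(ev^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  ca <- qnorm(conf)
  if (!is.finite(h0) || h0 <= 0) {
    return(as.numeric(quantile(q_train, conf)))
  }
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
           th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

t2_limit <- function(A, n, conf = 0.95) {
  A * (n - 1) / (n - A) * qf(conf, A, n - A)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("PLSDA model:", length(x$class_names), "classes,",
      x$n_lv, "latent variables\n")
  cat("X variance captured per LV (%):",
      paste(sprintf("%.2f", x$variance_captured), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a PLSDA model: LV pseudospectra
#'
#' @param x A `plsda_model`.
#' @param ... Unused.
#' @return A tibble with columns `lv`, `wavenumber`, `loading`,
#'   `variance_captured`.
#' @export
tidy.plsda_model <- function(x, ...) {
  p <- length(x$wavenumber)
  tibble(
    lv = rep(seq_len(x$n_lv), each = p),
    wavenumber = rep(x$wavenumber, times = x$n_lv),
    loading = as.vector(x$loadings),
    variance_captured = rep(x$variance_captured, each = p)
  )
}

#' One-line model summary
#'
#' @param x A `plsda_model`.
#' @param ... Unused.
#' @return A one-row tibble: sample count, class count, LV count, total X
#'   variance captured.
#' @export
glance.plsda_model <- function(x, ...) {
  tibble(n = nrow(x$scores), n_classes = length(x$class_names),
         n_lv = x$n_lv,
         x_variance_captured = sum(x$variance_captured))
}

#' Predict classes for new spectra
#'
#' Projects new spectra through the model and assigns the class with the
#' largest predicted indicator. When true labels are supplied, a
#' per-class sensitivity/specificity report is attached.
#'
#' @param object A `plsda_model`.
#' @param newdata A spectra tibble or numeric matrix on the training axis.
#' @param y_true Optional true class labels.
#' @param ... Unused.
#' @return A `plsda_prediction`: list with `predictions` (tibble: id,
#'   predicted class, continuous indicator per class, scores) and, when
#'   labels were given, `report` (see [classification_report()]).
#' @export
predict.plsda_model <- function(object, newdata, y_true = NULL, ...) {
  d <- plsda_xy(newdata, y = y_true, require_y = FALSE)
  if (ncol(d$X) != length(object$x_mean)) {
    abort("axis mismatch: new spectra are not on the training axis.")
  }
  Xc <- sweep(d$X, 2, object$x_mean)
  Yhat <- sweep(Xc %*% object$coef, 2, object$y_mean, "+")
  scores <- Xc %*% object$weights
  pred <- object$class_names[max.col(Yhat, ties.method = "first")]
  preds <- tibble(id = d$ids, predicted = pred)
  colnames(Yhat) <- paste0("ind_", object$class_names)
  preds <- dplyr::bind_cols(preds, as_tibble(Yhat))
  colnames(scores) <- paste0("lv", seq_len(object$n_lv))
  preds <- dplyr::bind_cols(preds, as_tibble(scores))
  out <- list(predictions = preds, class_names = object$class_names)
  if (!is.null(d$y)) {
    out$report <- classification_report(d$y, pred, object$class_names)
  }
  structure(out, class = "plsda_prediction")
}

#' Per-class classification report
#'
#' One-vs-rest sensitivity `TP / (TP + FN)` and specificity
#' `TN / (TN + FP)` for each class, plus the confusion matrix.
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param classes Class set (defaults to the union of labels).
#' @return A `classification_report`: list with `metrics` (tibble: class,
#'   sensitivity, specificity, n) and `confusion` (truth x predicted
#'   table).
#' @export
classification_report <- function(truth, predicted,
                                  classes = sort(unique(c(truth, predicted)))) {
  truth <- factor(truth, levels = classes)
  predicted <- factor(predicted, levels = classes)
  conf <- table(truth = truth, predicted = predicted)
  metrics <- dplyr::bind_rows(lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- sum(truth != cl & predicted != cl)
    fp <- sum(truth != cl & predicted == cl)
    tibble(class = cl,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
           n = tp + fn)
  }))
  structure(list(metrics = metrics, confusion = conf),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}

#' Venetian-blinds fold assignment
#'
#' Sample `i` (in dataset order) is held out in fold `((i - 1) mod
#' splits) + 1`: the standard interleaved ("venetian blinds") scheme.
#'
#' @param n Number of samples.
#' @param splits Number of folds.
#' @return Integer fold index per sample.
#' @export
venetian_blinds <- function(n, splits = 10) {
  stopifnot(splits >= 2)
  ((seq_len(n) - 1) %% splits) + 1L
}

#' Cross-validate a PLSDA model with venetian blinds
#'
#' Refits the model with each interleaved fold held out and pools the
#' held-out predictions into a single cross-validated per-class
#' sensitivity/specificity report.
#'
#' @param x A spectra tibble with a `class` column, or a matrix.
#' @param n_lv Number of latent variables.
#' @param splits Number of venetian-blinds folds (default 10).
#' @param y Labels when `x` is a matrix.
#' @param shuffle_seed Optional seed for a seeded pre-shuffle of sample
#'   order before fold assignment; by default dataset order is used as
#'   given.
#' @return A `plsda_cv`: list with `report` ([classification_report()]),
#'   `predictions` (pooled held-out tibble: id, truth, predicted, fold),
#'   `folds`, `n_lv`, `splits`.
#' @export
cross_validate <- function(x, n_lv = 3, splits = 10, y = NULL,
                           shuffle_seed = NULL) {
  d <- plsda_xy(x, y)
  n <- nrow(d$X)
  ord <- seq_len(n)
  if (!is.null(shuffle_seed)) {
    ord <- withr::with_seed(as.integer(shuffle_seed), sample.int(n))
  }
  folds <- integer(n)
  folds[ord] <- venetian_blinds(n, splits)
  tab <- table(d$y)
  if (any(tab < splits)) {
    abort("every class needs at least `splits` members for venetian blinds.")
  }
  pred <- character(n)
  for (k in seq_len(splits)) {
    tr <- folds != k
    if (length(unique(d$y[tr])) < length(unique(d$y))) {
      abort(paste0("fold ", k, " training set lost an entire class; ",
                   "reorder samples or use fewer splits."))
    }
    m <- fit_plsda(d$X[tr, , drop = FALSE], n_lv = n_lv, y = d$y[tr])
    pr <- predict(m, d$X[!tr, , drop = FALSE])
    pred[!tr] <- pr$predictions$predicted
  }
  structure(list(
    report = classification_report(d$y, pred, unique(d$y)),
    predictions = tibble(id = d$ids, truth = d$y, predicted = pred,
                         fold = folds),
    folds = folds, n_lv = n_lv, splits = splits
  ), class = "plsda_cv")
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat("PLSDA venetian-blinds cross-validation (", x$splits, " splits, ",
      x$n_lv, " LVs)\n", sep = "")
  print(x$report$metrics)
  invisible(x)
}

#' Q-residual / Hotelling T2 outlier diagnostics and exclusion
#'
#' For every sample, Q is the squared residual off the latent-variable
#' subspace and T2 the Mahalanobis-type leverage within it (sum over LVs
#' of score^2 / score variance). A sample is excluded only when both
#' statistics exceed their 95% reference limits — the conservative rule
#' that removes the small fraction of trapping events that are neither
#' described by the model subspace nor close to the score centroid. The
#' model is refit on the survivors.
#'
#' @param model A `plsda_model`.
#' @param x The spectra (tibble or matrix) the model was fit on.
#' @param y Labels when `x` is a matrix.
#' @return A list: `diagnostics` (tibble: id, Q, T2, excluded), `mask`
#'   (logical keep vector), `model` (refit on survivors; the original
#'   model if nothing was excluded).
#' @export
exclude_outliers <- function(model, x, y = NULL) {
  d <- plsda_xy(x, y)
  Xc <- sweep(d$X, 2, model$x_mean)
  Tn <- Xc %*% model$weights
  E <- Xc - Tn %*% t(model$loadings)
  Q <- rowSums(E^2)
  T2 <- rowSums(sweep(Tn^2, 2, model$score_var, "/"))
  excluded <- Q > model$q_limit & T2 > model$t2_limit
  if (mean(excluded) > 0.2) {
    warn(paste0(sprintf("%.1f", 100 * mean(excluded)),
                "% of samples excluded; model may be unstable."))
  }
  refit <- model
  if (any(excluded)) {
    refit <- fit_plsda(d$X[!excluded, , drop = FALSE], n_lv = model$n_lv,
                       y = d$y[!excluded])
  }
  list(diagnostics = tibble(id = d$ids, Q = Q, T2 = T2,
                            excluded = excluded),
       mask = !excluded, model = refit)
}

#' One-vs-rest ROC curves and AUC
#'
#' Builds a ROC curve per class from the continuous predicted indicator
#' variables and integrates the area under each by the trapezoid rule;
#' the macro-average AUC is reported alongside.
#'
#' @param model A `plsda_model`.
#' @param x Labeled spectra (tibble with `class`, or matrix with `y`).
#' @param y Labels when `x` is a matrix.
#' @return A list: `curves` (tibble: class, fpr, tpr), `auc` (tibble:
#'   class, auc), `macro_auc`.
#' @export
roc_curves <- function(model, x, y = NULL) {
  d <- plsda_xy(x, y)
  pr <- predict(model, d$X)
  curves <- list(); aucs <- list()
  for (cl in model$class_names) {
    if (!cl %in% d$y) {
      inform(paste0("class `", cl, "` absent from labels; skipped."))
      next
    }
    sc <- pr$predictions[[paste0("ind_", cl)]]
    r <- roc_points(d$y == cl, sc)
    curves[[cl]] <- tibble(class = cl, fpr = r$fpr, tpr = r$tpr)
    aucs[[cl]] <- tibble(class = cl, auc = r$auc)
  }
  auc <- dplyr::bind_rows(aucs)
  list(curves = dplyr::bind_rows(curves), auc = auc,
       macro_auc = mean(auc$auc))
}

# ROC from binary truth + continuous score; AUC by trapezoid.
roc_points <- function(is_pos, score) {
  o <- order(score, decreasing = TRUE)
  pos <- is_pos[o]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  # collapse ties on score
  keep <- c(diff(score[o]) != 0, TRUE)
  tpr <- c(0, tp[keep] / sum(is_pos))
  fpr <- c(0, fp[keep] / sum(!is_pos))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Tidy a cross-validation result: per-class metrics
#'
#' @param x A `plsda_cv`.
#' @param ... Unused.
#' @return The per-class sensitivity/specificity tibble.
#' @export
tidy.plsda_cv <- function(x, ...) {
  x$report$metrics
}

#' One-line cross-validation summary
#'
#' @param x A `plsda_cv`.
#' @param ... Unused.
#' @return A one-row tibble: folds, LVs, mean sensitivity/specificity.
#' @export
glance.plsda_cv <- function(x, ...) {
  tibble(splits = x$splits, n_lv = x$n_lv,
         mean_sensitivity = mean(x$report$metrics$sensitivity),
         mean_specificity = mean(x$report$metrics$specificity))
}

#' Plot the latent-variable pseudospectra of a PLSDA model
#'
#' @param object A `plsda_model`.
#' @param ... Unused.
#' @return A ggplot of loadings against wavenumber, faceted by LV.
#' @export
autoplot.plsda_model <- function(object, ...) {
  df <- tidy.plsda_model(object)
  df$lv <- sprintf("LV%d (%.1f%%)", df$lv, df$variance_captured)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$loading)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~lv, ncol = 1) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "loading") +
    ggplot2::theme_minimal()
}

#' Score plot for a fitted PLSDA model
#'
#' @param model A `plsda_model`.
#' @param lv Two latent variables to plot.
#' @return A ggplot scatter of training scores colored by class.
#' @export
plot_scores <- function(model, lv = c(1, 2)) {
  df <- tibble(x = model$scores[, lv[1]], y = model$scores[, lv[2]],
               class = model$y_train)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = paste0("LV", lv[1], " (",
                             sprintf("%.1f", model$variance_captured[lv[1]]),
                             "%)"),
                  y = paste0("LV", lv[2], " (",
                             sprintf("%.1f", model$variance_captured[lv[2]]),
                             "%)")) +
    ggplot2::theme_minimal()
}
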