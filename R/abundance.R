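#' Normalize spectra to unit Euclidean length
#'
#' Both the EV mixture spectra and the recovered pure component spectra
#' are vector-normalized before convex-mixing abundance estimation, so
#' weights reflect spectral shape rather than absolute intensity.
#'
#' @param x A spectra tibble.
#' @return The unit-normalized spectra tibble.
#' @export
unit_normalize <- function(x) {
  map_spectra(x, function(y, wn) {
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) abort("cannot unit-normalize an all-zero spectrum.")
    y / nrm
  })
}

#' Non-negative least squares with an exact sum-to-one constraint
#'
#' Solves `min || s - C w ||^2` subject to `w >= 0` and `sum(w) = 1`.
#' A moderately weighted augmented row gives a warm start (a large
#' weight would swamp the NNLS solver's norm-scaled tolerance); the
#' active set is then polished by the exact equality-constrained KKT
#' solve, dropping any component that turns negative.
#'
#' @param C Component matrix (channels x m).
#' @param s Spectrum vector.
#' @param gamma Weight of the sum-to-one augmented row in the warm
#'   start.
#' @return The weight vector (length m), exactly on the simplex.
#' @export
nnls_sum_to_one <- function(C, s, gamma = 100) {
  w <- pracma::lsqnonneg(rbind(C, gamma), c(s, gamma))$x
  active <- w > 1e-10
  if (!any(active)) active <- rep(TRUE, ncol(C))
  repeat {
    Ca <- C[, active, drop = FALSE]
    m <- sum(active)
    M <- rbind(cbind(crossprod(Ca), rep(1, m)), c(rep(1, m), 0))
    sol <- solve(M, c(crossprod(Ca, s), 1))
    wa <- sol[seq_len(m)]
    if (all(wa >= -1e-12) || m == 1) {
      w[] <- 0
      w[active] <- pmax(wa, 0)
      w <- w / sum(w)
      break
    }
    idx <- which(active)
    active[idx[which.min(wa)]] <- FALSE
  }
  w
}

#' Convex-mixing abundance estimation
#'
#' Estimates non-negative, sum-to-one component weights for every
#' spectrum by least squares against the unit-normalized component
#' spectra (columns of `C`). Two formulations are available:
#'
#' * `scale = "free"` (default): minimizes `|| s - beta * C w ||^2` over
#'   the simplex with a free intensity scale `beta`, computed as plain
#'   non-negative least squares followed by normalization of the weights
#'   to unit sum. Because the Euclidean norm of a convex mixture depends
#'   on its composition, unit-length normalization of `s` leaves exactly
#'   such a residual scale factor; the free-scale fit is therefore exact
#'   on noise-free convex mixtures of the components.
#' * `scale = "fixed"`: the strict constrained problem
#'   `min || s - C w ||^2` s.t. `w >= 0`, `sum(w) = 1` at fixed scale
#'   (see [nnls_sum_to_one()]).
#'
#' @param x A spectra tibble (EV spectra, BTEM-branch preprocessed).
#' @param components A named list of `pure_component` objects, or a
#'   numeric matrix with one column per component (channels x m) on the
#'   same axis as `x`.
#' @param scale `"free"` or `"fixed"` (see above).
#' @return A tibble with one row per spectrum: `id`, any `class`/`batch`
#'   metadata, one weight column per component, and `residual_norm` (the
#'   Euclidean misfit on unit-length spectra, at the fitted scale).
#'   Weights are non-negative and sum to 1 within 1e-8.
#' @export
fit_abundances <- function(x, components, scale = c("free", "fixed")) {
  scale <- match.arg(scale)
  u <- unstack_spectra(unit_normalize(x))
  if (is.list(components) && !is.matrix(components)) {
    nm <- vapply(components, function(cp) cp$name, "")
    C <- vapply(components, function(cp) {
      if (length(cp$spectrum$intensity) != length(u$wavenumber)) {
        abort("component and spectra axes differ in length.")
      }
      cp$spectrum$intensity
    }, numeric(length(u$wavenumber)))
    colnames(C) <- nm
  } else {
    C <- as.matrix(components)
    if (is.null(colnames(C))) {
      colnames(C) <- paste0("component_", seq_len(ncol(C)))
    }
  }
  if (ncol(C) < 2) abort("at least 2 components are required.")
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  if (qr(C)$rank < ncol(C)) {
    warn("component matrix is rank deficient; abundances are not unique.")
  }
  W <- t(apply(u$X, 1, function(s) {
    if (scale == "free") {
      u_raw <- pracma::lsqnonneg(C, s)$x
      if (sum(u_raw) <= 0) abort("NNLS returned an all-zero fit.")
      w <- u_raw / sum(u_raw)
      c(w, sqrt(sum((s - C %*% u_raw)^2)))
    } else {
      w <- nnls_sum_to_one(C, s)
      c(w, sqrt(sum((s - C %*% w)^2)))
    }
  }))
  colnames(W) <- c(paste0("w_", colnames(C)), "residual_norm")
  keep <- intersect(c("id", "class", "batch"), names(u$meta))
  dplyr::bind_cols(u$meta[, keep, drop = FALSE], as_tibble(W))
}

#' Summarize per-EV compositions by class
#'
#' Class-level summaries of the convex-mixing weights: per-class mean
#' composition (pie-chart data; each class mean sums to 1) and the
#' distribution of each component (median, quartiles, and 1.5 x IQR
#' whiskers, matching violin/box-style presentation).
#'
#' @param profiles Abundance tibble from [fit_abundances()].
#' @param labels Optional class labels (defaults to the `class` column).
#' @return A `composition_summary`: list with `means` (class x component
#'   mean weights, long tibble), `distributions` (class x component
#'   median/quartiles/whiskers), and `profiles` (the labeled input).
#' @export
summarize_composition <- function(profiles, labels = NULL) {
  if (!is.null(labels)) profiles$class <- labels
  if (!"class" %in% names(profiles)) abort("profiles must carry class labels.")
  wcols <- grep("^w_", names(profiles), value = TRUE)
  empty <- setdiff(unique(profiles$class),
                   unique(profiles$class[stats::complete.cases(profiles[wcols])]))
  if (length(empty) > 0) {
    inform(paste0("class(es) without complete profiles skipped: ",
                  paste(empty, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(profiles, dplyr::all_of(wcols),
                              names_to = "component", values_to = "weight")
  long$component <- sub("^w_", "", long$component)
  means <- long |>
    dplyr::group_by(.data$class, .data$component) |>
    dplyr::summarise(mean_weight = mean(.data$weight), .groups = "drop")
  dists <- long |>
    dplyr::group_by(.data$class, .data$component) |>
    dplyr::summarise(
      median = median(.data$weight),
      q25 = quantile(.data$weight, 0.25),
      q75 = quantile(.data$weight, 0.75),
      .groups = "drop") |>
    dplyr::mutate(iqr = .data$q75 - .data$q25,
                  whisker_lo = .data$q25 - 1.5 * .data$iqr,
                  whisker_hi = .data$q75 + 1.5 * .data$iqr)
  structure(list(means = means, distributions = dists,
                 profiles = profiles),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Per-class mean composition:\n")
  print(tidyr::pivot_wider(x$means, names_from = "component",
                           values_from = "mean_weight"))
  invisible(x)
}

#' Pie charts of per-class mean composition
#'
#' @param summary A `composition_summary`.
#' @return A ggplot with one pie per class.
#' @export
plot_composition_pies <- function(summary) {
  ggplot2::ggplot(summary$means,
                  ggplot2::aes(x = "", y = .data$mean_weight,
                               fill = .data$component)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = NULL, y = NULL, fill = "component") +
    ggplot2::theme_void()
}

#' Violin plots of per-EV component weights by class
#'
#' The median is marked with a white point, in the conventional
#' violin-plot presentation of compositional distributions.
#'
#' @param summary A `composition_summary`.
#' @return A ggplot faceted by component.
#' @export
plot_composition_violins <- function(summary) {
  wcols <- grep("^w_", names(summary$profiles), value = TRUE)
  long <- tidyr::pivot_longer(summary$profiles, dplyr::all_of(wcols),
                              names_to = "component", values_to = "weight")
  long$component <- sub("^w_", "", long$component)
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$weight,
                                     fill = .data$class)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::stat_summary(fun = median, geom = "point", colour = "white",
                          size = 2) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative abundance") +
    ggplot2::theme_minimal()
}
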