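#' Asymmetric least-squares Whittaker baseline for one signal
#'
#' Estimates a smooth baseline z minimizing
#' `sum(w_i (y_i - z_i)^2) + lambda * sum((diff(z, differences = 2))^2)`
#' with asymmetric weights `w_i = p` where `y_i > z_i` and `1 - p`
#' otherwise, iterated until the weight assignment stabilizes. Small `p`
#' lets peaks stand above the baseline while the baseline hugs the signal
#' from below.
#'
#' @param y Numeric signal (counts).
#' @param lambda Smoothing weight (> 0); larger values give a stiffer
#'   baseline whose curvature tends to zero.
#' @param p Asymmetry parameter in (0, 1).
#' @param max_iter Maximum weight iterations.
#' @param tol Convergence tolerance on the mean absolute weight change.
#' @param penalty Optional precomputed `lambda * t(D) %*% D` penalty
#'   matrix, to share across many signals of the same length.
#' @return The baseline vector `z` with attribute `"iterations"`.
#' @export
whittaker_asls <- function(y, lambda = 1e4, p = 1e-4, max_iter = 50,
                           tol = 1e-6, penalty = NULL) {
  stopifnot(lambda > 0, p > 0, p < 1)
  n <- length(y)
  if (n < 3) abort("signal too short for a second-difference penalty.")
  P <- penalty
  if (is.null(P)) {
    D <- Matrix::diff(Matrix::Diagonal(n), differences = 2)
    P <- lambda * Matrix::crossprod(D)
  }
  w <- rep(1, n)
  z <- y
  tie <- 1e-10 * pmax(abs(y), 1)  # ties go below: avoids weight flip-flop
  for (it in seq_len(max_iter)) {
    z <- as.vector(Matrix::solve(Matrix::Diagonal(x = w) + P, w * y))
    w_new <- ifelse(y - z > tie, p, 1 - p)
    delta <- mean(abs(w_new - w))
    w <- w_new
    if (delta < tol) {
      attr(z, "iterations") <- it
      return(z)
    }
  }
  abort(paste0("Whittaker baseline did not converge after ", max_iter,
               " iterations."))
}

#' Whittaker baseline subtraction for a spectra tibble
#'
#' Applies [whittaker_asls()] to every spectrum and subtracts the
#' estimated baseline. The corrected intensities are returned unclipped;
#' the per-spectrum baselines are attached as attribute `"baseline"`
#' (a spectra tibble of the same shape).
#'
#' @param x A spectra tibble.
#' @param lambda,p,max_iter,tol See [whittaker_asls()].
#' @return The baseline-corrected spectra tibble.
#' @export
whittaker_baseline <- function(x, lambda = 1e4, p = 1e-4, max_iter = 50,
                               tol = 1e-6) {
  u <- unstack_spectra(x)
  n <- ncol(u$X)
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2)
  P <- lambda * Matrix::crossprod(D)
  Z <- t(apply(u$X, 1, whittaker_asls, lambda = lambda, p = p,
               max_iter = max_iter, tol = tol, penalty = P))
  ub <- u
  ub$X <- Z
  u$X <- u$X - Z
  out <- restack_spectra(u)
  attr(out, "baseline") <- restack_spectra(ub)
  out
}
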