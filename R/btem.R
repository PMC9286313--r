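#' Singular value decomposition basis of a spectra ensemble
#'
#' Right singular vectors of the (uncentered) spectra matrix, ordered by
#' singular value, form the loading-vector basis in which band-target
#' entropy minimization searches for pure component spectra. Signs are
#' fixed so the largest-magnitude element of each vector is positive,
#' making the decomposition reproducible.
#'
#' @param x A spectra tibble or numeric matrix (rows = spectra),
#'   typically after the BTEM-branch preprocessing (pooled classes,
#'   Whittaker baseline with lambda 1e4, p 1e-4).
#' @param k_max Number of loading vectors to retain (default 25; 10
#'   suffice for lipid and protein recovery, 25 for nucleic acids).
#' @param wavenumber Wavenumber axis for matrix input (taken from the
#'   tibble otherwise; defaults to the channel index).
#' @return A `btem_basis`: list with `v` (channels x k loading vectors),
#'   `d` (singular values), `wavenumber`, `k_max`.
#' @export
btem_decompose <- function(x, k_max = 25, wavenumber = NULL) {
  if (is.data.frame(x)) {
    u <- unstack_spectra(x)
    X <- u$X; wn <- u$wavenumber
  } else {
    X <- x; wn <- wavenumber %||% seq_len(ncol(x))
  }
  r <- min(dim(X))
  if (k_max > r) {
    inform(paste0("k_max = ", k_max, " exceeds the matrix rank bound ", r,
                  "; truncated."))
    k_max <- r
  }
  s <- svd(X, nu = 0, nv = k_max)
  v <- s$v
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  structure(list(v = v, d = s$d, wavenumber = wn, k_max = k_max),
            class = "btem_basis")
}

#' Band target window
#'
#' @param name Component name.
#' @param window `c(lo, hi)` wavenumber window (cm^-1) inside which the
#'   recovered spectrum must attain its global maximum.
#' @param k Number of loading vectors used for this target.
#' @return A `band_target` list.
#' @export
band_target <- function(name, window, k = 10) {
  stopifnot(length(window) == 2, window[1] < window[2], k >= 1)
  structure(list(name = name, window = window, k = k),
            class = "band_target")
}

#' Default band targets for the four EV biomolecular components
#'
#' Windows around the characteristic bands: phenylalanine 1004 cm^-1
#' (protein), the DNA ring-breathing mode at 723 cm^-1 (nucleic acid,
#' recovered with 25 loading vectors), the CH2 bend at 1442 cm^-1
#' (phosphatidylcholine-like) and the 989 cm^-1 band
#' (sphingomyelin-like).
#'
#' @param k Loading vectors for the lipid/protein targets.
#' @param k_nucleic_acid Loading vectors for the nucleic-acid target.
#' @return A named list of [band_target()] objects.
#' @export
default_band_targets <- function(k = 10, k_nucleic_acid = 25) {
  list(
    protein = band_target("protein", c(994, 1014), k),
    nucleic_acid = band_target("nucleic_acid", c(713, 733), k_nucleic_acid),
    phosphatidylcholine_like =
      band_target("phosphatidylcholine_like", c(1427, 1457), k),
    sphingomyelin_like =
      band_target("sphingomyelin_like", c(979, 999), k)
  )
}

#' BTEM entropy objective
#'
#' For rotation coefficients `t`, the candidate spectrum is the linear
#' combination of the first `k` loading vectors, rescaled so its maximum
#' inside the band-target window equals 1 (which makes the objective
#' invariant to the scale of `t`). The objective is the Shannon entropy
#' of the normalized absolute first derivative — low when the spectrum
#' consists of few, simple bands — plus a quadratic penalty on negative
#' intensities and a large constant penalty if the global maximum falls
#' outside the target window.
#'
#' @param t Rotation coefficient vector (length `k`).
#' @param basis A `btem_basis`.
#' @param target A [band_target()].
#' @param penalty_weight Weight of the negativity penalty.
#' @param window_penalty Constant added when the global maximum escapes
#'   the window (or the candidate is non-positive there).
#' @return The scalar objective value.
#' @export
entropy_objective <- function(t, basis, target, penalty_weight = 3,
                              window_penalty = 1e6) {
  k <- length(t)
  s <- as.vector(basis$v[, seq_len(k), drop = FALSE] %*% t)
  win <- basis$wavenumber >= target$window[1] &
    basis$wavenumber <= target$window[2]
  if (!any(win)) abort("band-target window lies outside the data range.")
  m <- max(s[win])
  if (!is.finite(m) || m <= 0) return(window_penalty)
  s <- s / m
  pen <- if (max(s) > 1 + 1e-12) window_penalty else 0
  dh <- abs(diff(s))
  tot <- sum(dh)
  if (tot == 0) return(pen + penalty_weight * sum(pmin(s, 0)^2))
  h <- dh / tot
  h <- h[h > 0]
  -sum(h * log(h)) + penalty_weight * sum(pmin(s, 0)^2) + pen
}

#' Simulated-annealing schedule for BTEM
#'
#' The default effort scales with the rotation dimension `k`: searching
#' 25 loading vectors needs substantially more proposals than 10 to
#' reach comparable convergence. `NULL` entries are resolved per target
#' as `epochs = max(200, 20 k)`, `moves = max(50, 4 k)`,
#' `polish_iter = 200 k`.
#'
#' @param epochs Number of cooling epochs (`NULL` = scale with k).
#' @param moves Proposals per epoch (`NULL` = scale with k).
#' @param cooling Geometric temperature factor per epoch.
#' @param init_draws Random draws used to set the initial temperature
#'   from the spread of the objective (the best draw also seeds the
#'   annealing state).
#' @param step0 Initial Gaussian proposal standard deviation (annealed
#'   with the square root of the relative temperature).
#' @param polish_iter Nelder-Mead iterations refining the best state of
#'   each annealing run (`NULL` = scale with k).
#' @return A list of schedule parameters.
#' @export
sa_config <- function(epochs = NULL, moves = NULL, cooling = 0.95,
                      init_draws = 50, step0 = 0.5, polish_iter = NULL) {
  list(epochs = epochs, moves = moves, cooling = cooling,
       init_draws = init_draws, step0 = step0, polish_iter = polish_iter)
}

# Resolve k-dependent schedule defaults.
sa_resolve <- function(control, k) {
  control$epochs <- control$epochs %||% max(200, 20 * k)
  control$moves <- control$moves %||% max(50, 4 * k)
  control$polish_iter <- control$polish_iter %||% (200 * k)
  control
}

# One seeded simulated-annealing run over rotation coefficients:
# pseudorandom initialization at the best of the temperature-calibration
# draws, exponential cooling, Gaussian proposals annealed with the
# temperature, and a derivative-free simplex polish of the best state.
sa_run <- function(objective, k, seed, control) {
  withr::with_seed(as.integer(seed), {
    draws <- lapply(seq_len(control$init_draws), function(i) rnorm(k))
    es <- vapply(draws, objective, numeric(1))
    temp0 <- max(sd(es), 1e-3)
    temp <- temp0
    t_cur <- draws[[which.min(es)]]
    e_cur <- min(es)
    t_best <- t_cur; e_best <- e_cur
    for (ep in seq_len(control$epochs)) {
      step <- max(0.02, control$step0 * sqrt(temp / temp0))
      for (mv in seq_len(control$moves)) {
        t_new <- t_cur + rnorm(k, sd = step)
        e_new <- objective(t_new)
        if (e_new < e_cur || runif(1) < exp((e_cur - e_new) / temp)) {
          t_cur <- t_new; e_cur <- e_new
          if (e_new < e_best) { t_best <- t_new; e_best <- e_new }
        }
      }
      temp <- temp * control$cooling
    }
    if (k > 1) {  # at k = 1 the objective depends only on sign(t)
      polish <- stats::optim(t_best, objective, method = "Nelder-Mead",
                             control = list(maxit = control$polish_iter,
                                            reltol = 1e-10))
      if (polish$value < e_best) {
        t_best <- polish$par
        e_best <- polish$value
      }
    }
    list(t = t_best, objective = e_best)
  })
}

#' Recover one pure component spectrum by band-target entropy minimization
#'
#' Runs `n_restarts` independently seeded simulated-annealing searches
#' over the rotation coefficients (pseudorandom initialization) and
#' reports the run with the lowest entropy objective. The returned
#' spectrum is clipped at zero and normalized to unit length.
#'
#' @param basis A `btem_basis` (computed with at least the target's `k`
#'   loading vectors).
#' @param target A [band_target()].
#' @param seed Master seed; restart seeds are derived from it.
#' @param n_restarts Number of simulated-annealing restarts (default 10).
#' @param control A [sa_config()].
#' @param penalty_weight Negativity penalty weight.
#' @return A `pure_component`: list with `name`, `spectrum` (tibble:
#'   `wavenumber`, `intensity`; unit norm), `entropy` (best objective),
#'   `coefficients`, `k`, and `restarts` (tibble of per-restart seeds and
#'   objectives).
#' @export
recover_component <- function(basis, target, seed = 1, n_restarts = 10,
                              control = sa_config(), penalty_weight = 3) {
  k <- target$k
  if (k > ncol(basis$v)) {
    abort(paste0("target `", target$name, "` needs k = ", k,
                 " loading vectors; basis has ", ncol(basis$v), "."))
  }
  control <- sa_resolve(control, k)
  obj <- function(t) entropy_objective(t, basis, target, penalty_weight)
  runs <- lapply(seq_len(n_restarts), function(r) {
    s <- derive_seed(seed, paste0("btem_", target$name), r)
    c(sa_run(obj, k, s, control), list(seed = s, restart = r))
  })
  objs <- vapply(runs, function(r) r$objective, 0)
  best <- runs[[which.min(objs)]]
  s <- as.vector(basis$v[, seq_len(k), drop = FALSE] %*% best$t)
  win <- basis$wavenumber >= target$window[1] &
    basis$wavenumber <= target$window[2]
  if (max(s[win]) <= 0 || which.max(s) != which(win)[which.max(s[win])]) {
    abort(paste0("no restart satisfied the band-target maximum constraint ",
                 "for `", target$name, "`."))
  }
  s <- pmax(s, 0)
  s <- s / sqrt(sum(s^2))
  structure(list(
    name = target$name,
    spectrum = tibble(wavenumber = basis$wavenumber, intensity = s),
    entropy = best$objective,
    coefficients = best$t,
    k = k,
    restarts = tibble(restart = seq_len(n_restarts),
                      seed = vapply(runs, function(r) r$seed, 0L),
                      objective = objs)
  ), class = "pure_component")
}

#' Recover several pure components
#'
#' Convenience wrapper running [recover_component()] for every target in
#' a list (e.g. [default_band_targets()]).
#'
#' @param x Preprocessed pooled spectra (tibble or matrix).
#' @param targets List of [band_target()] objects.
#' @param seed Master seed.
#' @param n_restarts,control,penalty_weight See [recover_component()].
#' @return A named list of `pure_component` objects.
#' @export
recover_components <- function(x, targets = default_band_targets(),
                               seed = 1, n_restarts = 10,
                               control = sa_config(), penalty_weight = 3) {
  k_max <- max(vapply(targets, function(t) t$k, 0))
  basis <- btem_decompose(x, k_max = k_max)
  out <- lapply(targets, function(tg) {
    recover_component(basis, tg, seed = seed, n_restarts = n_restarts,
                      control = control, penalty_weight = penalty_weight)
  })
  names(out) <- vapply(targets, function(t) t$name, "")
  out
}

#' @export
print.pure_component <- function(x, ...) {
  cat("BTEM pure component `", x$name, "`: k = ", x$k,
      ", entropy = ", sprintf("%.4f", x$entropy), "\n", sep = "")
  invisible(x)
}

#' Tidy a recovered pure component
#'
#' @param x A `pure_component`.
#' @param ... Unused.
#' @return A tibble with `component`, `wavenumber`, `intensity`.
#' @export
tidy.pure_component <- function(x, ...) {
  dplyr::mutate(x$spectrum, component = x$name, .before = 1)
}
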