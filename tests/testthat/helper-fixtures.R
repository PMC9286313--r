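# Shared small fixtures, built in code. A reduced 256-channel axis keeps
# the Whittaker/SVD-heavy tests fast while spanning all reference bands.

small_axis <- function(n = 256) wavenumber_axis(n_channels = n)

# A clean smooth single-spectrum tibble on an arbitrary axis.
smooth_spectrum <- function(n = 200, id = "s1") {
  w <- seq(600, 1800, length.out = n)
  tibble::tibble(id = id, channel = seq_len(n), wavenumber = w,
                 intensity = 50 + 30 * sin(w / 120) + 0.01 * w)
}

# Random multi-spectrum tibble on a nonuniform axis.
random_spectra <- function(n_spec = 5, n_chan = 40, seed = 1,
                           meta = NULL) {
  withr::with_seed(seed, {
    ax <- wavenumber_axis(n_chan, c(600, 1800), curvature = 0.3)
    X <- matrix(runif(n_spec * n_chan, 10, 100), nrow = n_spec)
    u <- list(ids = sprintf("r%02d", seq_len(n_spec)), channel = ax$channel,
              wavenumber = ax$wavenumber, X = X,
              meta = tibble::tibble(id = sprintf("r%02d", seq_len(n_spec))))
    out <- restack_spectra(u)
    if (!is.null(meta)) out <- dplyr::left_join(out, meta, by = "id")
    out
  })
}

# Two noise-free components with disjoint bands, plus mixtures of them.
disjoint_two_component_data <- function(n = 40, n_chan = 300, seed = 3) {
  w <- seq(600, 1800, length.out = n_chan)
  c1 <- pseudo_voigt(w, 800, 14) + 0.4 * pseudo_voigt(w, 900, 14)
  c2 <- pseudo_voigt(w, 1500, 14) + 0.4 * pseudo_voigt(w, 1300, 14)
  c1 <- c1 / sqrt(sum(c1^2)); c2 <- c2 / sqrt(sum(c2^2))
  withr::with_seed(seed, {
    a <- runif(n, 0.15, 0.85)
    X <- outer(a, c1) + outer(1 - a, c2)
  })
  list(wavenumber = w, X = X, c1 = c1, c2 = c2, mix = a)
}
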