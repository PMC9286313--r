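#' CCD pixel-to-wavenumber axis
#'
#' Builds a mildly nonlinear (quadratic) map from CCD channel index to
#' Raman shift, emulating the dispersion of a real spectrograph: channel
#' spacing in cm^-1 varies smoothly across the detector, so downstream
#' wavenumber binning must count channels per bin rather than assume a
#' uniform axis.
#'
#' @param n_channels Number of CCD channels.
#' @param range Wavenumber range `c(lo, hi)` in cm^-1.
#' @param curvature Quadratic warp in `[0, 1)`; 0 gives a uniform axis.
#' @return A tibble with columns `channel` and `wavenumber` (strictly
#'   increasing).
#' @export
wavenumber_axis <- function(n_channels = 1024, range = c(600, 1800),
                            curvature = 0.2) {
  stopifnot(n_channels >= 2, range[1] < range[2],
            curvature >= 0, curvature < 1)
  u <- (seq_len(n_channels) - 1) / (n_channels - 1)
  w <- range[1] + diff(range) * ((1 - curvature) * u + curvature * u^2)
  tibble(channel = seq_len(n_channels), wavenumber = w)
}

#' Class profile for the synthetic EV generator
#'
#' Describes one EV population: the mean biomolecular composition (convex
#' weights over the four pure components), the spread of per-vesicle
#' composition, and the acquisition noise characteristics.
#'
#' @param class_name Class label.
#' @param mean_weights Named 4-vector of mean component fractions in the
#'   order `protein`, `nucleic_acid`, `phosphatidylcholine_like`,
#'   `sphingomyelin_like`; must be non-negative and sum to 1.
#' @param weight_dispersion Dirichlet concentration parameter; larger
#'   values give tighter per-EV composition around the mean. `Inf` makes
#'   every EV exactly the mean composition.
#' @param snr Signal-to-noise ratio: peak biomolecular signal divided by
#'   the noise standard deviation at the peak.
#' @param spike_rate Expected number of cosmic spikes per spectrum.
#' @return A `class_profile` list.
#' @export
class_profile <- function(class_name, mean_weights,
                          weight_dispersion = 1000, snr = 60,
                          spike_rate = 0.05) {
  stopifnot(length(mean_weights) == 4, all(mean_weights >= 0),
            abs(sum(mean_weights) - 1) < 1e-9,
            snr > 0, spike_rate >= 0, weight_dispersion > 0)
  comp <- c("protein", "nucleic_acid", "phosphatidylcholine_like",
            "sphingomyelin_like")
  if (is.null(names(mean_weights))) names(mean_weights) <- comp
  stopifnot(identical(names(mean_weights), comp))
  structure(list(class_name = class_name, mean_weights = mean_weights,
                 weight_dispersion = weight_dispersion, snr = snr,
                 spike_rate = spike_rate),
            class = "class_profile")
}

#' Default cancer / noncancer class profiles
#'
#' The default populations realize the compositional contrast observed
#' between EVs of cancerous and noncancerous origin: noncancer EVs carry
#' a markedly higher relative nucleic-acid fraction, cancer EVs a strongly
#' increased total lipid (phosphatidylcholine-like plus
#' sphingomyelin-like) fraction.
#'
#' @param weight_dispersion,snr,spike_rate Passed to [class_profile()].
#' @return A named list of two `class_profile` objects.
#' @export
default_class_profiles <- function(weight_dispersion = 1000, snr = 60,
                                   spike_rate = 0.05) {
  list(
    noncancer = class_profile(
      "noncancer", c(protein = 0.35, nucleic_acid = 0.30,
                     phosphatidylcholine_like = 0.25,
                     sphingomyelin_like = 0.10),
      weight_dispersion, snr, spike_rate),
    cancer = class_profile(
      "cancer", c(protein = 0.30, nucleic_acid = 0.15,
                  phosphatidylcholine_like = 0.40,
                  sphingomyelin_like = 0.15),
      weight_dispersion, snr, spike_rate)
  )
}

#' PBS/water background template
#'
#' Smooth aqueous-buffer background with the broad water bending feature
#' near 1640 cm^-1 and a slowly varying low-wavenumber hump; no sharp
#' biomolecular bands.
#'
#' @param axis A wavenumber axis ([wavenumber_axis()]).
#' @param amplitude Peak background level in counts.
#' @return Numeric vector of background counts per channel.
#' @export
pbs_template <- function(axis, amplitude = 60) {
  w <- axis$wavenumber
  shape <- 0.35 +
    0.55 * exp(-((w - 1640) / 110)^2) +
    0.25 * exp(-((w - 850) / 320)^2) +
    0.10 * (w - min(w)) / diff(range(w))
  amplitude * shape / max(shape)
}

#' Synthetic instrument relative response
#'
#' Relative sensitivity of the emulated spectrograph/CCD across the
#' fingerprint region (slow roll-off away from the blaze optimum). The
#' generator multiplies every incident spectrum by this response; its
#' reciprocal is the correction curve applied during preprocessing.
#'
#' @param wavenumbers Wavenumber grid (cm^-1).
#' @return Relative sensitivity per channel (in (0, 1]).
#' @export
instrument_response <- function(wavenumbers) {
  u <- (wavenumbers - min(wavenumbers)) / diff(range(wavenumbers))
  0.65 + 0.35 * exp(-((u - 0.35) / 0.45)^2)
}

#' Synthetic relative-intensity response correction curve
#'
#' A smooth, strictly positive multiplicative correction factor per
#' wavenumber, of the kind derived from a NIST relative-intensity standard
#' for 785 nm excitation. Synthetic stand-in: the reciprocal of the
#' emulated [instrument_response()], so that correction restores the
#' incident intensities.
#'
#' @param wavenumbers Wavenumber grid (cm^-1).
#' @return A tibble with columns `wavenumber` and `factor` (all > 0).
#' @export
synthetic_response_curve <- function(wavenumbers) {
  tibble(wavenumber = wavenumbers,
         factor = 1 / instrument_response(wavenumbers))
}

# Dirichlet draw around mean weights with concentration kappa.
rdirichlet_mean <- function(mean_weights, kappa) {
  if (!is.finite(kappa)) return(mean_weights)
  g <- rgamma(length(mean_weights), shape = kappa * mean_weights, rate = 1)
  if (sum(g) <= 0) return(mean_weights)
  w <- g / sum(g)
  names(w) <- names(mean_weights)
  w
}

#' Generate one synthetic single-EV Raman spectrum
#'
#' The generative model: per-EV composition is a Dirichlet perturbation of
#' the class mean weights; the biomolecular signal is the convex
#' combination of the four pure component spectra scaled to `amplitude`
#' counts at its peak; a smooth low-order baseline, the PBS background,
#' heteroscedastic Gaussian noise (variance affine in the total signal,
#' approximating shot noise on CCD counts), and Poisson-count cosmic
#' spikes (amplitude at least 20x the local noise sigma) are added.
#'
#' @param profile A [class_profile()].
#' @param truths Component truths from [make_component_truths()].
#' @param axis Wavenumber axis ([wavenumber_axis()]).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param amplitude Peak biomolecular signal in counts.
#' @param baseline_amplitude Peak amplitude of the smooth baseline drift.
#' @param pbs Background counts per channel (vector or scalar 0).
#' @param response Instrument relative response per channel (vector, or
#'   scalar 1 for a flat response); the incident spectrum is multiplied
#'   by it before noise is added.
#' @param id Spectrum id string.
#' @return A one-spectrum spectra tibble with metadata columns `class`
#'   and the true generating weights (`w_protein`, `w_nucleic_acid`,
#'   `w_phosphatidylcholine_like`, `w_sphingomyelin_like`).
#' @export
generate_ev_spectrum <- function(profile, truths, axis, seed,
                                 amplitude = 400, baseline_amplitude = 40,
                                 pbs = pbs_template(axis),
                                 response = instrument_response(axis$wavenumber),
                                 id = profile$class_name) {
  stopifnot(inherits(profile, "class_profile"))
  comp <- names(profile$mean_weights)
  stopifnot(all(comp %in% names(truths)))
  wn <- axis$wavenumber
  p <- length(wn)
  if (length(pbs) == 1) pbs <- rep(pbs, p)
  withr::with_seed(as.integer(seed), {
    w <- rdirichlet_mean(profile$mean_weights, profile$weight_dispersion)
    Tm <- do.call(rbind, truths[comp])
    mixture <- as.vector(w %*% Tm)
    signal <- amplitude * mixture / max(vapply(truths[comp], max, 0))
    u <- (wn - wn[1]) / (wn[p] - wn[1])
    b <- runif(1, 0.5, 1) + runif(1, -0.5, 0.5) * u +
      runif(1, -0.4, 0.4) * u^2
    baseline <- baseline_amplitude * pmax(b, 0) / max(max(b), 1e-12)
    if (length(response) == 1) response <- rep(response, p)
    total <- response * (signal + baseline + pbs)
    sigma0 <- if (is.finite(profile$snr)) {
      max(response * signal) / profile$snr
    } else 0
    sigma <- sigma0 * sqrt(0.5 + 0.5 * total / max(total))
    noise <- rnorm(p) * sigma
    y <- total + noise
    n_spikes <- rpois(1, profile$spike_rate)
    spike_ch <- integer(0)
    if (n_spikes > 0) {
      spike_ch <- sample.int(p, min(n_spikes, p))
      amp_sigma <- if (sigma0 > 0) sigma[spike_ch] else max(signal) * 0.05
      y[spike_ch] <- y[spike_ch] + (20 + rexp(length(spike_ch), 1 / 10)) *
        amp_sigma
    }
    out <- tibble(
      id = id,
      channel = axis$channel,
      wavenumber = wn,
      intensity = y,
      class = profile$class_name,
      w_protein = w[["protein"]],
      w_nucleic_acid = w[["nucleic_acid"]],
      w_phosphatidylcholine_like = w[["phosphatidylcholine_like"]],
      w_sphingomyelin_like = w[["sphingomyelin_like"]]
    )
    attr(out, "spike_channels") <- sort(spike_ch)
    out
  })
}

#' Simulation configuration
#'
#' @param classes List of [class_profile()] objects (distinct names).
#' @param axis Wavenumber axis.
#' @param n_per_class Spectra per class.
#' @param seed Master seed for the dataset (one batch = one seed).
#' @param amplitude,baseline_amplitude,pbs,response See
#'   [generate_ev_spectrum()].
#' @param batch Batch ("isolation") label attached to every spectrum.
#' @return A `sim_config` list.
#' @export
sim_config <- function(classes = default_class_profiles(),
                       axis = wavenumber_axis(),
                       n_per_class = 100, seed = 1,
                       amplitude = 400, baseline_amplitude = 40,
                       pbs = pbs_template(axis),
                       response = instrument_response(axis$wavenumber),
                       batch = "I") {
  if (length(classes) == 0) abort("`classes` must contain at least one class.")
  nms <- vapply(classes, function(cl) cl$class_name, "")
  if (anyDuplicated(nms)) abort("class name collision in `classes`.")
  stopifnot(n_per_class >= 1)
  structure(list(classes = classes, axis = axis,
                 n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed), amplitude = amplitude,
                 baseline_amplitude = baseline_amplitude, pbs = pbs,
                 response = response, batch = batch),
            class = "sim_config")
}

#' Generate a synthetic single-EV dataset
#'
#' Draws `n_per_class` spectra for every class profile on the shared axis.
#' Per-spectrum seeds are derived from the configuration seed, so the
#' whole dataset is byte-reproducible, and two configurations differing
#' only in seed emulate independent isolation batches of the same
#' populations.
#'
#' @param config A [sim_config()].
#' @return A spectra tibble with metadata columns `class`, `batch` and the
#'   true generating weights. The per-spectrum ground-truth weight table
#'   is available via [true_weights()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truths <- make_component_truths(config$axis)
  rows <- list()
  k <- 0L
  for (cl in config$classes) {
    for (i in seq_len(config$n_per_class)) {
      k <- k + 1L
      s <- generate_ev_spectrum(
        cl, truths, config$axis,
        seed = derive_seed(config$seed, paste0("spectrum_", cl$class_name), i),
        amplitude = config$amplitude,
        baseline_amplitude = config$baseline_amplitude,
        pbs = config$pbs, response = config$response,
        id = sprintf("%s_%s_%03d", config$batch, cl$class_name, i))
      rows[[k]] <- s
    }
  }
  out <- dplyr::bind_rows(rows)
  out$batch <- config$batch
  out
}

#' Ground-truth composition weights of a synthetic dataset
#'
#' @param x A spectra tibble produced by [generate_dataset()].
#' @return A tibble with one row per spectrum: id, class, and the four
#'   generating weights.
#' @export
true_weights <- function(x) {
  m <- spectra_meta(x)
  keep <- intersect(c("id", "class", "batch", "w_protein", "w_nucleic_acid",
                      "w_phosphatidylcholine_like", "w_sphingomyelin_like"),
                    names(m))
  m[, keep, drop = FALSE]
}

#' Generate a synthetic PBS reference set
#'
#' `n` noisy realizations of the PBS/water background template, used for
#' the 95%-of-mean background subtraction step.
#'
#' @param axis Wavenumber axis.
#' @param n Number of reference acquisitions (the preprocessing protocol
#'   uses 200-220 per isolation and integration time).
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation in counts.
#' @param amplitude Template peak amplitude in counts.
#' @param response Instrument relative response (as in
#'   [generate_ev_spectrum()]); the references are measured through it.
#' @return A spectra tibble of `n` background spectra.
#' @export
generate_pbs_reference <- function(axis, n = 200, seed = 1, noise_sd = 2,
                                   amplitude = 60,
                                   response = instrument_response(axis$wavenumber)) {
  if (n < 1) abort("`n` must be at least 1.")
  template <- pbs_template(axis, amplitude)
  if (length(response) == 1) response <- rep(response, nrow(axis))
  p <- nrow(axis)
  withr::with_seed(as.integer(seed), {
    X <- matrix(rnorm(n * p, sd = noise_sd), nrow = n, byrow = TRUE)
    X <- sweep(X, 2, response * template, "+")
  })
  restack_spectra(list(
    ids = sprintf("pbs_%04d", seq_len(n)),
    channel = axis$channel, wavenumber = axis$wavenumber, X = X,
    meta = tibble(id = sprintf("pbs_%04d", seq_len(n)))
  ))
}
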