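#' Preprocessing pipeline configuration
#'
#' Parameters of the single-EV spectral processing chain, applied in this
#' order by [preprocess_pipeline()]: cosmic-spike removal, relative
#' intensity response correction, min/max post-thresholding, subtraction
#' of a fraction of the mean PBS background, fingerprint crop, Whittaker
#' baseline subtraction, first-order Savitzky-Golay smoothing, and
#' normalization by the area under the curve.
#'
#' Setting a step's parameters to `NULL` (or infinite thresholds) disables
#' that step.
#'
#' @param spike_amp_threshold Spike amplitude threshold in multiples of
#'   the robust local-residual sigma; `NULL` disables spike removal.
#' @param spike_d2_threshold Second-difference threshold (same units).
#' @param spike_window Odd window length for the running median.
#' @param pbs_fraction Fraction of the mean PBS spectrum subtracted
#'   (default 0.95).
#' @param crop Fingerprint crop `c(lo, hi)` in cm^-1, or `NULL`.
#' @param whittaker_lambda,whittaker_p Baseline parameters
#'   (see [whittaker_asls()]); `whittaker_lambda = NULL` disables.
#' @param whittaker_max_iter Maximum baseline weight iterations.
#' @param sg_order,sg_frame Savitzky-Golay polynomial order and odd frame
#'   length; `sg_frame = NULL` disables smoothing.
#' @param normalize Normalize each spectrum to unit area under the curve.
#' @param min_intensity,max_intensity Post-threshold bounds on the
#'   per-spectrum maximum intensity; infinite bounds disable filtering.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spike_amp_threshold = 8, spike_d2_threshold = 8,
                            spike_window = 9, pbs_fraction = 0.95,
                            crop = c(600, 1800), whittaker_lambda = 1e4,
                            whittaker_p = 1e-4, whittaker_max_iter = 50,
                            sg_order = 1, sg_frame = 7, normalize = TRUE,
                            min_intensity = -Inf, max_intensity = Inf) {
  if (!is.null(pbs_fraction)) {
    stopifnot(pbs_fraction > 0, pbs_fraction <= 1)
  }
  if (!is.null(sg_frame)) {
    if (sg_frame %% 2 == 0) abort("`sg_frame` must be odd.")
    if (sg_frame <= sg_order) abort("`sg_frame` must exceed `sg_order`.")
  }
  if (!is.null(crop)) stopifnot(length(crop) == 2, crop[1] < crop[2])
  if (!is.null(spike_window)) stopifnot(spike_window %% 2 == 1)
  structure(list(spike_amp_threshold = spike_amp_threshold,
                 spike_d2_threshold = spike_d2_threshold,
                 spike_window = spike_window, pbs_fraction = pbs_fraction,
                 crop = crop, whittaker_lambda = whittaker_lambda,
                 whittaker_p = whittaker_p,
                 whittaker_max_iter = whittaker_max_iter,
                 sg_order = sg_order, sg_frame = sg_frame,
                 normalize = normalize, min_intensity = min_intensity,
                 max_intensity = max_intensity),
            class = "pipeline_config")
}

# Spike detection/replacement for one intensity vector. Returns the
# cleaned vector with attribute "spikes" = flagged channel indices.
despike_vector <- function(y, amp_threshold = 8, d2_threshold = 8,
                           window = 9) {
  n <- length(y)
  if (n < 5) abort("spectrum too short for spike detection (< 5 channels).")
  med <- stats::runmed(y, min(window, n - (1 - n %% 2)), endrule = "median")
  resid <- y - med
  sigma_amp <- mad(resid)
  d2 <- c(0, diff(y, differences = 2), 0)
  sigma_d2 <- mad(d2)
  flagged <- abs(resid) > amp_threshold * sigma_amp &
    abs(d2) > d2_threshold * sigma_d2
  if (all(flagged)) abort("all channels flagged as spikes; degenerate spectrum.")
  if (any(flagged)) {
    ok <- which(!flagged)
    y[flagged] <- approx(ok, y[ok], xout = which(flagged), rule = 2)$y
  }
  attr(y, "spikes") <- which(flagged)
  y
}

#' Remove cosmic spikes
#'
#' Channels where both the deviation from a running median and the second
#' difference exceed robust (MAD-based) thresholds are flagged as cosmic
#' spikes and replaced by linear interpolation from the nearest unflagged
#' neighbors. Unflagged channels are never altered. Requiring both
#' criteria keeps genuine narrow Raman bands intact.
#'
#' @param x A spectra tibble.
#' @param cfg A [pipeline_config()].
#' @return The despiked spectra tibble, with attribute `"spikes"`: a
#'   tibble of flagged `(id, channel)` pairs.
#' @export
remove_cosmic_spikes <- function(x, cfg = pipeline_config()) {
  u <- unstack_spectra(x)
  spikes <- list()
  for (i in seq_len(nrow(u$X))) {
    cleaned <- despike_vector(u$X[i, ], cfg$spike_amp_threshold,
                              cfg$spike_d2_threshold, cfg$spike_window)
    hit <- attr(cleaned, "spikes")
    if (length(hit) > 0) {
      spikes[[length(spikes) + 1]] <-
        tibble(id = u$ids[i], channel = u$channel[hit])
    }
    u$X[i, ] <- as.vector(cleaned)
  }
  out <- restack_spectra(u)
  attr(out, "spikes") <- if (length(spikes) > 0) dplyr::bind_rows(spikes) else
    tibble(id = character(0), channel = integer(0))
  out
}

#' Apply a relative-intensity response correction
#'
#' Multiplies every channel by the correction factor interpolated from
#' the supplied response curve (e.g. one derived from a NIST
#' relative-intensity standard).
#'
#' @param x A spectra tibble.
#' @param curve A tibble with columns `wavenumber` and `factor` (> 0).
#' @return The corrected spectra tibble.
#' @export
apply_response_correction <- function(x, curve) {
  stopifnot(all(c("wavenumber", "factor") %in% names(curve)))
  if (any(curve$factor <= 0)) abort("response correction factors must be > 0.")
  u <- unstack_spectra(x)
  f <- approx(curve$wavenumber, curve$factor, xout = u$wavenumber)$y
  if (anyNA(f)) abort("response curve does not cover the spectrum range.")
  u$X <- sweep(u$X, 2, f, "*")
  restack_spectra(u)
}

#' Min/max post-thresholding of a spectra ensemble
#'
#' Removes spectra whose maximum intensity falls below `min_intensity`
#' (background-only traps) or above `max_intensity` (aggregates /
#' non-single-particle events). Survivor order is preserved.
#'
#' @param x A spectra tibble.
#' @param cfg A [pipeline_config()].
#' @return The filtered spectra tibble with attribute `"rejected"`: the
#'   ids of removed spectra.
#' @export
threshold_filter <- function(x, cfg = pipeline_config()) {
  u <- unstack_spectra(x)
  mx <- apply(u$X, 1, max)
  drop <- mx < cfg$min_intensity | mx > cfg$max_intensity
  out <- dplyr::filter(x, !.data$id %in% u$ids[drop])
  attr(out, "rejected") <- u$ids[drop]
  out
}

#' Subtract the averaged PBS background
#'
#' Subtracts `pbs_fraction` (default 0.95) of the column-wise mean of a
#' PBS reference set from every spectrum. The caller is responsible for
#' supplying the PBS set matched to the isolation batch and acquisition
#' time of `x`.
#'
#' @param x A spectra tibble.
#' @param pbs A spectra tibble of PBS reference acquisitions on the same
#'   axis as `x`.
#' @param cfg A [pipeline_config()].
#' @return The background-subtracted spectra tibble.
#' @export
subtract_background <- function(x, pbs, cfg = pipeline_config()) {
  u <- unstack_spectra(x)
  up <- unstack_spectra(pbs)
  if (ncol(u$X) != ncol(up$X) ||
      max(abs(u$wavenumber - up$wavenumber)) > 1e-9) {
    abort("axis mismatch between spectra and PBS reference set.")
  }
  mean_pbs <- colMeans(up$X)
  u$X <- sweep(u$X, 2, cfg$pbs_fraction * mean_pbs, "-")
  restack_spectra(u)
}

#' Crop to the fingerprint region
#'
#' @param x A spectra tibble.
#' @param cfg A [pipeline_config()] whose `crop` gives the retained
#'   wavenumber interval (inclusive).
#' @return The cropped spectra tibble.
#' @export
crop_fingerprint <- function(x, cfg = pipeline_config()) {
  lo <- cfg$crop[1]; hi <- cfg$crop[2]
  out <- dplyr::filter(x, .data$wavenumber >= lo, .data$wavenumber <= hi)
  if (nrow(out) == 0) {
    abort(paste0("crop [", lo, ", ", hi, "] does not overlap the axis."))
  }
  out
}

#' Savitzky-Golay smoothing of a single signal
#'
#' Interior channels are replaced by the value at the window center of
#' the least-squares polynomial over the full frame; edge channels use a
#' symmetrically shrunken window (order reduced to fit), leaving the
#' first and last channel untouched. The spectra-tibble verb is
#' [savgol_smooth()].
#'
#' @param y Numeric signal.
#' @param order Polynomial order.
#' @param frame Odd frame length (> order, <= length(y)).
#' @return The smoothed signal.
#' @export
sg_smooth_vector <- function(y, order = 1, frame = 7) {
  n <- length(y)
  if (frame %% 2 == 0) abort("Savitzky-Golay frame must be odd.")
  if (frame <= order) abort("frame must exceed polynomial order.")
  if (frame > n) abort("frame longer than the spectrum.")
  h <- (frame - 1) / 2
  A <- outer(-h:h, 0:order, "^")
  w_center <- solve(crossprod(A), t(A))[1, ]
  out <- y
  idx <- (h + 1):(n - h)
  out[idx] <- as.vector(stats::filter(y, rev(w_center), sides = 2))[idx]
  for (i in seq_len(h)[-1]) {  # edges; endpoints (hw 0) stay as-is
    for (pos in c(i, n - i + 1)) {
      hw <- i - 1
      ord <- min(order, 2 * hw)
      Ae <- outer(-hw:hw, 0:ord, "^")
      we <- solve(crossprod(Ae), t(Ae))[1, ]
      out[pos] <- sum(we * y[(pos - hw):(pos + hw)])
    }
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' First-order (by default) Savitzky-Golay filter with a 7-channel frame:
#' each interior channel is replaced by the value at the window center of
#' the least-squares polynomial fitted over the frame. Near the edges the
#' window shrinks symmetrically, avoiding padding artifacts.
#'
#' @param x A spectra tibble.
#' @param cfg A [pipeline_config()] (fields `sg_order`, `sg_frame`).
#' @return The smoothed spectra tibble.
#' @export
savgol_smooth <- function(x, cfg = pipeline_config()) {
  map_spectra(x, function(y, wn) sg_smooth_vector(y, cfg$sg_order,
                                                  cfg$sg_frame))
}

#' Normalize spectra to unit area under the curve
#'
#' Divides each spectrum by its trapezoidal area over the wavenumber axis
#' (not the channel index: the CCD axis is nonuniform in cm^-1), so
#' spectra become comparable regardless of absolute scattering intensity.
#'
#' @param x A spectra tibble.
#' @return The area-normalized spectra tibble (area of every spectrum is
#'   1 within 1e-9).
#' @export
normalize_auc <- function(x) {
  map_spectra(x, function(y, wn) {
    a <- trapz_area(wn, y)
    if (a <= 0) abort("area under the curve must be positive for normalization.")
    y / a
  })
}

#' Full spectral preprocessing pipeline
#'
#' Applies the processing chain in its canonical order: cosmic-spike
#' removal, response correction, min/max post-thresholding, subtraction
#' of 95% of the mean PBS background, fingerprint crop, Whittaker
#' baseline subtraction, first-order Savitzky-Golay smoothing (frame 7),
#' and normalization by the area under the curve. The PBS reference set
#' passes through the same spike removal and response correction before
#' averaging, and is cropped alongside the data.
#'
#' @param x A spectra tibble.
#' @param pbs A PBS reference spectra tibble (same axis), or `NULL` to
#'   skip background subtraction.
#' @param curve A response curve tibble, or `NULL` to skip correction.
#' @param cfg A [pipeline_config()].
#' @return The processed spectra tibble, with attribute `"log"` (character
#'   vector describing each applied step) and attributes `"spikes"` and
#'   `"rejected"` from the corresponding steps.
#' @export
preprocess_pipeline <- function(x, pbs = NULL, curve = NULL,
                                cfg = pipeline_config()) {
  log <- character(0)
  spikes <- NULL; rejected <- NULL
  if (!is.null(cfg$spike_amp_threshold)) {
    x <- remove_cosmic_spikes(x, cfg)
    spikes <- attr(x, "spikes")
    if (!is.null(pbs)) pbs <- remove_cosmic_spikes(pbs, cfg)
    log <- c(log, sprintf("despike: amp %gs, d2 %gs, window %d; %d flagged",
                          cfg$spike_amp_threshold, cfg$spike_d2_threshold,
                          cfg$spike_window, nrow(spikes)))
  }
  if (!is.null(curve)) {
    x <- apply_response_correction(x, curve)
    if (!is.null(pbs)) pbs <- apply_response_correction(pbs, curve)
    log <- c(log, "response correction applied")
  }
  if (is.finite(cfg$min_intensity) || is.finite(cfg$max_intensity)) {
    x <- threshold_filter(x, cfg)
    rejected <- attr(x, "rejected")
    log <- c(log, sprintf("threshold filter [%g, %g]: %d removed",
                          cfg$min_intensity, cfg$max_intensity,
                          length(rejected)))
  }
  if (!is.null(pbs) && !is.null(cfg$pbs_fraction)) {
    x <- subtract_background(x, pbs, cfg)
    log <- c(log, sprintf("PBS subtraction: %g x mean of %d references",
                          cfg$pbs_fraction, length(unique(pbs$id))))
  }
  if (!is.null(cfg$crop)) {
    x <- crop_fingerprint(x, cfg)
    log <- c(log, sprintf("crop [%g, %g] cm^-1", cfg$crop[1], cfg$crop[2]))
  }
  if (!is.null(cfg$whittaker_lambda)) {
    x <- whittaker_baseline(x, cfg$whittaker_lambda, cfg$whittaker_p,
                            cfg$whittaker_max_iter)
    attr(x, "baseline") <- NULL
    log <- c(log, sprintf("Whittaker baseline: lambda %g, p %g",
                          cfg$whittaker_lambda, cfg$whittaker_p))
  }
  if (!is.null(cfg$sg_frame)) {
    x <- savgol_smooth(x, cfg)
    log <- c(log, sprintf("Savitzky-Golay: order %d, frame %d",
                          cfg$sg_order, cfg$sg_frame))
  }
  if (isTRUE(cfg$normalize)) {
    x <- normalize_auc(x)
    log <- c(log, "area normalization")
  }
  attr(x, "log") <- log
  attr(x, "spikes") <- spikes
  attr(x, "rejected") <- rejected
  x
}
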