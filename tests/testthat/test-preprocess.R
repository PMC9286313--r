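test_that("spike removal is the identity on clean spectra and repairs injected spikes", {
  s <- smooth_spectrum(200)
  out <- remove_cosmic_spikes(s, pipeline_config())
  expect_equal(out$intensity, s$intensity)
  expect_equal(nrow(attr(out, "spikes")), 0)

  # single delta of 50x the local noise sigma at channel k
  withr::with_seed(8, {
    noisy <- s
    noise <- rnorm(200, sd = 1)
    noisy$intensity <- noisy$intensity + noise
    k <- 97
    spiked <- noisy
    spiked$intensity[k] <- spiked$intensity[k] + 50
    out <- remove_cosmic_spikes(spiked, pipeline_config())
    flags <- attr(out, "spikes")
    expect_equal(flags$channel, k)
    expect_lt(abs(out$intensity[k] - noisy$intensity[k]), 3)
    # unflagged channels are untouched
    expect_equal(out$intensity[-k], spiked$intensity[-k])

    # two adjacent spikes are both flagged (a directly neighboring
    # channel may be swept up by the second-difference criterion) and
    # the whole block is bridged back to the clean signal
    spiked2 <- noisy
    spiked2$intensity[120:121] <- spiked2$intensity[120:121] + c(60, 45)
    out2 <- remove_cosmic_spikes(spiked2, pipeline_config())
    flagged2 <- attr(out2, "spikes")$channel
    expect_true(all(c(120, 121) %in% flagged2))
    expect_true(all(flagged2 %in% 118:123))
    expect_lt(max(abs(out2$intensity[118:123] - noisy$intensity[118:123])), 3)
  })
})

test_that("spike removal rejects spectra that are too short or fully flagged", {
  s <- smooth_spectrum(4)
  expect_error(remove_cosmic_spikes(s, pipeline_config()), "5 channels")
})

test_that("response correction multiplies by the interpolated factor", {
  s <- random_spectra(3, 30)
  flat <- tibble::tibble(wavenumber = c(500, 2000), factor = c(1, 1))
  expect_equal(apply_response_correction(s, flat)$intensity, s$intensity)
  twice <- tibble::tibble(wavenumber = c(500, 2000), factor = c(2, 2))
  expect_equal(apply_response_correction(s, twice)$intensity,
               2 * s$intensity)
  # linear ramp vs an independent elementwise loop
  ramp <- tibble::tibble(wavenumber = seq(500, 2000, length.out = 50),
                         factor = seq(0.5, 1.8, length.out = 50))
  out <- apply_response_correction(s, ramp)
  expected <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    f <- approx(ramp$wavenumber, ramp$factor, xout = s$wavenumber[i])$y
    expected[i] <- s$intensity[i] * f
  }
  expect_equal(out$intensity, expected, tolerance = 1e-12)
  bad <- tibble::tibble(wavenumber = c(500, 2000), factor = c(1, -1))
  expect_error(apply_response_correction(s, bad), "> 0")
})

test_that("threshold filter keeps exactly the spectra a per-row check keeps", {
  x <- random_spectra(10, 25, seed = 5)
  cfg <- pipeline_config(min_intensity = -Inf, max_intensity = Inf)
  expect_equal(threshold_filter(x, cfg), x, ignore_attr = TRUE)
  cfg2 <- pipeline_config(min_intensity = 85, max_intensity = 97)
  out <- threshold_filter(x, cfg2)
  u <- unstack_spectra(x)
  keep_oracle <- u$ids[vapply(seq_len(nrow(u$X)), function(i) {
    m <- max(u$X[i, ]); m >= 85 && m <= 97
  }, logical(1))]
  expect_identical(unique(out$id), keep_oracle)
  expect_setequal(attr(out, "rejected"), setdiff(u$ids, keep_oracle))
})

test_that("PBS subtraction removes the configured fraction of the reference mean", {
  axis <- small_axis(64)
  pbs <- generate_pbs_reference(axis, 200, seed = 2, noise_sd = 1)
  mean_pbs <- colMeans(unstack_spectra(pbs)$X)
  s <- restack_spectra(list(ids = "m", channel = axis$channel,
                            wavenumber = axis$wavenumber,
                            X = matrix(mean_pbs, 1),
                            meta = tibble::tibble(id = "m")))
  out <- subtract_background(s, pbs, pipeline_config(pbs_fraction = 0.95))
  expect_equal(out$intensity, 0.05 * mean_pbs, tolerance = 1e-10,
               ignore_attr = TRUE)
  out1 <- subtract_background(s, pbs, pipeline_config(pbs_fraction = 1))
  expect_equal(out1$intensity, rep(0, 64), tolerance = 1e-10,
               ignore_attr = TRUE)
  # random spectra against the loop oracle
  x <- restack_spectra(list(ids = c("a", "b"), channel = axis$channel,
                            wavenumber = axis$wavenumber,
                            X = matrix(runif(128, 0, 50), 2),
                            meta = tibble::tibble(id = c("a", "b"))))
  out2 <- subtract_background(x, pbs, pipeline_config())
  ux <- unstack_spectra(x); uo <- unstack_spectra(out2)
  for (i in 1:2) for (j in c(1, 30, 64)) {
    expect_equal(uo$X[i, j], ux$X[i, j] - 0.95 * mean_pbs[j])
  }
  shifted <- dplyr::mutate(pbs, wavenumber = wavenumber + 5)
  expect_error(subtract_background(s, shifted, pipeline_config()),
               "axis mismatch")
})

test_that("fingerprint crop retains exactly the in-range channels", {
  n <- 80
  w <- seq(500, 2000, length.out = n)
  x <- tibble::tibble(id = "s", channel = seq_len(n), wavenumber = w,
                      intensity = runif(n))
  out <- crop_fingerprint(x, pipeline_config(crop = c(600, 1800)))
  expect_equal(nrow(out), sum(w >= 600 & w <= 1800))
  full <- crop_fingerprint(x, pipeline_config(crop = c(400, 2100)))
  expect_equal(full, x)
  expect_error(crop_fingerprint(x, pipeline_config(crop = c(3000, 3100))),
               "overlap")
})

test_that("Whittaker baseline obeys its analytic limits and the dense-solve oracle", {
  # lambda -> 0: baseline equals the input
  y <- c(5, 9, 2, 7, 4, 8, 1, 6, 3, 7)
  z <- whittaker_asls(y, lambda = 1e-10, p = 0.5)
  expect_equal(as.vector(z), y, tolerance = 1e-6)
  # constant input: baseline is that constant, corrected is zero
  yc <- rep(4.2, 30)
  zc <- whittaker_asls(yc, lambda = 10, p = 0.1)
  expect_equal(as.vector(zc), yc, tolerance = 1e-9)

  # n = 50 random signal vs a dense linear-solve oracle at every
  # weight iteration
  withr::with_seed(10, {
    y50 <- cumsum(rnorm(50)) + 20 + 3 * dnorm(seq(-3, 3, length.out = 50))
  })
  lambda <- 1e4; p <- 1e-4
  D <- diff(diag(50), differences = 2)
  w <- rep(1, 50)
  z_oracle <- NULL
  for (it in 1:50) {
    z_oracle <- solve(diag(w) + lambda * crossprod(D), w * y50)
    w_new <- ifelse(y50 > z_oracle, p, 1 - p)
    if (mean(abs(w_new - w)) < 1e-6) break
    w <- w_new
  }
  z_pkg <- whittaker_asls(y50, lambda, p)
  expect_equal(as.vector(z_pkg), as.vector(z_oracle), tolerance = 1e-8)

  # stiffness limit: larger lambda flattens the baseline curvature
  d2 <- function(z) sum(diff(z, differences = 2)^2)
  z1 <- whittaker_asls(y50, 1e2, 1e-4)
  z2 <- whittaker_asls(y50, 1e6, 1e-4)
  z3 <- whittaker_asls(y50, 1e10, 1e-4)
  expect_gt(d2(z1), d2(z2))
  expect_gt(d2(z2), d2(z3))
  expect_lt(d2(z3), 1e-8 * d2(z1))
})

test_that("Savitzky-Golay smoothing reproduces polynomials and the windowed regression oracle", {
  # exactly linear input is invariant for order 1, frame 7
  n <- 60
  lin <- 2 + 0.3 * seq_len(n)
  expect_equal(sg_smooth_vector(lin, 1, 7), lin, tolerance = 1e-12)
  # constant input unchanged everywhere including edges
  expect_equal(sg_smooth_vector(rep(7, n), 1, 7), rep(7, n))
  # random input: interior equals the explicit per-window least squares fit
  withr::with_seed(11, y <- runif(n))
  out <- sg_smooth_vector(y, 1, 7)
  for (i in c(4, 10, 33, 57)) {
    win <- (i - 3):(i + 3)
    fit <- lm(y[win] ~ I(win - i))
    expect_equal(out[i], unname(coef(fit)[1]), tolerance = 1e-10)
  }
  expect_error(sg_smooth_vector(y, 1, 6), "odd")
  # interior agrees with the reference implementation in `signal`
  ref <- signal::sgolayfilt(y, p = 1, n = 7)
  expect_equal(out[4:(n - 3)], ref[4:(n - 3)], tolerance = 1e-10)
})

test_that("area normalization yields unit area and is scale-invariant and idempotent", {
  n <- 50
  w <- seq(600, 1800, length.out = n)
  con <- tibble::tibble(id = "c", channel = seq_len(n), wavenumber = w,
                        intensity = rep(3.5, n))
  out <- normalize_auc(con)
  expect_equal(out$intensity, rep(1 / 1200, n), tolerance = 1e-12)
  expect_equal(normalize_auc(out)$intensity, out$intensity,
               tolerance = 1e-12)
  x <- random_spectra(4, 35, seed = 7)
  nx <- normalize_auc(x)
  un <- unstack_spectra(nx)
  for (i in 1:4) {
    area <- sum(diff(un$wavenumber) *
                  (un$X[i, -1] + un$X[i, -ncol(un$X)]) / 2)
    expect_equal(area, 1, tolerance = 1e-9)
  }
  scaled <- dplyr::mutate(x, intensity = intensity * 7.3)
  expect_equal(normalize_auc(scaled)$intensity, nx$intensity,
               tolerance = 1e-12)
  neg <- dplyr::mutate(con, intensity = -1)
  expect_error(normalize_auc(neg), "positive")
})

test_that("the pipeline applies steps in order and reduces to the identity when disabled", {
  x <- random_spectra(3, 40, seed = 9)
  off <- pipeline_config(spike_amp_threshold = NULL, crop = NULL,
                         whittaker_lambda = NULL, sg_frame = NULL,
                         normalize = FALSE)
  expect_equal(preprocess_pipeline(x, NULL, NULL, off), x,
               ignore_attr = TRUE)

  # permuting baseline subtraction and normalization changes the result
  cfg <- pipeline_config(spike_amp_threshold = NULL, crop = NULL,
                         sg_frame = NULL)
  in_order <- preprocess_pipeline(x, NULL, NULL, cfg)
  swapped <- whittaker_baseline(normalize_auc(x), 1e4, 1e-4)
  expect_gt(max(abs(in_order$intensity - swapped$intensity)), 1e-6)
})

test_that("a noise-free convex mixture survives the full pipeline nearly unchanged", {
  # full 1024-channel axis: the 7-channel smoothing frame spans ~8 cm^-1
  # there, narrow next to the 12 cm^-1 bands (at 256 channels the same
  # frame would span ~33 cm^-1 and flatten them)
  axis <- wavenumber_axis()
  truths <- make_component_truths(axis)
  prof <- class_profile("c", c(0.3, 0.2, 0.35, 0.15),
                        weight_dispersion = Inf, snr = Inf, spike_rate = 0)
  d <- dplyr::bind_rows(lapply(1:3, function(i) {
    generate_ev_spectrum(prof, truths, axis, seed = i,
                         baseline_amplitude = 0, pbs = 0, response = 1,
                         id = paste0("s", i))
  }))
  # spike removal presumes noise-dominated residuals; on strictly
  # noise-free input the MAD noise scale collapses, so the stage is off
  out <- preprocess_pipeline(d, NULL, NULL,
                             pipeline_config(spike_amp_threshold = NULL))
  mix <- as.vector(prof$mean_weights %*% do.call(rbind, truths))
  u <- unstack_spectra(out)
  keep <- axis$wavenumber >= 600 & axis$wavenumber <= 1800
  mixc <- mix[keep]
  cs <- sum(u$X[1, ] * mixc) / sqrt(sum(u$X[1, ]^2) * sum(mixc^2))
  expect_gt(cs, 0.99)
  # last-step contract: unit area for every spectrum
  for (i in 1:3) {
    area <- sum(diff(u$wavenumber) *
                  (u$X[i, -1] + u$X[i, -ncol(u$X)]) / 2)
    expect_equal(area, 1, tolerance = 1e-9)
  }
})
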