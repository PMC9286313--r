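#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows distinct pull n across all_of any_of first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats approx mad median qf qnorm quantile rnorm rpois runif
#'   rexp sd setNames predict
#' @importFrom utils head tail read.table write.csv
NULL

# Columns that define the spectral part of a spectra tibble; everything else
# that is constant within an id is treated as per-spectrum metadata.
.spec_cols <- c("id", "channel", "wavenumber", "intensity")

#' Validate a long spectra tibble
#'
#' A spectra tibble is the package's exchange format: one row per
#' (spectrum, channel) with columns `id`, `channel`, `wavenumber`,
#' `intensity` plus optional per-spectrum metadata columns (e.g. `class`,
#' `batch`). All spectra must share one wavenumber axis, strictly
#' increasing in `channel` order.
#'
#' @param x A data frame to validate.
#' @param min_channels Minimum number of channels required per spectrum.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_spectra <- function(x, min_channels = 2L) {
  if (!is.data.frame(x)) abort("`x` must be a data frame of spectra.")
  missing_cols <- setdiff(.spec_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("spectra tibble is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("spectra tibble is empty.")
  if (!is.numeric(x$wavenumber) || !is.numeric(x$intensity)) {
    abort("`wavenumber` and `intensity` must be numeric.")
  }
  u <- unstack_spectra(x)
  if (ncol(u$X) < min_channels) {
    abort(paste0("spectra must have at least ", min_channels, " channels."))
  }
  if (any(diff(u$wavenumber) <= 0)) {
    abort("wavenumber axis must be strictly increasing.")
  }
  invisible(x)
}

#' Convert a long spectra tibble to matrix form
#'
#' @param x A spectra tibble (see [validate_spectra()]).
#' @return A list with `ids` (spectrum ids in first-appearance order),
#'   `channel`, `wavenumber`, `X` (numeric matrix, one row per spectrum),
#'   and `meta` (per-spectrum metadata tibble, one row per id).
#' @export
unstack_spectra <- function(x) {
  ids <- unique(x$id)
  xo <- dplyr::arrange(x, match(.data$id, ids), .data$channel)
  counts <- table(factor(xo$id, levels = ids))
  if (length(unique(as.integer(counts))) != 1) {
    abort("ragged spectra: all spectra must share one channel axis.")
  }
  p <- as.integer(counts[1])
  first <- xo[seq_len(p), ]
  wn <- first$wavenumber
  ch <- first$channel
  wn_all <- matrix(xo$wavenumber, ncol = p, byrow = TRUE)
  if (length(ids) > 1 && max(abs(sweep(wn_all, 2, wn))) > 1e-9) {
    abort("spectra do not share a common wavenumber axis.")
  }
  X <- matrix(xo$intensity, ncol = p, byrow = TRUE,
              dimnames = list(ids, NULL))
  meta_cols <- setdiff(names(x), c("channel", "wavenumber", "intensity"))
  meta <- xo[seq(1, nrow(xo), by = p), meta_cols, drop = FALSE]
  meta <- as_tibble(meta)
  list(ids = ids, channel = ch, wavenumber = wn, X = X, meta = meta)
}

#' Convert matrix form back to a long spectra tibble
#'
#' @param u A list as produced by [unstack_spectra()] (fields `ids`,
#'   `channel`, `wavenumber`, `X`, `meta`).
#' @return A spectra tibble.
#' @export
restack_spectra <- function(u) {
  n <- nrow(u$X)
  p <- ncol(u$X)
  out <- tibble(
    id = rep(u$ids, each = p),
    channel = rep(u$channel, times = n),
    wavenumber = rep(u$wavenumber, times = n),
    intensity = as.vector(t(u$X))
  )
  extra <- u$meta[, setdiff(names(u$meta), "id"), drop = FALSE]
  if (ncol(extra) > 0) {
    extra_rep <- extra[rep(seq_len(n), each = p), , drop = FALSE]
    out <- dplyr::bind_cols(out, extra_rep)
  }
  out
}

# Apply a per-spectrum function f(y) -> y' to every spectrum, preserving
# metadata. f receives the intensity vector and the shared wavenumber axis.
map_spectra <- function(x, f, ...) {
  u <- unstack_spectra(x)
  u$X <- t(apply(u$X, 1, function(y) f(y, u$wavenumber, ...)))
  restack_spectra(u)
}

#' Per-spectrum metadata of a spectra tibble
#'
#' @param x A spectra tibble.
#' @return A tibble with one row per spectrum id.
#' @export
spectra_meta <- function(x) {
  unstack_spectra(x)$meta
}

#' Derive a reproducible stage seed from a master seed
#'
#' All randomness in the package flows from one master seed; per-stage and
#' per-spectrum seeds are derived by stable string hashing so stages are
#' reproducible independently of each other.
#'
#' @param master Master seed (integer).
#' @param stage Stage label (character scalar).
#' @param index Optional integer index within the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1)
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(master) %% m)
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  h <- (h * 131 + (as.numeric(index) %% m)) %% m
  as.integer(h %% (m - 1)) + 1L
}

# Trapezoidal integral of y over x (nonuniform axis allowed).
trapz_area <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
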