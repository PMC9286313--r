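#' Build a dimensional reduction array (DRA)
#'
#' A DRA condenses an ensemble of Raman spectra into a heatmap of mean
#' intensity per fixed-width wavenumber bin, with rows either the class
#' means or the individual spectra. Because the CCD axis is nonlinear in
#' cm^-1, channels are assigned to bins by wavenumber value, so the
#' number of data points per bin varies and is reported alongside the
#' means.
#'
#' Bins are half-open `[edge, edge + bin_size)` anchored at the range low
#' edge; the final (possibly partial) bin is closed at the range high
#' edge. A bin containing no channels yields `NA`, never zero, so empty
#' bins cannot distort the color scale.
#'
#' @param x A spectra tibble.
#' @param bin_size Bin width in cm^-1 (default 50).
#' @param range Wavenumber range `c(lo, hi)`; defaults to the data range.
#' @param rows `"class"` for class-mean rows (mean over spectra, then
#'   over channels in the bin) or `"id"` for one row per spectrum.
#' @return A `dra` tibble with columns `row`, `bin`, `lo`, `hi`, `mid`,
#'   `value`, `n_points`, and attributes `bin_edges` and `range`.
#' @export
build_dra <- function(x, bin_size = 50, range = NULL, rows = c("class", "id")) {
  rows <- match.arg(rows)
  stopifnot(bin_size > 0)
  u <- unstack_spectra(x)
  if (is.null(range)) range <- base::range(u$wavenumber)
  lo <- range[1]; hi <- range[2]
  stopifnot(lo < hi)
  n_bins <- ceiling((hi - lo) / bin_size - 1e-12)
  edges <- c(lo + bin_size * (0:(n_bins - 1)), hi)
  in_range <- u$wavenumber >= lo & u$wavenumber <= hi
  if (!any(in_range)) abort("DRA range does not overlap the wavenumber axis.")
  # half-open [e_j, e_{j+1}) bins, last closed at hi
  bin_of <- findInterval(u$wavenumber[in_range], edges,
                         rightmost.closed = TRUE)
  if (rows == "class") {
    if (!"class" %in% names(u$meta)) {
      abort("rows = \"class\" requires a `class` metadata column.")
    }
    groups <- u$meta$class
    row_levels <- unique(groups)
    M <- do.call(rbind, lapply(row_levels, function(g) {
      colMeans(u$X[groups == g, , drop = FALSE])
    }))
  } else {
    row_levels <- u$ids
    M <- u$X
  }
  Mr <- M[, in_range, drop = FALSE]
  n_points <- tabulate(bin_of, nbins = n_bins)
  cells <- lapply(seq_along(row_levels), function(i) {
    vals <- vapply(seq_len(n_bins), function(b) {
      v <- Mr[i, bin_of == b]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    tibble(row = row_levels[i], bin = seq_len(n_bins),
           lo = edges[seq_len(n_bins)], hi = edges[-1],
           mid = (edges[seq_len(n_bins)] + edges[-1]) / 2,
           value = vals, n_points = n_points)
  })
  out <- dplyr::bind_rows(cells)
  attr(out, "bin_edges") <- edges
  attr(out, "range") <- c(lo, hi)
  class(out) <- c("dra", class(out))
  out
}

#' DRA over a spectral subrange
#'
#' Rebuilds the DRA restricted to a wavenumber subrange, so the color
#' scale is set by the subrange minimum and maximum. Useful when a single
#' strong band (e.g. the CH2 bend at 1442 cm^-1) would otherwise dominate
#' the full-range scale and mask protein/nucleic-acid variation.
#'
#' @param x A spectra tibble.
#' @param range Subrange `c(lo, hi)` in cm^-1 (must lie within the data).
#' @param bin_size Bin width in cm^-1.
#' @param rows Row grouping, as in [build_dra()].
#' @return A `dra` tibble.
#' @export
subrange_dra <- function(x, range, bin_size = 50, rows = c("class", "id")) {
  dr <- base::range(unstack_spectra(x)$wavenumber)
  if (range[1] < dr[1] - 1e-9 || range[2] > dr[2] + 1e-9) {
    abort("subrange must lie within the data range.")
  }
  build_dra(x, bin_size = bin_size, range = range, rows = match.arg(rows))
}

# Perceptually uniform palettes accepted by default for DRA rendering.
.uniform_colormaps <- c("viridis", "magma", "plasma", "inferno", "cividis")

#' Plot a DRA heatmap
#'
#' @param object A `dra` object.
#' @param colormap One of the perceptually uniform ggplot2 viridis-family
#'   options (`r paste(.uniform_colormaps, collapse = ", ")`).
#' @param ... Unused.
#' @return A ggplot object; missing (empty-bin) cells are drawn in grey.
#' @export
autoplot.dra <- function(object, colormap = "viridis", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_tile(width = object$hi - object$lo) +
    ggplot2::scale_fill_viridis_c(option = colormap, na.value = "grey60",
                                  name = "mean\nintensity") +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a DRA heatmap to an image file
#'
#' Refuses non-perceptually-uniform ("rainbow"-style) colormaps unless
#' explicitly overridden: with a color scale spanning the cell minimum to
#' maximum, a non-uniform gradient exaggerates some intensity differences
#' and hides others.
#'
#' @param h A `dra` object.
#' @param out Output file path (`.png` or `.svg`).
#' @param colormap Colormap name.
#' @param allow_nonuniform Set `TRUE` to force a non-approved colormap.
#' @param width,height,dpi Image geometry passed to [ggplot2::ggsave()].
#' @return `out`, invisibly.
#' @export
render_dra <- function(h, out, colormap = "viridis",
                       allow_nonuniform = FALSE,
                       width = 7, height = 4, dpi = 150) {
  if (!colormap %in% .uniform_colormaps && !allow_nonuniform) {
    abort(paste0("colormap `", colormap, "` is not perceptually uniform; ",
                 "approved maps: ", paste(.uniform_colormaps, collapse = ", "),
                 ". Override with allow_nonuniform = TRUE."))
  }
  cmap <- if (colormap %in% .uniform_colormaps) colormap else "viridis"
  pl <- autoplot.dra(h, colormap = cmap)
  if (!colormap %in% .uniform_colormaps) {
    pl <- pl + ggplot2::scale_fill_gradientn(
      colours = grDevices::rainbow(16), na.value = "grey60")
  }
  ggplot2::ggsave(out, pl, width = width, height = height, dpi = dpi)
  invisible(out)
}

#' Export a DRA as a rows-by-bins CSV table
#'
#' @param h A `dra` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dra_csv <- function(h, path) {
  wide <- tidyr::pivot_wider(
    as_tibble(h)[, c("row", "mid", "value")],
    names_from = "mid", values_from = "value", names_prefix = "bin_")
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
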