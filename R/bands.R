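#' Reference Raman band assignments for EV biomolecular composition
#'
#' Band centers (cm^-1) of the major biomolecular Raman features observed
#' in single-EV fingerprint spectra, with their conventional vibrational
#' assignments (lipid CH2 modes, protein amide/phenylalanine modes, nucleic
#' acid ring-breathing and backbone modes).
#'
#' @return A tibble with columns `band` (compound family), `assignment`
#'   (vibrational mode), `center` (Raman shift, cm^-1).
#' @export
raman_band_table <- function() {
  tibble::tribble(
    ~band,           ~assignment,                                   ~center,
    "lipoprotein",   "cholesterol",                                  609,
    "lipoprotein",   "cholesterol",                                  698,
    "nucleic_acid",  "DNA ring breathing modes",                     723,
    "protein",       "tyrosine, glycans",                            845,
    "protein",       "tyrosine, glycans",                            884,
    "protein",       "C-C stretch protein beta-sheet",               989,
    "protein",       "phenylalanine",                               1004,
    "lipid",         "C-C stretch lipids",                          1064,
    "protein_na",    "C-N stretch proteins, PO2 stretch DNA",       1084,
    "protein_na",    "C-N stretch proteins",                        1128,
    "nucleic_acid",  "cytosine, guanine",                           1185,
    "protein_na",    "amide-III proteins, DNA ring breathing",      1256,
    "lipid",         "CH2 twist lipids",                            1295,
    "protein_na",    "amide-III proteins, DNA ring breathing",      1337,
    "protein_na",    "guanine, tryptophan",                         1354,
    "protein_na",    "DNA ring breathing modes",                    1371,
    "lipid",         "C=O stretch, CH2 lipids",                     1399,
    "lipid",         "CH2 bend lipids",                             1442
  )
}

#' Band definition helper
#'
#' @param center Band center (Raman shift, cm^-1).
#' @param height Relative intensity (unitless, >= 0).
#' @param width Full width at half maximum (cm^-1, > 0).
#' @param assignment Free-text label for the vibrational mode.
#' @return A one-row tibble describing the band.
#' @export
band_spec <- function(center, height = 1, width = 12, assignment = "") {
  stopifnot(width > 0, height >= 0)
  tibble(center = center, height = height, width = width,
         assignment = assignment)
}

# Band sets defining the four pure biomolecular components. Relative
# heights are chosen so that each component has a distinct dominant band:
# phenylalanine 1004 for protein, the 723 ring-breathing mode for nucleic
# acids, the CH2 bend at 1442 for both lipid species, with the 989 band
# distinguishing the sphingomyelin-like from the phosphatidylcholine-like
# component.
component_band_sets <- function() {
  list(
    protein = tibble::tribble(
      ~center, ~height,
      845,  0.35,
      884,  0.35,
      1004, 1.00,
      1128, 0.30,
      1256, 0.45,
      1337, 0.40
    ),
    nucleic_acid = tibble::tribble(
      ~center, ~height,
      723,  1.00,
      1084, 0.55,
      1185, 0.30,
      1337, 0.35,
      1354, 0.35,
      1371, 0.30
    ),
    phosphatidylcholine_like = tibble::tribble(
      ~center, ~height,
      1064, 0.50,
      1295, 0.60,
      1399, 0.30,
      1442, 1.00
    ),
    sphingomyelin_like = tibble::tribble(
      ~center, ~height,
      989,  1.00,
      1064, 0.40,
      1295, 0.45,
      1442, 0.70
    )
  )
}

#' Pseudo-Voigt line profile
#'
#' Fixed 50/50 Lorentzian/Gaussian mixture, unit peak height, parameterized
#' by the full width at half maximum. Typical condensed-phase Raman bands
#' are intermediate between the two limits, which this profile captures.
#'
#' @param x Evaluation points (cm^-1).
#' @param center Peak center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1).
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @return Profile values at `x` (unit peak height).
#' @export
pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  hw <- fwhm / 2
  lor <- 1 / (1 + ((x - center) / hw)^2)
  gau <- exp(-log(2) * ((x - center) / hw)^2)
  eta * lor + (1 - eta) * gau
}

#' Construct the pure biomolecular component spectra
#'
#' Builds unit-length, non-negative "ground truth" spectra for the four
#' biomolecular species that dominate single-EV fingerprint spectra:
#' protein, nucleic acid, and two lipid species (phosphatidylcholine-like
#' and sphingomyelin-like). Each component is a sum of pseudo-Voigt bands
#' at the canonical assignment positions (see [raman_band_table()]).
#'
#' @param axis A wavenumber axis as produced by [wavenumber_axis()].
#' @param fwhm Band full width at half maximum (cm^-1).
#' @return A named list of four unit-norm numeric vectors (one value per
#'   channel), with attribute `"bands"` carrying the band tables.
#' @export
make_component_truths <- function(axis, fwhm = 12) {
  wn <- axis$wavenumber
  rng <- range(wn)
  sets <- component_band_sets()
  out <- lapply(names(sets), function(nm) {
    bands <- sets[[nm]]
    bad <- bands$center < rng[1] | bands$center > rng[2]
    if (any(bad)) {
      abort(paste0("axis range [", rng[1], ", ", rng[2], "] excludes ",
                   nm, " band(s) at ",
                   paste(bands$center[bad], collapse = ", "), " cm^-1"))
    }
    s <- rowSums(vapply(seq_len(nrow(bands)), function(i) {
      bands$height[i] * pseudo_voigt(wn, bands$center[i], fwhm)
    }, numeric(length(wn))))
    s / sqrt(sum(s^2))
  })
  names(out) <- names(sets)
  attr(out, "bands") <- sets
  out
}
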