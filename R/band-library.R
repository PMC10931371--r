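#' Raman band library for the three cellular scene components
#'
#' Band positions follow published assignments for polystyrene (aromatic ring
#' modes and backbone CH modes), cellular lipids (CH deformation and C=C / CH
#' stretching modes) and water (the broad H-O-H bending hump near 1644
#' cm\eqn{^{-1}}). Relative intensities and widths are package choices tuned to
#' give the components their characteristic appearance: the polystyrene ring
#' breathing mode at 1001 cm\eqn{^{-1}} dominates its spectrum, lipids are
#' strongest in the CH-stretch region, and water is a single very broad band.
#'
#' @return A tibble with columns `component`, `center` (cm\eqn{^{-1}}),
#'   `rel_intensity` (unitless, in (0, 1]), `fwhm` (cm\eqn{^{-1}}) and
#'   `shape` (one of `"gaussian"`, `"lorentzian"`, `"pseudo-voigt"`).
#' @examples
#' band_library()
#' @export
band_library <- function() {
  ps <- tibble::tibble(
    component = "polystyrene",
    center = c(621, 1001, 1031, 1201, 1450, 1604, 2913, 3057),
    rel_intensity = c(0.30, 1.00, 0.45, 0.25, 0.30, 0.35, 0.60, 0.35),
    fwhm = c(10, 8, 10, 12, 14, 10, 14, 12),
    shape = "pseudo-voigt"
  )
  lipid <- tibble::tibble(
    component = "lipid",
    center = c(1302, 1442, 1656, 2882, 2929),
    rel_intensity = c(0.50, 0.80, 0.55, 1.00, 0.60),
    fwhm = c(18, 16, 14, 20, 20),
    shape = "pseudo-voigt"
  )
  water <- tibble::tibble(
    component = "water",
    center = 1644,
    rel_intensity = 1.0,
    fwhm = 200,
    shape = "gaussian"
  )
  dplyr::bind_rows(ps, lipid, water)
}

validate_band_library <- function(library) {
  stopifnot(is.data.frame(library),
            all(c("component", "center", "rel_intensity", "fwhm", "shape")
                %in% names(library)))
  if (any(library$center <= 0)) abort("band centers must be positive")
  if (any(library$rel_intensity <= 0 | library$rel_intensity > 1))
    abort("rel_intensity must lie in (0, 1]")
  if (any(library$fwhm <= 0)) abort("fwhm must be positive")
  bad <- setdiff(unique(library$shape),
                 c("gaussian", "lorentzian", "pseudo-voigt"))
  if (length(bad)) abort(paste("unknown band shape:", bad[1]))
  invisible(library)
}

# single band profile on an axis, peak height 1 at the center
band_profile <- function(axis, center, fwhm, shape, voigt_eta = 0.3) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gamma <- fwhm / 2
  g <- exp(-((axis - center)^2) / (2 * sigma^2))
  l <- gamma^2 / ((axis - center)^2 + gamma^2)
  switch(shape,
    "gaussian" = g,
    "lorentzian" = l,
    "pseudo-voigt" = voigt_eta * l + (1 - voigt_eta) * g,
    abort(paste("unknown band shape:", shape))
  )
}

# vector form used throughout the generators and classifiers
ref_spectrum_vec <- function(label, axis, library = band_library()) {
  if (length(axis) == 0) abort("wavenumber axis is empty")
  if (any(diff(axis) <= 0)) abort("wavenumber axis must be strictly increasing")
  validate_band_library(library)
  bands <- library[library$component == label, , drop = FALSE]
  if (nrow(bands) == 0) {
    abort(paste0("unknown component label: '", label, "'"))
  }
  s <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    s <- s + bands$rel_intensity[i] *
      band_profile(axis, bands$center[i], bands$fwhm[i], bands$shape[i])
  }
  m <- max(s)
  if (m > 0) s <- s / m
  s
}

#' Reference spectrum of a scene component
#'
#' Evaluates the sum of the component's band profiles on a wavenumber axis and
#' peak-normalizes the result to a maximum of 1.
#'
#' @param label Component label present in `library` (by default one of
#'   `"polystyrene"`, `"lipid"`, `"water"`).
#' @param axis Strictly increasing wavenumber axis (cm\eqn{^{-1}}).
#' @param library Band library tibble, see [band_library()].
#' @return A tibble with columns `wavenumber` and `intensity`.
#' @examples
#' ps <- reference_spectrum("polystyrene", seq(600, 3100, by = 2))
#' peak_positions(ps$intensity, ps$wavenumber)
#' @export
reference_spectrum <- function(label, axis, library = band_library()) {
  tibble::tibble(wavenumber = axis,
                 intensity = ref_spectrum_vec(label, axis, library))
}

#' Detect peak positions in a spectrum
#'
#' Local maxima whose topographic prominence is at least
#' `prominence_fraction` times the global maximum, reported as axis values.
#'
#' @param intensity Numeric spectrum.
#' @param axis Wavenumber axis matching `intensity`.
#' @param prominence_fraction Minimum prominence as a fraction of the global
#'   maximum intensity (default 0.1).
#' @return Numeric vector of peak wavenumbers (possibly empty).
#' @export
peak_positions <- function(intensity, axis, prominence_fraction = 0.1) {
  n <- length(intensity)
  stopifnot(length(axis) == n)
  if (n == 0) abort("spectrum is empty")
  if (n < 3) return(numeric(0))
  s <- as.numeric(intensity)
  # a two-channel plateau (band center between grid points) counts once,
  # at its left channel
  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  if (!length(cand)) return(numeric(0))
  thr <- prominence_fraction * max(s)
  prom <- vapply(cand, function(i) peak_prominence(s, i), numeric(1))
  axis[cand[prom >= thr]]
}

# prominence: height above the higher of the two valley floors, each side
# explored until terrain rises above the peak (or the spectrum ends)
peak_prominence <- function(s, i) {
  n <- length(s)
  h <- s[i]
  left <- s[seq_len(i - 1)]
  higher_l <- which(left > h)
  lmin <- min(if (length(higher_l)) s[(max(higher_l) + 1):(i - 1)] else left)
  right <- s[(i + 1):n]
  higher_r <- which(right > h)
  rmin <- min(if (length(higher_r)) s[(i + 1):(i + min(higher_r) - 1)] else right)
  h - max(lmin, rmin)
}
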