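#' Simulate a Raman image scan of a cell with internalized polystyrene
#'
#' Builds a hyperspectral cube on a regular grid in which every pixel spectrum
#' is a non-negative mixture of three reference components: a water background,
#' lipid droplets, and polystyrene nanoparticle clusters. On top of the clean
#' mixture the generator adds a smooth polynomial baseline, Poisson shot noise
#' scaled to a target peak signal-to-noise ratio plus weak Gaussian read noise,
#' and sparse single-channel cosmic-ray spikes. All randomness derives from
#' `seed`, so a fixed seed reproduces the fixture exactly.
#'
#' Default geometry emulates a single-cell scan: 25 µm x 25 µm at 0.5 µm
#' steps (50 x 50 pixels) in three z planes 1.5 µm apart.
#'
#' @param nx,ny,nz Grid dimensions (pixels / z planes).
#' @param step,z_step Spatial steps in µm.
#' @param axis Wavenumber axis (cm\eqn{^{-1}}), strictly increasing.
#' @param n_ps_clusters,n_lipid_droplets Numbers of planted polystyrene
#'   clusters and lipid droplets.
#' @param ps_radius,lipid_radius Region radii in pixels.
#' @param peak_height Intensity (counts) of the strongest clean band.
#' @param baseline_degree Degree of the additive polynomial baseline
#'   (0 disables it).
#' @param baseline_amp Baseline amplitude as a fraction of `peak_height`.
#' @param snr Peak signal-to-noise ratio of the shot noise (`Inf` disables
#'   noise).
#' @param spike_fraction Fraction of pixels receiving one cosmic spike
#'   (in \[0, 0.05\]).
#' @param library Band library, see [band_library()].
#' @param seed Integer seed (mandatory).
#' @return A list of class `raman_fixture`: `cube` (a [raman_cube()]),
#'   `truth_endmembers` (an `endmember_set` of the clean component spectra),
#'   `truth_abundance` (pixels x components matrix), `layout` (character
#'   vector of planted labels per pixel), and `seed`.
#' @examples
#' fx <- make_raman_fixture(nx = 12, ny = 12, nz = 1, snr = Inf,
#'                          baseline_degree = 0, spike_fraction = 0, seed = 1)
#' dim(fx$cube)
#' @export
make_raman_fixture <- function(nx = 50, ny = 50, nz = 3,
                               step = 0.5, z_step = 1.5,
                               axis = seq(600, 3100, by = 2),
                               n_ps_clusters = 3, n_lipid_droplets = 4,
                               ps_radius = 3, lipid_radius = 3,
                               peak_height = 100,
                               baseline_degree = 3, baseline_amp = 0.5,
                               snr = 20, spike_fraction = 0.005,
                               library = band_library(), seed) {
  if (missing(seed)) abort("a seed is mandatory for fixture generation")
  if (!is.finite(spike_fraction) || spike_fraction < 0 || spike_fraction > 0.05)
    abort("spike_fraction must lie in [0, 0.05]")
  if (!(snr > 0)) abort("snr must be positive")
  comps <- c("water", "polystyrene", "lipid")
  E <- do.call(rbind, lapply(comps, ref_spectrum_vec, axis = axis,
                             library = library))
  rownames(E) <- comps
  E <- E * peak_height

  withr::with_seed(seed, {
    lay <- plant_layout(nx, ny, nz, n_ps_clusters, n_lipid_droplets,
                        ps_radius, lipid_radius)
    npix <- nx * ny * nz
    A <- matrix(0, npix, 3, dimnames = list(NULL, comps))
    A[cbind(seq_len(npix), match(lay, comps))] <- 1
    clean <- A %*% E
    v <- clean
    peak <- max(clean)
    if (baseline_degree > 0) {
      u <- seq(-1, 1, length.out = length(axis))
      cf <- stats::rnorm(baseline_degree + 1)
      b <- drop(outer(u, 0:baseline_degree, `^`) %*% cf)
      b <- b - min(b)
      b <- b / max(max(b), 1e-12)
      scale_px <- stats::runif(npix, 0.5, 1.5) * baseline_amp * peak
      v <- v + outer(scale_px, b)
    }
    if (is.finite(snr)) {
      cc <- snr^2 / peak
      v <- matrix(stats::rpois(length(v), lambda = pmax(cc * v, 0)) / cc,
                  nrow = npix)
      v <- v + matrix(stats::rnorm(length(v), sd = 0.01 * peak), nrow = npix)
    }
    n_spike <- floor(spike_fraction * npix)
    if (n_spike > 0) {
      px <- sample.int(npix, n_spike)
      ch <- sample.int(length(axis), n_spike, replace = TRUE)
      idx <- cbind(px, ch)
      v[idx] <- v[idx] + 25 * pmax(abs(v[idx]), 0.1 * peak)
    }
    cube <- raman_cube(axis, v, c(nx, ny, nz), step = step, z_step = z_step)
    structure(
      list(cube = cube,
           truth_endmembers = endmember_set(axis, E, labels = comps),
           truth_abundance = A,
           layout = lay,
           seed = seed),
      class = "raman_fixture"
    )
  })
}

# label each voxel water/lipid/polystyrene: spherical inclusions on a water
# background; inclusions kept inside the central cell region of the grid
plant_layout <- function(nx, ny, nz, n_ps, n_lipid, ps_radius, lipid_radius) {
  co <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz),
                    KEEP.OUT.ATTRS = FALSE)
  lay <- rep("water", nrow(co))
  place <- function(n, r, label) {
    # clamp so inclusions fit even on very small grids
    r <- min(r, (min(nx, ny) - 1) / 2)
    for (i in seq_len(n)) {
      cx <- stats::runif(1, min(1 + r, (1 + nx) / 2), max(nx - r, (1 + nx) / 2))
      cy <- stats::runif(1, min(1 + r, (1 + ny) / 2), max(ny - r, (1 + ny) / 2))
      cz <- if (nz > 1) sample.int(nz, 1) else 1L
      hit <- (co$x - cx)^2 + (co$y - cy)^2 <= r^2 &
        abs(co$z - cz) <= 1
      lay[hit] <<- label
    }
  }
  place(n_lipid, lipid_radius, "lipid")
  place(n_ps, ps_radius, "polystyrene")
  lay
}

#' Set of endmember spectra
#'
#' @param axis Wavenumber axis shared by all spectra.
#' @param spectra Matrix with one endmember per row.
#' @param labels Optional character labels per endmember.
#' @param indices Optional pixel indices the endmembers were drawn from.
#' @param volume Optional simplex volume attained (N-FINDR diagnostics).
#' @return An object of class `endmember_set`.
#' @export
endmember_set <- function(axis, spectra, labels = NULL, indices = NULL,
                          volume = NULL) {
  spectra <- matrix(spectra, ncol = length(axis))
  if (is.null(labels)) labels <- rep("unassigned", nrow(spectra))
  structure(
    list(axis = as.numeric(axis), spectra = spectra,
         labels = labels, k = nrow(spectra),
         indices = indices, volume = volume),
    class = "endmember_set"
  )
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> k = %d, %d channels; labels: %s\n",
              x$k, length(x$axis), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' @describeIn endmember_set Long-format view (`endmember`, `label`,
#'   `wavenumber`, `intensity`).
#' @param x An `endmember_set`.
#' @param ... Unused.
#' @export
as_tibble.endmember_set <- function(x, ...) {
  tibble::tibble(
    endmember = rep(seq_len(x$k), each = length(x$axis)),
    label = rep(x$labels, each = length(x$axis)),
    wavenumber = rep(x$axis, times = x$k),
    intensity = as.vector(t(x$spectra))
  )
}
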