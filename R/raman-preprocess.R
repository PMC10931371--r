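#' Preprocessing parameter set for the Raman pipeline
#'
#' @param despike_zmax Modified z-score threshold for cosmic-spike flagging
#'   (default 6).
#' @param despike_window Neighborhood half-width (channels) used when
#'   replacing flagged channels (default 5).
#' @param snip_iterations Maximum SNIP clipping window (channels, default 60).
#' @param silent_region Wavenumber bounds of the excised silent region
#'   (cm\eqn{^{-1}}, default 1800-2700; channels strictly inside the open
#'   interval are removed).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(despike_zmax = 6, despike_window = 5,
                              snip_iterations = 60,
                              silent_region = c(1800, 2700)) {
  if (snip_iterations < 1) abort("snip_iterations must be at least 1")
  if (silent_region[1] >= silent_region[2])
    abort("silent_region bounds must be increasing")
  structure(list(despike_zmax = despike_zmax,
                 despike_window = despike_window,
                 snip_iterations = snip_iterations,
                 silent_region = silent_region),
            class = "preprocess_params")
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' Cosmic spikes are single-channel events: the first difference into the
#' spike and the one out of it are both extreme, with opposite signs. A
#' channel is flagged when the modified z-scores of its two adjacent first
#' differences both exceed `zmax` in magnitude with opposite signs; flagged
#' channels are replaced by the mean of unflagged channels within `window`
#' channels on either side. Genuine Raman bands - even sharp ones - rise
#' over several channels with one-sided differences and are untouched.
#'
#' @param spectrum Numeric spectrum.
#' @param zmax Modified z-score threshold.
#' @param window Replacement neighborhood half-width (channels).
#' @return Despiked spectrum.
#' @export
despike <- function(spectrum, zmax = 6, window = 5) {
  s <- as.numeric(spectrum)
  n <- length(s)
  if (n < 2 * window) abort("spectrum shorter than twice the despike window")
  d <- diff(s)
  md <- stats::median(d)
  scale <- stats::median(abs(d - md))
  if (scale == 0) scale <- mean(abs(d - md)) / 0.7979  # robust fallback
  if (scale == 0) return(s)                            # constant spectrum
  z <- 0.6745 * (d - md) / scale
  # channel i sits between differences z[i-1] (into) and z[i] (out of)
  zin <- z[seq_len(n - 2)]
  zout <- z[seq_len(n - 2) + 1L]
  cand <- which((zin > zmax & zout < -zmax) | (zin < -zmax & zout > zmax)) + 1L
  # confirm single-channel locality: the jump into and out of a cosmic spike
  # dwarfs the slopes just outside it, whereas a sampled band apex has
  # differences comparable to its own flanks
  eps <- 1e-12 * max(abs(d), 1e-300)
  confirm <- function(i) {
    inner <- min(abs(d[i - 1]), abs(d[i]))
    outer <- max(if (i >= 3) abs(d[i - 2]) else 0,
                 if (i + 1 <= n - 1) abs(d[i + 1]) else 0)
    inner > 5 * (outer + eps)
  }
  mid <- cand[vapply(cand, confirm, logical(1))]
  # boundary channels only have a one-sided difference
  edges <- c(
    if (abs(z[1]) > zmax && abs(d[1]) > 5 * (abs(d[2]) + eps) && s[1] > s[2]) 1L,
    if (abs(z[n - 1]) > zmax && abs(d[n - 1]) > 5 * (abs(d[n - 2]) + eps) &&
          s[n] > s[n - 1]) n)
  flagged <- sort(unique(c(mid, edges)))
  if (!length(flagged)) return(s)
  ok <- !(seq_len(n) %in% flagged)
  out <- s
  for (i in flagged) {
    lo <- max(1, i - window); hi <- min(n, i + window)
    nb <- which(ok[lo:hi]) + lo - 1L
    out[i] <- if (length(nb)) mean(s[nb]) else md
  }
  out
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak clipping: the baseline
#' estimate starts at the spectrum and is clipped channel-wise to
#' min(v(i), (v(i-w) + v(i+w)) / 2) for an increasing window
#' w = 1..`iterations`. Clipping is performed on the intensity scale, which
#' keeps the operator exactly homogeneous (scaling a spectrum scales its
#' baseline), reproduces a constant or linear baseline exactly, and leaves
#' the corrected spectrum non-negative wherever the baseline touches.
#'
#' @param spectrum Numeric spectrum.
#' @param iterations Maximum clipping window in channels (>= 1 and smaller
#'   than the spectrum length).
#' @return A list with `baseline` and `corrected` (= spectrum - baseline).
#' @export
snip_baseline <- function(spectrum, iterations = 60) {
  s <- as.numeric(spectrum)
  n <- length(s)
  if (iterations < 1) abort("iterations must be at least 1")
  if (iterations >= n) abort("iterations must be smaller than the spectrum length")
  b <- drop(snip_baseline_mat(matrix(s, nrow = 1), iterations))
  list(baseline = b, corrected = s - b)
}

# vectorized SNIP over a matrix of row spectra (shared axis)
snip_baseline_mat <- function(V, iterations) {
  n <- ncol(V)
  Y <- V
  for (w in seq_len(iterations)) {
    idx <- (w + 1):(n - w)
    avg <- (Y[, idx - w, drop = FALSE] + Y[, idx + w, drop = FALSE]) / 2
    Y[, idx] <- pmin(Y[, idx, drop = FALSE], avg)
  }
  Y
}

#' Mean-normalize a spectrum
#'
#' @param spectrum Numeric spectrum with positive mean.
#' @return Spectrum scaled so that its mean is exactly 1.
#' @export
normalize_mean <- function(spectrum) {
  m <- mean(spectrum)
  if (!is.finite(m) || m <= 0)
    abort("degenerate pixel: spectrum mean is not positive",
          class = "psuptake_degenerate_pixel")
  spectrum / m
}

#' Excise the silent spectral region from a cube
#'
#' Removes all channels whose wavenumber lies strictly inside the open
#' interval `region` (a channel exactly at a bound is retained). Biological
#' samples carry no Raman bands there, so dropping it concentrates the
#' unmixing on informative channels.
#'
#' @param cube A [raman_cube()].
#' @param region Two wavenumbers (cm\eqn{^{-1}}), default `c(1800, 2700)`.
#' @return A `raman_cube` on the reduced axis.
#' @export
cut_silent_region <- function(cube, region = c(1800, 2700)) {
  stopifnot(inherits(cube, "raman_cube"))
  if (region[1] >= region[2]) abort("silent region bounds must be increasing")
  keep <- !(cube$axis > region[1] & cube$axis < region[2])
  if (!any(keep)) abort("silent region covers the whole axis")
  raman_cube(cube$axis[keep], cube$intensities[, keep, drop = FALSE],
             cube$dims, step = cube$step, z_step = cube$z_step,
             degenerate = cube$degenerate)
}

#' Preprocess a Raman cube
#'
#' Applies, per pixel and in this order: cosmic-spike removal, SNIP baseline
#' correction, mean normalization, and excision of the silent spectral
#' region. Pixels whose baseline-corrected spectrum has non-positive mean
#' cannot be normalized; they are zeroed and flagged degenerate so that
#' downstream unmixing skips them.
#'
#' @param cube A [raman_cube()].
#' @param params A [preprocess_params()].
#' @return A preprocessed `raman_cube` whose `degenerate` field flags
#'   excluded pixels.
#' @export
preprocess <- function(cube, params = preprocess_params()) {
  stopifnot(inherits(cube, "raman_cube"))
  V <- cube$intensities
  V <- t(apply(V, 1, despike, zmax = params$despike_zmax,
               window = params$despike_window))
  B <- snip_baseline_mat(V, params$snip_iterations)
  V <- V - B
  m <- rowMeans(V)
  degenerate <- !is.finite(m) | m <= 0
  if (any(degenerate)) {
    warn(sprintf("%d degenerate pixel(s) flagged and excluded from unmixing",
                 sum(degenerate)))
    V[degenerate, ] <- 0
  }
  V[!degenerate, ] <- V[!degenerate, , drop = FALSE] / m[!degenerate]
  out <- raman_cube(cube$axis, V, cube$dims, step = cube$step,
                    z_step = cube$z_step, degenerate = degenerate)
  cut_silent_region(out, params$silent_region)
}
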