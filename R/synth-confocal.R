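#' Cell-line segmentation profiles
#'
#' Minimum nucleus areas follow the analysis settings used for the three cell
#' models: 20 µm² for THP-1 macrophages and 10 µm² for the A549 and CaCo-2
#' epithelial lines; the circularity filter spans the full 0-1 range for all
#' three (a configurable no-op kept for faithfulness).
#'
#' @param cell_line One of `"THP-1"`, `"A549"`, `"CaCo-2"`.
#' @return A list with `min_nucleus_area` (µm²) and `circularity_range`.
#' @export
cell_line_profile <- function(cell_line = c("THP-1", "A549", "CaCo-2")) {
  cell_line <- match.arg(cell_line)
  list(
    cell_line = cell_line,
    min_nucleus_area = if (cell_line == "THP-1") 20 else 10,
    circularity_range = c(0, 1)
  )
}

#' Simulate a confocal field of view of bead-exposed cells
#'
#' Renders a 4-channel 8-bit z-stack (bead fluorescence, DAPI nuclei, actin,
#' brightfield) with known ground truth. Cells are non-overlapping discs with
#' an elliptical nucleus, an actin rim, and a textured brightfield footprint.
#' Beads are sub-resolution Gaussian puncta (sigma about 1 px) planted inside
#' cell areas; the total bead count is Poisson with mean
#' `bead_rate * concentration * n_cells`, so planted bead area scales with the
#' nominal exposure concentration. `n_small_objects` optionally plants bright
#' nucleus-like debris below the cell line's minimum-area filter to exercise
#' the size filter.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel size in µm/px (default 0.684, a 350 µm field at
#'   512 px).
#' @param nz Number of z planes (1 µm apart by default).
#' @param n_cells Number of cells to plant (placement is rejection-sampled;
#'   the realized count is in `truth_nuclei_count`).
#' @param cell_line Cell line profile, see [cell_line_profile()].
#' @param concentration Nominal exposure concentration in µg/cm².
#' @param time_h Exposure time in hours (metadata only).
#' @param bead_rate Expected beads per cell per (µg/cm²).
#' @param bead_amplitude Peak bead intensity (8-bit).
#' @param background Mean background level (8-bit).
#' @param noise_sd Gaussian noise sd added to every channel.
#' @param n_small_objects Number of sub-threshold bright objects in the
#'   nuclei channel.
#' @param seed Integer seed (mandatory).
#' @return A list of class `confocal_fixture` with the rendered `stack`
#'   (a [confocal_stack()]), `truth_nuclei_count`, `truth_nuclei_labels`
#'   (2D integer label image), `truth_bead_mask` (2D logical, projected,
#'   pre-noise, at half the bead amplitude), `truth_bead_signal` (the
#'   projected pre-noise bead intensity itself, for halo-aware scoring),
#'   `truth_cell_mask` (2D logical), `nominal_concentration`,
#'   `exposure_time`, and `seed`.
#' @export
make_confocal_fixture <- function(width = 512, height = 512,
                                  pixel_size = 0.684, nz = 5,
                                  n_cells = 15,
                                  cell_line = "THP-1",
                                  concentration = 15.63,
                                  time_h = 24,
                                  bead_rate = 0.4,
                                  bead_amplitude = 200,
                                  background = 10,
                                  noise_sd = 4,
                                  n_small_objects = 0,
                                  seed) {
  if (missing(seed)) abort("a seed is mandatory for fixture generation")
  if (width <= 0 || height <= 0) abort("image size must be positive")
  if (pixel_size <= 0) abort("pixel_size must be positive")
  if (n_cells < 0) abort("n_cells must be non-negative")
  if (concentration < 0) abort("concentration must be non-negative")
  profile <- cell_line_profile(cell_line)

  withr::with_seed(seed, {
    # --- geometry -----------------------------------------------------------
    nuc_r_um <- stats::runif(n_cells, 3.2, 4.6)      # nucleus semi-major, um
    cell_r_um <- nuc_r_um * stats::runif(n_cells, 2.0, 2.6)
    cell_r <- cell_r_um / pixel_size
    centers <- place_centers(n_cells, width, height, cell_r,
                             min_gap = 4 / pixel_size)
    nplaced <- nrow(centers)
    cell_r <- cell_r[seq_len(nplaced)]
    nuc_r <- nuc_r_um[seq_len(nplaced)] / pixel_size

    xg <- matrix(seq_len(width), width, height)
    yg <- matrix(seq_len(height), width, height, byrow = TRUE)

    nuclei_lab <- matrix(0L, width, height)
    cell_mask <- matrix(FALSE, width, height)
    nuc_img <- matrix(0, width, height)
    actin_img <- matrix(0, width, height)
    bf_img <- matrix(120, width, height)

    for (i in seq_len(nplaced)) {
      dx <- xg - centers[i, 1]; dy <- yg - centers[i, 2]
      r2 <- dx^2 + dy^2
      inside_cell <- r2 <= cell_r[i]^2
      cell_mask <- cell_mask | inside_cell
      # elliptical nucleus, random orientation and mild eccentricity
      th <- stats::runif(1, 0, pi)
      ecc <- stats::runif(1, 0.75, 1)
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      inside_nuc <- (u / nuc_r[i])^2 + (v / (ecc * nuc_r[i]))^2 <= 1
      nuclei_lab[inside_nuc] <- i
      nuc_img[inside_nuc] <- 180
      ring <- r2 <= cell_r[i]^2 & r2 >= (0.82 * cell_r[i])^2
      actin_img[ring] <- 160
      actin_img[inside_cell & !ring] <- pmax(actin_img[inside_cell & !ring], 45)
      bf_img[inside_cell] <- 120 + stats::runif(sum(inside_cell), -25, 25)
      # dark optical rim at the cell boundary, inside the true cell area
      rim <- r2 <= cell_r[i]^2 & r2 >= (0.88 * cell_r[i])^2
      bf_img[rim] <- 70
    }

    # --- beads --------------------------------------------------------------
    n_beads <- if (nplaced > 0 && concentration > 0)
      stats::rpois(1, bead_rate * concentration * nplaced) else 0L
    bead_clean <- array(0, dim = c(width, height, nz))
    if (n_beads > 0) {
      owner <- sample.int(nplaced, n_beads, replace = TRUE)
      rr <- sqrt(stats::runif(n_beads)) * 0.85 * cell_r[owner]
      aa <- stats::runif(n_beads, 0, 2 * pi)
      bx <- centers[owner, 1] + rr * cos(aa)
      by <- centers[owner, 2] + rr * sin(aa)
      bz <- sample.int(nz, n_beads, replace = TRUE)
      for (b in seq_len(n_beads)) {
        bead_clean[, , bz[b]] <- bead_clean[, , bz[b]] +
          punctum(xg, yg, bx[b], by[b], sigma = 1, amp = bead_amplitude)
      }
    }
    bead_proj <- apply(bead_clean, c(1, 2), max)   # pre-noise projected signal
    truth_bead_mask <- bead_proj >= 0.5 * bead_amplitude

    # --- sub-threshold debris in the nuclei channel -------------------------
    if (n_small_objects > 0) {
      small_area_um2 <- 0.45 * profile$min_nucleus_area
      small_r <- sqrt(small_area_um2 / pi) / pixel_size
      for (i in seq_len(n_small_objects)) {
        cx <- stats::runif(1, 2 * small_r, width - 2 * small_r)
        cy <- stats::runif(1, 2 * small_r, height - 2 * small_r)
        hit <- (xg - cx)^2 + (yg - cy)^2 <= small_r^2
        nuc_img[hit] <- 180
      }
    }

    # --- assemble z-stacks with a dome-shaped axial profile -----------------
    zc <- (nz + 1) / 2
    zprof <- exp(-((seq_len(nz) - zc)^2) / (2 * max(nz / 3, 1)^2))
    stack3d <- function(img2d) {
      arr <- array(0, dim = c(width, height, nz))
      for (z in seq_len(nz)) arr[, , z] <- img2d * zprof[z]
      arr
    }
    ch <- list(
      beads = bead_clean + background / 2,
      nuclei = stack3d(nuc_img) + background,
      actin = stack3d(actin_img) + background,
      brightfield = array(rep(bf_img, nz), dim = c(width, height, nz))
    )
    ch <- lapply(ch, function(a) {
      a <- a + array(stats::rnorm(length(a), sd = noise_sd), dim = dim(a))
      array(as.integer(pmin(pmax(round(a), 0), 255)), dim = dim(a))
    })

    structure(
      list(stack = confocal_stack(ch, pixel_size = pixel_size, z_step = 1),
           truth_nuclei_count = nplaced,
           truth_nuclei_labels = nuclei_lab,
           truth_bead_mask = truth_bead_mask,
           truth_bead_signal = bead_proj,
           truth_cell_mask = cell_mask,
           nominal_concentration = concentration,
           exposure_time = time_h,
           cell_line = profile$cell_line,
           seed = seed),
      class = "confocal_fixture"
    )
  })
}

# gaussian punctum clipped to a small support window for speed
punctum <- function(xg, yg, cx, cy, sigma, amp) {
  out <- matrix(0, nrow(xg), ncol(xg))
  x0 <- max(1, floor(cx - 4 * sigma)); x1 <- min(nrow(xg), ceiling(cx + 4 * sigma))
  y0 <- max(1, floor(cy - 4 * sigma)); y1 <- min(ncol(xg), ceiling(cy + 4 * sigma))
  if (x0 > x1 || y0 > y1) return(out)
  xs <- x0:x1; ys <- y0:y1
  g <- outer(xs, ys, function(x, y)
    amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
  out[xs, ys] <- g
  out
}

# rejection-sample non-overlapping cell centers; gives up after a fixed
# number of attempts so crowded requests return fewer cells
place_centers <- function(n, width, height, radii, min_gap = 6,
                          max_attempts = 4000) {
  centers <- matrix(numeric(0), ncol = 2)
  kept_r <- numeric(0)
  attempts <- 0
  i <- 1
  while (i <= n && attempts < max_attempts) {
    attempts <- attempts + 1
    r <- radii[i]
    cx <- stats::runif(1, r + 2, width - r - 2)
    cy <- stats::runif(1, r + 2, height - r - 2)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(d < kept_r + r + min_gap)) next
    }
    centers <- rbind(centers, c(cx, cy))
    kept_r <- c(kept_r, r)
    i <- i + 1
  }
  centers
}
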