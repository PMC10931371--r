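#' Segmentation parameter set for the fluorescence pipeline
#'
#' Defaults follow the published analysis settings where stated (nuclei blur
#' sigma 3 px, minimum nucleus area per cell line, circularity 0-1) and
#' documented package choices elsewhere (Canny sigma, maximum-filter and
#' morphology radii, contrast stretch percentiles).
#'
#' @param nuclei_blur_sigma Gaussian blur sigma for the nuclei channel (px).
#' @param nuclei_threshold `"auto"` (Otsu) or a manual 8-bit value.
#' @param min_nucleus_area Minimum retained nucleus area in µm².
#' @param circularity_range Inclusive circularity filter bounds in \[0, 1\].
#' @param canny_sigma Gaussian sigma of the Canny detector (px).
#' @param maxfilter_radius Maximum-filter radius applied to the edge map (px).
#' @param morph_radius Disc radius of the closing/opening steps (px).
#' @param bead_threshold `"calibrate"` (from control images, see
#'   [calibrate_bead_threshold()]) or a manual 8-bit value.
#' @param contrast_percentiles Lower/upper percentiles of the brightfield
#'   contrast stretch.
#' @param cell_line Optional cell line; fills `min_nucleus_area` and
#'   `circularity_range` from [cell_line_profile()].
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(nuclei_blur_sigma = 3,
                                nuclei_threshold = "auto",
                                min_nucleus_area = 20,
                                circularity_range = c(0, 1),
                                canny_sigma = 2,
                                maxfilter_radius = 3,
                                morph_radius = 5,
                                bead_threshold = "calibrate",
                                contrast_percentiles = c(1, 99),
                                cell_line = NULL) {
  if (!is.null(cell_line)) {
    prof <- cell_line_profile(cell_line)
    min_nucleus_area <- prof$min_nucleus_area
    circularity_range <- prof$circularity_range
  }
  if (min_nucleus_area <= 0) abort("min_nucleus_area must be positive")
  if (any(circularity_range < 0) || any(circularity_range > 1) ||
      circularity_range[1] > circularity_range[2])
    abort("circularity_range must be an ordered subinterval of [0, 1]")
  structure(list(
    nuclei_blur_sigma = nuclei_blur_sigma,
    nuclei_threshold = nuclei_threshold,
    min_nucleus_area = min_nucleus_area,
    circularity_range = circularity_range,
    canny_sigma = canny_sigma,
    maxfilter_radius = maxfilter_radius,
    morph_radius = morph_radius,
    bead_threshold = bead_threshold,
    contrast_percentiles = contrast_percentiles
  ), class = "segmentation_params")
}

#' Z-projection of a confocal stack
#'
#' Collapses every channel to a single 2D image. Maximum-intensity projection
#' is the default: beads are sparse bright puncta and the maximum preserves
#' them wherever they sit along z. A sum projection is available by flag.
#'
#' @param stack A [confocal_stack()].
#' @param method `"max"` (default) or `"sum"`.
#' @return Named list of 2D matrices, one per channel.
#' @export
z_project <- function(stack, method = c("max", "sum")) {
  stopifnot(inherits(stack, "confocal_stack"))
  method <- match.arg(method)
  if (dim(stack)[3] < 1) abort("stack has no z planes")
  f <- if (method == "max") function(a) apply(a, c(1, 2), max)
       else function(a) apply(a, c(1, 2), sum)
  lapply(stack$channels, f)
}

#' Segment and count cell nuclei
#'
#' The chain applied to the (projected) nuclei channel: Gaussian blur, global
#' threshold (Otsu by default, manual 8-bit value optionally), hole filling,
#' watershed splitting of touching nuclei on the distance transform, then a
#' filter on physical area (µm², via `pixel_size`) and circularity
#' \eqn{4\pi A / P^2}.
#'
#' @param nuclei_image 2D numeric matrix (8-bit scale).
#' @param params A [segmentation_params()].
#' @param pixel_size Pixel size in µm/px.
#' @return A list of class `nuclei_segmentation`: `label_image`, `count`,
#'   `areas` (µm²), `circularities`.
#' @export
segment_nuclei <- function(nuclei_image, params = segmentation_params(),
                           pixel_size) {
  if (pixel_size <= 0) abort("pixel_size must be positive")
  img <- as.matrix(nuclei_image)
  if (!length(img)) abort("empty image")
  empty <- function() structure(list(
    label_image = matrix(0L, nrow(img), ncol(img)), count = 0L,
    areas = numeric(0), circularities = numeric(0)),
    class = "nuclei_segmentation")
  if (diff(range(img)) == 0) return(empty())

  blurred <- EBImage::gblur(img / 255, sigma = params$nuclei_blur_sigma)
  thr <- params$nuclei_threshold
  thr01 <- if (identical(thr, "auto")) EBImage::otsu(EBImage::Image(blurred))
           else as.numeric(thr) / 255
  mask <- blurred > thr01
  if (!any(mask)) return(empty())
  mask <- EBImage::fillHull(mask)
  # low tolerance: the blur fills the waist between touching nuclei, so the
  # distance-map saddle between their seeds can be shallow
  labels <- EBImage::watershed(EBImage::distmap(mask), tolerance = 0.3, ext = 1)
  labels <- matrix(as.integer(labels), nrow(img), ncol(img))

  feats <- EBImage::computeFeatures.shape(labels)
  if (is.null(feats) || nrow(feats) == 0) return(empty())
  area_um2 <- feats[, "s.area"] * pixel_size^2
  circ <- pmin(4 * pi * feats[, "s.area"] / pmax(feats[, "s.perimeter"], 1)^2, 1)
  keep <- area_um2 >= params$min_nucleus_area &
    circ >= params$circularity_range[1] &
    circ <= params$circularity_range[2]
  old_ids <- as.integer(rownames(feats))[keep]
  relab <- matrix(0L, nrow(img), ncol(img))
  for (j in seq_along(old_ids)) relab[labels == old_ids[j]] <- j
  structure(list(
    label_image = relab,
    count = length(old_ids),
    areas = unname(area_um2[keep]),
    circularities = unname(circ[keep])
  ), class = "nuclei_segmentation")
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf("<nuclei_segmentation> %d nuclei, mean area %.1f um^2\n",
              x$count, if (x$count) mean(x$areas) else NA_real_))
  invisible(x)
}

#' Cell-area mask from the actin channel
#'
#' Thresholds the actin/autofluorescence channel, then closes and hole-fills
#' the mask so that cell interiors enclosed by the actin rim are included.
#'
#' @param actin_image 2D numeric matrix (8-bit scale).
#' @param threshold `"auto"` (Otsu) or a manual 8-bit value.
#' @param morph_radius Disc radius of the closing step (px).
#' @return Logical matrix marking cellular area.
#' @export
segment_cell_area_actin <- function(actin_image, threshold = "auto",
                                    morph_radius = 5) {
  img <- as.matrix(actin_image)
  if (!length(img)) abort("empty image")
  if (diff(range(img)) == 0) {
    # uniform frame: saturated -> everything cellular, blank -> nothing
    return(matrix(img[1] >= 128, nrow(img), ncol(img)))
  }
  thr01 <- if (identical(threshold, "auto")) EBImage::otsu(EBImage::Image(img / 255))
           else as.numeric(threshold) / 255
  mask <- img / 255 > thr01
  brush <- EBImage::makeBrush(2 * morph_radius + 1, shape = "disc")
  mask <- EBImage::closing(mask, brush)
  mask <- EBImage::fillHull(mask)
  matrix(as.logical(mask), nrow(img), ncol(img))
}

#' Cell-area mask from the brightfield channel
#'
#' Applied in order: percentile contrast enhancement, Canny edge detection,
#' maximum filter, binary closing and opening, hole filling; connected
#' regions smaller than the minimum nucleus area are discarded.
#'
#' @param bf_image 2D numeric matrix (8-bit scale).
#' @param params A [segmentation_params()].
#' @param pixel_size Pixel size in µm/px (for the small-region removal).
#' @return Logical matrix marking cellular area.
#' @export
segment_cell_area_brightfield <- function(bf_image,
                                          params = segmentation_params(),
                                          pixel_size = 0.684) {
  img <- as.matrix(bf_image)
  if (!length(img)) abort("empty image")
  if (diff(range(img)) == 0)
    return(matrix(FALSE, nrow(img), ncol(img)))
  # contrast enhancement: linear stretch between the given percentiles
  qs <- stats::quantile(img, params$contrast_percentiles / 100)
  if (diff(qs) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  stretched <- pmin(pmax((img - qs[1]) / diff(qs), 0), 1) * 255

  edges <- canny_edges(stretched, sigma = params$canny_sigma)
  if (!any(edges)) return(matrix(FALSE, nrow(img), ncol(img)))
  maxbrush <- EBImage::makeBrush(2 * params$maxfilter_radius + 1, "disc")
  mask <- EBImage::dilate(edges, maxbrush)
  brush <- EBImage::makeBrush(2 * params$morph_radius + 1, "disc")
  mask <- EBImage::closing(mask, brush)
  mask <- EBImage::fillHull(mask)
  mask <- EBImage::opening(mask, brush)
  # the maximum filter grew every edge outward by its radius, and the edge
  # ridge itself is 1-2 px wide; shrink the filled mask back so the boundary
  # tracks the outermost true edge
  mask <- EBImage::erode(mask, EBImage::makeBrush(2 * params$maxfilter_radius + 3,
                                                  "disc"))
  mask <- matrix(as.logical(mask), nrow(img), ncol(img))
  drop_small_regions(mask, params$min_nucleus_area / pixel_size^2)
}

drop_small_regions <- function(mask, min_px) {
  labs <- EBImage::bwlabel(mask)
  if (max(labs) == 0) return(mask)
  sizes <- tabulate(labs[labs > 0])
  small <- which(sizes < min_px)
  if (length(small)) mask[matrix(labs %in% small, nrow(mask), ncol(mask))] <- FALSE
  mask
}

# Canny edge detector: Gaussian smoothing, Sobel gradients, non-maximum
# suppression along the quantized gradient direction, hysteresis linking.
# The strong-edge threshold comes from Otsu on the gradient magnitudes, so
# it adapts to the fraction of the frame covered by textured objects.
canny_edges <- function(img, sigma = 2, low_frac = 0.4) {
  g <- EBImage::gblur(img / 255, sigma = sigma)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(g, kx)
  gy <- EBImage::filter2(g, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi
  dir <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  nms <- matrix(FALSE, nrow(mag), ncol(mag))
  for (d in 0:3) {
    o <- off[[d + 1]]
    n1 <- shift_mat(mag, o[1], o[2])
    n2 <- shift_mat(mag, -o[1], -o[2])
    nms <- nms | (dir == d & mag >= n1 & mag >= n2)
  }
  mx <- max(mag)
  if (mx <= 1e-8) return(matrix(FALSE, nrow(mag), ncol(mag)))
  high <- EBImage::otsu(EBImage::Image(mag / mx)) * mx
  low <- low_frac * high
  weak <- nms & mag >= low
  strong <- nms & mag >= high
  if (!any(strong)) return(matrix(FALSE, nrow(mag), ncol(mag)))
  labs <- EBImage::bwlabel(weak)
  keep <- unique(labs[strong])
  matrix(labs %in% keep[keep > 0], nrow(mag), ncol(mag))
}

shift_mat <- function(m, dx, dy) {
  n <- matrix(0, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1 & xs_src <= nrow(m)
  oky <- ys_src >= 1 & ys_src <= ncol(m)
  n[xs[okx], ys[oky]] <- m[xs_src[okx], ys_src[oky]]
  n
}

#' Calibrate the bead-fluorescence threshold from control images
#'
#' Pools the bead-channel intensities inside the cellular area of control
#' fields (cells never exposed to nanoparticles, so any signal is
#' autofluorescence) and returns a high percentile of that distribution,
#' rounded up. The value can always be overridden manually downstream.
#'
#' @param control_images List of 2D bead-channel matrices.
#' @param cell_masks List of logical masks matching `control_images`.
#' @param percentile Percentile of the pooled control intensities
#'   (default 99.95).
#' @return Integer 8-bit threshold in \[1, 255\].
#' @export
calibrate_bead_threshold <- function(control_images, cell_masks,
                                     percentile = 99.95) {
  if (!length(control_images)) abort("at least one control image is required")
  if (length(cell_masks) != length(control_images))
    abort("one cell mask per control image is required")
  vals <- unlist(purrr::map2(control_images, cell_masks,
                             function(img, m) as.matrix(img)[as.matrix(m)]))
  if (!length(vals)) abort("all control cell masks are empty")
  thr <- ceiling(stats::quantile(vals, percentile / 100, names = FALSE))
  as.integer(min(max(thr, 1), 255))
}

#' Mask bead-fluorescence pixels inside the cellular area
#'
#' Pixels at or above the threshold that also lie inside the cell mask;
#' everything outside cells is discarded so residual extracellular beads do
#' not contribute. The result is an 8-bit binary image with foreground 255.
#'
#' @param bead_image 2D numeric matrix (8-bit scale).
#' @param threshold 8-bit threshold in \[1, 255\].
#' @param cell_mask Logical matrix of cellular area.
#' @return Matrix with values in \{0, 255\}.
#' @export
mask_beads <- function(bead_image, threshold, cell_mask) {
  img <- as.matrix(bead_image)
  m <- as.matrix(cell_mask)
  if (!all(dim(img) == dim(m))) abort("bead image and cell mask differ in shape")
  if (threshold < 1 || threshold > 255) abort("threshold must lie in [1, 255]")
  (img >= threshold & (m > 0)) * 255
}

#' Count bead pixels in a binary mask
#'
#' Implements the published pixel-counting rule: the number of image pixels
#' times the mean gray value, divided by 255 - which for a \{0, 255\} binary
#' image equals the number of foreground pixels exactly.
#'
#' @param binary_mask Matrix with values in \{0, 255\}.
#' @return Integer foreground pixel count.
#' @export
count_bead_pixels <- function(binary_mask) {
  m <- as.matrix(binary_mask)
  if (!all(m %in% c(0, 255))) abort("mask must be binary with values 0 / 255")
  as.integer(round(length(m) * mean(m) / 255))
}

#' Bead pixels per cell
#'
#' @param bead_pixels Foreground bead-pixel count.
#' @param n_nuclei Number of nuclei in the field of view (>= 1).
#' @return `bead_pixels / n_nuclei`.
#' @export
beads_per_cell <- function(bead_pixels, n_nuclei) {
  if (n_nuclei == 0) abort("no cells detected (n_nuclei = 0)",
                           class = "psuptake_no_cells")
  bead_pixels / n_nuclei
}

#' Quantify nanoparticle uptake in one field of view
#'
#' End-to-end chain: z-projection, nuclei segmentation and counting,
#' cell-area masking (actin channel preferred; brightfield fallback when the
#' actin mask fails to cover the nuclei), bead-pixel masking inside the cell
#' area, and the bead-pixels-per-cell ratio.
#'
#' @param stack A [confocal_stack()] with at least `beads` and `nuclei`
#'   channels plus `actin` or `brightfield`.
#' @param params A [segmentation_params()].
#' @param bead_threshold Optional 8-bit bead threshold; required unless
#'   `params$bead_threshold` is numeric.
#' @param cell_line,concentration,time_h,replicate Metadata copied into the
#'   record.
#' @return One-row tibble (an uptake record): `bead_pixels`, `n_nuclei`,
#'   `bead_px_per_cell`, `bead_area_um2`, `fov_area_um2`, metadata columns
#'   and a `valid` flag (FALSE when no cells were detected).
#' @export
quantify_fov <- function(stack, params = segmentation_params(),
                         bead_threshold = NULL,
                         cell_line = NA_character_, concentration = NA_real_,
                         time_h = NA_real_, replicate = NA_integer_) {
  stopifnot(inherits(stack, "confocal_stack"))
  roles <- names(stack$channels)
  if (!all(c("beads", "nuclei") %in% roles))
    abort("stack must provide 'beads' and 'nuclei' channels")
  if (!any(c("actin", "brightfield") %in% roles))
    abort("stack must provide an 'actin' or 'brightfield' channel for cell-area masking")
  thr <- bead_threshold
  if (is.null(thr)) {
    if (is.numeric(params$bead_threshold)) thr <- params$bead_threshold
    else abort("bead threshold not set: pass bead_threshold= or a numeric params$bead_threshold")
  }
  proj <- z_project(stack)
  nuc <- segment_nuclei(proj$nuclei, params, stack$pixel_size)
  cell_mask <- NULL
  if ("actin" %in% roles) {
    cm <- segment_cell_area_actin(proj$actin, morph_radius = params$morph_radius)
    nuc_px <- nuc$label_image > 0
    # sufficient when it covers the segmented nuclei (or no nuclei exist to
    # judge by); otherwise fall back to brightfield
    covered <- if (any(nuc_px)) mean(cm[nuc_px]) else 1
    if (any(cm) && covered >= 0.5) cell_mask <- cm
  }
  if (is.null(cell_mask) && "brightfield" %in% roles) {
    cell_mask <- segment_cell_area_brightfield(proj$brightfield, params,
                                               stack$pixel_size)
  }
  if (is.null(cell_mask))
    abort("cell-area masking failed: actin mask insufficient and no brightfield channel")
  bead_mask <- mask_beads(proj$beads, thr, cell_mask)
  bead_pixels <- count_bead_pixels(bead_mask)
  valid <- nuc$count > 0
  bpc <- if (valid) beads_per_cell(bead_pixels, nuc$count) else {
    warn("no cells detected in field of view; record flagged invalid")
    NA_real_
  }
  d <- dim(stack)
  tibble::tibble(
    bead_pixels = bead_pixels,
    n_nuclei = nuc$count,
    bead_px_per_cell = bpc,
    bead_area_um2 = bead_pixels * stack$pixel_size^2,
    fov_area_um2 = d[1] * d[2] * stack$pixel_size^2,
    cell_line = cell_line,
    concentration = concentration,
    time_h = time_h,
    replicate = replicate,
    valid = valid
  )
}
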