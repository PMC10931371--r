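test_that("z-projection takes the per-channel maximum across planes", {
  one <- confocal_stack(list(nuclei = matrix(7, 4, 4)), pixel_size = 1)
  expect_equal(z_project(one)$nuclei, matrix(7, 4, 4))
  two <- array(0, dim = c(2, 2, 2))
  two[, , 1] <- 10; two[, , 2] <- 200
  st <- confocal_stack(list(nuclei = two), pixel_size = 1)
  expect_true(all(z_project(st)$nuclei == 200))
  expect_true(all(z_project(st, method = "sum")$nuclei == 210))
})

test_that("projected bead area covers every single plane's bead area", {
  fx <- make_confocal_fixture(width = 128, height = 128, n_cells = 4, nz = 4,
                              concentration = 31.25, noise_sd = 0, seed = 11)
  proj <- z_project(fx$stack)$beads
  per_plane <- vapply(1:4, function(z) sum(fx$stack$channels$beads[, , z] >= 100),
                      numeric(1))
  expect_gte(sum(proj >= 100), max(per_plane))
})

test_that("nuclei segmentation recovers planted, well-separated disks", {
  expect_equal(segment_nuclei(matrix(0, 64, 64), segmentation_params(), 1)$count, 0)

  # 12 disks of about 60 um^2 (r = 4.4 px at 1 um/px), min area 20 um^2
  centers <- as.matrix(expand.grid(x = c(30, 70, 110, 150),
                                   y = c(40, 100, 160)))
  img <- disk_image(200, centers, rep(4.4, 12))
  seg <- segment_nuclei(img, segmentation_params(min_nucleus_area = 20), 1)
  expect_equal(seg$count, 12)
  expect_true(all(seg$areas >= 20))

  # 30 um^2 disk retained, 8 um^2 disk filtered at the A549/CaCo-2 profile
  # (0.5 um/px; manual threshold, as the blurred small disk otherwise smears
  # into a faint but above-Otsu blob)
  p2 <- segmentation_params(cell_line = "A549", nuclei_threshold = 100)
  img2 <- disk_image(120, rbind(c(40, 60), c(90, 60)),
                     c(sqrt(30 / pi), sqrt(8 / pi)) / 0.5)
  seg2 <- segment_nuclei(img2, p2, 0.5)
  expect_equal(seg2$count, 1)
  expect_true(all(seg2$areas >= 10))
})

test_that("watershed splits two overlapping nuclei", {
  r <- 8
  # centers 1.8 r apart: overlap of about 20% of the radius
  img <- disk_image(80, rbind(c(32, 40), c(32 + 1.8 * r, 40)), c(r, r))
  seg <- segment_nuclei(img, segmentation_params(min_nucleus_area = 20), 1)
  expect_equal(seg$count, 2)
})

test_that("raising the minimum area never increases the nuclei count", {
  fx <- make_confocal_fixture(width = 192, height = 192, n_cells = 6, nz = 2,
                              concentration = 0, seed = 12)
  img <- z_project(fx$stack)$nuclei
  counts <- vapply(c(5, 20, 60, 120), function(a)
    segment_nuclei(img, segmentation_params(min_nucleus_area = a),
                   fx$stack$pixel_size)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("actin masking covers planted cell areas and rejects background", {
  expect_false(any(segment_cell_area_actin(matrix(0, 32, 32))))
  expect_true(all(segment_cell_area_actin(matrix(255, 32, 32))))
  fx <- make_confocal_fixture(width = 192, height = 192, n_cells = 5, nz = 2,
                              concentration = 0, seed = 13)
  m <- segment_cell_area_actin(z_project(fx$stack)$actin)
  expect_gte(mean(m[fx$truth_cell_mask]), 0.95)
})

test_that("brightfield masking recovers cells from edges and texture", {
  expect_false(any(segment_cell_area_brightfield(matrix(50, 64, 64),
                                                 segmentation_params(), 1)))
  fx <- make_confocal_fixture(width = 256, height = 256, n_cells = 6, nz = 2,
                              concentration = 0, seed = 14)
  m <- segment_cell_area_brightfield(z_project(fx$stack)$brightfield,
                                     segmentation_params(cell_line = "THP-1"),
                                     fx$stack$pixel_size)
  tr <- fx$truth_cell_mask
  expect_gte(mean(m[tr]), 0.9)
  expect_gte(sum(m & tr) / sum(m | tr), 0.7)

  # single high-contrast disk comes back as a filled disk
  img <- matrix(120, 128, 128)
  truth <- (row(img) - 64)^2 + (col(img) - 64)^2 <= 30^2
  img[truth] <- 40
  md <- segment_cell_area_brightfield(img, segmentation_params(), 1)
  expect_gte(sum(md & truth) / sum(md | truth), 0.85)
})

test_that("bead threshold calibration follows the control distribution", {
  m <- matrix(TRUE, 50, 50)
  expect_equal(calibrate_bead_threshold(list(matrix(0, 50, 50)), list(m)), 1L)
  expect_equal(calibrate_bead_threshold(list(matrix(10, 50, 50)), list(m)), 10L)
  withr::with_seed(15, {
    ctrl <- matrix(rnorm(400 * 400, mean = 20, sd = 2), 400, 400)
  })
  thr <- calibrate_bead_threshold(list(ctrl), list(matrix(TRUE, 400, 400)))
  expect_true(thr %in% c(27L, 28L))
  # planted beads at 200 all survive that threshold
  expect_true(all(200 >= thr))
  expect_error(calibrate_bead_threshold(list(), list()), "at least one")
  expect_error(calibrate_bead_threshold(list(ctrl), list(matrix(FALSE, 400, 400))),
               "empty")
})

test_that("bead masking respects threshold and cell area", {
  img <- matrix(0, 40, 40); img[5, 5] <- 250
  outside <- matrix(FALSE, 40, 40); outside[20:40, ] <- TRUE
  expect_equal(sum(mask_beads(img, 100, outside)), 0)
  img2 <- matrix(254, 8, 8)
  expect_equal(sum(mask_beads(img2, 255, matrix(TRUE, 8, 8))), 0)
  expect_error(mask_beads(img, 100, matrix(TRUE, 3, 3)), "shape")
})

test_that("bead recall and false positives behave at the calibrated threshold", {
  ctrl <- make_confocal_fixture(width = 256, height = 256, n_cells = 6, nz = 2,
                                concentration = 0, seed = 16)
  cm <- segment_cell_area_actin(z_project(ctrl$stack)$actin)
  thr <- calibrate_bead_threshold(list(z_project(ctrl$stack)$beads), list(cm))
  fx <- make_confocal_fixture(width = 256, height = 256, n_cells = 6, nz = 2,
                              concentration = 31.25, seed = 17)
  proj <- z_project(fx$stack)
  mask <- mask_beads(proj$beads, thr, segment_cell_area_actin(proj$actin))
  tr <- fx$truth_bead_mask
  expect_gte(sum(mask > 0 & tr) / sum(tr), 0.95)
  # false positives scored over pixels carrying no bead signal at all, so
  # the faint halo of each sub-resolution punctum is not miscounted
  clean <- fx$truth_bead_signal < 0.05 * 200
  expect_lte(sum(mask > 0 & clean) / sum(clean), 0.01)
})

test_that("pixel counting matches brute-force foreground counts exactly", {
  m <- disk_mask(10, 5, 5, 3)
  expect_identical(count_bead_pixels(m), as.integer(sum(m == 255)))
  expect_identical(count_bead_pixels(matrix(0, 12, 12)), 0L)
  expect_identical(count_bead_pixels(matrix(255, 64, 64)), 4096L)
  expect_error(count_bead_pixels(matrix(c(0, 128), 2, 2)), "binary")
})

test_that("beads per cell divides and guards the empty field", {
  expect_equal(beads_per_cell(50, 10), 5)
  expect_equal(beads_per_cell(0, 7), 0)
  expect_equal(beads_per_cell(17, 4), 4.25)
  expect_error(beads_per_cell(10, 0), class = "psuptake_no_cells")
})

test_that("raising the bead threshold never increases the count", {
  fx <- make_confocal_fixture(width = 192, height = 192, n_cells = 5, nz = 2,
                              concentration = 31.25, seed = 18)
  proj <- z_project(fx$stack)
  cm <- segment_cell_area_actin(proj$actin)
  counts <- vapply(c(30, 80, 150, 220), function(t)
    count_bead_pixels(mask_beads(proj$beads, t, cm)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("beads planted outside the cell mask contribute nothing", {
  img <- matrix(0, 60, 60)
  img[50, 50] <- 240   # bright punctum far from any cell
  cellm <- matrix(FALSE, 60, 60); cellm[10:25, 10:25] <- TRUE
  expect_equal(count_bead_pixels(mask_beads(img, 100, cellm)), 0L)
})

test_that("end-to-end quantification matches planted truth", {
  fx0 <- make_confocal_fixture(width = 192, height = 192, n_cells = 6, nz = 2,
                               concentration = 0, seed = 19)
  rec0 <- quantify_fov(fx0$stack, segmentation_params(cell_line = "THP-1"),
                       bead_threshold = 100)
  expect_equal(rec0$bead_px_per_cell, 0)
  expect_true(rec0$valid)

  fx <- make_confocal_fixture(width = 256, height = 256, n_cells = 8, nz = 3,
                              concentration = 31.25, seed = 20)
  rec <- quantify_fov(fx$stack, segmentation_params(cell_line = "THP-1"),
                      bead_threshold = 100)
  truth_ratio <- sum(fx$truth_bead_mask) / fx$truth_nuclei_count
  expect_equal(rec$n_nuclei, fx$truth_nuclei_count)
  expect_lt(abs(rec$bead_px_per_cell - truth_ratio) / truth_ratio, 0.25)

  rec2 <- quantify_fov(fx$stack, segmentation_params(cell_line = "THP-1"),
                       bead_threshold = 100)
  expect_identical(rec, rec2)
})

test_that("a field with no cells is flagged invalid with a warning", {
  blank <- confocal_stack(list(
    beads = array(0, c(64, 64, 1)),
    nuclei = array(0, c(64, 64, 1)),
    actin = array(255, c(64, 64, 1))), pixel_size = 1)
  expect_warning(rec <- quantify_fov(blank, segmentation_params(),
                                     bead_threshold = 100), "no cells")
  expect_false(rec$valid)
  expect_true(is.na(rec$bead_px_per_cell))
})
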