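test_that("raman fixtures are deterministic in the seed", {
  a <- make_raman_fixture(nx = 12, ny = 12, nz = 2, seed = 1)
  b <- make_raman_fixture(nx = 12, ny = 12, nz = 2, seed = 1)
  expect_identical(a$cube$intensities, b$cube$intensities)
  expect_identical(a$layout, b$layout)
  c <- make_raman_fixture(nx = 12, ny = 12, nz = 2, seed = 2)
  expect_false(identical(a$cube$intensities, c$cube$intensities))
})

test_that("noiseless cubes equal the planted mixture exactly", {
  fx <- noiseless_cube(seed = 3)
  recon <- fx$truth_abundance %*% fx$truth_endmembers$spectra
  expect_lt(max(abs(recon - fx$cube$intensities)) /
              max(abs(fx$cube$intensities)), 1e-10)
  expect_true(all(fx$truth_abundance >= 0))
  expect_length(fx$layout, prod(dim(fx$cube)))
})

test_that("spiked pixels carry one large single-channel excursion", {
  fx <- make_raman_fixture(nx = 20, ny = 20, nz = 1,
                           n_ps_clusters = 2, n_lipid_droplets = 2,
                           snr = Inf, baseline_degree = 0,
                           spike_fraction = 0.05, seed = 4)
  clean <- noiseless_cube(seed = 4, nx = 20)$cube$intensities
  # same seed, same layout draw: difference isolates the spikes
  d <- fx$cube$intensities - clean
  spiked_px <- which(rowSums(d != 0) > 0)
  expect_length(spiked_px, floor(0.05 * 400))
  for (i in spiked_px[1:5]) {
    expect_equal(sum(d[i, ] != 0), 1)
    ch <- which(d[i, ] != 0)
    expect_gte(d[i, ch], 20 * clean[i, ch] - 1e-9)
  }
})

test_that("spike fraction outside [0, 0.05] is rejected", {
  expect_error(make_raman_fixture(nx = 8, ny = 8, spike_fraction = 0.2,
                                  seed = 1), "spike_fraction")
  expect_error(make_raman_fixture(nx = 8, ny = 8, snr = -1, seed = 1), "snr")
})

test_that("confocal fixtures are deterministic and zero-dose has no beads", {
  a <- make_confocal_fixture(width = 128, height = 128, n_cells = 5, nz = 2,
                             concentration = 0, seed = 5)
  b <- make_confocal_fixture(width = 128, height = 128, n_cells = 5, nz = 2,
                             concentration = 0, seed = 5)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth_nuclei_labels, b$truth_nuclei_labels)
  expect_false(any(a$truth_bead_mask))
  expect_equal(a$truth_nuclei_count, 5)
})

test_that("ground truth is internally consistent", {
  fx <- make_confocal_fixture(width = 192, height = 192, n_cells = 6, nz = 3,
                              concentration = 31.25, seed = 6)
  # distinct labels match the reported count
  expect_equal(length(setdiff(unique(as.vector(fx$truth_nuclei_labels)), 0)),
               fx$truth_nuclei_count)
  # label components are connected
  labs <- EBImage::bwlabel(fx$truth_nuclei_labels > 0)
  expect_equal(max(labs), fx$truth_nuclei_count)
  # bead mask lies inside the planted cell area
  expect_true(all(fx$truth_cell_mask[fx$truth_bead_mask]))
})

test_that("planted bead area grows with exposure concentration", {
  mean_area <- function(conc) {
    mean(vapply(1:25, function(s) {
      fx <- make_confocal_fixture(width = 128, height = 128, n_cells = 5,
                                  nz = 2, concentration = conc,
                                  seed = 7000 + s)
      sum(fx$truth_bead_mask)
    }, numeric(1)))
  }
  areas <- vapply(c(7.81, 15.63, 31.25), mean_area, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("dose-response sets follow the planted line", {
  exact <- make_dose_response_set(2, 1, noise_sd = 0, n_replicates = 3,
                                  seed = 8)
  expect_equal(exact$bead_px_per_cell, 1 + 2 * exact$concentration)
  flat <- make_dose_response_set(0, 5, noise_sd = 0, n_replicates = 2,
                                 seed = 8)
  expect_true(all(flat$bead_px_per_cell == 5))
  expect_setequal(unique(exact$concentration), c(7.81, 15.63, 31.25))
  expect_identical(make_dose_response_set(2, 1, 1, 4, seed = 9),
                   make_dose_response_set(2, 1, 1, 4, seed = 9))
  expect_error(make_dose_response_set(2, 1, 1, n_replicates = 1, seed = 1),
               "n_replicates")
})

test_that("OLS slope estimates from generated sets are unbiased", {
  slopes <- vapply(1:200, function(s) {
    df <- make_dose_response_set(2, 5, noise_sd = 1, n_replicates = 10,
                                 seed = 9000 + s)
    fit_dose_response(df)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 2), 0.05)
})
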