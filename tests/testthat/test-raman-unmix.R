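test_that("N-FINDR recovers planted endmembers from noiseless cubes", {
  fx <- noiseless_cube(seed = 31)
  em <- nfindr_extract(fx$cube, k = 3, n_restarts = 5, seed = 32)
  cs <- match_cosines(em$spectra, fx$truth_endmembers$spectra)
  expect_true(all(cs >= 0.999))
  # returned endmembers are actual pixel spectra
  expect_true(all(em$indices %in% seq_len(nrow(fx$cube$intensities))))
  for (i in seq_len(em$k))
    expect_equal(em$spectra[i, ], fx$cube$intensities[em$indices[i], ])
})

test_that("accepted simplex volumes increase strictly", {
  fx <- noiseless_cube(seed = 33)
  em <- nfindr_extract(fx$cube, k = 3, n_restarts = 3, seed = 34)
  tr <- attr(em, "volume_trace")
  expect_true(all(diff(tr) > 0))
})

test_that("degenerate unmixing requests fail loudly", {
  ax <- seq(600, 1700, by = 2)
  same <- raman_cube(ax, matrix(rep(ref_spec <- runif(length(ax)), 9),
                                9, byrow = TRUE), c(3, 3, 1))
  one <- nfindr_extract(same, k = 1, n_restarts = 1, seed = 1)
  expect_equal(drop(one$spectra), same$intensities[1, ])
  expect_error(nfindr_extract(same, k = 3, n_restarts = 1, seed = 1),
               "rank-deficient|distinct")
  small <- raman_cube(ax, matrix(runif(2 * length(ax)), 2), c(2, 1, 1))
  expect_error(nfindr_extract(small, k = 5, n_restarts = 1, seed = 1),
               "exceeds")
})

test_that("NNLS returns exact abundances for exact mixtures", {
  ax <- seq(600, 1700, by = 2)
  e1 <- ref_vec("polystyrene", ax)
  e2 <- ref_vec("lipid", ax)
  em <- endmember_set(ax, rbind(e1, e2))
  px <- rbind(e1, 0.3 * e1 + 0.7 * e2, 0 * e1)
  cube <- raman_cube(ax, px, c(3, 1, 1))
  ab <- nnls_abundances(cube, em)
  expect_equal(ab$abundance[1, ], c(1, 0), tolerance = 1e-8)
  expect_equal(ab$abundance[2, ], c(0.3, 0.7), tolerance = 1e-6)
  expect_equal(ab$abundance[3, ], c(0, 0))
  expect_true(all(ab$abundance >= 0))
})

test_that("abundances are non-negative on noisy cubes", {
  fx <- make_raman_fixture(nx = 10, ny = 10, nz = 1, seed = 35)
  pre <- preprocess(fx$cube)
  em <- nfindr_extract(pre, k = 3, n_restarts = 3, seed = 36)
  ab <- nnls_abundances(pre, em)
  expect_true(all(ab$abundance >= 0))
  expect_true(all(ab$residual >= 0))
})

test_that("truth endmembers reconstruct noiseless cubes almost exactly", {
  fx <- noiseless_cube(seed = 37)
  ab <- nnls_abundances(fx$cube, fx$truth_endmembers)
  recon <- ab$abundance %*% fx$truth_endmembers$spectra
  rel <- abs(recon - fx$cube$intensities) / max(fx$cube$intensities)
  expect_lt(max(rel), 1e-6)
})

test_that("band images light up planted polystyrene regions", {
  ax <- seq(600, 3100, by = 2)
  uni <- raman_cube(ax, matrix(2, 16, length(ax)), c(4, 4, 1))
  bi <- band_intensity_image(uni)
  expect_true(all(bi$images[[1]] == 2))

  fx <- noiseless_cube(seed = 38)
  bi2 <- band_intensity_image(fx$cube, center = 1000, width = 25)
  vals <- as.vector(bi2$images[[1]])
  ps <- fx$layout == "polystyrene"
  water <- fx$layout == "water"
  expect_gt(mean(vals[ps]), 3 * mean(vals[water]))

  pre <- preprocess(fx$cube)
  expect_error(band_intensity_image(pre, center = 2200, width = 25),
               "no channels")
})

test_that("endmember classification assigns by spectral similarity", {
  ax <- seq(600, 3100, by = 2)
  ps <- ref_vec("polystyrene", ax)
  em <- endmember_set(ax, rbind(ps, 2 * ps))
  cl <- classify_endmembers(em)
  expect_equal(cl$labels, c("polystyrene", "polystyrene"))

  withr::with_seed(39, noise <- abs(rnorm(length(ax))))
  cl2 <- classify_endmembers(endmember_set(ax, rbind(noise)))
  expect_equal(cl2$labels, "unassigned")

  lip <- ref_vec("lipid", ax)
  cl3 <- classify_endmembers(endmember_set(ax, rbind(lip)))
  expect_equal(cl3$labels, "lipid")
})

test_that("layout matching pairs endmembers with planted components", {
  fx <- noiseless_cube(seed = 40)
  em <- nfindr_extract(fx$cube, k = 3, n_restarts = 5, seed = 41)
  ab <- nnls_abundances(fx$cube, em)
  m <- match_endmembers_to_layout(ab, fx$layout)
  expect_setequal(names(m), c("lipid", "polystyrene", "water"))
  expect_equal(sort(unname(m)), 1:3)
  # the matched polystyrene endmember really is polystyrene
  truth_ps <- fx$truth_endmembers$spectra[
    fx$truth_endmembers$labels == "polystyrene", ]
  expect_gte(cosine(em$spectra[m[["polystyrene"]], ], truth_ps), 0.999)
})

test_that("peak detection finds the published polystyrene bands", {
  ax <- seq(600, 3100, by = 2)
  ps <- ref_vec("polystyrene", ax)
  pk <- peak_positions(ps, ax, prominence_fraction = 0.1)
  for (b in c(621, 1001, 1604)) expect_true(any(abs(pk - b) <= 2))
})
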