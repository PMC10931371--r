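# shared helpers for building tiny fixtures in code

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# best cosine match of each truth endmember among extracted spectra
match_cosines <- function(extracted, truth) {
  vapply(seq_len(nrow(truth)), function(j) {
    max(vapply(seq_len(nrow(extracted)),
               function(i) cosine(extracted[i, ], truth[j, ]), numeric(1)))
  }, numeric(1))
}

# small noiseless three-component cube with guaranteed pure pixels
noiseless_cube <- function(seed, nx = 20, ny = 20) {
  make_raman_fixture(nx = nx, ny = ny, nz = 1,
                     n_ps_clusters = 2, n_lipid_droplets = 2,
                     snr = Inf, baseline_degree = 0, spike_fraction = 0,
                     seed = seed)
}

# binary 0/255 mask with a planted disk
disk_mask <- function(n, cx, cy, r) {
  xg <- matrix(seq_len(n), n, n)
  yg <- t(xg)
  ((xg - cx)^2 + (yg - cy)^2 <= r^2) * 255
}

# 2D image with disks of given centers/radii at a set intensity
disk_image <- function(n, centers, radii, value = 200, background = 0) {
  img <- matrix(background, n, n)
  xg <- matrix(seq_len(n), n, n)
  yg <- t(xg)
  for (i in seq_len(nrow(centers))) {
    img[(xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= radii[i]^2] <- value
  }
  img
}

# vector form of a reference spectrum
ref_vec <- function(label, axis) reference_spectrum(label, axis)$intensity
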