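#' N-FINDR endmember extraction
#'
#' Searches for the `k` pixel spectra spanning the maximum-volume simplex in
#' the (k-1)-dimensional principal-component projection of the cube, under the
#' pure-pixel assumption: each pure component is present unmixed in at least
#' one pixel, so the simplex vertices are actual measured spectra. Starting
#' from `k` random pixels, single-vertex replacements are accepted only when
#' they strictly increase the simplex volume, until no replacement improves;
#' the best of `n_restarts` seeded restarts is returned.
#'
#' @param cube A (preprocessed) [raman_cube()]; degenerate pixels are
#'   excluded.
#' @param k Number of endmembers (>= 1).
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Integer seed (mandatory; restarts are seeded).
#' @return An [endmember_set()] whose `indices` are pixel row indices into
#'   the cube, `volume` the attained simplex volume, and attribute
#'   `volume_trace` the accepted-volume sequence of the winning restart.
#' @export
nfindr_extract <- function(cube, k, n_restarts = 5, seed) {
  stopifnot(inherits(cube, "raman_cube"))
  if (missing(seed)) abort("a seed is mandatory for N-FINDR restarts")
  if (k < 1) abort("k must be at least 1")
  good <- which(!cube$degenerate)
  if (k > length(good)) abort("k exceeds the number of non-degenerate pixels")
  X <- cube$intensities[good, , drop = FALSE]
  if (k == 1) {
    i <- good[1]
    return(endmember_set(cube$axis, cube$intensities[i, , drop = FALSE],
                         indices = i, volume = 0))
  }
  pc <- stats::prcomp(X, center = TRUE, rank. = k - 1)
  if (ncol(pc$x) < k - 1 ||
      pc$sdev[k - 1] < 1e-10 * max(pc$sdev[1], .Machine$double.eps))
    abort("fewer distinct spectral components than k (rank-deficient cube)")
  Y <- pc$x[, seq_len(k - 1), drop = FALSE]
  P <- cbind(1, Y)                       # rows: [1, y_1 .. y_{k-1}]
  npx <- nrow(P)

  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      idx <- sample.int(npx, k)
      M <- t(P[idx, , drop = FALSE])     # k x k, columns are vertices
      vol <- abs(det(M))
      trace <- vol
      repeat {
        improved <- FALSE
        for (j in seq_len(k)) {
          # the determinant with column j replaced by candidate p is linear
          # in p; cofactor expansion gives its coefficients even when the
          # current simplex is degenerate (volume 0)
          cf <- cofactor_column(M, j)
          vals <- abs(drop(P %*% cf))
          cand <- which.max(vals)
          if (vals[cand] > vol * (1 + 1e-12) + .Machine$double.xmin &&
              !(cand %in% idx)) {
            idx[j] <- cand
            M[, j] <- P[cand, ]
            vol <- vals[cand]
            trace <- c(trace, vol)
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      if (is.null(best) || vol > best$vol)
        best <- list(idx = idx, vol = vol, trace = trace)
    }
  })
  em_idx <- good[best$idx]
  out <- endmember_set(cube$axis, cube$intensities[em_idx, , drop = FALSE],
                       indices = em_idx,
                       volume = best$vol / factorial(k - 1))
  attr(out, "volume_trace") <- best$trace / factorial(k - 1)
  out
}

# signed cofactors of column j: det(M with column j <- v) == sum(v * cf)
cofactor_column <- function(M, j) {
  k <- nrow(M)
  vapply(seq_len(k), function(i) {
    (-1)^(i + j) * det(M[-i, -j, drop = FALSE])
  }, numeric(1))
}

#' Non-negative least-squares abundance maps
#'
#' Per pixel, solves min ||E a - s|| subject to a >= 0 where the columns of E
#' are the endmember spectra. No sum-to-one constraint is imposed; the
#' per-pixel residual norm is kept for quality control. Degenerate pixels
#' receive zero abundances.
#'
#' @param cube A (preprocessed) [raman_cube()].
#' @param endmembers An [endmember_set()] on the same axis, with linearly
#'   independent spectra.
#' @return An object of class `abundance_stack`: `abundance` (pixels x k
#'   matrix), `residual` (per-pixel norm), `dims`, `labels`.
#' @export
nnls_abundances <- function(cube, endmembers) {
  stopifnot(inherits(cube, "raman_cube"), inherits(endmembers, "endmember_set"))
  if (length(endmembers$axis) != length(cube$axis))
    abort("endmember axis does not match the cube axis")
  E <- t(endmembers$spectra)            # channels x k
  if (qr(E)$rank < ncol(E)) abort("endmember spectra are linearly dependent")
  npix <- nrow(cube$intensities)
  k <- ncol(E)
  A <- matrix(0, npix, k)
  res <- numeric(npix)
  for (i in seq_len(npix)) {
    if (cube$degenerate[i]) next
    s <- cube$intensities[i, ]
    if (all(s == 0)) next
    fit <- pracma::lsqnonneg(E, s)
    A[i, ] <- fit$x
    res[i] <- sqrt(max(fit$resid.norm, 0))
  }
  structure(list(abundance = A, residual = res, dims = cube$dims,
                 labels = endmembers$labels),
            class = "abundance_stack")
}

#' @export
print.abundance_stack <- function(x, ...) {
  cat(sprintf("<abundance_stack> %d pixels x %d endmembers (%s)\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' @describeIn nnls_abundances Long-format view of an abundance stack
#'   (`x`, `y`, `z`, `endmember`, `label`, `abundance`).
#' @param x An `abundance_stack`.
#' @param ... Unused.
#' @export
as_tibble.abundance_stack <- function(x, ...) {
  co <- expand.grid(x = seq_len(x$dims[1]), y = seq_len(x$dims[2]),
                    z = seq_len(x$dims[3]), KEEP.OUT.ATTRS = FALSE)
  k <- ncol(x$abundance)
  em <- rep(seq_len(k), each = nrow(co))
  lab <- rep(x$labels, each = nrow(co))
  ab <- as.vector(x$abundance)
  tibble::tibble(
    x = rep(co$x, times = k),
    y = rep(co$y, times = k),
    z = rep(co$z, times = k),
    endmember = em,
    label = lab,
    abundance = ab
  )
}

#' Univariate band-intensity image
#'
#' Mean intensity per pixel over the channels inside the window
#' `center +/- width/2`, one image per z plane - the classic quick look at
#' e.g. the polystyrene ring-breathing band around 1000 cm\eqn{^{-1}}
#' (width 25 cm\eqn{^{-1}}).
#'
#' @param cube A [raman_cube()].
#' @param center Window center (cm\eqn{^{-1}}), default 1000.
#' @param width Window width (cm\eqn{^{-1}}), default 25.
#' @return An object of class `band_image`: `center`, `width`, `images`
#'   (list of matrices, one per z plane).
#' @export
band_intensity_image <- function(cube, center = 1000, width = 25) {
  stopifnot(inherits(cube, "raman_cube"))
  keep <- cube$axis >= center - width / 2 & cube$axis <= center + width / 2
  if (!any(keep))
    abort("band window contains no channels (is it inside the cut silent region?)")
  vals <- rowMeans(cube$intensities[, keep, drop = FALSE])
  d <- cube$dims
  images <- lapply(seq_len(d[3]), function(z) {
    matrix(vals[((z - 1) * d[1] * d[2] + 1):(z * d[1] * d[2])], d[1], d[2])
  })
  structure(list(center = center, width = width, images = images),
            class = "band_image")
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Assign component labels to extracted endmembers
#'
#' Each endmember receives the library component whose reference spectrum
#' (evaluated on the working axis) has the highest cosine similarity;
#' endmembers below `min_similarity` stay `"unassigned"`. Several endmembers
#' may share a label - polystyrene typically appears twice, at different
#' intensities.
#'
#' @param endmembers An [endmember_set()].
#' @param library Band library, see [band_library()].
#' @param min_similarity Minimum cosine similarity for assignment
#'   (default 0.5).
#' @return The `endmember_set` with `labels` filled in and a `similarity`
#'   attribute (endmember x component matrix).
#' @export
classify_endmembers <- function(endmembers, library = band_library(),
                                min_similarity = 0.5) {
  stopifnot(inherits(endmembers, "endmember_set"))
  comps <- unique(library$component)
  if (!length(comps)) abort("component library is empty")
  refs <- vapply(comps, function(lb)
    ref_spectrum_vec(lb, endmembers$axis, library), numeric(length(endmembers$axis)))
  sim <- matrix(0, endmembers$k, length(comps),
                dimnames = list(NULL, comps))
  for (i in seq_len(endmembers$k)) {
    em <- pmax(endmembers$spectra[i, ], 0)   # compare emission-like shape
    sim[i, ] <- vapply(seq_along(comps),
                       function(j) cosine_similarity(em, refs[, j]), numeric(1))
  }
  lab <- comps[max.col(sim)]
  lab[apply(sim, 1, max) < min_similarity] <- "unassigned"
  endmembers$labels <- lab
  attr(endmembers, "similarity") <- sim
  endmembers
}

#' Match endmembers to a planted component layout
#'
#' Identifies which extracted endmember corresponds to each planted component
#' by correlating its abundance map with the component's indicator over the
#' planted layout, assigning greedily from the strongest correlation down,
#' one endmember per component.
#'
#' @param abundances An `abundance_stack`.
#' @param layout Character vector of planted component labels per pixel.
#' @return Named integer vector: for each component present in `layout`, the
#'   matched endmember index.
#' @export
match_endmembers_to_layout <- function(abundances, layout) {
  stopifnot(inherits(abundances, "abundance_stack"))
  comps <- sort(unique(layout))
  A <- abundances$abundance
  if (length(layout) != nrow(A)) abort("layout length does not match pixel count")
  score <- matrix(-Inf, ncol(A), length(comps),
                  dimnames = list(NULL, comps))
  for (j in seq_along(comps)) {
    ind <- as.numeric(layout == comps[j])
    if (stats::sd(ind) == 0) next
    for (e in seq_len(ncol(A)))
      score[e, j] <- suppressWarnings(stats::cor(A[, e], ind))
  }
  score[!is.finite(score)] <- -Inf
  out <- stats::setNames(rep(NA_integer_, length(comps)), comps)
  sc <- score
  for (step in seq_len(min(dim(sc)))) {
    pos <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    out[comps[pos[2]]] <- pos[1]
    sc[pos[1], ] <- -Inf
    sc[, pos[2]] <- -Inf
    if (all(!is.finite(sc))) break
  }
  out
}
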