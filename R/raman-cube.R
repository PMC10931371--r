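#' Construct a Raman hyperspectral cube
#'
#' A cube couples a strictly increasing wavenumber axis with one spectrum per
#' spatial pixel on an `nx` by `ny` grid, optionally over several z planes.
#' Pixels are stored row-major with x varying fastest, matching
#' `expand.grid(x, y, z)` order.
#'
#' @param axis Strictly increasing wavenumber axis (cm\eqn{^{-1}}).
#' @param intensities Numeric matrix, one row per pixel, `length(axis)`
#'   columns.
#' @param dims Integer vector `c(nx, ny, nz)`.
#' @param step Spatial step size in µm (x/y).
#' @param z_step z-plane spacing in µm.
#' @param degenerate Optional logical vector flagging pixels excluded from
#'   unmixing (e.g. zero after preprocessing).
#' @return An object of class `raman_cube`.
#' @export
raman_cube <- function(axis, intensities, dims, step = 0.5, z_step = 1.5,
                       degenerate = NULL) {
  axis <- as.numeric(axis)
  if (length(axis) == 0) abort("wavenumber axis is empty")
  if (any(diff(axis) <= 0)) abort("wavenumber axis must be strictly increasing")
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(axis))
    abort("intensity matrix must have one column per wavenumber channel")
  dims <- as.integer(dims)
  if (length(dims) == 2) dims <- c(dims, 1L)
  if (prod(dims) != nrow(intensities))
    abort("grid dimensions do not match the number of pixel spectra")
  if (is.null(degenerate)) degenerate <- rep(FALSE, nrow(intensities))
  structure(
    list(axis = axis, intensities = intensities, dims = dims,
         step = step, z_step = z_step, degenerate = degenerate),
    class = "raman_cube"
  )
}

#' @export
print.raman_cube <- function(x, ...) {
  cat(sprintf(
    "<raman_cube> %d x %d x %d pixels, %d channels (%.0f-%.0f cm-1), step %.2g um\n",
    x$dims[1], x$dims[2], x$dims[3], length(x$axis),
    min(x$axis), max(x$axis), x$step))
  invisible(x)
}

#' @export
dim.raman_cube <- function(x) x$dims

cube_coords <- function(cube) {
  d <- cube$dims
  expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]),
              KEEP.OUT.ATTRS = FALSE)
}

#' Long-format view of a Raman cube
#'
#' @param x A `raman_cube`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `z`, `wavenumber`, `intensity`.
#' @export
as_tibble.raman_cube <- function(x, ...) {
  co <- cube_coords(x)
  nchan <- length(x$axis)
  wn <- rep(x$axis, times = nrow(co))
  iv <- as.vector(t(x$intensities))
  tibble::tibble(
    x = rep(co$x, each = nchan),
    y = rep(co$y, each = nchan),
    z = rep(co$z, each = nchan),
    wavenumber = wn,
    intensity = iv
  )
}

#' Read / write a Raman cube
#'
#' Two containers are supported, chosen by file extension: a long-format CSV
#' (`x, y, z, wavenumber, intensity`; text, order-independent) and an RDS
#' binary container that round-trips the axis and intensities exactly.
#'
#' @param cube A `raman_cube`.
#' @param path File path ending in `.csv` or `.rds`.
#' @param step,z_step Spatial steps (µm) used when reading a CSV, which does
#'   not carry them.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns a
#'   `raman_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "raman_cube"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(cube, path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- as_tibble(cube)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    abort("unsupported cube container (use .csv or .rds)")
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, step = 0.5, z_step = 1.5) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    cube <- readRDS(path)
    if (!inherits(cube, "raman_cube")) abort("RDS file does not hold a raman_cube")
    return(cube)
  }
  if (!grepl("\\.csv$", path, ignore.case = TRUE))
    abort("unsupported cube container (use .csv or .rds)")
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "wavenumber", "intensity")
  if (!all(need %in% names(df))) abort("cube CSV must have columns x, y, z, wavenumber, intensity")
  axis <- sort(unique(df$wavenumber))
  if (any(diff(axis) <= 0)) abort("wavenumber axis must be strictly increasing")
  df <- df[order(df$z, df$y, df$x, df$wavenumber), ]
  dims <- c(length(unique(df$x)), length(unique(df$y)), length(unique(df$z)))
  npix <- prod(dims)
  if (nrow(df) != npix * length(axis))
    abort("ragged cube: every pixel must carry the full wavenumber axis")
  key <- paste(df$x, df$y, df$z)
  per_pixel <- table(key)
  if (any(per_pixel != length(axis)) ||
      anyDuplicated(df[c("x", "y", "z", "wavenumber")]))
    abort("ragged cube: duplicate or missing wavenumbers for some pixels")
  intens <- matrix(df$intensity, nrow = npix, ncol = length(axis), byrow = TRUE)
  raman_cube(axis, intens, dims, step = step, z_step = z_step)
}
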