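#' Construct a multi-channel confocal z-stack
#'
#' Channels are named by role (`beads`, `nuclei`, `actin`, `brightfield`) and
#' stored as 3D arrays (`width` x `height` x `z`), 8-bit intensity range
#' 0-255. All channels must share dimensions.
#'
#' @param channels Named list of 3D numeric arrays (a 2D matrix is treated as
#'   a single-plane stack).
#' @param pixel_size Pixel size in µm/px (> 0).
#' @param z_step z spacing in µm.
#' @return An object of class `confocal_stack`.
#' @export
confocal_stack <- function(channels, pixel_size, z_step = 1) {
  if (!length(channels) || is.null(names(channels)))
    abort("channels must be a named list")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    if (length(dim(ch)) != 3) abort("each channel must be a 2D or 3D array")
    ch
  })
  d <- dim(channels[[1]])
  for (ch in channels) {
    if (!identical(dim(ch), d)) abort("all channels must share dimensions")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    abort("pixel_size must be positive")
  structure(list(channels = channels, pixel_size = pixel_size,
                 z_step = z_step),
            class = "confocal_stack")
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<confocal_stack> %d x %d px, %d z-planes, %.3g um/px; channels: %s\n",
              d[1], d[2], d[3], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.confocal_stack <- function(x) dim(x$channels[[1]])

#' Write / read a confocal stack as per-channel multi-page TIFF
#'
#' Each channel role is written as `<role>.tif` (one page per z plane, 8-bit)
#' next to a `stack.json` sidecar holding pixel size, z step and the channel
#' roles.
#'
#' @param stack A `confocal_stack`.
#' @param dir Directory to write into (created if missing).
#' @return `write_stack` returns `dir` invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "confocal_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (role in names(stack$channels)) {
    ch <- stack$channels[[role]]
    pages <- lapply(seq_len(dim(ch)[3]), function(z) {
      pmin(pmax(ch[, , z], 0), 255) / 255
    })
    tiff::writeTIFF(pages, file.path(dir, paste0(role, ".tif")),
                    bits.per.sample = 8)
  }
  meta <- list(pixel_size = stack$pixel_size, z_step = stack$z_step,
               channels = names(stack$channels))
  jsonlite::write_json(meta, file.path(dir, "stack.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @param channel_map Optional named character vector mapping roles to TIFF
#'   file names (without directory); defaults to `<role>.tif` per the sidecar.
#' @param pixel_size Optional pixel size override (µm/px). When it conflicts
#'   with the sidecar metadata the override wins with a warning.
#' @param z_step Optional z-step override (µm).
#' @export
read_stack <- function(dir, channel_map = NULL, pixel_size = NULL,
                       z_step = NULL) {
  meta_path <- file.path(dir, "stack.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list()
  roles <- if (!is.null(channel_map)) names(channel_map)
           else unlist(meta$channels)
  if (is.null(roles) || !length(roles))
    abort("no channel roles: provide channel_map or a stack.json sidecar")
  channels <- list()
  for (role in roles) {
    fname <- if (!is.null(channel_map)) channel_map[[role]]
             else paste0(role, ".tif")
    path <- file.path(dir, fname)
    if (!file.exists(path))
      abort(paste0("missing channel '", role, "' (file ", fname, ")"))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- as.integer(round(pages[[z]] * 255))
    channels[[role]] <- arr
  }
  ps <- meta$pixel_size
  if (!is.null(pixel_size)) {
    if (!is.null(ps) && !isTRUE(all.equal(ps, pixel_size)))
      warn(sprintf("pixel size: config %.4g um/px overrides metadata %.4g um/px",
                   pixel_size, ps))
    ps <- pixel_size
  }
  if (is.null(ps)) abort("pixel size not available from metadata or argument")
  zs <- if (!is.null(z_step)) z_step else if (!is.null(meta$z_step)) meta$z_step else 1
  confocal_stack(channels, pixel_size = ps, z_step = zs)
}
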