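#' Multi-channel 3D image stack
#'
#' Container for a deconvolved multi-channel fluorescence acquisition: a
#' numeric array indexed `[y, x, z, channel]` plus a role for each channel.
#' Recognised roles are `"nuclear_stain"` (DAPI), `"ddr_marker"` (e.g. 53BP1
#' or pKAP1), `"telomere_marker"` (e.g. TRF1/TRF2) and `"lamin"` (lamin A/C).
#'
#' @param data numeric array, `dim = c(height, width, n_sections, n_channels)`.
#'   A 3D array is promoted to a single-channel stack.
#' @param channels character vector of channel roles, one per channel slab.
#' @param pixel_size_um optional physical pixel size (micrometres).
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, channels, pixel_size_um = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L, length(channels) == dim(data)[4L])
  if (any(data < 0)) stop("intensities must be nonnegative")
  dimnames(data) <- list(NULL, NULL, NULL, channels)
  structure(
    list(data = data, channels = as.character(channels),
         pixel_size_um = pixel_size_um),
    class = "image_stack")
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack an [image_stack]
#' @param role channel role to extract
#' @return numeric array `[y, x, z]`
#' @export
stack_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  i <- match(role, stack$channels)
  if (is.na(i))
    stop("channel role '", role, "' not present (have: ",
         paste(stack$channels, collapse = ", "), ")")
  stack$data[, , , i, drop = TRUE]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack %d x %d px, %d z-sections, %d channel(s): %s>\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Write a stack as a multi-page TIFF
#'
#' Pages are ordered z-within-channel; channel roles, z-count, intensity
#' scale and pixel size are written to a JSON sidecar (`<path>.json`) so
#' that [read_stack()] can restore the stack losslessly. Intensities are
#' stored as 32-bit samples scaled to the unit interval.
#'
#' @param stack an [image_stack]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1)  # writeTIFF stores samples in [0, 1]
  pages <- list()
  for (ci in seq_len(d[4])) for (zi in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- stack$data[, , zi, ci] / scale
  meta <- jsonlite::toJSON(list(channels = stack$channels, n_z = d[3],
                                scale = scale,
                                pixel_size_um = stack$pixel_size_um),
                           auto_unbox = TRUE, null = "null")
  writeLines(as.character(meta), paste0(path, ".json"))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF file path
#' @return an [image_stack]
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("no stack metadata found for ", path)
  meta <- jsonlite::fromJSON(sidecar)
  n_z <- meta$n_z
  n_c <- length(pages) / n_z
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], n_z, n_c))
  k <- 1L
  for (ci in seq_len(n_c)) for (zi in seq_len(n_z)) {
    arr[, , zi, ci] <- pages[[k]] * (meta$scale %||% 1)
    k <- k + 1L
  }
  image_stack(arr, meta$channels, meta$pixel_size_um %||% NULL)
}
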