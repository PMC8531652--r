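#' Image stacks
#'
#' An `image_stack` wraps a 3D voxel intensity array together with its pixel
#' size metadata. It is the unit of training and evaluation: one stack
#' corresponds to one imaged slice culture. Arrays are laid out `(y, x, z)`
#' so that `stack$data[, , k]` is the k-th z-slice as an ordinary R matrix.
#'
#' Point coordinates used throughout the package are 1-based `(x, y, z)`
#' voxel indices (`x` = column, `y` = row, `z` = slice). On-disk JSON uses
#' 0-based `(x, y, z)`; the readers and writers convert.
#'
#' @param data numeric 3D array, dimensions `(y, x, z)`. A matrix is
#'   promoted to a single-slice stack.
#' @param pixel_size_um in-plane pixel size in micrometres (default 0.52,
#'   the acquisition scale all size thresholds are calibrated to).
#' @param z_step_um axial step between slices in micrometres (default 2).
#' @param stack_id optional identifier string.
#' @return an `image_stack` object (list with `data`, `pixel_size_um`,
#'   `z_step_um`, `stack_id`).
#' @export
image_stack <- function(data, pixel_size_um = 0.52, z_step_um = 2,
                        stack_id = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L, all(dim(data) > 0L))
  storage.mode(data) <- "double"
  structure(
    list(data = data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         stack_id = stack_id),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack '%s': %d x %d px, %d slice(s), %.3g um/px, z-step %.3g um\n",
              if (is.null(x$stack_id)) "?" else x$stack_id,
              d[2], d[1], d[3], x$pixel_size_um, x$z_step_um))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Read / write a stack as a multi-page TIFF
#'
#' One TIFF page per z-slice, 32-bit float samples. Intensities are written
#' as-is; stacks should be on a [0, 1]-ish scale before writing (TIFF float
#' pages carry arbitrary values but [0,1] keeps viewers happy).
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @param pixel_size_um,z_step_um metadata to attach on read (TIFF tags are
#'   not relied upon).
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$data)[3]), function(k) stack$data[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, pixel_size_um = 0.52, z_step_um = 2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  image_stack(data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
              stack_id = sub("\\.tiff?$", "", basename(path)))
}

#' Normalize a stack to the unit interval
#'
#' Affinely rescales the whole stack so its minimum maps to 0 and its
#' maximum to 1. All feature generation assumes this normalization, which
#' makes the bank invariant to global intensity scaling of the raw data.
#' A constant stack has no dynamic range and maps to all zeros with a
#' warning.
#'
#' @param stack an [image_stack()].
#' @return the normalized [image_stack()].
#' @export
normalize_stack <- function(stack) {
  rng <- range(stack$data)
  if (rng[1] == rng[2]) {
    warning("constant stack: normalizing to all zeros")
    stack$data[] <- 0
    return(stack)
  }
  stack$data <- (stack$data - rng[1]) / (rng[2] - rng[1])
  stack
}

#' Maximum-intensity z-projection
#'
#' @param stack an [image_stack()] or 3D array.
#' @return a matrix (y, x).
#' @export
max_projection <- function(stack) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  if (dim(a)[3] == 1L) return(a[, , 1])
  apply(a, c(1, 2), max)
}

# internal: linear index into (y,x,z) array from 1-based x/y/z vectors
vox_index <- function(x, y, z, dims) {
  as.integer((y - 1) + dims[1] * ((x - 1) + dims[2] * (z - 1)) + 1)
}
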