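#' Reference feature-bank configuration
#'
#' The spatial feature bank highlights bright, compact, circular structure
#' against diffuse background. The reference configuration has exactly 116
#' channels, composed as:
#'
#' * Gaussian derivatives at `sigma` 1, 3, 6 px: first and second derivative
#'   along x, y, z, the mixed x&y derivative (first and second order per
#'   axis) and the mixed x&y&z derivative (first and second order per axis)
#'   - 10 directions x 3 scales = 30 channels.
#' * Laguerre-Gauss filters (`s = 0.5`, `q = 2`, `r = 0`,
#'   `p, l` in 0..2), applied per z-slice: 9 response channels, plus the
#'   first and second Gaussian derivatives (sigma 1 px) of each response
#'   along x, y and z (54 channels), plus the 9 LGF responses of the
#'   structure-tensor coherency image - 72 channels.
#' * White top-hat transforms with disc diameters 3, 4, 5, 7, 9, 13, 15,
#'   18 px - 8 channels.
#' * Local entropy filters with window sizes 3, 5, 7, 9, 13, 17 px - 6
#'   channels.
#'
#' Filter sizes cover the typical 5-15 px pycnotic nucleus with a margin at
#' both ends.
#'
#' @param sigmas Gaussian derivative scales (px).
#' @param lgf_p,lgf_l Laguerre-Gauss radial/azimuthal order grids.
#' @param lgf_s,lgf_q,lgf_r Laguerre-Gauss shape parameters.
#' @param lgf_deriv_sigma scale (px) of the Gaussian derivatives taken of
#'   each LGF response.
#' @param tophat_sizes white top-hat disc diameters (px).
#' @param entropy_sizes local-entropy window sizes (px).
#' @param entropy_levels gray-level quantization for the entropy filter.
#' @param coherency_sigma_grad,coherency_sigma_tensor structure tensor
#'   scales (px).
#' @param pixel_size_um reference pixel size; stacks deviating from it by
#'   more than 5% are resampled before feature generation (the bank's size
#'   parameters are calibrated to this resolution).
#' @return a `feature_config` list.
#' @export
feature_config <- function(sigmas = c(1, 3, 6),
                           lgf_p = 0:2, lgf_l = 0:2,
                           lgf_s = 0.5, lgf_q = 2, lgf_r = 0,
                           lgf_deriv_sigma = 1,
                           tophat_sizes = c(3, 4, 5, 7, 9, 13, 15, 18),
                           entropy_sizes = c(3, 5, 7, 9, 13, 17),
                           entropy_levels = 64L,
                           coherency_sigma_grad = 1,
                           coherency_sigma_tensor = 3,
                           pixel_size_um = 0.52) {
  cfg <- structure(
    list(sigmas = sigmas, lgf_p = lgf_p, lgf_l = lgf_l, lgf_s = lgf_s,
         lgf_q = lgf_q, lgf_r = lgf_r, lgf_deriv_sigma = lgf_deriv_sigma,
         tophat_sizes = tophat_sizes, entropy_sizes = entropy_sizes,
         entropy_levels = as.integer(entropy_levels),
         coherency_sigma_grad = coherency_sigma_grad,
         coherency_sigma_tensor = coherency_sigma_tensor,
         pixel_size_um = pixel_size_um),
    class = "feature_config"
  )
  cfg
}

# the ten derivative multi-directions: orders (y, x, z) per axis
derivative_directions <- function() {
  list(dx1 = c(0, 1, 0), dx2 = c(0, 2, 0),
       dy1 = c(1, 0, 0), dy2 = c(2, 0, 0),
       dz1 = c(0, 0, 1), dz2 = c(0, 0, 2),
       dxy1 = c(1, 1, 0), dxy2 = c(2, 2, 0),
       dxyz1 = c(1, 1, 1), dxyz2 = c(2, 2, 2))
}

#' Channel registry of a feature configuration
#'
#' Enumerates every channel the configuration generates, with its bank and
#' generating parameters. The reference configuration yields exactly 116
#' uniquely named channels.
#'
#' @param config a [feature_config()].
#' @return data frame with columns `channel`, `bank`, `name`.
#' @export
feature_registry <- function(config = feature_config()) {
  rows <- list()
  add <- function(bank, name) rows[[length(rows) + 1L]] <<- data.frame(bank = bank, name = name)
  for (s in config$sigmas)
    for (d in names(derivative_directions()))
      add("gaussian_derivative", sprintf("gauss_%s_s%g", d, s))
  for (p in config$lgf_p)
    for (l in config$lgf_l)
      add("lgf", sprintf("lgf_p%d_l%d", p, l))
  for (p in config$lgf_p)
    for (l in config$lgf_l)
      for (d in c("dx1", "dx2", "dy1", "dy2", "dz1", "dz2"))
        add("lgf_derivative", sprintf("lgf_p%d_l%d_%s", p, l, d))
  for (p in config$lgf_p)
    for (l in config$lgf_l)
      add("lgf_coherency", sprintf("lgf_p%d_l%d_coh", p, l))
  for (sz in config$tophat_sizes) add("tophat", sprintf("tophat_%g", sz))
  for (sz in config$entropy_sizes) add("entropy", sprintf("entropy_%g", sz))
  out <- do.call(rbind, rows)
  out$channel <- seq_len(nrow(out))
  out[, c("channel", "bank", "name")]
}

# R grows its vector-heap GC trigger only gradually, so once a large output
# matrix is live, almost every filter allocation forces a full collection.
# Reserving the expected working set once up front raises the trigger and
# keeps the bank's per-channel allocations cheap.
reserve_heap <- function(n_doubles) {
  tmp <- numeric(min(n_doubles, 2.5e8))
  tmp[1] <- 1
  invisible(NULL)
}

# resample a stack's slices to the reference pixel size (bilinear)
resample_to_reference <- function(stack, pixel_size_um) {
  ratio <- stack$pixel_size_um / pixel_size_um
  if (abs(ratio - 1) <= 0.05) return(stack)
  d <- dim(stack$data)
  ny <- max(2L, round(d[1] * ratio)); nx <- max(2L, round(d[2] * ratio))
  out <- array(0, dim = c(ny, nx, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- EBImage::resize(stack$data[, , k], w = ny, h = nx)
  image_stack(out, pixel_size_um = pixel_size_um, z_step_um = stack$z_step_um,
              stack_id = stack$stack_id)
}

#' Build the full feature volume of a stack
#'
#' Normalizes the stack to `[0, 1]`, resamples it to the reference pixel
#' size if needed, and computes every channel of the configuration. With
#' `voxels` given (linear indices into the `(y, x, z)` array), only those
#' rows are retained, which keeps the memory footprint proportional to the
#' labeled voxels while each filter still runs on the full volume.
#'
#' @param stack an [image_stack()].
#' @param config a [feature_config()].
#' @param voxels optional integer vector of linear voxel indices.
#' @return a `feature_volume`: list with `values` (voxels x channels
#'   matrix), `registry`, `dim` (stack dims) and `voxels`.
#' @export
build_feature_volume <- function(stack, config = feature_config(),
                                 voxels = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  stack <- resample_to_reference(stack, config$pixel_size_um)
  stack <- suppressWarnings(normalize_stack(stack))
  a <- stack$data
  dims <- dim(a)
  reg <- feature_registry(config)
  n_out <- if (is.null(voxels)) prod(dims) else length(voxels)
  if (is.null(voxels)) reserve_heap((nrow(reg) + 30) * prod(dims))
  # preallocated once and filled column-wise in place (no closure, so the
  # matrix keeps reference count 1 and columns are written without copies)
  values <- matrix(0, n_out, nrow(reg))
  full <- is.null(voxels)
  any_truncated <- FALSE
  col <- 0L

  for (s in config$sigmas)
    for (d in derivative_directions()) {
      v <- gaussian_derivative3d(a, s, d)
      if (isTRUE(attr(v, "truncated"))) any_truncated <- TRUE
      col <- col + 1L
      values[, col] <- if (full) as.vector(v) else v[voxels]
    }

  lgf_responses <- vector("list", length(config$lgf_p) * length(config$lgf_l))
  li <- 0L
  for (p in config$lgf_p)
    for (l in config$lgf_l) {
      kern <- lgf_kernel(p, l, config$lgf_s, config$lgf_q, config$lgf_r)
      resp <- a
      for (k in seq_len(dims[3])) resp[, , k] <- conv2d_reflect(a[, , k], kern)
      li <- li + 1L
      lgf_responses[[li]] <- resp
      col <- col + 1L
      values[, col] <- if (full) as.vector(resp) else resp[voxels]
    }
  for (resp in lgf_responses)
    for (d in derivative_directions()[c("dx1", "dx2", "dy1", "dy2", "dz1", "dz2")]) {
      v <- gaussian_derivative3d(resp, config$lgf_deriv_sigma, d)
      col <- col + 1L
      values[, col] <- if (full) as.vector(v) else v[voxels]
    }
  rm(lgf_responses)

  if (length(config$lgf_p) > 0 && length(config$lgf_l) > 0) {
    coh <- coherency_image(a, config$coherency_sigma_grad,
                           config$coherency_sigma_tensor)
    for (p in config$lgf_p)
      for (l in config$lgf_l) {
        kern <- lgf_kernel(p, l, config$lgf_s, config$lgf_q, config$lgf_r)
        resp <- coh
        for (k in seq_len(dims[3])) resp[, , k] <- conv2d_reflect(coh[, , k], kern)
        col <- col + 1L
        values[, col] <- if (full) as.vector(resp) else resp[voxels]
      }
  }

  for (sz in config$tophat_sizes) {
    col <- col + 1L
    v <- tophat_filter(a, sz)
    values[, col] <- if (full) as.vector(v) else v[voxels]
  }
  for (sz in config$entropy_sizes) {
    col <- col + 1L
    v <- entropy_filter(a, sz, config$entropy_levels)
    values[, col] <- if (full) as.vector(v) else v[voxels]
  }

  if (col != nrow(reg))
    stop(sprintf("channel count mismatch: computed %d, registry lists %d",
                 col, nrow(reg)))
  if (any_truncated)
    warning("z kernels reduced to fit the stack's z extent")
  colnames(values) <- reg$name
  structure(list(values = values, registry = reg, dim = dims,
                 voxels = voxels),
            class = "feature_volume")
}

#' @export
print.feature_volume <- function(x, ...) {
  cat(sprintf("feature_volume: %d voxels x %d channels (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$registry$bank), collapse = ", ")))
  invisible(x)
}

#' Fit / apply the PCA de-correlation
#'
#' Features in the bank are strongly correlated (e.g. top-hat transforms of
#' neighboring sizes), so a centered, scaled PCA is fitted on labeled
#' training voxels and its components replace the raw channels for all
#' classification steps.
#'
#' @param samples numeric matrix (voxels x channels) of labeled training
#'   voxels; with fewer rows than channels the component count is truncated
#'   with a warning.
#' @param scale divide channels by their standard deviation before the
#'   rotation (constant channels get unit scale).
#' @param max_rows random subsample cap applied before fitting (memory
#'   guard); `seed` controls the subsample.
#' @param seed RNG seed for the subsample.
#' @return a `pca_model`: `rotation`, `center`, `scale`, `var_explained`.
#' @export
fit_pca <- function(samples, scale = TRUE, max_rows = 5e5, seed = 1L) {
  stopifnot(is.matrix(samples), nrow(samples) >= 2)
  if (nrow(samples) > max_rows) {
    samples <- withr::with_seed(seed,
      samples[sample.int(nrow(samples), max_rows), , drop = FALSE])
  }
  if (nrow(samples) <= ncol(samples))
    warning("fewer samples than channels: component count truncated")
  scl <- if (scale) {
    s <- apply(samples, 2, sd)
    s[s == 0 | !is.finite(s)] <- 1
    s
  } else FALSE
  fit <- prcomp(samples, center = TRUE, scale. = scl)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(rotation = fit$rotation,
                 center = fit$center,
                 scale = if (isFALSE(scl)) rep(1, ncol(samples)) else scl,
                 var_explained = ev),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param x a matrix or `feature_volume` to project.
#' @param model a `pca_model`.
#' @param k number of leading components to keep (default: all).
#' @return `project_pca`: matrix of component scores (voxels x k).
#' @export
project_pca <- function(x, model, k = NULL) {
  m <- if (inherits(x, "feature_volume")) x$values else x
  stopifnot(ncol(m) == nrow(model$rotation))
  scores <- sweep(sweep(m, 2, model$center), 2, model$scale, `/`) %*%
    model$rotation
  if (!is.null(k)) scores <- scores[, seq_len(k), drop = FALSE]
  scores
}

# project onto a column subset of the rotation only (cheaper than scoring
# all components when just the ranked top-k are consumed)
project_pca_cols <- function(m, model, cols) {
  stopifnot(ncol(m) == nrow(model$rotation))
  sweep(sweep(m, 2, model$center), 2, model$scale, `/`) %*%
    model$rotation[, cols, drop = FALSE]
}

#' Components needed to explain a variance fraction
#'
#' @param model a `pca_model`.
#' @param fraction target fraction of total variance, in `(0, 1]`.
#' @return smallest component count whose cumulative explained variance
#'   reaches `fraction`.
#' @export
components_for_variance <- function(model, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  cum <- cumsum(model$var_explained)
  idx <- which(cum >= fraction - 1e-12)
  if (length(idx) == 0) length(cum) else idx[1]
}

#' Write the explained-variance table of a PCA model
#'
#' @param model a `pca_model`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_pca_variance <- function(model, path) {
  df <- data.frame(component = seq_along(model$var_explained),
                   var_explained = model$var_explained,
                   cumulative = cumsum(model$var_explained))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
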