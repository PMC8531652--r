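#' Expert annotations for one stack
#'
#' Point clicks mark (a subset of) the PI-positive pycnotic nuclei; planar
#' polygons outline true-negative background regions. Coordinates are
#' 1-based `(x, y, z)` voxel indices in memory; the JSON files use 0-based
#' coordinates.
#'
#' @param clicks data frame with columns `x`, `y`, `z`.
#' @param negative_polygons list of `list(z, x, y)`: a z-slice index and the
#'   ordered polygon vertices (continuous pixel coordinates, at least 3).
#' @param stack_id optional identifier.
#' @return an `annotation_set`.
#' @export
annotation_set <- function(clicks, negative_polygons = list(), stack_id = NULL) {
  stopifnot(is.data.frame(clicks), all(c("x", "y", "z") %in% names(clicks)))
  for (p in negative_polygons)
    if (length(p$x) < 3 || length(p$x) != length(p$y))
      stop("negative polygons need at least 3 vertices with matching x/y")
  structure(list(clicks = clicks, negative_polygons = negative_polygons,
                 stack_id = stack_id),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s': %d clicks, %d negative polygons\n",
              if (is.null(x$stack_id)) "?" else x$stack_id,
              nrow(x$clicks), length(x$negative_polygons)))
  invisible(x)
}

#' Read / write annotations as JSON
#'
#' The schema stores clicks as 0-based `[x, y, z]` triplets and polygons as
#' `{z, x: [...], y: [...]}` with 0-based coordinates.
#'
#' @param ann an [annotation_set()].
#' @param path file path.
#' @export
write_annotations <- function(ann, path) {
  obj <- list(
    stack_id = ann$stack_id,
    clicks = unname(lapply(seq_len(nrow(ann$clicks)), function(i)
      c(ann$clicks$x[i] - 1, ann$clicks$y[i] - 1, ann$clicks$z[i] - 1))),
    negative_polygons = unname(lapply(ann$negative_polygons, function(p)
      list(z = p$z - 1, x = p$x - 1, y = p$y - 1)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  clicks <- if (length(obj$clicks) == 0) {
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
  } else {
    m <- if (is.matrix(obj$clicks)) obj$clicks else do.call(rbind, obj$clicks)
    data.frame(x = m[, 1] + 1, y = m[, 2] + 1, z = m[, 3] + 1)
  }
  polys <- lapply(seq_along(obj$negative_polygons$z), function(i)
    list(z = obj$negative_polygons$z[[i]] + 1,
         x = unlist(obj$negative_polygons$x[i]) + 1,
         y = unlist(obj$negative_polygons$y[i]) + 1))
  if (is.null(obj$negative_polygons$z)) {
    polys <- lapply(obj$negative_polygons, function(p)
      list(z = p$z + 1, x = unlist(p$x) + 1, y = unlist(p$y) + 1))
  }
  annotation_set(clicks, polys, stack_id = obj$stack_id)
}

#' h-maxima transform and significant-maximum domes
#'
#' `hmaxima_transform` suppresses local maxima shallower than depth `h` by
#' grayscale reconstruction of `f - h` under `f`. The voxels where the
#' original image still exceeds the reconstruction (`dome_mask`) form the
#' "domes" of the significant maxima: compact caps of height up to `h`
#' around each surviving peak. These domes are what expert clicks are
#' snapped to and what seeds a nucleus' positive pixel region.
#'
#' @param stack an [image_stack()] normalized to `[0, 1]`, or 3D array.
#' @param h maximum depth (intensity units on the normalized scale, > 0).
#' @param tol numeric tolerance for dome membership.
#' @return `hmaxima_transform`: the reconstructed array; `dome_mask`: a
#'   logical array marking dome voxels.
#' @export
hmaxima_transform <- function(stack, h) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  stopifnot(h > 0)
  reconstruct_dilate3d(a - h, a)
}

#' @rdname hmaxima_transform
#' @export
dome_mask <- function(stack, h, tol = 1e-9) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  (a - hmaxima_transform(a, h)) > tol
}

#' Snap expert clicks to significant local maxima
#'
#' Clicking on a bright nucleus rarely hits its intensity peak exactly.
#' Each click is therefore moved to the brightest voxel of the h-maxima
#' dome nearest to it (within `search_radius`), by hill-climbing within the
#' dome's connected component until a fixed point is reached - so refining
#' already-refined seeds changes nothing. Clicks with no dome within reach
#' are flagged, not dropped.
#'
#' @param stack an [image_stack()] normalized to `[0, 1]`.
#' @param clicks data frame with `x`, `y`, `z` (1-based voxel coordinates).
#' @param h h-maxima depth (default 0.1 on the normalized scale).
#' @param search_radius in-plane search radius in px (default 5, matched to
#'   the 5-15 px nucleus scale).
#' @return data frame `x`, `y`, `z`, `flagged`; flagged rows keep their
#'   original coordinates.
#' @export
refine_clicks_hmax <- function(stack, clicks, h = 0.1, search_radius = 5) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  rng <- diff(range(a))
  if (h >= rng)
    stop(sprintf(
      "h = %g is at least the dynamic range %g: all maxima suppressed (affects all %d clicks)",
      h, rng, nrow(clicks)))
  dm <- dome_mask(a, h)
  labs <- label_components3d(dm)
  dims <- dim(a)
  n <- nrow(clicks)
  out <- data.frame(x = clicks$x, y = clicks$y, z = clicks$z,
                    flagged = logical(n))
  if (n == 0) return(out)

  ball <- function(cx, cy, cz) {
    xs <- max(1, floor(cx - search_radius)):min(dims[2], ceiling(cx + search_radius))
    ys <- max(1, floor(cy - search_radius)):min(dims[1], ceiling(cy + search_radius))
    zs <- max(1, cz - 1):min(dims[3], cz + 1)
    g <- expand.grid(y = ys, x = xs, z = zs)
    d2 <- (g$x - cx)^2 + (g$y - cy)^2
    g[d2 <= search_radius^2, , drop = FALSE]
  }

  for (i in seq_len(n)) {
    cx <- clicks$x[i]; cy <- clicks$y[i]; cz <- clicks$z[i]
    idx0 <- vox_index(cx, cy, cz, dims)
    comp <- if (dm[idx0]) labs[idx0] else {
      b <- ball(cx, cy, cz)
      bi <- vox_index(b$x, b$y, b$z, dims)
      in_dome <- dm[bi]
      if (!any(in_dome)) {
        out$flagged[i] <- TRUE
        next
      }
      d2 <- (b$x - cx)^2 + (b$y - cy)^2 + (b$z - cz)^2
      labs[bi[in_dome][which.min(d2[in_dome])]]
    }
    # hill-climb inside the component until the position is a fixed point
    px <- cx; py <- cy; pz <- cz
    repeat {
      b <- ball(px, py, pz)
      bi <- vox_index(b$x, b$y, b$z, dims)
      ok <- labs[bi] == comp
      if (!any(ok)) break
      vals <- a[bi[ok]]
      best <- which.max(vals)
      bx <- b$x[ok][best]; by <- b$y[ok][best]; bz <- b$z[ok][best]
      if (bx == px && by == py && bz == pz) break
      px <- bx; py <- by; pz <- bz
    }
    out$x[i] <- px; out$y[i] <- py; out$z[i] <- pz
  }
  out
}

#' Rasterize negative polygons into a binary volume
#'
#' Marks every pixel whose center lies strictly inside a polygon on that
#' polygon's z-slice, using the even-odd (crossing number) fill rule.
#' Pixel centers on a polygon edge count as outside.
#'
#' @param polygons list of `list(z, x, y)` planar polygons (vertices in
#'   continuous pixel coordinates, 1-based frame).
#' @param shape `(z, y, x)` voxel counts of the target volume.
#' @return logical array `(y, x, z)`.
#' @export
rasterize_negatives <- function(polygons, shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  vol <- array(FALSE, dim = c(ny, nx, nz))
  for (p in polygons) {
    if (length(p$x) < 3) stop("polygon with fewer than 3 vertices")
    xs <- max(1, floor(min(p$x))):min(nx, ceiling(max(p$x)))
    ys <- max(1, floor(min(p$y))):min(ny, ceiling(max(p$y)))
    if (length(xs) == 0 || length(ys) == 0) next
    g <- expand.grid(y = ys, x = xs)
    inside <- point_in_polygon(g$x, g$y, p$x, p$y)
    sl <- vol[, , p$z]
    sl[cbind(g$y[inside], g$x[inside])] <- TRUE
    vol[, , p$z] <- sl
  }
  vol
}

# even-odd crossing-number test, vectorized over query points; strictly
# inside (boundary points are outside)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint[crosses])
    }
    j <- i
  }
  inside
}

#' Build a ternary per-voxel label mask
#'
#' Positive voxels are the h-maxima dome component containing each refined
#' seed, clipped to a ball of `max_radius` px around the seed (the in-plane
#' half of the largest typical nucleus); negative voxels come from the
#' rasterized polygon volume; everything else stays unlabeled. A voxel
#' claimed by both classes resolves to positive with a warning, since
#' clicks are deliberate point statements while polygons are coarse
#' regions.
#'
#' @param stack an [image_stack()] normalized to `[0, 1]`.
#' @param seeds refined seed data frame from [refine_clicks_hmax()]
#'   (flagged seeds are skipped).
#' @param negative_volume logical array from [rasterize_negatives()].
#' @param h h-maxima depth used for the dome decomposition.
#' @param max_radius clip radius in px around each seed (default 15).
#' @return a `label_mask`: list with `mask` (integer array, 0 = unlabeled,
#'   1 = negative, 2 = positive), `n_positive`, `n_negative`.
#' @export
build_label_mask <- function(stack, seeds = NULL, negative_volume = NULL,
                             h = 0.1, max_radius = 15) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  dims <- dim(a)
  mask <- array(0L, dim = dims)
  if (!is.null(negative_volume)) mask[negative_volume] <- 1L

  if (!is.null(seeds) && nrow(seeds) > 0) {
    use <- if ("flagged" %in% names(seeds)) !seeds$flagged else rep(TRUE, nrow(seeds))
    if (any(use)) {
      dm <- dome_mask(a, h)
      labs <- label_components3d(dm)
      pos <- array(FALSE, dim = dims)
      for (i in which(use)) {
        idx <- vox_index(seeds$x[i], seeds$y[i], seeds$z[i], dims)
        comp <- labs[idx]
        if (comp == 0L) next
        xs <- max(1, floor(seeds$x[i] - max_radius)):min(dims[2], ceiling(seeds$x[i] + max_radius))
        ys <- max(1, floor(seeds$y[i] - max_radius)):min(dims[1], ceiling(seeds$y[i] + max_radius))
        zs <- seq_len(dims[3])
        g <- expand.grid(y = ys, x = xs, z = zs)
        keep <- (g$x - seeds$x[i])^2 + (g$y - seeds$y[i])^2 <= max_radius^2
        gi <- vox_index(g$x[keep], g$y[keep], g$z[keep], dims)
        pos[gi[labs[gi] == comp]] <- TRUE
      }
      conflict <- pos & (mask == 1L)
      if (any(conflict))
        warning(sprintf("%d voxel(s) labeled both positive and negative; resolved to positive",
                        sum(conflict)))
      mask[pos] <- 2L
    }
  }
  structure(list(mask = mask,
                 n_positive = sum(mask == 2L),
                 n_negative = sum(mask == 1L)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d positive, %d negative, %d unlabeled voxels\n",
              x$n_positive, x$n_negative,
              length(x$mask) - x$n_positive - x$n_negative))
  invisible(x)
}

#' Read / write a label mask as an 8-bit multi-page TIFF
#'
#' Values 0 (unlabeled), 1 (negative), 2 (positive); the round trip is
#' bit-exact.
#'
#' @param label a `label_mask`.
#' @param path file path.
#' @export
write_label_mask <- function(label, path) {
  pages <- lapply(seq_len(dim(label$mask)[3]),
                  function(k) label$mask[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask <- array(as.integer(round(unlist(pages) * 255)),
                dim = c(dim(pages[[1]]), length(pages)))
  structure(list(mask = mask, n_positive = sum(mask == 2L),
                 n_negative = sum(mask == 1L)),
            class = "label_mask")
}
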