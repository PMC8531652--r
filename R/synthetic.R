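#' Configuration for synthetic stack generation
#'
#' The generator emulates the statistical structure of propidium-iodide
#' stained slice-culture stacks that the segmentation pipeline assumes:
#' bright, roughly circular pycnotic nuclei 5-15 px across on a smooth,
#' region-dependent background with additive noise, optional touching
#' nucleus pairs, and an incompletely labeling expert.
#'
#' The two damage classes mirror the qualitative difference between lesioned
#' and control cultures: `"high"` stacks carry more nuclei and a stronger
#' background field than `"low"` stacks. Class presets fill `n_nuclei` and
#' `background` when these are not given explicitly.
#'
#' @param shape integer vector `(z, y, x)` of voxel counts. The default
#'   8 x 256 x 256 is the desk-scale working size; pixel metadata stays at
#'   0.52 um/px so all size thresholds transfer to full-size acquisitions.
#' @param n_nuclei number of nuclei, or `NULL` to use the damage-class
#'   preset (high: 50, low: 30 at the reference 256 x 256 slice area,
#'   scaled with area for other shapes).
#' @param diameter_range in-plane nucleus diameter interval in px, within
#'   `[3, 30]`; default `c(5, 15)`, the typical pycnotic nucleus size.
#' @param nucleus_peak_intensity interval of nucleus peak amplitudes
#'   (arbitrary units, pre-normalization).
#' @param background list with `amplitude` (low-frequency polynomial field
#'   amplitude) and `noise_sd` (additive Gaussian pixel noise), or `NULL`
#'   for the class preset (high: 0.20/0.03, low: 0.08/0.02).
#' @param overlap_fraction fraction of nuclei placed as touching pairs
#'   (center distance 0.8-1.2 x mean radius, so each nucleus still roughly
#'   resembles a circle).
#' @param label_fraction fraction of nuclei the simulated expert clicks on.
#' @param damage_class `"high"` or `"low"`.
#' @param n_negative_polygons number of nucleus-free rectangular negative
#'   regions to record.
#' @param seed integer RNG seed; the same config generates bit-identical
#'   stacks.
#' @return a `synth_config` list.
#' @export
synth_config <- function(shape = c(8, 256, 256),
                         n_nuclei = NULL,
                         diameter_range = c(5, 15),
                         nucleus_peak_intensity = c(0.6, 1.0),
                         background = NULL,
                         overlap_fraction = 0,
                         label_fraction = 0.9,
                         damage_class = c("low", "high"),
                         n_negative_polygons = 6,
                         seed = 1L) {
  damage_class <- match.arg(damage_class)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            diameter_range[1] >= 3, diameter_range[2] <= 30,
            diameter_range[1] <= diameter_range[2],
            overlap_fraction >= 0, overlap_fraction <= 1,
            label_fraction >= 0, label_fraction <= 1)
  # class presets are densities (counts at the reference 256 x 256 slice
  # area), so smaller stacks stay placeable
  area_factor <- prod(shape[2:3]) / (256 * 256)
  preset <- if (damage_class == "high") {
    list(n_nuclei = max(2L, round(50 * area_factor)),
         background = list(amplitude = 0.20, noise_sd = 0.03))
  } else {
    list(n_nuclei = max(2L, round(30 * area_factor)),
         background = list(amplitude = 0.08, noise_sd = 0.02))
  }
  if (is.null(n_nuclei)) n_nuclei <- preset$n_nuclei
  if (is.null(background)) background <- preset$background
  stopifnot(n_nuclei >= 0)
  structure(
    list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
         diameter_range = diameter_range,
         nucleus_peak_intensity = nucleus_peak_intensity,
         background = background, overlap_fraction = overlap_fraction,
         label_fraction = label_fraction, damage_class = damage_class,
         n_negative_polygons = n_negative_polygons, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# smooth low-order polynomial background field, one coefficient set per
# stack with a mild per-slice modulation
synth_background <- function(ny, nx, nz, amplitude) {
  u <- matrix(seq(-1, 1, length.out = nx), ny, nx, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = ny), ny, nx)
  terms <- list(matrix(1, ny, nx), u, v, u * v, u^2, v^2)
  coef <- rnorm(6)
  zmod <- 1 + 0.2 * sin(seq(0, pi, length.out = nz) + runif(1, 0, pi))
  field <- Reduce(`+`, Map(`*`, terms, coef))
  field <- (field - min(field)) / max(1e-12, diff(range(field)))
  bg <- array(0, dim = c(ny, nx, nz))
  for (k in seq_len(nz)) bg[, , k] <- amplitude * (0.25 + field * zmod[k])
  bg
}

# axial semi-axis of a nucleus: its physical radius expressed in z-steps
axial_radius <- function(r_px, pixel_size_um = 0.52, z_step_um = 2) {
  max(0.8, r_px * pixel_size_um / z_step_um)
}

#' Generate one synthetic stack with ground truth
#'
#' Nuclei are rendered as ellipsoidal indicator volumes (in-plane radius
#' from `diameter_range`, axial semi-axis scaled by the pixel/z-step ratio)
#' convolved with a small Gaussian (sigma 1 px in-plane), which produces the
#' bright compact smooth maxima that the h-maxima click refinement and the
#' feature bank assume. The background is a low-order 2D polynomial field
#' per slice plus Gaussian pixel noise. A fraction of nuclei is placed as
#' touching pairs to emulate overlap.
#'
#' @param config a [synth_config()].
#' @return a list with `stack` (an [image_stack()]) and `truth` (a
#'   `synth_ground_truth`: `nuclei` data frame with 1-based center
#'   coordinates `x, y, z`, `radius`, `rz`, `peak`, `overlap`, `pair`;
#'   `negative_polygons` list of `list(z, x, y)` planar polygons).
#' @export
generate_stack <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_stack_impl(config))
}

generate_stack_impl <- function(config) {
  nz <- config$shape[1]; ny <- config$shape[2]; nx <- config$shape[3]
  n <- config$n_nuclei
  bg <- synth_background(ny, nx, nz, config$background$amplitude)

  radii <- runif(n, config$diameter_range[1] / 2, config$diameter_range[2] / 2)
  peaks <- runif(n, config$nucleus_peak_intensity[1],
                 config$nucleus_peak_intensity[2])
  n_pair_members <- 2L * floor(round(n * config$overlap_fraction) / 2)

  centers <- matrix(NA_real_, n, 3)  # x, y, z
  pair_id <- rep(NA_integer_, n)
  placed <- 0L
  clearance <- function(i, x, y) {
    if (placed == 0L) return(TRUE)
    j <- seq_len(placed)
    d <- sqrt((centers[j, 1] - x)^2 + (centers[j, 2] - y)^2)
    all(d > radii[j] + radii[i] + 2)
  }
  place_one <- function(i, near = NULL) {
    rz <- axial_radius(radii[i])
    for (try in 1:400) {
      if (is.null(near)) {
        x <- runif(1, radii[i] + 3, nx - radii[i] - 2)
        y <- runif(1, radii[i] + 3, ny - radii[i] - 2)
        z <- runif(1, 1 + min(rz, (nz - 1) / 2), nz - min(rz, (nz - 1) / 2))
      } else {
        d <- runif(1, 0.8, 1.2) * (radii[i] + radii[near]) / 2
        a <- runif(1, 0, 2 * pi)
        x <- centers[near, 1] + d * cos(a)
        y <- centers[near, 2] + d * sin(a)
        z <- centers[near, 3]
        if (x < radii[i] + 3 || x > nx - radii[i] - 2 ||
            y < radii[i] + 3 || y > ny - radii[i] - 2) next
      }
      ok <- if (is.null(near)) clearance(i, x, y) else {
        j <- setdiff(seq_len(placed), near)
        length(j) == 0 ||
          all(sqrt((centers[j, 1] - x)^2 + (centers[j, 2] - y)^2) >
                radii[j] + radii[i] + 2)
      }
      if (ok) {
        centers[i, ] <<- c(x, y, z)
        placed <<- placed + 1L
        return(TRUE)
      }
    }
    FALSE
  }

  i <- 1L
  pair_counter <- 0L
  while (i <= n) {
    if (i <= n_pair_members) {
      pair_counter <- pair_counter + 1L
      if (!place_one(i)) stop("nucleus placement failed: stack too crowded")
      pair_id[i] <- pair_counter
      if (!place_one(i + 1L, near = i)) stop("nucleus placement failed: stack too crowded")
      pair_id[i + 1L] <- pair_counter
      i <- i + 2L
    } else {
      if (!place_one(i)) stop("nucleus placement failed: stack too crowded")
      i <- i + 1L
    }
  }

  # render ellipsoid indicators, then smooth
  vol <- array(0, dim = c(ny, nx, nz))
  indicator <- array(FALSE, dim = c(ny, nx, nz))
  if (n > 0) {
    for (i in seq_len(n)) {
      r <- radii[i]; rz <- axial_radius(r)
      cx <- centers[i, 1]; cy <- centers[i, 2]; cz <- centers[i, 3]
      xs <- max(1, floor(cx - r - 1)):min(nx, ceiling(cx + r + 1))
      ys <- max(1, floor(cy - r - 1)):min(ny, ceiling(cy + r + 1))
      zs <- max(1, floor(cz - rz - 1)):min(nz, ceiling(cz + rz + 1))
      for (z in zs) {
        dz2 <- ((z - cz) / rz)^2
        if (dz2 > 1) next
        dx <- outer(rep(1, length(ys)), xs - cx)
        dy <- outer(ys - cy, rep(1, length(xs)))
        inside <- (dx^2 + dy^2) / r^2 + dz2 <= 1
        sl <- vol[ys, xs, z]
        sl[inside] <- pmax(sl[inside], peaks[i])
        vol[ys, xs, z] <- sl
        ind <- indicator[ys, xs, z]
        indicator[ys, xs, z] <- ind | inside
      }
    }
    vol <- gaussian_smooth3d(vol, sigma = c(1, 1, 0.5))
  }

  data <- vol + bg + array(rnorm(length(bg), 0, config$background$noise_sd),
                           dim = dim(bg))
  data[data < 0] <- 0

  nuclei <- data.frame(
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = radii, rz = vapply(radii, axial_radius, 0), peak = peaks,
    overlap = !is.na(pair_id), pair = pair_id
  )[seq_len(n), , drop = FALSE]

  polys <- synth_negative_polygons(config, nuclei, nx, ny, nz)

  truth <- structure(list(nuclei = nuclei, negative_polygons = polys),
                     class = "synth_ground_truth")
  stack <- image_stack(data, stack_id = sprintf("synth_seed%d", config$seed))
  list(stack = stack, truth = truth)
}

# rectangles with half-integer corners (so the strictly-inside pixel count
# is exactly width x height), guaranteed clear of all nuclei
synth_negative_polygons <- function(config, nuclei, nx, ny, nz) {
  polys <- list()
  tries <- 0L
  while (length(polys) < config$n_negative_polygons && tries < 500L) {
    tries <- tries + 1L
    w <- sample(15:30, 1); h <- sample(15:30, 1)
    x0 <- sample(seq_len(nx - w - 1), 1)
    y0 <- sample(seq_len(ny - h - 1), 1)
    z <- sample(seq_len(nz), 1)
    clear <- TRUE
    if (nrow(nuclei) > 0) {
      near_z <- abs(nuclei$z - z) <= nuclei$rz + 1.5
      if (any(near_z)) {
        nn <- nuclei[near_z, , drop = FALSE]
        # circle (center, radius + smoothing margin) vs rectangle distance
        cx <- pmin(pmax(nn$x, x0 + 0.5), x0 + w + 0.5)
        cy <- pmin(pmax(nn$y, y0 + 0.5), y0 + h + 0.5)
        d <- sqrt((nn$x - cx)^2 + (nn$y - cy)^2)
        clear <- all(d > nn$radius + 3)
      }
    }
    if (clear) {
      polys[[length(polys) + 1L]] <- list(
        z = z,
        x = c(x0 + 0.5, x0 + w + 0.5, x0 + w + 0.5, x0 + 0.5),
        y = c(y0 + 0.5, y0 + 0.5, y0 + h + 0.5, y0 + h + 0.5)
      )
    }
  }
  polys
}

#' Voxel mask of ground-truth nuclei
#'
#' Rasterizes the ellipsoidal nucleus supports of a ground truth into a
#' logical volume. Used by the separability and connected-component
#' invariant checks and by object-level evaluation against ground truth.
#'
#' @param truth a `synth_ground_truth`.
#' @param shape `(z, y, x)` voxel counts of the corresponding stack.
#' @param dilate extra in-plane margin in px added to each radius.
#' @return logical array `(y, x, z)`.
#' @export
nucleus_mask <- function(truth, shape, dilate = 0) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  m <- array(FALSE, dim = c(ny, nx, nz))
  nn <- truth$nuclei
  for (i in seq_len(nrow(nn))) {
    r <- nn$radius[i] + dilate; rz <- nn$rz[i]
    cx <- nn$x[i]; cy <- nn$y[i]; cz <- nn$z[i]
    xs <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
    zs <- max(1, floor(cz - rz)):min(nz, ceiling(cz + rz))
    for (z in zs) {
      dz2 <- ((z - cz) / rz)^2
      if (dz2 > 1) next
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      sl <- m[ys, xs, z]
      m[ys, xs, z] <- sl | ((dx^2 + dy^2) / r^2 + dz2 <= 1)
    }
  }
  m
}

#' Simulate expert annotations for a ground truth
#'
#' Emulates the acquisition of training data: the expert clicks on a subset
#' of the positive nuclei (`label_fraction` of them, imprecisely, jittered
#' by up to 2 px in-plane) and outlines polygonal negative regions in the
#' background. The unclicked nuclei stay unlabeled, reproducing the
#' incomplete labeling the pipeline has to tolerate.
#'
#' @param truth a `synth_ground_truth` from [generate_stack()].
#' @param config the [synth_config()] that generated it.
#' @return an [annotation_set()] with one click per marked nucleus and the
#'   negative polygons copied from the truth.
#' @export
generate_annotations <- function(truth, config) {
  n <- nrow(truth$nuclei)
  n_marked <- round(config$label_fraction * n)
  withr::with_seed(config$seed + 7L, {
    idx <- if (n_marked > 0) sort(sample.int(n, n_marked)) else integer(0)
    if (length(idx) > 0) {
      a <- runif(length(idx), 0, 2 * pi)
      d <- runif(length(idx), 0, 2)
      clicks <- data.frame(
        x = round(truth$nuclei$x[idx] + d * cos(a)),
        y = round(truth$nuclei$y[idx] + d * sin(a)),
        z = round(truth$nuclei$z[idx])
      )
      clicks$x <- pmin(pmax(clicks$x, 1), config$shape[3])
      clicks$y <- pmin(pmax(clicks$y, 1), config$shape[2])
      clicks$z <- pmin(pmax(clicks$z, 1), config$shape[1])
    } else {
      clicks <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
    }
    annotation_set(clicks, truth$negative_polygons)
  })
}

#' Generate a labeled cohort of synthetic stacks
#'
#' Produces `n_stacks` stacks of which `round(high_fraction * n_stacks)`
#' use the "high" damage parameter set (more nuclei, stronger background)
#' and the rest "low". Per-stack seeds are derived deterministically from
#' the base config's seed, so the same base reproduces the same cohort.
#'
#' @param n_stacks number of stacks (>= 2).
#' @param high_fraction fraction of "high"-damage stacks.
#' @param base a [synth_config()]; its shape, diameter range, overlap and
#'   label fractions carry over, while `n_nuclei` and `background` follow
#'   the per-class presets.
#' @return a list of `n_stacks` elements, each
#'   `list(stack, truth, annotations, damage)`.
#' @export
generate_cohort <- function(n_stacks, high_fraction, base = synth_config()) {
  stopifnot(n_stacks >= 2)
  n_high <- round(high_fraction * n_stacks)
  damage <- rep(c("high", "low"), c(n_high, n_stacks - n_high))
  lapply(seq_len(n_stacks), function(i) {
    cfg <- synth_config(
      shape = base$shape,
      diameter_range = base$diameter_range,
      nucleus_peak_intensity = base$nucleus_peak_intensity,
      overlap_fraction = base$overlap_fraction,
      label_fraction = base$label_fraction,
      damage_class = damage[i],
      n_negative_polygons = base$n_negative_polygons,
      seed = base$seed + i * 101L
    )
    gs <- generate_stack(cfg)
    gs$stack$stack_id <- sprintf("stack%02d_%s", i, damage[i])
    ann <- generate_annotations(gs$truth, cfg)
    ann$stack_id <- gs$stack$stack_id
    list(stack = gs$stack, truth = gs$truth, annotations = ann,
         damage = damage[i], config = cfg)
  })
}

#' Write a cohort to disk
#'
#' Stacks go to multi-page TIFF, ground truth and annotations to JSON
#' (0-based `(x, y, z)` coordinates), and damage labels to a cohort
#' manifest CSV.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(el) {
    id <- el$stack$stack_id
    write_stack_tiff(normalize_stack(el$stack), file.path(dir, paste0(id, ".tiff")))
    write_annotations(el$annotations, file.path(dir, paste0(id, "_annotations.json")))
    truth_json <- list(
      nuclei = lapply(seq_len(nrow(el$truth$nuclei)), function(i) {
        nn <- el$truth$nuclei[i, ]
        list(center = c(nn$x - 1, nn$y - 1, nn$z - 1), radius = nn$radius,
             peak = nn$peak, overlap = nn$overlap)
      }),
      negative_polygons = lapply(el$truth$negative_polygons, function(p)
        list(z = p$z - 1, x = p$x - 1, y = p$y - 1))
    )
    jsonlite::write_json(truth_json, file.path(dir, paste0(id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(stack_id = id, damage = el$damage,
               n_nuclei = nrow(el$truth$nuclei))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(manifest)
}
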