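#' Clean a predicted segmentation mask
#'
#' Three steps, in order: (1) positives darker than `dim_fraction` times the
#' stack's maximal intensity are set negative (strictly lower is removed);
#' (2) a morphological closing (3x3 square, per z-slice) bridges one-pixel
#' gaps; (3) connected components smaller than `min_size` voxels
#' (strictly `< min_size`) are removed.
#'
#' @param mask logical array (y, x, z), `TRUE` = positive.
#' @param stack the matching [image_stack()] (intensity source for the dim
#'   cut).
#' @param dim_fraction intensity cut as a fraction of the stack maximum
#'   (default 0.1).
#' @param min_size minimum component size in voxels (default 30).
#' @return the cleaned logical array.
#' @export
clean_mask <- function(mask, stack, dim_fraction = 0.1, min_size = 30) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  stopifnot(all(dim(mask) == dim(a)))
  mask <- mask & (a >= dim_fraction * max(a))
  brush <- matrix(1, 3, 3)
  for (k in seq_len(dim(mask)[3]))
    mask[, , k] <- EBImage::closing(mask[, , k] * 1, brush) > 0.5
  labs <- label_components3d(mask)
  if (max(labs) > 0) {
    sizes <- tabulate(labs[labs > 0], nbins = max(labs))
    drop <- which(sizes < min_size)
    if (length(drop)) mask[labs %in% drop] <- FALSE
  }
  mask
}

# chain-code perimeter from an ordered contour (axial steps 1, diagonal
# sqrt(2)), plus the pi offset term: the contour runs through boundary
# pixel centers, half a pixel inside the silhouette, and dilating a convex
# outline by 0.5 px adds 2*pi*0.5 to its length
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(pi)   # single pixel: perimeter of a unit-diameter disc
  d <- contour[c(2:n, 1), , drop = FALSE] - contour
  sum(sqrt(rowSums(d^2))) + pi
}

#' Extract objects and their morphological descriptors
#'
#' Objects are the 8-connected components of the maximum-intensity
#' z-projection of the positive mask (object-level analysis is planar: the
#' descriptors and the circular Hough transform live in the image plane,
#' while classification is voxel-wise). Each object carries the ten
#' morphological descriptors used by the false-positive filter: area,
#' convex area, eccentricity, equivalent diameter, extent, major and minor
#' axis length, perimeter, solidity and circularity (`4*pi*area /
#' perimeter^2`).
#'
#' Axis lengths and eccentricity come from the second central moments of
#' the pixel set (normalized so a filled ellipse recovers its axes); the
#' convex area is the area of the convex hull of the pixel squares (so a
#' filled convex shape has solidity 1); the perimeter is the
#' bias-corrected chain-code length of the outer contour.
#'
#' @param mask logical array (y, x, z) or matrix, a cleaned positive mask.
#' @return a `detected_objects` data frame: `label`, `centroid_x`,
#'   `centroid_y`, `area`, `convex_area`, `eccentricity`,
#'   `equiv_diameter`, `extent`, `major_axis`, `minor_axis`, `perimeter`,
#'   `solidity`, `circularity`; attribute `pixels` holds each object's
#'   (y, x) pixel coordinates.
#' @export
extract_objects <- function(mask) {
  proj <- if (is.matrix(mask)) mask else max_projection(mask * 1) > 0.5
  labs <- label_components3d(array(proj, dim = c(dim(proj), 1L)))[, , 1]
  n_obj <- max(labs)
  empty <- data.frame(label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area = numeric(0),
                      convex_area = numeric(0), eccentricity = numeric(0),
                      equiv_diameter = numeric(0), extent = numeric(0),
                      major_axis = numeric(0), minor_axis = numeric(0),
                      perimeter = numeric(0), solidity = numeric(0),
                      circularity = numeric(0))
  if (n_obj == 0)
    return(structure(empty, pixels = list(), class = c("detected_objects", "data.frame")))

  contours <- EBImage::ocontour(labs)
  pixels <- vector("list", n_obj)
  rows <- lapply(seq_len(n_obj), function(i) {
    idx <- which(labs == i, arr.ind = TRUE)   # (row = y, col = x)
    pixels[[i]] <<- idx
    ys <- idx[, 1]; xs <- idx[, 2]
    a <- length(ys)
    cx <- mean(xs); cy <- mean(ys)
    # second central moments (+1/12: variance of the unit pixel square)
    mxx <- mean((xs - cx)^2) + 1 / 12
    myy <- mean((ys - cy)^2) + 1 / 12
    mxy <- mean((xs - cx) * (ys - cy))
    tr <- mxx + myy
    gap <- sqrt((mxx - myy)^2 + 4 * mxy^2)
    l1 <- (tr + gap) / 2; l2 <- (tr - gap) / 2
    major <- 4 * sqrt(l1); minor <- 4 * sqrt(max(l2, 0))
    ecc <- if (l1 > 0) sqrt(pmax(0, 1 - l2 / l1)) else 0
    # convex hull over pixel corners so convex shapes get solidity 1
    cxs <- c(xs - 0.5, xs + 0.5, xs + 0.5, xs - 0.5)
    cys <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
    hull <- chull(cxs, cys)
    hx <- cxs[hull]; hy <- cys[hull]
    conv <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    bbox <- (diff(range(xs)) + 1) * (diff(range(ys)) + 1)
    # ocontour returns 0-based (x, y); chain length only needs differences
    per <- chain_perimeter(contours[[i]])
    data.frame(label = i, centroid_x = cx, centroid_y = cy, area = a,
               convex_area = conv,
               eccentricity = min(ecc, 1 - 1e-12),
               equiv_diameter = sqrt(4 * a / pi),
               extent = a / bbox, major_axis = major, minor_axis = minor,
               perimeter = per, solidity = min(a / conv, 1),
               circularity = 4 * pi * a / per^2)
  })
  structure(do.call(rbind, rows), pixels = pixels,
            class = c("detected_objects", "data.frame"))
}

#' Match detected objects to manual annotations
#'
#' Greedy nearest-first assignment between object centroids and manual
#' points in the image plane: pairs are considered in order of increasing
#' distance, an object is `true_positive` if its matched manual point is a
#' positive, `false_positive` if a negative, and `discarded` if no point
#' lies strictly closer than `radius` px (10 px at exactly 10.000 px is
#' "not closer than" and does not match). Each manual point is consumed by
#' at most one object. On an exact distance tie between a positive and a
#' negative point, the positive wins.
#'
#' @param objects a `detected_objects` data frame.
#' @param positive_points,negative_points data frames with `x`, `y`
#'   (planar coordinates of manual clicks / negative markers).
#' @param radius matching radius in px (default 10, strict `<`).
#' @return a `match_report`: list with `verdicts` (per-object factor),
#'   `counts`, `recall` (matched positive points / all positive points;
#'   `NA` if there are none).
#' @export
match_objects <- function(objects, positive_points,
                          negative_points = data.frame(x = numeric(0), y = numeric(0)),
                          radius = 10) {
  n_obj <- nrow(objects)
  verdict <- rep("discarded", n_obj)
  pts <- rbind(
    if (nrow(positive_points)) data.frame(x = positive_points$x, y = positive_points$y, type = "pos"),
    if (nrow(negative_points)) data.frame(x = negative_points$x, y = negative_points$y, type = "neg")
  )
  matched_pos <- 0L
  if (n_obj > 0 && !is.null(pts) && nrow(pts) > 0) {
    d <- outer(objects$centroid_x, pts$x, `-`)^2 +
      outer(objects$centroid_y, pts$y, `-`)^2
    cand <- which(d < radius^2, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      dist <- sqrt(d[cand])
      type_rank <- ifelse(pts$type[cand[, 2]] == "pos", 0L, 1L)  # ties -> positive
      ord <- order(dist, type_rank)
      obj_used <- logical(n_obj)
      pt_used <- logical(nrow(pts))
      for (r in ord) {
        oi <- cand[r, 1]; pj <- cand[r, 2]
        if (obj_used[oi] || pt_used[pj]) next
        obj_used[oi] <- TRUE
        pt_used[pj] <- TRUE
        if (pts$type[pj] == "pos") {
          verdict[oi] <- "true_positive"
          matched_pos <- matched_pos + 1L
        } else {
          verdict[oi] <- "false_positive"
        }
      }
    }
  }
  verdict <- factor(verdict, levels = c("true_positive", "false_positive", "discarded"))
  n_pos <- if (is.null(pts)) 0L else sum(pts$type == "pos")
  structure(list(verdicts = verdict, counts = table(verdict),
                 recall = if (n_pos > 0) matched_pos / n_pos else NA_real_),
            class = "match_report")
}

fp_feature_columns <- c("area", "convex_area", "eccentricity",
                        "equiv_diameter", "extent", "major_axis",
                        "minor_axis", "perimeter", "solidity", "circularity")

#' Train the false-positive object filter
#'
#' An SVM with radial-basis kernel on the ten standardized morphological
#' descriptors, separating objects verdicted `true_positive` from
#' `false_positive` (discarded objects are excluded). The assumed outlier
#' fraction of 0.05 is realized as a nu-SVM slack budget: up to 5% of the
#' training points may fall outside their margin (nu is capped below the
#' class-balance feasibility bound when one class is very rare). With
#' fewer than 2 false positives the filter degenerates to the identity
#' with a warning - the regime where the upstream classifier leaves almost
#' nothing to filter.
#'
#' Validation uses repeated stratified 70/30 splits preserving the
#' true-to-false-positive ratio, reporting accuracy, sensitivity
#' (correctly kept true positives) and specificity (correctly removed
#' false positives).
#'
#' @param objects a `detected_objects` data frame.
#' @param verdicts factor from [match_objects()].
#' @param n_splits cross-validation divisions (default 200).
#' @param holdout_fraction test fraction (default 0.3).
#' @param outlier_fraction nu slack budget (default 0.05).
#' @param seed RNG seed.
#' @return an `fp_filter`: `type` ("svm" or "identity"), fitted `svm`,
#'   standardization, and `cv` (per-split accuracy/sensitivity/specificity
#'   with medians and sds).
#' @export
train_fp_svm <- function(objects, verdicts, n_splits = 200L,
                         holdout_fraction = 0.3, outlier_fraction = 0.05,
                         seed = 1L) {
  keep <- verdicts %in% c("true_positive", "false_positive")
  x <- as.matrix(objects[keep, fp_feature_columns])
  y <- droplevels(factor(verdicts[keep],
                         levels = c("true_positive", "false_positive")))
  if (sum(y == "false_positive") < 2 || sum(y == "true_positive") < 2) {
    warning("fewer than 2 objects in a verdict class: false-positive filter is the identity")
    return(structure(list(type = "identity", cv = NULL), class = "fp_filter"))
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  nu_cap <- 0.9 * 2 * min(table(y)) / length(y)
  nu <- min(outlier_fraction, nu_cap)

  fit_one <- function(xtr, ytr, s) {
    withr::with_seed(s,
      e1071::svm(xtr, ytr, type = "nu-classification", kernel = "radial",
                 nu = min(nu, 0.9 * 2 * min(table(ytr)) / length(ytr)),
                 scale = FALSE))
  }
  cv <- lapply(seq_len(n_splits), function(i) {
    hold <- stratified_holdout(y, holdout_fraction, seed + i)
    fit <- fit_one(xs[!hold, , drop = FALSE], y[!hold], seed + i)
    pred <- predict(fit, xs[hold, , drop = FALSE])
    truth <- y[hold]
    data.frame(
      accuracy = mean(pred == truth),
      sensitivity = mean(pred[truth == "true_positive"] == "true_positive"),
      specificity = mean(pred[truth == "false_positive"] == "false_positive")
    )
  })
  cv <- do.call(rbind, cv)
  fit <- fit_one(xs, y, seed)
  structure(list(type = "svm", svm = fit, center = ctr, scale = scl,
                 nu = nu, cv = cv,
                 cv_median = vapply(cv, median, 0),
                 cv_sd = vapply(cv, sd, 0)),
            class = "fp_filter")
}

#' Remove objects the filter predicts to be false positives
#'
#' @param objects a `detected_objects` data frame.
#' @param filter an `fp_filter` (identity filters keep everything).
#' @return the kept subset of `objects`, with a logical attribute `kept`
#'   marking the decision per input object.
#' @export
filter_false_positives <- function(objects, filter) {
  if (nrow(objects) == 0 || filter$type == "identity") {
    return(structure(objects, kept = rep(TRUE, nrow(objects))))
  }
  x <- as.matrix(objects[, fp_feature_columns])
  xs <- sweep(sweep(x, 2, filter$center), 2, filter$scale, `/`)
  pred <- predict(filter$svm, xs)
  kept <- pred == "true_positive"
  structure(objects[kept, , drop = FALSE], kept = as.logical(kept))
}

# intersection-over-union of two discs at center distance d (vectorized
# over the first circle's d and r)
circle_iou <- function(d, r1, r2) {
  lens <- function(d, r1, r2) {
    # area of intersection of two discs
    full <- pmin(r1, r2)^2 * pi
    sep <- d >= r1 + r2
    inside <- d <= abs(r1 - r2)
    d2 <- pmax(d, 1e-9)
    a1 <- r1^2 * suppressWarnings(acos(pmin(1, pmax(-1, (d2^2 + r1^2 - r2^2) / (2 * d2 * r1)))))
    a2 <- r2^2 * suppressWarnings(acos(pmin(1, pmax(-1, (d2^2 + r2^2 - r1^2) / (2 * d2 * r2)))))
    tri <- 0.5 * sqrt(pmax(0, (-d2 + r1 + r2) * (d2 + r1 - r2) *
                             (d2 - r1 + r2) * (d2 + r1 + r2)))
    out <- a1 + a2 - tri
    out[sep] <- 0
    out[inside] <- full[inside]
    out
  }
  inter <- lens(d, r1, r2)
  union <- pi * r1^2 + pi * r2^2 - inter
  inter / union
}

#' Split overlapping nuclei with a circular Hough transform
#'
#' Edge pixels of the mask's maximum-intensity projection vote on circle
#' centers over a radius grid spanning the pycnotic-nucleus range
#' (2.5-7.5 px radius for 5-15 px diameters). Voting is
#' gradient-directed: each edge pixel votes only along its inward boundary
#' normal, so votes converge onto a point only where the local boundary
#' curvature matches the candidate radius. Candidate centers are the
#' local maxima of each radius layer (layer peaks sit exactly at circle
#' centers, whereas radius-pooled maps pull the peaks of touching circles
#' toward each other), with scores normalized by circumference so small
#' circles compete fairly. Candidates above a low score floor are then *verified*
#' against the mask: a circle is kept only if at least `support_min` of
#' its circumference lies within `support_tol` px of a mask boundary
#' pixel, which rejects phantom circles in the interior of large ragged
#' objects while keeping genuinely touching nuclei, whose hidden arc is
#' only about a third of the circumference. Finally non-maximum
#' suppression (ordered by boundary support) enforces a minimum center
#' separation (default: the smallest configured radius, plus suppression
#' inside 0.85 of an accepted radius) and an overlap rule: a candidate
#' disc overlapping an accepted disc by more than 0.3
#' intersection-over-union is a duplicate detection of the same nucleus,
#' while two touching nuclei one radius apart overlap by only about 0.24.
#'
#' The default radius range (2.5-9 px) extends the nominal 2.5-7.5 px
#' pycnotic radius range by the 1-1.5 px the segmentation mask dilates a
#' nucleus beyond its nominal extent; without the extension the largest
#' nuclei get systematically under-sized circles and weak suppression.
#'
#' @param mask logical array or matrix (cleaned, filtered positive mask).
#' @param radius_range circle radius interval in px.
#' @param radius_step radius grid step (default 0.5).
#' @param threshold normalized-score threshold relative to the strongest
#'   candidate (default 0.2; the verification step, not this threshold,
#'   does the heavy pruning).
#' @param min_separation minimum distance between accepted centers
#'   (default `radius_range[1]`).
#' @param support_tol distance (px) within which a circumference point
#'   counts as boundary-supported (default 1.5).
#' @param support_min minimal supported circumference fraction
#'   (default 0.5).
#' @return a `circle_set` data frame: `x`, `y`, `radius`, `score`,
#'   `support`.
#' @export
split_objects_hough <- function(mask, radius_range = c(2.5, 9),
                                radius_step = 0.5, threshold = 0.2,
                                min_separation = NULL,
                                support_tol = 1.5, support_min = 0.5) {
  proj <- if (is.matrix(mask)) mask > 0 else max_projection(mask * 1) > 0.5
  if (is.null(min_separation)) min_separation <- radius_range[1]
  empty <- structure(data.frame(x = numeric(0), y = numeric(0),
                                radius = numeric(0), score = numeric(0),
                                support = numeric(0)),
                     class = c("circle_set", "data.frame"))
  if (!any(proj)) return(empty)
  er <- EBImage::erode(proj * 1, matrix(1, 3, 3)) > 0.5
  edge <- which(proj & !er, arr.ind = TRUE)
  if (nrow(edge) == 0) edge <- which(proj, arr.ind = TRUE)
  ny <- nrow(proj); nx <- ncol(proj)
  radii <- seq(radius_range[1], radius_range[2], by = radius_step)

  # inward boundary normals from the gradient of the smoothed silhouette
  # (the mask is 1 inside, so its gradient points inward at the boundary)
  sm <- gaussian_smooth3d(array(proj * 1, dim = c(ny, nx, 1L)), c(1, 1, 0))
  gx <- gaussian_derivative3d(sm, 1, c(0, 1, 0))[, , 1]
  gy <- gaussian_derivative3d(sm, 1, c(1, 0, 0))[, , 1]
  gmag <- sqrt(gx[edge]^2 + gy[edge]^2)
  ok <- gmag > 1e-8
  edge <- edge[ok, , drop = FALSE]
  nxv <- gx[edge] / gmag[ok]
  nyv <- gy[edge] / gmag[ok]
  if (nrow(edge) == 0) return(empty)

  smooth2d <- function(mat) {
    conv3d_sep(array(mat, dim = c(ny, nx, 1L)),
               ky = gaussian_kernel_1d(1, 0, 5),
               kx = gaussian_kernel_1d(1, 0, 5))[, , 1]
  }
  # per-radius accumulators; candidates are the 3x3 local maxima within
  # each radius layer (peaks of a layer sit exactly at circle centers,
  # whereas radius-pooled maps pull the peaks of touching circles toward
  # each other), scored by circumference-normalized vote mass so small
  # circles compete fairly with large ones
  cand_y <- integer(0); cand_x <- integer(0)
  cand_r <- numeric(0); cand_v <- numeric(0)
  max_vote <- 0
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    cy <- round(edge[, 1] + r * nyv)
    cx <- round(edge[, 2] + r * nxv)
    keep <- cy >= 1 & cy <= ny & cx >= 1 & cx <= nx
    layer <- smooth2d(matrix(tabulate((cx[keep] - 1) * ny + cy[keep],
                                      nbins = ny * nx), ny, nx))
    max_vote <- max(max_vote, max(layer))
    pk <- which(layer > 0 &
                  layer >= rbind(layer[-1, ], -1) &
                  layer >= rbind(-1, layer[-ny, ]) &
                  layer >= cbind(layer[, -1], -1) &
                  layer >= cbind(-1, layer[, -nx]) &
                  layer >= rbind(cbind(layer[-1, -1], -1), -1) &
                  layer >= rbind(-1, cbind(-1, layer[-ny, -nx])) &
                  layer >= rbind(cbind(-1, layer[-1, -nx]), -1) &
                  layer >= rbind(-1, cbind(layer[-ny, -1], -1)),
                arr.ind = TRUE)
    if (nrow(pk) > 0) {
      cand_y <- c(cand_y, pk[, 1]); cand_x <- c(cand_x, pk[, 2])
      cand_r <- c(cand_r, rep(r, nrow(pk))); cand_v <- c(cand_v, layer[pk])
    }
  }
  if (length(cand_y) == 0 || max_vote <= 0) return(empty)
  keep <- cand_v >= 0.1 * max_vote
  cand <- cbind(cand_y[keep], cand_x[keep])
  r_best <- cand_r[keep]
  score <- cand_v[keep] / (2 * pi * r_best)
  keep <- score >= threshold * max(score)
  cand <- cand[keep, , drop = FALSE]
  r_best <- r_best[keep]
  score <- score[keep]

  # verification: fraction of the circumference lying on the mask boundary
  edgeimg <- matrix(0, ny, nx)
  edgeimg[edge] <- 1
  dm <- EBImage::distmap(1 - edgeimg)
  theta <- seq(0, 2 * pi, length.out = 33)[-33]
  support <- vapply(seq_len(nrow(cand)), function(i) {
    px <- round(cand[i, 2] + r_best[i] * cos(theta))
    py <- round(cand[i, 1] + r_best[i] * sin(theta))
    ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
    if (!any(ok)) return(0)
    mean(dm[cbind(py[ok], px[ok])] <= support_tol)
  }, 0)
  keep <- support >= support_min
  cand <- cand[keep, , drop = FALSE]
  r_best <- r_best[keep]
  score <- score[keep]
  support <- support[keep]
  if (nrow(cand) == 0) return(empty)

  ord <- order(-(score * support))
  sel <- integer(0)
  sel_x <- numeric(0); sel_y <- numeric(0); sel_r <- numeric(0)
  for (i in ord) {
    y <- cand[i, 1]; x <- cand[i, 2]; r <- r_best[i]
    if (length(sel_x) > 0) {
      d <- sqrt((sel_x - x)^2 + (sel_y - y)^2)
      if (any(d < pmax(min_separation, 0.85 * sel_r)) ||
          any(circle_iou(d, sel_r, r) > 0.3)) next
    }
    sel_x <- c(sel_x, x); sel_y <- c(sel_y, y); sel_r <- c(sel_r, r)
    sel <- c(sel, i)
  }
  structure(data.frame(x = sel_x, y = sel_y, radius = sel_r,
                       score = score[sel], support = support[sel]),
            class = c("circle_set", "data.frame"))
}

#' Object recall against manual positive points
#'
#' Fraction of manual positive points that have a detection center strictly
#' closer than `radius` px, each manual point countable once (greedy
#' nearest-first assignment). With no manual positives the recall is
#' undefined and `NA` is returned.
#'
#' @param centers data frame with `x`, `y` (object centroids or Hough
#'   circle centers).
#' @param positive_points data frame with `x`, `y` of manual positives.
#' @param radius matching radius in px (default 10, strict `<`).
#' @return recall fraction in `[0, 1]`, or `NA_real_`.
#' @export
compute_recall <- function(centers, positive_points, radius = 10) {
  n_pos <- nrow(positive_points)
  if (n_pos == 0) {
    message("no manual positive points: recall is undefined")
    return(NA_real_)
  }
  if (nrow(centers) == 0) return(0)
  d <- outer(centers$x, positive_points$x, `-`)^2 +
    outer(centers$y, positive_points$y, `-`)^2
  cand <- which(d < radius^2, arr.ind = TRUE)
  if (nrow(cand) == 0) return(0)
  ord <- order(d[cand])
  c_used <- logical(nrow(centers)); p_used <- logical(n_pos)
  matched <- 0L
  for (r in ord) {
    ci <- cand[r, 1]; pj <- cand[r, 2]
    if (c_used[ci] || p_used[pj]) next
    c_used[ci] <- TRUE; p_used[pj] <- TRUE
    matched <- matched + 1L
  }
  matched / n_pos
}

#' Write detected objects (with verdicts) as CSV
#'
#' @param objects a `detected_objects` data frame.
#' @param path CSV output path.
#' @param verdicts optional factor from [match_objects()].
#' @param kept optional logical from [filter_false_positives()].
#' @export
write_objects <- function(objects, path, verdicts = NULL, kept = NULL) {
  df <- as.data.frame(objects)
  if (!is.null(verdicts)) df$verdict <- as.character(verdicts)
  if (!is.null(kept)) df$kept <- kept
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
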