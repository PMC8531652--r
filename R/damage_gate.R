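#' Gate configuration
#'
#' The whole-stack "high"/"low" damage gate works on a bag of visual words:
#' dense local gradient-histogram descriptors of the maximum-intensity
#' z-projection, quantized against a k-means vocabulary, histogrammed per
#' stack and classified by a linear SVM on L1-normalized histograms.
#'
#' @param vocabulary_size number of visual words (k-means centroids).
#' @param patch_size square descriptor patch width in px.
#' @param step patch grid stride in px.
#' @param n_orientations gradient orientation bins per descriptor.
#' @param seed RNG seed for the vocabulary.
#' @return a `gate_config`.
#' @export
gate_config <- function(vocabulary_size = 100L, patch_size = 16L, step = 12L,
                        n_orientations = 8L, seed = 1L) {
  structure(list(vocabulary_size = as.integer(vocabulary_size),
                 patch_size = as.integer(patch_size), step = as.integer(step),
                 n_orientations = as.integer(n_orientations),
                 seed = as.integer(seed)),
            class = "gate_config")
}

#' Dense local descriptors of a stack projection
#'
#' Gradient-orientation histograms (magnitude weighted) plus intensity
#' statistics of the patch (mean, standard deviation, maximum and the
#' fraction of bright pixels), on a regular patch grid over the normalized
#' maximum-intensity z-projection. The intensity statistics carry the
#' nucleus-density and background-level differences that distinguish the
#' damage classes.
#'
#' @param stack an [image_stack()].
#' @param config a [gate_config()].
#' @return matrix (patches x `n_orientations + 4`).
#' @export
bovw_descriptors <- function(stack, config = gate_config()) {
  proj <- max_projection(suppressWarnings(normalize_stack(stack)))
  pvol <- array(proj, dim = c(dim(proj), 1L))
  gx <- gaussian_derivative3d(pvol, 1, c(0, 1, 0))[, , 1]
  gy <- gaussian_derivative3d(pvol, 1, c(1, 0, 0))[, , 1]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                      # (-pi, pi]
  nb <- config$n_orientations
  bin <- pmin(floor((ang + pi) / (2 * pi) * nb) + 1L, nb)
  ps <- config$patch_size
  ys <- seq(1, nrow(proj) - ps + 1, by = config$step)
  xs <- seq(1, ncol(proj) - ps + 1, by = config$step)
  desc <- matrix(0, length(ys) * length(xs), nb + 4L)
  r <- 0L
  for (y0 in ys) for (x0 in xs) {
    r <- r + 1L
    ry <- y0:(y0 + ps - 1L); rx <- x0:(x0 + ps - 1L)
    m <- mag[ry, rx]; b <- bin[ry, rx]
    hist <- vapply(seq_len(nb), function(k) sum(m[b == k]), 0)
    tot <- sum(hist)
    if (tot > 0) hist <- hist / tot
    p <- proj[ry, rx]
    desc[r, ] <- c(hist, mean(p), sd(p), max(p), mean(p > 0.5))
  }
  desc
}

assign_words <- function(desc, centers) {
  d2 <- outer(rowSums(desc^2), rowSums(centers^2), `+`) -
    2 * desc %*% t(centers)
  max.col(-d2)
}

bovw_histogram <- function(desc, centers) {
  w <- assign_words(desc, centers)
  h <- tabulate(w, nbins = nrow(centers))
  h / max(1, sum(h))
}

#' Train the high/low damage gate
#'
#' Fits the k-means visual vocabulary on the pooled training descriptors
#' and a linear SVM on the per-stack word histograms.
#'
#' @param stacks list of [image_stack()]s, or a precomputed list of
#'   descriptor matrices from [bovw_descriptors()].
#' @param labels character/factor of `"high"`/`"low"` per stack, both
#'   present.
#' @param config a [gate_config()].
#' @return a `bovw_model`: `centers`, `svm`, `config`, `levels`.
#' @export
train_damage_svm <- function(stacks, labels, config = gate_config()) {
  labels <- factor(labels, levels = c("high", "low"))
  if (any(table(labels) == 0)) stop("both damage classes must be present")
  desc <- lapply(stacks, function(s)
    if (is.matrix(s)) s else bovw_descriptors(s, config))
  pooled <- do.call(rbind, desc)
  kcent <- min(config$vocabulary_size, nrow(unique(pooled)))
  km <- withr::with_seed(config$seed,
    kmeans(pooled, centers = kcent, iter.max = 30, nstart = 2))
  hists <- t(vapply(desc, bovw_histogram, numeric(kcent),
                    centers = km$centers))
  colnames(hists) <- paste0("w", seq_len(ncol(hists)))
  fit <- withr::with_seed(config$seed,
    e1071::svm(hists, labels, kernel = "linear", scale = FALSE))
  structure(list(centers = km$centers, svm = fit, config = config,
                 levels = levels(labels)),
            class = "bovw_model")
}

#' Predict the damage class of a stack
#'
#' @param model a `bovw_model`.
#' @param stack an [image_stack()] or descriptor matrix.
#' @return `"high"` or `"low"`.
#' @export
predict_damage <- function(model, stack) {
  desc <- if (is.matrix(stack)) stack else bovw_descriptors(stack, model$config)
  h <- matrix(bovw_histogram(desc, model$centers), 1)
  colnames(h) <- paste0("w", seq_len(ncol(h)))
  as.character(predict(model$svm, h))
}

#' Cross-validate the damage gate
#'
#' Repeated stratified 70/30 splits (class ratio preserved); vocabulary and
#' SVM are refitted on each training split and scored on the held-out
#' stacks.
#'
#' @param stacks list of stacks or descriptor matrices.
#' @param labels `"high"`/`"low"` per stack.
#' @param config a [gate_config()].
#' @param n_splits number of random divisions (default 200).
#' @param holdout_fraction test fraction per split (default 0.3).
#' @param seed RNG seed.
#' @return numeric vector of per-split accuracies with attributes
#'   `median` and `sd`.
#' @export
crossvalidate_gate <- function(stacks, labels, config = gate_config(),
                               n_splits = 200L, holdout_fraction = 0.3,
                               seed = 1L) {
  labels <- factor(labels, levels = c("high", "low"))
  stopifnot(length(stacks) >= 4)
  if (any(table(labels) < 2))
    stop("stratification impossible: a class has fewer than 2 stacks")
  desc <- lapply(stacks, function(s)
    if (is.matrix(s)) s else bovw_descriptors(s, config))
  acc <- vapply(seq_len(n_splits), function(i) {
    hold <- stratified_holdout(labels, holdout_fraction, seed + i)
    cfg <- config
    cfg$seed <- config$seed + i
    model <- train_damage_svm(desc[!hold], labels[!hold], cfg)
    pred <- vapply(desc[hold], function(d) predict_damage(model, d), "")
    mean(pred == as.character(labels[hold]))
  }, 0)
  structure(acc, median = median(acc), sd = sd(acc))
}

#' Route a stack to its damage-matched segmentation model
#'
#' In the gated topology each damage class has its own trained pixel
#' classifier; the bypass topology uses one model trained on all data and
#' ignores the gate.
#'
#' @param stack an [image_stack()] (or descriptor matrix).
#' @param gate_model a `bovw_model`, or `NULL` in bypass mode.
#' @param registry named list of `pixel_classifier`s: `high`, `low`, and/or
#'   `all`.
#' @param bypass if `TRUE`, return `registry$all` regardless of the gate.
#' @return list with `model` (the chosen `pixel_classifier`) and `damage`
#'   (the predicted class, or `"all"` in bypass mode).
#' @export
route <- function(stack, gate_model, registry, bypass = FALSE) {
  if (bypass || is.null(gate_model)) {
    if (is.null(registry$all))
      stop("bypass topology requires an 'all' model in the registry")
    return(list(model = registry$all, damage = "all"))
  }
  damage <- predict_damage(gate_model, stack)
  model <- registry[[damage]]
  if (is.null(model))
    stop(sprintf("no segmentation model registered for damage class '%s'", damage))
  list(model = model, damage = damage)
}
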