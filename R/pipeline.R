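#' Pipeline configuration
#'
#' Bundles every tunable of the counting pipeline. The `topology` selects
#' between the gated layout (a damage gate routes each stack to a
#' class-specific segmentation model) and the single-model layout (one
#' model trained on all data, no gating).
#'
#' @param topology `"gated"` or `"single"`.
#' @param feature_config a [feature_config()].
#' @param classifier a [classifier_spec()] (the `k` field is chosen at
#'   training time from `variance_fraction`).
#' @param gate a [gate_config()].
#' @param variance_fraction PCA variance fraction determining the feature
#'   count (default 0.99).
#' @param h h-maxima depth for click refinement (normalized intensity).
#' @param search_radius click snap radius in px.
#' @param max_radius positive-region clip radius in px.
#' @param dim_fraction,min_size mask cleaning parameters, see
#'   [clean_mask()].
#' @param hough_radius_range,match_radius object splitting / matching
#'   parameters in px.
#' @param use_fp_filter apply the morphology SVM filter when available.
#' @param seed master RNG seed recorded in the manifest.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(topology = c("gated", "single"),
                            feature_config = pycnoseg::feature_config(),
                            classifier = classifier_spec("rf"),
                            gate = gate_config(),
                            variance_fraction = 0.99,
                            h = 0.1, search_radius = 5, max_radius = 15,
                            dim_fraction = 0.1, min_size = 30,
                            hough_radius_range = c(2.5, 9),
                            match_radius = 10,
                            use_fp_filter = TRUE,
                            seed = 1L) {
  topology <- match.arg(topology)
  structure(list(topology = topology, feature_config = feature_config,
                 classifier = classifier, gate = gate,
                 variance_fraction = variance_fraction, h = h,
                 search_radius = search_radius, max_radius = max_radius,
                 dim_fraction = dim_fraction, min_size = min_size,
                 hough_radius_range = hough_radius_range,
                 match_radius = match_radius,
                 use_fp_filter = use_fp_filter, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; the nested
#' `feature_config`, `classifier` (`kind` plus parameter overrides) and
#' `gate` blocks map to [feature_config()], [classifier_spec()] and
#' [gate_config()]. Keys that are absent keep their defaults, and unknown
#' keys are an error (typo guard).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  args <- list()
  plain <- c("topology", "variance_fraction", "h", "search_radius",
             "max_radius", "dim_fraction", "min_size", "hough_radius_range",
             "match_radius", "use_fp_filter", "seed")
  for (nm in names(obj)) {
    if (nm %in% plain) {
      args[[nm]] <- obj[[nm]]
    } else if (nm == "feature_config") {
      args$feature_config <- do.call(feature_config, obj[[nm]])
    } else if (nm == "classifier") {
      cl <- obj[[nm]]
      args$classifier <- classifier_spec(cl$kind %||% "rf",
                                         params = cl[setdiff(names(cl), "kind")])
    } else if (nm == "gate") {
      args$gate <- do.call(gate_config, obj[[nm]])
    } else {
      stop(sprintf("unknown pipeline configuration key '%s'", nm))
    }
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Turn a stack plus annotations into labeled training voxels
#'
#' Runs the annotation pipeline (click refinement against the h-maxima
#' domes, polygon rasterization, label-mask construction) and extracts the
#' full feature bank at the labeled voxels only.
#'
#' @param stack an [image_stack()].
#' @param annotations an [annotation_set()] for that stack.
#' @param config a [pipeline_config()].
#' @param damage optional damage class label carried through.
#' @return list with `features` (labeled voxels x channels), `labels`
#'   (factor "neg"/"pos"), `stack_id`, `damage`, `voxels` (linear
#'   indices) and `label_mask`.
#' @export
prepare_training_data <- function(stack, annotations, config = pipeline_config(),
                                  damage = NULL) {
  nstack <- suppressWarnings(normalize_stack(stack))
  seeds <- refine_clicks_hmax(nstack, annotations$clicks, config$h,
                              config$search_radius)
  dims <- dim(nstack$data)
  negvol <- rasterize_negatives(annotations$negative_polygons,
                                shape = c(dims[3], dims[1], dims[2]))
  lm <- build_label_mask(nstack, seeds, negvol, h = config$h,
                         max_radius = config$max_radius)
  voxels <- which(lm$mask > 0L)
  labels <- factor(ifelse(lm$mask[voxels] == 2L, "pos", "neg"),
                   levels = c("neg", "pos"))
  fv <- build_feature_volume(stack, config$feature_config, voxels = voxels)
  list(features = fv$values, labels = labels, stack_id = stack$stack_id,
       damage = damage, voxels = voxels, label_mask = lm)
}

# fit PCA + ranking + classifier on a pool of training sets; returns a
# self-contained segmentation entry
fit_segmentation_entry <- function(training_sets, config, seed) {
  x <- do.call(rbind, lapply(training_sets, `[[`, "features"))
  y <- factor(unlist(lapply(training_sets, function(ts) as.character(ts$labels))),
              levels = c("neg", "pos"))
  pca <- fit_pca(x, seed = seed)
  s <- project_pca(x, pca)
  ranking <- rank_components_wilcoxon(s[y == "pos", , drop = FALSE],
                                      s[y == "neg", , drop = FALSE])
  k <- components_for_variance(pca, config$variance_fraction)
  cols <- ranking$component[seq_len(k)]
  spec <- classifier_spec(config$classifier$kind, k = k,
                          params = config$classifier$params)
  model <- train_model(spec, s[, cols, drop = FALSE], y, seed = seed)
  list(model = model, pca = pca, cols = cols, k = k)
}

#' Train the segmentation model registry
#'
#' For the gated topology, one model per damage class plus an all-data
#' model; for the single topology, the all-data model only.
#'
#' @param training_sets list from [prepare_training_data()], each with a
#'   `damage` field for the gated topology.
#' @param config a [pipeline_config()].
#' @return named list of segmentation entries (`high`, `low`, `all` as
#'   applicable), each `list(model, pca, cols, k)`.
#' @export
train_segmentation_models <- function(training_sets, config = pipeline_config()) {
  registry <- list()
  if (config$topology == "gated") {
    for (cl in c("high", "low")) {
      sets <- Filter(function(ts) identical(ts$damage, cl), training_sets)
      if (length(sets) == 0)
        stop(sprintf("gated topology needs training stacks of class '%s'", cl))
      registry[[cl]] <- fit_segmentation_entry(sets, config, config$seed)
    }
  }
  registry$all <- fit_segmentation_entry(training_sets, config, config$seed)
  registry
}

#' Segment one stack and count its pycnotic nuclei
#'
#' Feature extraction, PCA projection, voxel classification, mask
#' cleaning, optional false-positive filtering and circular Hough
#' splitting; the final count is the number of detected circles.
#'
#' @param stack an [image_stack()].
#' @param entry a segmentation entry from [train_segmentation_models()].
#' @param config a [pipeline_config()].
#' @param fp_filter optional `fp_filter` from [train_fp_svm()].
#' @return list with `count`, `circles`, `objects`, `kept_objects`,
#'   `mask` (cleaned logical array).
#' @export
count_nuclei <- function(stack, entry, config = pipeline_config(),
                         fp_filter = NULL) {
  nstack <- suppressWarnings(normalize_stack(stack))
  # voxels below the dim cut are set negative by clean_mask regardless of
  # the classifier, so only the candidates above it are classified
  candidates <- which(nstack$data >= config$dim_fraction * max(nstack$data))
  fv <- build_feature_volume(stack, config$feature_config, voxels = candidates)
  scores <- project_pca_cols(fv$values, entry$pca, entry$cols)
  pred <- predict_classes(entry$model, scores)
  mask <- array(FALSE, dim = dim(stack$data))
  mask[candidates] <- pred == entry$model$levels[2]
  mask <- clean_mask(mask, nstack, config$dim_fraction, config$min_size)
  objects <- extract_objects(mask)
  kept <- objects
  if (config$use_fp_filter && !is.null(fp_filter) && nrow(objects) > 0) {
    kept <- filter_false_positives(objects, fp_filter)
    if (nrow(kept) < nrow(objects)) {
      keep_labels <- kept$label
      proj <- max_projection(mask * 1) > 0.5
      labs <- label_components3d(array(proj, dim = c(dim(proj), 1L)))[, , 1]
      drop2d <- labs > 0 & !(labs %in% keep_labels)
      for (k in seq_len(dim(mask)[3])) {
        sl <- mask[, , k]
        sl[drop2d] <- FALSE
        mask[, , k] <- sl
      }
    }
  }
  circles <- split_objects_hough(mask, config$hough_radius_range)
  list(count = nrow(circles), circles = circles, objects = objects,
       kept_objects = kept, mask = mask)
}

#' Run the full counting pipeline over a set of stacks
#'
#' Routes each stack through the configured topology (gate, segmentation,
#' cleaning, false-positive filter, Hough splitting) and collects
#' per-stack dead-cell counts plus a manifest that fully determines the
#' outputs. A failure on one stack is logged and the remaining stacks
#' proceed; the overall `status` is then `"partial"`.
#'
#' @param config a [pipeline_config()].
#' @param stacks list of [image_stack()]s.
#' @param registry segmentation registry from
#'   [train_segmentation_models()].
#' @param gate_model optional `bovw_model` (required for the gated
#'   topology).
#' @param fp_filter optional `fp_filter`.
#' @return a `pipeline_result`: `counts` data frame (`stack_id`, `damage`,
#'   `count`, `ok`), `details` per stack, `manifest`, `status`.
#' @export
run_pipeline <- function(config, stacks, registry, gate_model = NULL,
                         fp_filter = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- lapply(stacks, function(stack) {
    tryCatch({
      routed <- if (config$topology == "gated") {
        route(stack, gate_model, registry)
      } else {
        route(stack, NULL, registry, bypass = TRUE)
      }
      res <- count_nuclei(stack, routed$model, config, fp_filter)
      list(ok = TRUE, damage = routed$damage, count = res$count, detail = res)
    }, error = function(e) {
      warning(sprintf("stack '%s' failed: %s", stack$stack_id, conditionMessage(e)))
      list(ok = FALSE, damage = NA_character_, count = NA_integer_,
           detail = NULL)
    })
  })
  counts <- data.frame(
    stack_id = vapply(stacks, function(s) if (is.null(s$stack_id)) "?" else s$stack_id, ""),
    damage = vapply(results, `[[`, "", "damage"),
    count = vapply(results, function(r) as.integer(r$count), 1L),
    ok = vapply(results, `[[`, TRUE, "ok")
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("pycnoseg")),
    topology = config$topology,
    classifier = config$classifier$kind,
    seed = config$seed,
    variance_fraction = config$variance_fraction,
    parameters = list(h = config$h, search_radius = config$search_radius,
                      max_radius = config$max_radius,
                      dim_fraction = config$dim_fraction,
                      min_size = config$min_size,
                      hough_radius_range = config$hough_radius_range,
                      match_radius = config$match_radius),
    counts = counts$count
  )
  structure(list(counts = counts,
                 details = lapply(results, `[[`, "detail"),
                 manifest = manifest,
                 status = if (all(counts$ok)) "ok" else "partial"),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (%s): %d stack(s)\n", x$status, nrow(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Write a pipeline manifest as JSON
#'
#' @param result a `pipeline_result`.
#' @param path JSON output path.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
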