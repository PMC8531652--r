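#' Rank PCA components by class separation
#'
#' Two-sided Wilcoxon rank-sum test of positive against negative voxels for
#' each component, sorted by ascending p-value (most discriminative first).
#' Because the test is rank-based, the ranking is invariant under strictly
#' monotone transforms of any component. A component constant across both
#' classes separates nothing and gets p = 1 (ranked last); p ties break by
#' ascending component index.
#'
#' @param positive,negative numeric matrices (voxels x components) of the
#'   two classes; same number of columns.
#' @return a `feature_ranking`: data frame with `component` and `p_value`,
#'   sorted ascending by p.
#' @export
rank_components_wilcoxon <- function(positive, negative) {
  stopifnot(is.matrix(positive), is.matrix(negative),
            ncol(positive) == ncol(negative),
            nrow(positive) > 0, nrow(negative) > 0)
  p <- vapply(seq_len(ncol(positive)), function(j)
    rank_sum_p(positive[, j], negative[, j]), 0)
  ord <- order(p, seq_along(p))
  structure(data.frame(component = ord, p_value = p[ord]),
            class = c("feature_ranking", "data.frame"))
}

# two-sided rank-sum p-value: stats::wilcox.test (exact where it applies)
# for small samples, and the tie-corrected, continuity-corrected normal
# approximation for large ones, where the exact test is both unavailable
# and unnecessary
rank_sum_p <- function(x, y) {
  v <- c(x, y)
  if (length(unique(v)) == 1L) return(1)
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (n <= 200) return(suppressWarnings(wilcox.test(x, y)$p.value))
  r <- rank(v)
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie_counts <- rle(sort(v))$lengths
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  z <- z - sign(z) * 0.5                 # continuity correction
  min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
}

# stratified random holdout: TRUE rows are held out
stratified_holdout <- function(labels, fraction, seed) {
  withr::with_seed(seed, {
    hold <- logical(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      n_hold <- max(1L, round(fraction * length(idx)))
      hold[sample(idx, n_hold)] <- TRUE
    }
    hold
  })
}

# stratified fold assignment; every training set (all folds but one) must
# contain both classes
stratified_folds <- function(labels, n_folds, seed) {
  tab <- table(labels)
  if (any(tab < 2))
    stop("stratified folding impossible: a class has fewer than 2 samples")
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in names(tab)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Cross-validated choice of the feature count
#'
#' For each candidate count `k`, trains the classifier on the top-`k`
#' ranked components and measures accuracy. A stratified 30% holdout is
#' fixed once per run; the 10 folds resample the remaining 70% into
#' training sets, and each fold's model is scored on the holdout. The
#' optimal count is the smallest `k` attaining the maximal mean accuracy.
#'
#' @param samples numeric matrix (voxels x components, PCA scores).
#' @param labels factor/character vector with two classes.
#' @param ranking a `feature_ranking` from [rank_components_wilcoxon()].
#' @param spec a [classifier_spec()]; its `k` field is ignored (swept).
#' @param ks candidate feature counts (default `1:ncol(samples)`).
#' @param holdout_fraction fraction reserved for testing (default 0.3).
#' @param n_folds folds over the training pool (default 10).
#' @param seed RNG seed for the holdout, folds and model training.
#' @return an `accuracy_curve`: data frame `k`, `mean_accuracy`,
#'   `sd_accuracy`, with attribute `optimal_k`.
#' @export
select_feature_count_cv <- function(samples, labels, ranking, spec,
                                    ks = NULL, holdout_fraction = 0.3,
                                    n_folds = 10, seed = 1L) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2, is.matrix(samples))
  if (is.null(ks)) ks <- seq_len(ncol(samples))
  stopifnot(max(ks) <= ncol(samples))
  hold <- stratified_holdout(labels, holdout_fraction, seed)
  pool <- which(!hold)
  fold <- stratified_folds(labels[pool], n_folds, seed + 1L)
  ord <- ranking$component

  rows <- lapply(ks, function(k) {
    cols <- ord[seq_len(k)]
    acc <- vapply(seq_len(n_folds), function(f) {
      tr <- pool[fold != f]
      model <- train_model(classifier_spec(spec$kind, k = k, params = spec$params),
                           samples[tr, cols, drop = FALSE], labels[tr],
                           seed = seed + f)
      pred <- predict_classes(model, samples[hold, cols, drop = FALSE])
      mean(pred == labels[hold])
    }, 0)
    data.frame(k = k, mean_accuracy = mean(acc), sd_accuracy = sd(acc))
  })
  curve <- do.call(rbind, rows)
  best <- curve$k[which.max(curve$mean_accuracy)]
  structure(curve, class = c("accuracy_curve", "data.frame"),
            optimal_k = best)
}

#' Write an accuracy curve as CSV
#'
#' @param curve an `accuracy_curve`.
#' @param path CSV output path.
#' @export
write_accuracy_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
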