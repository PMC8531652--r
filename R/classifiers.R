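#' Pixel classifier specification
#'
#' Four classifier families are supported, with the reference
#' hyperparameters of the pipeline:
#'
#' * `"nb"` - naive Bayes with Gaussian class-conditionals.
#' * `"da"` - discriminant analysis with a quadratic discriminator; a
#'   degenerate class covariance falls back to a ridge-regularized Gaussian
#'   discriminant (ridge term logged in the model).
#' * `"rf"` - random forest with 100 trees and minimum terminal node size
#'   100. Split predictors are chosen by standard impurity search; the
#'   platform-specific interaction-curvature split test has no portable
#'   equivalent, and tree count / leaf size dominate behavior.
#' * `"mlp"` - multilayer perceptron with one hidden layer of 100 units and
#'   L2 penalty 0.0001, trained by quasi-Newton optimization on
#'   standardized inputs (the stochastic-gradient batch size 5000 and
#'   initial learning rate 0.1 of the reference description do not apply to
#'   a full-batch optimizer; they are recorded in the spec for
#'   provenance).
#'
#' @param kind one of `"nb"`, `"da"`, `"rf"`, `"mlp"`.
#' @param k number of (ranked) PCA components the model consumes.
#' @param params named list overriding the per-kind defaults
#'   (`rf`: `ntree`, `nodesize`; `mlp`: `size`, `decay`, `maxit`,
#'   `max_rows`; `da`: `ridge`; all: `max_rows` subsample cap).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rf", "mlp", "nb", "da"), k = 1L,
                            params = list()) {
  kind <- match.arg(kind)
  stopifnot(k >= 1)
  defaults <- switch(kind,
    nb  = list(max_rows = 2e5),
    da  = list(ridge = 1e-6, max_rows = 2e5),
    rf  = list(ntree = 100L, nodesize = 100L, max_rows = 3e4),
    mlp = list(size = 100L, decay = 1e-4, maxit = 30L, max_rows = 2e4,
               batch_size = 5000L, initial_lr = 0.1)
  )
  defaults[names(params)] <- params
  structure(list(kind = kind, k = as.integer(k), params = defaults),
            class = "classifier_spec")
}

as_binary_factor <- function(labels) {
  f <- factor(labels)
  stopifnot(nlevels(f) == 2)
  f
}

#' Train a pixel classifier
#'
#' @param spec a [classifier_spec()].
#' @param samples numeric matrix (voxels x `spec$k` components).
#' @param labels two-class factor/character vector ("neg"/"pos" by
#'   convention; the second factor level is treated as positive).
#' @param seed RNG seed (subsampling, forest bootstrap, MLP init).
#' @return a fitted `pixel_classifier` carrying the spec, seed and fit.
#' @export
train_model <- function(spec, samples, labels, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(samples))
  labels <- as_binary_factor(labels)
  stopifnot(nrow(samples) == length(labels))
  cap <- spec$params$max_rows
  if (!is.null(cap) && nrow(samples) > cap) {
    keep <- withr::with_seed(seed, sample.int(nrow(samples), cap))
    samples <- samples[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (nlevels(droplevels(labels)) < 2) stop("both classes must be present")
  colnames(samples) <- paste0("c", seq_len(ncol(samples)))

  fit <- withr::with_seed(seed, switch(spec$kind,
    nb = e1071::naiveBayes(as.data.frame(samples), labels),
    da = fit_quadratic_da(samples, labels, spec$params$ridge),
    rf = randomForest::randomForest(samples, labels,
                                    ntree = spec$params$ntree,
                                    nodesize = spec$params$nodesize),
    mlp = {
      ctr <- colMeans(samples)
      scl <- apply(samples, 2, sd)
      scl[scl == 0] <- 1
      xs <- sweep(sweep(samples, 2, ctr), 2, scl, `/`)
      net <- nnet::nnet(xs, as.numeric(labels) - 1,
                        size = spec$params$size, decay = spec$params$decay,
                        maxit = spec$params$maxit, entropy = TRUE,
                        MaxNWts = 1e6, trace = FALSE)
      list(net = net, center = ctr, scale = scl)
    }
  ))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 levels = levels(labels), seed = seed,
                 k = ncol(samples)),
            class = "pixel_classifier")
}

# quadratic discriminant with ridge fallback for degenerate covariances
fit_quadratic_da <- function(samples, labels, ridge) {
  qfit <- tryCatch(MASS::qda(samples, labels), error = function(e) NULL)
  if (!is.null(qfit)) return(list(qda = qfit, ridge = 0))
  classes <- levels(labels)
  per <- lapply(classes, function(cl) {
    x <- samples[labels == cl, , drop = FALSE]
    cv <- stats::cov(x) + ridge * diag(ncol(x))
    list(mean = colMeans(x), cov = cv, inv = solve(cv),
         logdet = determinant(cv, logarithm = TRUE)$modulus,
         logprior = log(nrow(x) / nrow(samples)))
  })
  names(per) <- classes
  list(gda = per, ridge = ridge)
}

#' Predict class labels for component samples
#'
#' @param model a `pixel_classifier`.
#' @param samples numeric matrix with `model$k` columns.
#' @param threshold decision threshold on the positive-class score for
#'   probabilistic models (default 0.5).
#' @return factor with the training levels.
#' @export
predict_classes <- function(model, samples, threshold = 0.5) {
  stopifnot(inherits(model, "pixel_classifier"))
  if (ncol(samples) != model$k)
    stop(sprintf("model expects %d components, got %d", model$k, ncol(samples)))
  colnames(samples) <- paste0("c", seq_len(ncol(samples)))
  lv <- model$levels
  out <- switch(model$kind,
    nb = predict(model$fit, as.data.frame(samples)),
    da = {
      if (!is.null(model$fit$qda)) {
        predict(model$fit$qda, samples)$class
      } else {
        scores <- vapply(model$fit$gda, function(g) {
          d <- sweep(samples, 2, g$mean)
          -0.5 * rowSums((d %*% g$inv) * d) - 0.5 * as.numeric(g$logdet) +
            g$logprior
        }, numeric(nrow(samples)))
        factor(lv[max.col(scores)], levels = lv)
      }
    },
    rf = {
      prob <- predict(model$fit, samples, type = "prob")[, lv[2]]
      factor(ifelse(prob >= threshold, lv[2], lv[1]), levels = lv)
    },
    mlp = {
      xs <- sweep(sweep(samples, 2, model$fit$center), 2, model$fit$scale, `/`)
      prob <- as.numeric(predict(model$fit$net, xs))
      factor(ifelse(prob >= threshold, lv[2], lv[1]), levels = lv)
    }
  )
  out <- factor(out, levels = lv)
  names(out) <- NULL
  out
}

#' Predict a binary segmentation volume
#'
#' Applies a trained pixel classifier voxel-wise to projected PCA scores of
#' a full stack. No post-processing is applied here; see [clean_mask()].
#'
#' @param model a `pixel_classifier`.
#' @param scores matrix of PCA component scores for every voxel (at least
#'   `model$k` columns, ordered as the model's training components).
#' @param dims `(y, x, z)` dimensions of the stack.
#' @return logical array: `TRUE` = positive (pycnotic-nucleus signal).
#' @export
predict_mask <- function(model, scores, dims) {
  if (ncol(scores) < model$k)
    stop(sprintf("model expects %d components, got %d", model$k, ncol(scores)))
  stopifnot(nrow(scores) == prod(dims))
  pred <- predict_classes(model, scores[, seq_len(model$k), drop = FALSE])
  array(pred == model$levels[2], dim = dims)
}

#' Leave-one-stack-out evaluation
#'
#' Trains on the labeled voxels of all stacks but one and classifies the
#' held-out stack's labeled voxels, for each stack in turn. PCA and the
#' Wilcoxon component ranking are refitted on each training pool so the
#' held-out stack never influences feature extraction. Confusion counts
#' run over labeled voxels only; a stack with no labeled voxels is excluded
#' with a warning.
#'
#' @param training_sets list with one element per stack:
#'   `list(features, labels, stack_id, damage)`, where `features` is the
#'   (voxels x channels) raw feature matrix of the labeled voxels and
#'   `labels` the matching "neg"/"pos" factor. See
#'   [prepare_training_data()].
#' @param spec a [classifier_spec()], or a (possibly named) list of them:
#'   the expensive per-fold PCA and ranking are then shared across models.
#'   The spec's `k` is replaced per `variance_fraction` unless `fixed_k`
#'   is given.
#' @param variance_fraction choose the component count as the number of
#'   PCA components explaining this variance fraction (default 0.99).
#' @param fixed_k override the component count.
#' @param seed RNG seed.
#' @return an `eval_report` data frame: per stack `stack_id`, `damage`,
#'   `tp`, `tn`, `fp`, `fn`, `accuracy`; attribute `median_accuracy`.
#'   For a list of specs, a named list of `eval_report`s.
#' @export
evaluate_loo <- function(training_sets, spec, variance_fraction = 0.99,
                         fixed_k = NULL, seed = 1L) {
  single <- inherits(spec, "classifier_spec")
  specs <- if (single) list(spec) else spec
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, "", "kind")
  stopifnot(length(training_sets) >= 2)
  usable <- vapply(training_sets, function(ts) length(ts$labels) > 0, TRUE)
  if (!all(usable)) {
    warning(sprintf("%d stack(s) without labeled voxels excluded", sum(!usable)))
    training_sets <- training_sets[usable]
  }
  folds <- lapply(seq_along(training_sets), function(i) {
    pool <- training_sets[-i]
    xtr <- do.call(rbind, lapply(pool, `[[`, "features"))
    ytr <- factor(unlist(lapply(pool, function(ts) as.character(ts$labels))),
                  levels = c("neg", "pos"))
    pca <- fit_pca(xtr, seed = seed)
    str <- project_pca(xtr, pca)
    ranking <- rank_components_wilcoxon(str[ytr == "pos", , drop = FALSE],
                                        str[ytr == "neg", , drop = FALSE])
    k <- if (!is.null(fixed_k)) min(fixed_k, ncol(str))
         else components_for_variance(pca, variance_fraction)
    cols <- ranking$component[seq_len(k)]

    ts <- training_sets[[i]]
    ste <- project_pca(ts$features, pca)[, cols, drop = FALSE]
    yte <- factor(as.character(ts$labels), levels = c("neg", "pos"))

    per_spec <- lapply(specs, function(sp0) {
      sp <- classifier_spec(sp0$kind, k = k, params = sp0$params)
      model <- train_model(sp, str[, cols, drop = FALSE], ytr, seed = seed + i)
      pred <- predict_classes(model, ste)
      tp <- sum(pred == "pos" & yte == "pos")
      tn <- sum(pred == "neg" & yte == "neg")
      fp <- sum(pred == "pos" & yte == "neg")
      fn <- sum(pred == "neg" & yte == "pos")
      data.frame(stack_id = if (is.null(ts$stack_id)) as.character(i) else ts$stack_id,
                 damage = if (is.null(ts$damage)) NA_character_ else ts$damage,
                 tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn))
    })
    per_spec
  })
  reports <- lapply(names(specs), function(nm) {
    report <- do.call(rbind, lapply(folds, `[[`, nm))
    structure(report, class = c("eval_report", "data.frame"),
              median_accuracy = median(report$accuracy),
              model_kind = specs[[nm]]$kind)
  })
  names(reports) <- names(specs)
  if (single) reports[[1]] else reports
}

#' Write an evaluation report as CSV
#'
#' @param report an `eval_report`.
#' @param path CSV output path.
#' @export
write_eval_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Merge evaluation reports by pooling confusion counts
#'
#' Accuracy of the merged report per stack is recomputed from the pooled
#' counts, so merged TP equals the sum of subset TPs by construction.
#'
#' @param ... `eval_report` objects.
#' @return an `eval_report` with all rows.
#' @export
merge_eval_reports <- function(...) {
  reports <- list(...)
  merged <- do.call(rbind, lapply(reports, as.data.frame))
  structure(merged, class = c("eval_report", "data.frame"),
            median_accuracy = median(merged$accuracy))
}
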