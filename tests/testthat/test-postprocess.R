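test_that("mask cleaning applies the dim cut, closing and size rule in order", {
  ny <- 40; nx <- 60
  stack <- array(1, dim = c(ny, nx, 1))
  mask <- array(FALSE, dim = c(ny, nx, 1))
  # 29-px and 30-px strips at full intensity
  mask[5, 1:29, 1] <- TRUE
  mask[15, 1:30, 1] <- TRUE
  cleaned <- clean_mask(mask, stack)
  expect_equal(sum(cleaned[5, , 1]), 0)     # 29 px: removed (< 30)
  expect_equal(sum(cleaned[15, , 1]), 30)   # 30 px: kept

  # dim-pixel rule: strictly below 0.1 x max is cut before size filtering
  stack2 <- array(1, dim = c(ny, nx, 1))
  mask2 <- array(FALSE, dim = c(ny, nx, 1))
  mask2[25, 1:50, 1] <- TRUE
  stack2[25, 1:20, 1] <- 0.09    # dim segment, then a 30-px bright segment
  stack2[25, 21:50, 1] <- 0.11
  cleaned2 <- clean_mask(mask2, stack2)
  expect_false(any(cleaned2[25, 1:19, 1]))   # dim side gone
  expect_equal(sum(cleaned2[25, 21:50, 1]), 30)

  expect_equal(sum(clean_mask(array(FALSE, dim = c(8, 8, 2)),
                              array(1, dim = c(8, 8, 2)))), 0)
})

test_that("mask cleaning is idempotent", {
  gs <- small_synth(seed = 53)
  ns <- normalize_stack(gs$stack)
  mask <- ns$data > 0.4
  c1 <- clean_mask(mask, ns)
  c2 <- clean_mask(c1, ns)
  expect_identical(c1, c2)
})

test_that("closing bridges small gaps", {
  stack <- array(1, dim = c(20, 20, 1))
  mask <- array(FALSE, dim = c(20, 20, 1))
  mask[8:12, 5:9, 1] <- TRUE
  mask[8:12, 11:15, 1] <- TRUE   # one-column gap at x = 10
  cleaned <- clean_mask(mask, stack)
  expect_true(all(cleaned[8:12, 10, 1]))
})

test_that("object descriptors match analytic shapes", {
  disc <- disc_mask(11)
  obj <- extract_objects(disc)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$area, sum(disc))
  expect_equal(obj$circularity, 1, tolerance = 0.1)   # 4*pi*A/P^2 on the disc
  expect_equal(obj$equiv_diameter, sqrt(4 * sum(disc) / pi))
  expect_lt(obj$eccentricity, 0.1)
  expect_equal(obj$major_axis, 11, tolerance = 0.6)

  sq <- matrix(FALSE, 20, 20); sq[5:12, 6:13] <- TRUE
  osq <- extract_objects(sq)
  expect_equal(osq$solidity, 1)
  expect_equal(osq$extent, 1)
  expect_equal(osq$convex_area, 64)
  expect_equal(osq$area, 64)

  two <- matrix(FALSE, 40, 40)
  two[5:10, 5:10] <- TRUE; two[25:30, 25:30] <- TRUE
  otwo <- extract_objects(two)
  expect_equal(nrow(otwo), 2)
  px <- attr(otwo, "pixels")
  expect_equal(nrow(unique(rbind(px[[1]], px[[2]]))), nrow(px[[1]]) + nrow(px[[2]]))

  expect_equal(nrow(extract_objects(matrix(FALSE, 5, 5))), 0)
})

test_that("object matching enforces the strict 10-px rule", {
  mk_obj <- function(xs, ys) {
    m <- matrix(FALSE, 80, 80)
    for (i in seq_along(xs)) m[ys[i], xs[i]] <- TRUE
    extract_objects(m)
  }
  # single-pixel objects give exact centroids
  obj <- mk_obj(c(20, 50), c(20, 50))
  pos <- data.frame(x = 20 + 9.9, y = 20)      # 9.9 px away: match
  neg <- data.frame(x = 50 + 10.1, y = 50)     # 10.1 px away: no match
  rep <- match_objects(obj, pos, neg)
  expect_equal(as.character(rep$verdicts), c("true_positive", "discarded"))
  expect_equal(rep$recall, 1)

  # equidistant positive and negative at 9 px: positive wins the tie
  obj2 <- mk_obj(40, 40)
  rep2 <- match_objects(obj2, data.frame(x = 49, y = 40),
                        data.frame(x = 31, y = 40))
  expect_equal(as.character(rep2$verdicts), "true_positive")

  # each manual point is consumed at most once
  obj3 <- mk_obj(c(30, 33), c(30, 30))
  rep3 <- match_objects(obj3, data.frame(x = 31, y = 30))
  expect_equal(sum(rep3$verdicts == "true_positive"), 1)
  expect_equal(sum(rep3$verdicts == "discarded"), 1)

  # verdict counts partition the object list
  expect_equal(sum(rep3$counts), 2)
})

# synthetic object tables: compact round objects vs ragged elongated ones
shape_objects <- function(n_tp, n_fp, seed = 60) {
  withr::with_seed(seed, {
    tp <- data.frame(
      area = rnorm(n_tp, 80, 10), convex_area = rnorm(n_tp, 85, 10),
      eccentricity = runif(n_tp, 0, 0.3), equiv_diameter = rnorm(n_tp, 10, 1),
      extent = runif(n_tp, 0.7, 0.85), major_axis = rnorm(n_tp, 10, 1),
      minor_axis = rnorm(n_tp, 9, 1), perimeter = rnorm(n_tp, 33, 3),
      solidity = runif(n_tp, 0.9, 1), circularity = runif(n_tp, 0.85, 1)
    )
    fp <- data.frame(
      area = rnorm(n_fp, 60, 25), convex_area = rnorm(n_fp, 110, 30),
      eccentricity = runif(n_fp, 0.8, 0.99), equiv_diameter = rnorm(n_fp, 8, 2),
      extent = runif(n_fp, 0.2, 0.5), major_axis = rnorm(n_fp, 25, 6),
      minor_axis = rnorm(n_fp, 4, 1), perimeter = rnorm(n_fp, 70, 15),
      solidity = runif(n_fp, 0.4, 0.7), circularity = runif(n_fp, 0.1, 0.4)
    )
    list(objects = rbind(tp, fp),
         verdicts = factor(rep(c("true_positive", "false_positive"),
                               c(n_tp, n_fp)),
                           levels = c("true_positive", "false_positive", "discarded")))
  })
}

test_that("the morphology SVM separates compact from ragged objects", {
  d <- shape_objects(120, 120)
  f <- train_fp_svm(d$objects, d$verdicts, n_splits = 40, seed = 1)
  expect_equal(f$type, "svm")
  expect_gt(f$cv_median["sensitivity"], 0.9)
  expect_gt(f$cv_median["specificity"], 0.9)
  kept <- filter_false_positives(d$objects, f)
  expect_lte(nrow(kept), nrow(d$objects))
  expect_true(all(rownames(kept) %in% rownames(d$objects)))
})

test_that("extreme class imbalance drives specificity down, not sensitivity", {
  # the 71:1 true-to-false-positive regime: nearly all true positives are
  # kept while few false positives are caught
  d <- shape_objects(355, 5, seed = 61)
  f <- train_fp_svm(d$objects, d$verdicts, n_splits = 40, seed = 2)
  expect_gt(f$cv_median["sensitivity"], 0.97)
  expect_lt(f$cv_median["specificity"], f$cv_median["sensitivity"])
})

test_that("too few false positives degrade to the identity filter", {
  d <- shape_objects(50, 1, seed = 62)
  expect_warning(f <- train_fp_svm(d$objects, d$verdicts), "identity")
  expect_equal(f$type, "identity")
  kept <- filter_false_positives(d$objects, f)
  expect_equal(nrow(kept), nrow(d$objects))
})

test_that("Hough splitting resolves isolated and overlapping discs", {
  disc <- disc_mask(10, size = 40)
  circ <- split_objects_hough(disc)
  expect_equal(nrow(circ), 1)
  expect_lt(abs(circ$x - 20.5) + abs(circ$y - 20.5), 2.1)

  # two discs with centers one radius apart merge into one component but
  # produce two circles
  m2 <- two_disc_mask(c(25, 30), c(30, 30), radius = 5)
  expect_equal(nrow(extract_objects(m2)), 1)
  c2 <- split_objects_hough(m2)
  expect_equal(nrow(c2), 2)
  ord <- order(c2$x)
  expect_lt(abs(c2$x[ord[1]] - 25) + abs(c2$y[ord[1]] - 30), 2.1)
  expect_lt(abs(c2$x[ord[2]] - 30) + abs(c2$y[ord[2]] - 30), 2.1)

  expect_equal(nrow(split_objects_hough(matrix(FALSE, 30, 30))), 0)
})

test_that("recall follows the strict matching rule and its bounds", {
  pts <- data.frame(x = c(10, 30, 50), y = c(10, 30, 50))
  expect_equal(compute_recall(data.frame(x = c(11, 29, 51), y = c(10, 31, 49)), pts), 1)
  expect_equal(compute_recall(data.frame(x = numeric(0), y = numeric(0)), pts), 0)
  expect_equal(compute_recall(data.frame(x = 10 + 10, y = 10),
                              data.frame(x = 10, y = 10)), 0)  # exactly 10 px: no
  expect_message(r <- compute_recall(data.frame(x = 1, y = 1),
                                     data.frame(x = numeric(0), y = numeric(0))),
                 "undefined")
  expect_true(is.na(r))
})
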