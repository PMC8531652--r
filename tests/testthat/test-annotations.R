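# a single smooth blob with a known peak on a dark background
blob_stack <- function(center = c(20, 20, 2), peak = 0.9, radius = 4,
                       shape = c(4, 40, 40)) {
  vol <- array(0, dim = c(shape[2], shape[3], shape[1]))
  for (z in seq_len(shape[1])) for (y in seq_len(shape[2])) for (x in seq_len(shape[3])) {
    d2 <- (x - center[1])^2 + (y - center[2])^2 + 4 * (z - center[3])^2
    vol[y, x, z] <- peak * exp(-d2 / (2 * radius^2))
  }
  image_stack(vol, stack_id = "blob")
}

test_that("clicks already on a maximum are fixed points of refinement", {
  st <- blob_stack()
  out <- refine_clicks_hmax(st, data.frame(x = 20, y = 20, z = 2), h = 0.1)
  expect_equal(out$x, 20)
  expect_equal(out$y, 20)
  expect_equal(out$z, 2)
  expect_false(out$flagged)
})

test_that("off-center clicks snap to the intensity peak", {
  st <- blob_stack()
  out <- refine_clicks_hmax(st, data.frame(x = 22, y = 19, z = 2), h = 0.1)
  # brute-force argmax over the search ball around the click
  best <- c(-Inf, NA, NA, NA)
  for (z in 1:4) for (y in 14:24) for (x in 17:27) {
    if ((x - 22)^2 + (y - 19)^2 <= 25 && st$data[y, x, z] > best[1])
      best <- c(st$data[y, x, z], x, y, z)
  }
  expect_equal(c(out$x, out$y, out$z), best[2:4])
})

test_that("every click maps to a unique global maximum", {
  st <- blob_stack()
  clicks <- data.frame(x = c(18, 21, 23), y = c(18, 22, 20), z = c(2, 2, 2))
  out <- refine_clicks_hmax(st, clicks, h = 0.01)
  expect_true(all(out$x == 20 & out$y == 20 & out$z == 2))
})

test_that("refinement is idempotent on synthetic stacks", {
  gs <- small_synth(seed = 29)
  ns <- normalize_stack(gs$stack)
  ann <- generate_annotations(gs$truth, gs$config)
  s1 <- refine_clicks_hmax(ns, ann$clicks)
  s2 <- refine_clicks_hmax(ns, s1[, c("x", "y", "z")])
  expect_identical(s1[, c("x", "y", "z")], s2[, c("x", "y", "z")])
})

test_that("h at or above the dynamic range is an error naming the clicks", {
  st <- blob_stack()
  expect_error(refine_clicks_hmax(st, data.frame(x = 20, y = 20, z = 2), h = 1),
               "dynamic range")
})

test_that("clicks with no reachable maximum are flagged, not dropped", {
  st <- blob_stack()
  out <- refine_clicks_hmax(st, data.frame(x = 38, y = 38, z = 4), h = 0.1)
  expect_true(out$flagged)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 38)
})

test_that("polygon rasterization follows the even-odd pixel-center rule", {
  # 10x10 square with half-integer corners: exactly 100 strictly-inside centers
  poly <- list(z = 1, x = c(5.5, 15.5, 15.5, 5.5), y = c(3.5, 3.5, 13.5, 13.5))
  vol <- rasterize_negatives(list(poly), c(2, 30, 30))
  expect_equal(sum(vol), 100)
  # brute-force point-in-polygon oracle over the slice
  brute <- 0
  for (y in 1:30) for (x in 1:30) {
    # crossing number, straight from the definition
    inside <- FALSE
    vx <- poly$x; vy <- poly$y; j <- 4
    for (i in 1:4) {
      if ((vy[i] > y) != (vy[j] > y)) {
        xi <- vx[i] + (y - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
        if (x < xi) inside <- !inside
      }
      j <- i
    }
    brute <- brute + inside
  }
  expect_equal(sum(vol[, , 1]), brute)

  expect_equal(sum(rasterize_negatives(list(), c(2, 30, 30))), 0)

  # disjoint polygons: negative counts add
  p2 <- list(z = 2, x = c(20.5, 25.5, 25.5, 20.5), y = c(20.5, 20.5, 25.5, 25.5))
  both <- rasterize_negatives(list(poly, p2), c(2, 30, 30))
  expect_equal(sum(both), sum(vol) + 25)
})

test_that("degenerate polygons are rejected", {
  expect_error(rasterize_negatives(list(list(z = 1, x = c(1, 2), y = c(1, 2))),
                                   c(1, 10, 10)),
               "3 vertices")
  expect_error(annotation_set(data.frame(x = 1, y = 1, z = 1),
                              list(list(z = 1, x = c(1, 2), y = c(1, 2)))),
               "3 vertices")
})

test_that("label masks cover the h-maxima dome of each seeded nucleus", {
  st <- blob_stack()
  seeds <- refine_clicks_hmax(st, data.frame(x = 20, y = 20, z = 2), h = 0.1)
  lm <- build_label_mask(st, seeds, h = 0.1)
  # oracle: the dome of an isolated blob is everything above peak - h
  oracle <- st$data > (max(st$data) - 0.1 + 1e-9)
  expect_identical(lm$mask == 2L, oracle)
  expect_equal(lm$n_positive, sum(oracle))

  empty <- build_label_mask(st, NULL, NULL)
  expect_equal(empty$n_positive + empty$n_negative, 0)
})

test_that("positive/negative conflicts resolve to positive with a warning", {
  st <- blob_stack()
  seeds <- data.frame(x = 20, y = 20, z = 2, flagged = FALSE)
  neg <- rasterize_negatives(list(list(z = 2, x = c(15.5, 25.5, 25.5, 15.5),
                                       y = c(15.5, 15.5, 25.5, 25.5))),
                             c(4, 40, 40))
  expect_warning(lm <- build_label_mask(st, seeds, neg, h = 0.1),
                 "resolved to positive")
  expect_equal(lm$mask[20, 20, 2], 2L)
})

test_that("positive voxel count grows with the number of seeds", {
  gs <- small_synth(seed = 37)
  ns <- normalize_stack(gs$stack)
  ann <- generate_annotations(gs$truth, gs$config)
  seeds <- refine_clicks_hmax(ns, ann$clicks)
  counts <- vapply(c(2, 5, nrow(seeds)), function(n)
    build_label_mask(ns, seeds[seq_len(n), ], NULL)$n_positive, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("label masks round-trip bit-exactly through TIFF", {
  gs <- small_synth(seed = 41)
  ns <- normalize_stack(gs$stack)
  ann <- generate_annotations(gs$truth, gs$config)
  seeds <- refine_clicks_hmax(ns, ann$clicks)
  dims <- dim(ns$data)
  neg <- rasterize_negatives(ann$negative_polygons, c(dims[3], dims[1], dims[2]))
  lm <- build_label_mask(ns, seeds, neg)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_label_mask(lm, path)
  back <- read_label_mask(path)
  expect_identical(back$mask, lm$mask)
})
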