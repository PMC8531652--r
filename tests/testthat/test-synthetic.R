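test_that("empty stack contains background only", {
  cfg <- synth_config(shape = c(4, 48, 48), n_nuclei = 0, seed = 1)
  gs <- generate_stack(cfg)
  expect_equal(nrow(gs$truth$nuclei), 0)
  # background field + noise only: nothing approaching nucleus intensity
  expect_lt(max(gs$stack$data), cfg$nucleus_peak_intensity[1])
})

test_that("nucleus radii respect the configured diameter range", {
  gs <- small_synth(seed = 3)
  r <- gs$truth$nuclei$radius
  expect_true(all(r >= 2.5 & r <= 7.5))
  d2 <- generate_stack(synth_config(shape = c(4, 64, 64), n_nuclei = 6,
                                    diameter_range = c(6, 10), seed = 5))
  expect_true(all(d2$truth$nuclei$radius >= 3 & d2$truth$nuclei$radius <= 5))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(shape = c(4, 64, 64), seed = 9)
  a <- generate_stack(cfg)
  b <- generate_stack(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_annotations(a$truth, cfg),
                   generate_annotations(b$truth, cfg))
})

test_that("annotation click counts follow the label fraction", {
  cfg <- synth_config(shape = c(6, 128, 128), n_nuclei = 40,
                      label_fraction = 0.5, seed = 11)
  gs <- generate_stack(cfg)
  ann <- generate_annotations(gs$truth, cfg)
  expect_equal(nrow(ann$clicks), 20)   # round(0.5 * 40)

  cfg_all <- synth_config(shape = c(4, 64, 64), label_fraction = 1, seed = 2)
  gs_all <- generate_stack(cfg_all)
  expect_equal(nrow(generate_annotations(gs_all$truth, cfg_all)$clicks),
               nrow(gs_all$truth$nuclei))

  cfg_none <- synth_config(shape = c(4, 64, 64), label_fraction = 0, seed = 2)
  gs_none <- generate_stack(cfg_none)
  ann_none <- generate_annotations(gs_none$truth, cfg_none)
  expect_equal(nrow(ann_none$clicks), 0)
  expect_gt(length(ann_none$negative_polygons), 0)
})

test_that("clicks are jittered by at most 2 px from their nucleus center", {
  gs <- small_synth(seed = 13)
  ann <- generate_annotations(gs$truth, gs$config)
  # every click must lie within 2 px (plus rounding) of some nucleus center
  for (i in seq_len(nrow(ann$clicks))) {
    d <- sqrt((gs$truth$nuclei$x - ann$clicks$x[i])^2 +
                (gs$truth$nuclei$y - ann$clicks$y[i])^2)
    expect_lt(min(d), 2 + sqrt(2) / 2)
  }
})

test_that("cohorts split into damage classes exactly", {
  base <- synth_config(shape = c(4, 64, 64), seed = 21)
  cohort <- generate_cohort(10, 0.5, base)
  expect_equal(sum(vapply(cohort, `[[`, "", "damage") == "high"), 5)
  expect_equal(sum(vapply(cohort, `[[`, "", "damage") == "low"), 5)

  # the reference cohort proportion: 52 of 117 stacks are high damage
  big <- generate_cohort(117, 52 / 117, synth_config(shape = c(2, 56, 56), seed = 3))
  labels <- vapply(big, `[[`, "", "damage")
  expect_equal(sum(labels == "high"), 52)
  expect_equal(sum(labels == "low"), 65)

  again <- generate_cohort(10, 0.5, base)
  expect_identical(cohort[[4]]$stack$data, again[[4]]$stack$data)
})

test_that("nuclei are separable from background intensity", {
  for (cl in c("low", "high")) {
    gs <- small_synth(seed = 17, damage_class = cl)
    ns <- normalize_stack(gs$stack)
    nm <- nucleus_mask(gs$truth, gs$config$shape)
    expect_gt(mean(ns$data[nm]), quantile(ns$data[!nm], 0.95))
  }
})

test_that("ground-truth count matches connected bright components without overlap", {
  gs <- small_synth(seed = 19)
  nm <- nucleus_mask(gs$truth, gs$config$shape)
  labs <- pycnoseg:::label_components3d(nm)
  expect_equal(max(labs), nrow(gs$truth$nuclei))
})

test_that("negative polygons contain no nucleus voxels", {
  gs <- small_synth(seed = 23, damage_class = "high")
  dims <- dim(gs$stack$data)
  neg <- rasterize_negatives(gs$truth$negative_polygons,
                             c(dims[3], dims[1], dims[2]))
  nm <- nucleus_mask(gs$truth, gs$config$shape)
  expect_equal(sum(neg & nm), 0)
})

test_that("placement fails loudly when the stack cannot hold the nuclei", {
  cfg <- synth_config(shape = c(2, 32, 32), n_nuclei = 60, seed = 1)
  expect_error(generate_stack(cfg), "placement")
})

test_that("cohorts round-trip through disk as TIFF/JSON/CSV", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(2, 0.5, synth_config(shape = c(3, 48, 48), seed = 31))
  manifest <- write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  id <- cohort[[1]]$stack$stack_id
  st <- read_stack_tiff(file.path(dir, paste0(id, ".tiff")))
  expect_equal(dim(st$data), dim(cohort[[1]]$stack$data))
  ann <- read_annotations(file.path(dir, paste0(id, "_annotations.json")))
  expect_equal(ann$clicks, cohort[[1]]$annotations$clicks)
  expect_equal(length(ann$negative_polygons),
               length(cohort[[1]]$annotations$negative_polygons))
})
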