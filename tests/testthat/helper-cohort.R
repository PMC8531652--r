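# the study-scale synthetic cohorts used by the acceptance tests are
# expensive to build, so they are computed once per test run and shared

eval_cohort <- function() {
  if (is.null(.fixture_env$eval_cohort)) {
    base <- synth_config(seed = 42L)
    cohort <- generate_cohort(12, 0.5, base)
    cfg <- pipeline_config(seed = 42L)
    tsets <- lapply(cohort, function(el)
      suppressWarnings(prepare_training_data(el$stack, el$annotations, cfg,
                                             damage = el$damage)))
    .fixture_env$eval_cohort <- list(cohort = cohort, tsets = tsets,
                                     config = cfg)
  }
  .fixture_env$eval_cohort
}

overlap_cohort <- function() {
  if (is.null(.fixture_env$overlap_cohort)) {
    base <- synth_config(seed = 314L, overlap_fraction = 0.3,
                         label_fraction = 1)
    cohort <- generate_cohort(6, 0.5, base)
    cfg <- pipeline_config(seed = 314L)
    tsets <- lapply(cohort, function(el)
      suppressWarnings(prepare_training_data(el$stack, el$annotations, cfg,
                                             damage = el$damage)))
    .fixture_env$overlap_cohort <- list(cohort = cohort, tsets = tsets,
                                        config = cfg)
  }
  .fixture_env$overlap_cohort
}

# a small single-topology pipeline, trained and run on a 4-stack cohort
tiny_pipeline <- function() {
  if (is.null(.fixture_env$tiny_pipeline)) {
    cohort <- generate_cohort(4, 0.5, synth_config(shape = c(5, 96, 96), seed = 71,
                                                   label_fraction = 1))
    config <- pipeline_config(topology = "single",
                              classifier = classifier_spec("rf"),
                              seed = 71L)
    tsets <- lapply(cohort, function(el)
      suppressWarnings(prepare_training_data(el$stack, el$annotations, config,
                                             damage = el$damage)))
    registry <- suppressWarnings(train_segmentation_models(tsets, config))
    .fixture_env$tiny_pipeline <- list(cohort = cohort, config = config,
                                       tsets = tsets, registry = registry)
  }
  .fixture_env$tiny_pipeline
}

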