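# shared fixtures, all generated in code

# filled disc of the given diameter centered in a square matrix
disc_mask <- function(diameter, size = ceiling(diameter) + 10) {
  c0 <- (size + 1) / 2
  m <- matrix(FALSE, size, size)
  for (y in seq_len(size)) for (x in seq_len(size))
    if ((x - c0)^2 + (y - c0)^2 <= (diameter / 2)^2) m[y, x] <- TRUE
  m
}

# two filled discs with given centers/radius in one matrix
two_disc_mask <- function(c1, c2, radius, size = 60) {
  m <- matrix(FALSE, size, size)
  for (y in seq_len(size)) for (x in seq_len(size)) {
    if ((x - c1[1])^2 + (y - c1[2])^2 <= radius^2) m[y, x] <- TRUE
    if ((x - c2[1])^2 + (y - c2[2])^2 <= radius^2) m[y, x] <- TRUE
  }
  m
}

# small quick synthetic stack + truth, memoized per (seed, class)
.fixture_env <- new.env(parent = emptyenv())

small_synth <- function(seed = 7, damage_class = "low", overlap = 0) {
  key <- sprintf("synth_%d_%s_%g", seed, damage_class, overlap)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synth_config(shape = c(6, 96, 96), seed = seed,
                        damage_class = damage_class,
                        overlap_fraction = overlap)
    .fixture_env[[key]] <- c(generate_stack(cfg), list(config = cfg))
  }
  .fixture_env[[key]]
}
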