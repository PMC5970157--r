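# small configurations and grids used across the suite

tiny_config <- function(...) {
  defaults <- list(
    n_total = 1000L, n_groups = 10L, n_haplogroups = 50L,
    death_rate = 0.25, patrilineal = TRUE, n_generations = 10L, seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# one cultural group holding `sizes` across the first haplogroup columns
single_group_state <- function(sizes, n_haplogroups = max(length(sizes), 2L)) {
  counts <- matrix(0L, nrow = 1, ncol = n_haplogroups)
  counts[1, seq_along(sizes)] <- as.integer(sizes)
  grid_state(counts)
}

write_config_yaml <- function(path, ...) {
  cfg <- list(...)
  yaml::write_yaml(cfg, path)
  path
}
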