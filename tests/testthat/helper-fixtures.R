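# Shared fixtures, built once per test session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# A small dataset on a reduced workspace: fast to generate, enough for
# module-level behavior tests.
tiny_dataset <- function() {
  memo("tiny_ds", function() {
    cfg <- dataset_config(n_samples = 60, oversample = 3,
                          horizontal_offsets = 0, vertical_offsets = 30,
                          inplane_u = seq(-6, 9, by = 3))
    generate_dataset(cfg, seed = 421)
  })
}

tiny_arm <- function() arm_geometry()

# in-limit random poses
random_poses <- function(n, geom, seed = 1) {
  set.seed(seed)
  lims <- geom$joint_limits
  t(replicate(n, lims[, 1] + stats::runif(4) * (lims[, 2] - lims[, 1])))
}
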