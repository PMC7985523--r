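# Shared fixtures. The three desk-scale in-silico experiments are expensive
# (about 2-4 minutes each), so they are computed once per test run on first
# use and cached for every test that needs them.

.exp_cache <- new.env(parent = emptyenv())

cached_experiment <- function(kind) {
  if (is.null(.exp_cache[[kind]])) {
    .exp_cache[[kind]] <- run_insilico_experiment(
      kind, seed = 1, compare_lu = (kind == "generic"))
  }
  .exp_cache[[kind]]
}

# small phantom spec for fast generation-heavy tests
small_spec <- function(kind, seed = NULL, ...) {
  phantom_spec(kind, grid_shape = c(64L, 48L), voxel_size_mm = 0.2,
               seed = seed, ...)
}

# random sum-normalized spectra matrix
random_spectra <- function(n, k, seed = 1) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    m <- matrix(stats::rexp(n * k), n, k)
    m / rowSums(m)
  })
}
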