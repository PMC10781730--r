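# Shared fixtures, computed lazily once per test run.

.fix <- new.env(parent = emptyenv())

fix_trial40 <- function() {
  if (is.null(.fix$trial40)) .fix$trial40 <- canonical_trial(n_strides = 40)
  .fix$trial40
}

fix_states40 <- function() {
  if (is.null(.fix$states40)) .fix$states40 <- compute_states(fix_trial40())
  .fix$states40
}

fix_lib40 <- function() {
  if (is.null(.fix$lib40)) {
    st <- fix_states40()
    .fix$mask40 <- state_sample_mask(st, 2)
    .fix$lib40 <- build_library(st, .fix$mask40)
  }
  .fix$lib40
}

fix_mask40 <- function() {
  fix_lib40()
  .fix$mask40
}

# reduced-size pipeline configuration for the 40-stride fixture
fix_config <- function(...) {
  signature_config(n_test = 1200, n_centroids = 600, k_neighbors = 240,
                   resample_size = NULL, n_boot = 20, ...)
}

fix_result40 <- function() {
  if (is.null(.fix$result40))
    .fix$result40 <- identify_signatures(fix_trial40(), fix_config(), seed = 1)
  .fix$result40
}

# stacked-row indices of a sample set (exported nowhere; tests need it)
lib_rows <- function(lib, idx) templatesig:::.lib_rows(lib, idx)

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value - truth) / abs(truth), tol)
}
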