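# Shared fixtures, built once per test run.
#
# The full-size phantoms (128 x 128 x 192, the package default emulating a
# quarter-scale scanner grid) are used by the end-to-end validation tests;
# unit tests use a small 64 x 64 x 96 phantom for speed.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, .fixture_cache)) assign(name, make(), .fixture_cache)
  get(name, .fixture_cache)
}

phantom_default <- function() cached("ph_default", function()
  generate_phantom(phantom_spec("default")))

phantom_fibrotic <- function() cached("ph_fibrotic", function()
  generate_phantom(phantom_spec("fibrotic")))

phantom_small <- function() cached("ph_small", function()
  generate_phantom(phantom_spec("default", dims = c(64, 64, 96), seed = 7)))

segmented_default <- function() cached("seg_default", function() {
  ph <- phantom_default()
  segment_lung(ph$volume, base_slice = ph$base_slice)
})

segmented_fibrotic <- function() cached("seg_fibrotic", function() {
  ph <- phantom_fibrotic()
  segment_lung(ph$volume, base_slice = ph$base_slice)
})

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
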