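# Shared small-scale phantoms for unit tests. The ~4 mm field is kept but at a
# coarse pitch so individual tests stay fast; acceptance tests use the full
# cohort-evaluation scale.

test_spec <- function(stage = 1, seed = 1, frame = 512, pitch = 8, ...) {
  phantom_spec(stage = stage, frame_px = c(frame, frame),
               pixel_size_um = pitch, seed = seed, ...)
}

.phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(stage = 1, seed = 1, frame = 512, pitch = 8, ...) {
  key <- paste(stage, seed, frame, pitch, ..., sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(
      test_spec(stage = stage, seed = seed, frame = frame, pitch = pitch, ...))
  }
  .phantom_cache[[key]]
}
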