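# Small synthetic bundles are reused across test files; generation is
# deterministic per (seed, size, spec hash), so caching only saves time.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 1, size = "small") {
  key <- paste(seed, size)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture(seed = seed, size = size)
  }
  .fixture_cache[[key]]
}
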