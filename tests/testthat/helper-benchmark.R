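# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

benchmark_fixture <- function(seed = 42L) {
  cached(paste0("bench", seed), {
    b <- standard_benchmark(seed)
    b$stats <- compute_frame_statistics(b$frames)
    b
  })
}

low_snr_fixture <- function(seed = 42L) {
  cached(paste0("lowsnr", seed), low_snr_population(seed))
}
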