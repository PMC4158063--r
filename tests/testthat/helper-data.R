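# Shared fixtures. The full-scale simulated run is expensive, so it is built
# once per test session and cached.

.srdk_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.srdk_cache[[key]])) .srdk_cache[[key]] <- force(expr)
  .srdk_cache[[key]]
}

get_full_sim <- function() cached("full_sim", simulate_dataset(seed = 101L))

get_full_result <- function() cached("full_res", run_pipeline(get_full_sim()))

get_background_sim <- function() {
  cached("bg_sim",
         simulate_dataset(seed = 101L, n_hairpins = 0L, n_ssr_hairpins = 0L,
                          with_cascade = FALSE))
}

get_background_result <- function() {
  cached("bg_res", run_pipeline(get_background_sim()))
}

# A small single-hairpin dataset for unit tests of the discovery stage.
get_mini_sim <- function() {
  cached("mini_sim",
         simulate_dataset(seed = 7L, n_chrom = 1L, chrom_len = 12000L,
                          n_hairpins = 2L, n_ssr_hairpins = 1L,
                          n_transcripts = 4L, srna_depth = 2000L,
                          degradome_depth = 600L))
}

# Perfect-stem precursor with the mature on the 5' arm.
perfect_hairpin <- function(mature = "GCATCGGATTCAGCTAGCATGG",
                            loop = "CAACA", lead = "", trail = "") {
  paste0(lead, mature, loop, rc_str(mature), trail)
}
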