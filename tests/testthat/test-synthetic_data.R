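test_that("generators are deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(outdir = d1, seed = 5L, n_chrom = 1L, chrom_len = 9000L,
                   n_hairpins = 2L, n_ssr_hairpins = 1L, n_transcripts = 4L,
                   srna_depth = 1500L, degradome_depth = 400L)
  simulate_dataset(outdir = d2, seed = 5L, n_chrom = 1L, chrom_len = 9000L,
                   n_hairpins = 2L, n_ssr_hairpins = 1L, n_transcripts = 4L,
                   srna_depth = 1500L, degradome_depth = 400L)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the genome
  g3 <- simulate_genome(1L, 9000L, 2L, 1L, seed = 6L)
  g5 <- simulate_genome(1L, 9000L, 2L, 1L, seed = 5L)
  expect_false(identical(g3$genome, g5$genome))
})

test_that("planted hairpins fold back and carry their manifests", {
  sim <- get_mini_sim()
  mir <- sim$truth$mirnas
  expect_equal(nrow(mir), 2L)
  expect_equal(nchar(mir$mature_seq[mir$is_trigger]), 22L)
  expect_equal(substr(mir$mature_seq[mir$is_trigger], 1, 1), "T")  # 5' U
  for (r in seq_len(nrow(mir))) {
    g <- sim$genome[[mir$chrom[r]]]
    prec <- substr(g, mir$precursor_start[r], mir$precursor_end[r])
    if (mir$strand[r] == "-") prec <- rc_str(prec)
    expect_true(grepl(mir$mature_seq[r], prec, fixed = TRUE))
    expect_true(grepl(mir$star_seq[r], prec, fixed = TRUE))
    st <- fold_rna(substr(prec, 1, min(nchar(prec), 600)))
    expect_gte(st$pair_count, 16L)  # stem well above the 16-bp criterion
  }
  # SSR manifest points at a genuine tandem repeat on the stated strand
  ssr <- sim$truth$ssrs
  g <- sim$genome[[ssr$chrom[1]]]
  tract <- substr(g, ssr$start[1], ssr$end[1])
  if (ssr$strand[1] == "-") tract <- rc_str(tract)
  expect_equal(tract, strrep(ssr$unit[1], ssr$repeat_number[1]))
})

test_that("hairpin placement fails loudly when the genome is too small", {
  expect_error(simulate_genome(1L, 3000L, 12L, 0L, seed = 1L), "capacity")
  expect_error(simulate_genome(1L, 9000L, 1L, 2L, seed = 1L), ">=")
})

test_that("background libraries are 24-nt dominant (count-weighted)", {
  g0 <- simulate_genome(1L, 20000L, 0L, 0L, seed = 9L)
  lib <- simulate_srna_libraries(g0, tissues = "leaf", depth = 20000L,
                                 seed = 9L)
  df <- lib$libraries$leaf
  by_len <- tapply(df$count, nchar(df$sequence), sum)
  expect_equal(as.integer(names(which.max(by_len))), 24L)
  expect_error(simulate_srna_libraries(g0, tissues = "root", seed = 1L),
               "unknown tissue")
  expect_error(simulate_srna_libraries(g0, depth = 10L, seed = 1L),
               "at least 1000")
})

test_that("degradome plants create the intended T-plot shapes", {
  sim <- get_full_sim()
  tp <- build_tplots(sim$degradome, sim$transcripts)
  truth <- sim$truth$targets
  for (r in seq_len(nrow(truth))) {
    counts <- tp$plots$leaf[[truth$transcript_id[r]]]
    cc <- counts[truth$cleavage_site[r]]
    if (truth$category[r] == "I") {
      expect_equal(cc, max(counts))
      expect_equal(sum(counts == max(counts)), 1L)
    } else if (truth$category[r] == "II") {
      expect_lt(cc, max(counts))          # not the maximum...
      expect_gte(cc, 0.5 * max(counts))   # ...but a clear peak
    } else {
      expect_lt(cc, 0.5 * max(counts))
    }
  }
  # depth 0: empty library; signal_to_noise <= 0: error
  txs <- simulate_transcripts(simulate_genome(1L, 9000L, 1L, 0L, seed = 2L),
                              4L, 1000L, seed = 2L)
  empty <- simulate_degradome(txs, tissues = "leaf", depth = 0L, seed = 2L)
  expect_equal(nrow(empty$leaf), 0L)
  expect_error(simulate_degradome(txs, depth = 100L, signal_to_noise = 0,
                                  seed = 2L), "positive")
})

test_that("the phasing cascade emits exact 21-nt registers", {
  gsim <- simulate_genome(1L, 9000L, 1L, 0L, seed = 3L)
  txs <- simulate_transcripts(gsim, 4L, 1000L, seed = 3L, n_registers = 9L)
  casc <- simulate_phasing_cascade(txs, tissues = "leaf", seed = 3L)
  reg <- casc$registers
  c0 <- txs$truth$phasing$cleavage_site
  expect_equal(reg$start, c0 + 21L * (0:8))
  expect_equal(reg$start[9], c0 + 168L)
  expect_true(all(casc$srna$leaf$count >= 3L))
  expect_equal(casc$degradome$leaf$sequence,
               substr(txs$transcripts[[txs$truth$phasing$transcript_id]],
                      c0, c0 + 19L))
  # K = 1: a single register at the cleavage site
  txs1 <- simulate_transcripts(gsim, 4L, 1000L, seed = 3L, n_registers = 1L)
  casc1 <- simulate_phasing_cascade(txs1, tissues = "leaf", seed = 3L)
  expect_equal(casc1$registers$start, txs1$truth$phasing$cleavage_site)
  # capacity: registers that cannot fit raise an error
  expect_error(simulate_transcripts(gsim, 4L, 600L, seed = 3L,
                                    n_registers = 30L), "capacity")
})

test_that("sub-threshold plants are filtered out of the catalog", {
  sim <- get_full_sim()
  res <- get_full_result()
  mir <- sim$truth$mirnas
  sub <- mir[!mir$expressed, ]
  expect_gte(nrow(sub), 1L)
  expect_false(any(sub$mature_seq %in% res$catalog$sequences))
})
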