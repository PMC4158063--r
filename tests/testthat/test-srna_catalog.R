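test_that("per-library count filter honours the threshold boundary", {
  r1 <- strrep("ACGTA", 4)          # 20 nt
  r2 <- strrep("TGCAT", 4)
  reads <- list(
    leaf = data.frame(sequence = c(r1, r2), count = c(2L, 3L)),
    flower = data.frame(sequence = c(r1, r2), count = c(5L, 1L)))
  cat <- collapse_and_filter(reads, pipeline_config())
  i1 <- match(r1, cat$sequences); i2 <- match(r2, cat$sequences)
  expect_equal(unname(cat$counts[i1, "leaf"]), 0L)  # 2 < 3: absent from leaf
  expect_equal(unname(cat$counts[i2, "leaf"]), 3L)  # 3 >= 3: retained
  expect_equal(unname(cat$counts[i1, "flower"]), 5L)
  expect_equal(unname(cat$counts[i2, "flower"]), 0L)
})

test_that("low-quality reads are removed and duplicates merged", {
  short <- strrep("AC", 8)                         # 17 nt
  withN <- paste0(strrep("ACGT", 5), "N")
  good <- strrep("ACGTT", 4)
  reads <- list(leaf = data.frame(
    sequence = c(short, withN, good, tolower(good)),
    count = c(10L, 10L, 3L, 4L)))
  cat <- collapse_and_filter(reads)
  expect_equal(cat$sequences, good)
  expect_equal(unname(cat$counts[1, "leaf"]), 7L)  # case-merged
  expect_error(collapse_and_filter(list(data.frame(sequence = good, count = 5L))),
               "named")
})

test_that("library stats are internally consistent", {
  sim <- get_mini_sim()
  cat <- collapse_and_filter(sim$libraries)
  st <- cat$stats
  expect_true(all(st$total_clean <= st$total_raw))
  expect_true(all(st$unique_clean <= st$total_clean))
  for (l in st$library) {
    h <- cat$length_hist[cat$length_hist$library == l, ]
    expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  }
})

test_that("ncRNA flagging is an exact substring rule on either strand", {
  ref <- c(tRNA1 = paste0(strrep("GATTACA", 10), strrep("CCGGA", 4)))
  fwd <- substr(ref[[1]], 11, 31)      # 21-nt window of the reference
  rev <- rc_str(substr(ref[[1]], 40, 60))
  other <- strrep("ACGTT", 4)
  reads <- list(leaf = data.frame(sequence = c(fwd, rev, other),
                                  count = c(5L, 5L, 5L)))
  cat <- collapse_and_filter(reads)
  cat <- annotate_ncrna(cat, ref)
  expect_equal(cat$annotation[match(fwd, cat$sequences)], "ncRNA")
  expect_equal(cat$annotation[match(rev, cat$sequences)], "ncRNA")
  expect_equal(cat$annotation[match(other, cat$sequences)], "unannotated")
  cat2 <- annotate_ncrna(collapse_and_filter(reads), NULL)
  expect_true(all(cat2$annotation == "unannotated"))
})

test_that("genome mapping is exact-match on both strands with percentages", {
  set.seed(21)
  genome <- c(chr1 = random_dna(3000))
  g1 <- substr(genome[[1]], 100, 120)
  g2 <- substr(genome[[1]], 900, 921)
  g3 <- rc_str(substr(genome[[1]], 1500, 1520))   # minus-strand read
  absent <- paste0(strrep("ACGTT", 4), "A")
  reads <- list(leaf = data.frame(sequence = c(g1, g2, g3, absent),
                                  count = c(5L, 5L, 5L, 5L)))
  cat <- map_to_genome(collapse_and_filter(reads), genome)
  h3 <- cat$genome_hits[cat$genome_hits$sequence == g3, ]
  expect_equal(h3$strand, "-")
  expect_equal(c(h3$start, h3$end), c(1500L, 1520L))
  expect_false(absent %in% cat$genome_hits$sequence)
  expect_equal(cat$stats$pct_matched_unique, 75)   # 3 of 4
  # agreement with a naive scan
  for (s in c(g1, g2, g3, absent)) {
    expect_equal(sum(cat$genome_hits$sequence == s), oracle_map(s, genome))
  }
})

test_that("TPM normalization conserves totals", {
  sim <- get_mini_sim()
  cat <- tpm_normalize(collapse_and_filter(sim$libraries))
  for (l in colnames(cat$tpm)) {
    expect_equal(sum(cat$tpm[, l]), 1e6, tolerance = 1e-6)
    i <- which(cat$counts[, l] > 0)[1]
    expect_equal(cat$tpm[i, l],
                 cat$counts[i, l] / sum(cat$counts[, l]) * 1e6)
  }
  expect_equal(unname(cat$tpm[cat$counts[, 1] == 0, 1][1]), 0)
})

test_that("raising min_read_count never increases the catalog", {
  sim <- get_mini_sim()
  sizes <- vapply(1:6, function(m) {
    length(collapse_and_filter(sim$libraries,
                               pipeline_config(min_read_count = m))$sequences)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

fake_catalog <- function(tpm) {
  counts <- matrix(1L, nrow(tpm), ncol(tpm), dimnames = dimnames(tpm))
  structure(list(sequences = paste0("s", seq_len(nrow(tpm))),
                 counts = counts, tpm = tpm,
                 annotation = rep("unannotated", nrow(tpm)),
                 stats = data.frame(library = colnames(tpm),
                                    total_clean = 1e6)),
            class = "srdk_catalog")
}

test_that("tissue comparison classes follow the fold-change rules", {
  tpm <- matrix(c(5, 8, 12,
                  5, 4, 12,
                  25, 0, 12), nrow = 3,
                dimnames = list(NULL, c("leaf", "flower", "fruit")))
  cmp <- compare_tissues(fake_catalog(tpm), config = pipeline_config())
  # row 1: fruit 25 vs max(5,5)=5 -> 5x: enriched and strongly enriched
  expect_equal(cmp$enriched_in[1], "fruit")
  expect_equal(cmp$strongly_enriched_in[1], "fruit")
  expect_equal(cmp$fc_fruit[1], 5)
  # row 2: fruit absent (TPM 0), absence takes precedence
  expect_equal(cmp$absent_in[2], "fruit")
  expect_match(cmp$class[2], "^absent:")
  # row 3: flat 12s: highly expressed, nothing enriched
  expect_true(cmp$highly_expressed[3])
  expect_equal(cmp$class[3], "highly_expressed")
  expect_error(compare_tissues(fake_catalog(tpm), tissues = "leaf"),
               "two tissues")
  expect_error(compare_tissues(fake_catalog(tpm), tissues = c("leaf", "root")),
               "unknown tissue")
})
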