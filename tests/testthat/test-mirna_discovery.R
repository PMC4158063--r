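# The mini simulated dataset plants two hairpins on a single small
# chromosome: hp01 (known, the 22-nt 5'U trigger) and hp02 (a minus-strand
# SSR-loop precursor).

mini_catalog <- function() {
  sim <- get_mini_sim()
  cat <- collapse_and_filter(sim$libraries)
  cat <- annotate_ncrna(cat, sim$ncrna)
  tpm_normalize(map_to_genome(cat, sim$genome))
}

test_that("known matching: identity, threshold boundary, and 2-mismatch hit", {
  sim <- get_mini_sim()
  cat <- mini_catalog()
  mir <- sim$truth$mirnas
  mature <- mir$mature_seq[1]
  mut <- function(s, k) {      # reference differing from the read at k sites
    ch <- strsplit(s, "")[[1]]
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    idx <- seq(3, by = 5, length.out = k)
    ch[idx] <- flip[ch[idx]]
    paste(ch, collapse = "")
  }
  ref0 <- setNames(mature, "ref-exact")
  k0 <- match_known(cat, ref0, sim$genome)
  expect_equal(unique(k0$mirna_id), "ref-exact")
  expect_true(all(k0$ref_mismatches == 0L))
  expect_true(all(k0$mature_seq == mature))

  k2 <- match_known(cat, setNames(mut(mature, 2), "ref-2mm"), sim$genome)
  expect_equal(unique(k2$ref_mismatches), 2L)

  k3 <- match_known(cat, setNames(mut(mature, 3), "ref-3mm"), sim$genome)
  expect_false(mature %in% k3$mature_seq)

  expect_warning(ke <- match_known(cat, character(), sim$genome), "empty")
  expect_equal(nrow(ke), 0L)
})

test_that("raising max_mismatch never shrinks the known set", {
  sim <- get_mini_sim()
  cat <- mini_catalog()
  sizes <- vapply(0:3, function(mm) {
    nrow(match_known(cat, sim$mirna_ref, sim$genome,
                     pipeline_config(known_max_mismatch = mm)))
  }, 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("novel prediction recovers a planted hairpin and requires the star", {
  sim <- get_mini_sim()
  cat <- mini_catalog()
  mir <- sim$truth$mirnas
  novel <- predict_novel(cat, sim$genome)
  expect_true(all(mir$mature_seq %in% novel$mature_seq))
  expect_true(all(grepl("^csi-miRN\\d+", novel$mirna_id)))
  # reported matures are exact substrings of their reported precursors
  for (r in seq_len(nrow(novel))) {
    expect_true(grepl(novel$mature_seq[r], novel$precursor_seq[r],
                      fixed = TRUE) ||
                grepl(novel$mature_seq[r], rc_str(novel$precursor_seq[r]),
                      fixed = TRUE))
  }
  # remove the star reads: the loci must vanish
  strip <- function(df) df[!(df$sequence %in% mir$star_seq), ]
  sim2 <- sim
  sim2$libraries <- lapply(sim$libraries, strip)
  cat2 <- collapse_and_filter(sim2$libraries)
  cat2 <- tpm_normalize(map_to_genome(annotate_ncrna(cat2, sim2$ncrna),
                                      sim2$genome))
  novel2 <- predict_novel(cat2, sim2$genome)
  expect_false(any(mir$mature_seq %in% novel2$mature_seq))
})

test_that("known and novel sets are disjoint in the pipeline", {
  res <- get_full_result()
  expect_length(intersect(res$known$mature_seq, res$novel$mature_seq), 0L)
  # every reported mature is outside the terminal loop of a folded precursor
  expect_true(all(res$loci$mature_paired_fraction >= 0.6))
})

test_that("isoform pairs report separation and arms", {
  base <- data.frame(
    mirna_id = c("miR166j.1", "miR166j.3"),
    locus_id = c("a", "b"), status = "known", arm = c("5p", "3p"),
    mature_seq = "X", star_seq = "X", chrom = "chr1", strand = "+",
    precursor_start = 1000L, precursor_end = 1400L,
    mature_start = c(1010L, 1226L), mature_end = c(1031L, 1247L),
    precursor_seq = "N", dot_bracket = ".", stringsAsFactors = FALSE)
  pairs <- find_isoform_pairs(base)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$separation, 195L)   # 1226 - 1031
  expect_equal(c(pairs$arm_a, pairs$arm_b), c("5p", "3p"))
  expect_equal(nrow(find_isoform_pairs(base[1, ])), 0L)
})

test_that("genome distribution bins loci and flags co-location", {
  loci <- data.frame(mirna_id = c("a", "b", "c"), locus_id = c("a", "b", "c"),
                     chrom = c("chr1", "chr1", "chr2"), strand = "+",
                     precursor_start = c(1000L, 50000L, 1000L),
                     precursor_end = c(1100L, 50100L, 1100L),
                     stringsAsFactors = FALSE)
  d <- genome_distribution(loci, bin_size = 100000L)
  expect_equal(nrow(d), 2L)
  expect_true(d$colocated[d$chrom == "chr1"])
  expect_equal(d$n_loci[d$chrom == "chr1"], 2L)
  expect_equal(nrow(genome_distribution(loci[0, ])), 0L)
  expect_error(genome_distribution(loci, bin_size = 0), "positive")
})

test_that("uniformly planted loci pass a chi-square uniformity check", {
  res <- get_full_result()
  sim <- get_full_sim()
  loci <- unique(res$loci[, c("chrom", "precursor_start")])
  # pool positions across chromosomes of equal length; 5 equal-width bins
  pos <- loci$precursor_start / nchar(sim$genome[loci$chrom])
  counts <- table(cut(pos, breaks = seq(0, 1, length.out = 6)))
  p <- suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
  expect_gt(p, 0.01)
})
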