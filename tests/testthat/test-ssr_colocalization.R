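test_that("worked SSR examples: (CTT)15, boundary thresholds, nesting", {
  hit <- detect_ssrs(paste0("GGG", strrep("CTT", 15), "GGG"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit, "CTT")
  expect_equal(hit$repeat_number, 15L)
  expect_equal(hit$length, 45L)
  expect_equal(hit$class, "tri")

  di4 <- detect_ssrs("GGTATATATAGG")        # (TA)4 at the di threshold
  expect_equal(di4$unit, "TA")
  expect_equal(di4$repeat_number, 4L)
  expect_equal(nrow(detect_ssrs("GGTATATAGG")), 0L)   # (TA)3 below threshold

  # a (CTCT)n run reports the fundamental unit CT, never CTCT
  nested <- detect_ssrs(paste0("GGA", strrep("CTCT", 5), "AGG"))
  expect_equal(nested$unit, "CT")
  expect_equal(nested$repeat_number, 10L)

  # RNA alphabet input is accepted
  rna <- detect_ssrs(paste0("GGG", strrep("CUU", 15), "GGG"))
  expect_equal(rna$length, 45L)
})

test_that("detector agrees with the brute-force maximal-repeat oracle", {
  cfg <- pipeline_config()
  set.seed(51)
  for (rep in 1:10) {
    s <- random_dna(2000)
    # spike in some genuine repeats so the comparison is not vacuous
    ins <- paste0(strrep("AG", 6), random_dna(30), strrep("TTA", 4),
                  random_dna(20), strrep("A", 9))
    s <- paste0(substr(s, 1, 1000), ins, substr(s, 1001, 2000))
    got <- detect_ssrs(s, cfg$ssr_min_repeats)
    want <- oracle_ssrs(s, cfg$ssr_min_repeats)
    expect_equal(got[, c("start", "end", "unit", "repeat_number")], want,
                 ignore_attr = TRUE)
  }
})

test_that("no reported SSR is extendable by one unit in either direction", {
  set.seed(52)
  s <- paste0(random_dna(800), strrep("GAT", 5), random_dna(800))
  got <- detect_ssrs(s)
  for (r in seq_len(nrow(got))) {
    u <- got$unit[r]; k <- nchar(u)
    left <- substr(s, got$start[r] - k, got$start[r] - 1)
    right <- substr(s, got$end[r] + 1, got$end[r] + k)
    if (nchar(left) == k) expect_false(left == u)
    if (nchar(right) == k) expect_false(right == u)
  }
})

test_that("lowering thresholds never removes a reported SSR", {
  set.seed(53)
  s <- paste0(random_dna(300), strrep("TA", 5), random_dna(100),
              strrep("CTT", 4), random_dna(300))
  hi <- detect_ssrs(s, c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L,
                         `5` = 3L, `6` = 2L))
  lo <- detect_ssrs(s, c(`1` = 8L, `2` = 4L, `3` = 3L, `4` = 3L,
                         `5` = 3L, `6` = 2L))
  key <- function(df) paste(df$start, df$end, df$unit)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("co-localization is a 1-nt same-strand overlap rule", {
  ssrs <- data.frame(chrom = "chr1", strand = c("+", "+", "-", "+"),
                     start = c(150L, 200L, 160L, 500L),
                     end = c(170L, 210L, 180L, 520L),
                     unit = c("TA", "CTT", "TA", "AG"),
                     unit_len = c(2L, 3L, 2L, 2L),
                     repeat_number = c(10L, 4L, 10L, 10L),
                     length = c(21L, 11L, 21L, 21L),
                     class = c("di", "tri", "di", "di"),
                     stringsAsFactors = FALSE)
  loci <- data.frame(mirna_id = "m1", locus_id = "m1-1", chrom = "chr1",
                     strand = "+", precursor_start = 100L,
                     precursor_end = 200L, stringsAsFactors = FALSE)
  cl <- colocalize_ssrs(ssrs, loci)
  # fully inside: yes; 1-nt boundary overlap (200): yes; minus strand: no;
  # disjoint: no
  expect_equal(sort(cl$occurrences$start), c(150L, 200L))
  expect_equal(nrow(cl$precursors), 1L)
})

test_that("unit summaries reproduce composition percentages", {
  occ <- data.frame(unit = c("TA", "TA", "CTT"))
  sm <- summarize_ssr_units(occ)
  expect_equal(sm$modal_unit, "TA")
  expect_equal(sm$modal_unit_rna, "UA")
  expect_equal(ssr_composition_pct(sm, "di"), 66.7)
  expect_equal(ssr_composition_pct(sm, c("di", "tri")), 100.0)
  expect_equal(sum(sm$classes$pct), 100, tolerance = 0.1)

  one <- summarize_ssr_units(data.frame(unit = "AG"))
  expect_equal(ssr_composition_pct(one, "di"), 100.0)

  empty <- summarize_ssr_units(data.frame(unit = character()))
  expect_true(empty$undefined)
  expect_true(is.na(ssr_composition_pct(empty)))
})

test_that("planted SSR tracts co-localize with their precursors genome-wide", {
  sim <- get_full_sim()
  res <- get_full_result()
  planted <- sim$truth$ssrs
  occ <- res$colocalized$occurrences
  # every planted tract is found: same interval, same strand, same length
  # (one row per overlapping precursor locus, so >= 1; an SSR inside a
  # hairpin called at several near-identical loci appears once per locus)
  for (r in seq_len(nrow(planted))) {
    m <- occ[occ$chrom == planted$chrom[r] & occ$strand == planted$strand[r] &
               occ$start == planted$start[r] & occ$end == planted$end[r], ]
    expect_gte(nrow(m), 1L)
    expect_true(all(m$length == planted$length[r]), info = planted$hp_id[r])
  }
  # the longest planted tract is the 45-nt (CTT)15
  expect_equal(max(occ$length), 45L)
})
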