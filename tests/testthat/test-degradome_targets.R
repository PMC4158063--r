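test_that("alignment scoring follows the plant penalty scheme", {
  m <- "TTGACAGAAGATAGAGAGCAC"          # 21 nt
  perfect <- rc_str(m)
  s <- score_alignment(m, perfect)
  expect_equal(s$penalty, 0)
  expect_equal(s$alignment, strrep("|", 21))

  # single G:U at miRNA position 5 (core, double weighted): 0.5 x 2 = 1
  stopifnot(substr(m, 5, 5) == "C")
  m5 <- m; substr(m5, 5, 5) <- "T"       # T opposite the site's G: wobble
  s5 <- score_alignment(m5, perfect)
  expect_equal(s5$penalty, 1)
  expect_equal(substr(s5$alignment, 5, 5), "o")

  # single mismatch at position 20 (outside the core): 1
  site <- perfect
  substr(site, 21 - 20 + 1, 21 - 20 + 1) <- "C"  # opposite miRNA pos 20
  s20 <- score_alignment(m, site)
  if (s20$penalty == 0) skip("site mutation produced a pair by chance")
  expect_equal(s20$penalty, 1)
  expect_equal(substr(s20$alignment, 20, 20), "x")

  expect_error(score_alignment(m, substr(perfect, 1, 20)), "alignment error")
})

test_that("alignment scoring matches an independent recomputation", {
  set.seed(31)
  for (rep in 1:100) {
    m <- random_dna(sample(20:22, 1))
    site <- random_dna(nchar(m))
    expect_equal(score_alignment(m, site)$penalty, oracle_penalty(m, site))
  }
})

test_that("category classification matches its definition", {
  expect_equal(classify_category(c(0, 0, 50, 3, 1), 3), "I")
  expect_equal(classify_category(c(40, 0, 30, 3), 3), "II")   # >= 0.5 max
  expect_equal(classify_category(c(40, 0, 5, 3), 3), "III")
  expect_equal(classify_category(c(40, 0, 40, 3), 3), "II")   # shared max
  expect_error(classify_category(c(0, 0, 0), 1), "all-zero")
})

test_that("category is monotone in the cleavage count", {
  others <- c(40, 0, 3, 7, 12)
  ranks <- c(III = 1, II = 2, I = 3)
  cats <- vapply(0:60, function(cc) {
    if (cc == 0 && all(others == 0)) return(NA_character_)
    classify_category(c(others, cc), 6)
  }, "")
  expect_true(all(diff(ranks[cats]) >= 0))
})

test_that("T-plots count tag 5' ends on every matching transcript", {
  set.seed(32)
  tx <- c(t1 = random_dna(400), t2 = random_dna(400))
  shared <- substr(tx[["t1"]], 100, 119)
  tx[["t2"]] <- paste0(substr(tx[["t2"]], 1, 249), shared,
                       substr(tx[["t2"]], 270, 400))
  tags <- list(leaf = data.frame(sequence = c(shared, random_dna(20)),
                                 count = c(7L, 2L)))
  tp <- build_tplots(tags, tx)
  expect_equal(tp$plots$leaf$t1[100], 7L)
  expect_equal(tp$plots$leaf$t2[250], 7L)
  expect_equal(sum(tp$plots$leaf$t1), 7L)  # conservation: matched tags only
  expect_equal(tp$stats$matched_total, 7)
  expect_equal(tp$stats$total_tags, 9)
})

test_that("target calls need both a good alignment and site evidence", {
  set.seed(33)
  m <- "TTGACAGAAGATAGAGAGCAC"
  tx <- c(t1 = paste0(random_dna(150), rc_str(m), random_dna(150)))
  cleave <- 151 + 21 - 10                  # opposite miRNA position 10
  tag <- substr(tx[["t1"]], cleave, cleave + 19)
  tags <- list(leaf = data.frame(sequence = tag, count = 30L))
  tp <- build_tplots(tags, tx)
  q <- data.frame(mirna_id = "miRX", sequence = m)
  calls <- call_targets(q, tp)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$cleavage_site, cleave)
  expect_equal(calls$category, "I")
  expect_equal(calls$penalty, 0)

  # tags elsewhere only: no call
  tags2 <- list(leaf = data.frame(sequence = substr(tx[["t1"]], 10, 29),
                                  count = 30L))
  expect_equal(nrow(call_targets(q, build_tplots(tags2, tx))), 0L)

  # penalty above threshold: no call regardless of tags
  m2 <- m
  substr(m2, 3, 3) <- "C"; substr(m2, 8, 8) <- "T"   # core mismatches, pen 4
  q2 <- data.frame(mirna_id = "miRY", sequence = m2)
  pen <- score_alignment(m2, rc_str(m))$penalty
  expect_gt(pen, 3)
  calls3 <- call_targets(q2, tp, pipeline_config(penalty_threshold = pen - 0.5))
  expect_equal(nrow(calls3), 0L)
  calls4 <- call_targets(q2, tp, pipeline_config(penalty_threshold = pen))
  expect_equal(nrow(calls4), 1L)
})

test_that("planted degradome categories are recovered end to end", {
  sim <- get_full_sim()
  res <- get_full_result()
  truth <- sim$truth$targets
  mir <- sim$truth$mirnas
  for (want in c("II", "III")) {
    t <- truth[truth$category == want, ][1, ]
    ids <- res$loci$mirna_id[res$loci$mature_seq ==
                               mir$mature_seq[mir$hp_id == t$mirna]]
    got <- res$target_calls[res$target_calls$mirna_id %in% ids &
                              res$target_calls$transcript_id == t$transcript_id &
                              abs(res$target_calls$cleavage_site -
                                    t$cleavage_site) <= 1, ]
    expect_true(nrow(got) > 0)
    expect_true(all(got$category == want),
                info = paste("category", want))
  }
})
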