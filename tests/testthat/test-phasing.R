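test_that("phase enumeration tiles exact 21-nt registers to the 3' end", {
  set.seed(41)
  tx <- random_dna(200)
  ph <- enumerate_phases(tx, 101)          # 0-based offset 100
  expect_equal(ph$start, c(101, 122, 143, 164))   # 185 + 21 - 1 > 200
  expect_equal(ph$end - ph$start + 1, rep(21, 4))
  expect_equal(diff(ph$start), rep(21, 3))        # disjoint and contiguous
  expect_equal(ph$k, 1:4)
  expect_equal(ph$sequence[2], substr(tx, 122, 142))

  long <- random_dna(400)
  ph9 <- enumerate_phases(long, 50)
  expect_equal(ph9$start[9], 50 + 168)     # ninth register at c + 21*8
  expect_equal(nrow(enumerate_phases(tx, 200)), 0L)
  expect_error(enumerate_phases(tx, 300), "outside")
})

test_that("phasiRNA names are bijective with (trigger, transcript, k)", {
  nm <- phasi_name("csi-miR3954a", "Cs1g09635.1", 9L)
  expect_equal(nm, "csi-miR3954a-Cs1g09635.1-9")
  p <- parse_phasi_name(nm)
  expect_equal(p$trigger_id, "csi-miR3954a")
  expect_equal(p$transcript_id, "Cs1g09635.1")
  expect_equal(p$k, 9L)
  # round trip over generated cases
  set.seed(42)
  for (i in 1:25) {
    tr <- paste0("csi-miR", sample(100:9999, 1),
                 sample(c("", "a", "b.1", "-5p"), 1))
    tx <- sprintf("Cs%dg%05d.%d", sample(1:9, 1), sample(1:99999, 1),
                  sample(1:3, 1))
    k <- sample(1:30, 1)
    p <- parse_phasi_name(phasi_name(tr, tx, k))
    expect_equal(list(p$trigger_id, p$transcript_id, p$k), list(tr, tx, k))
  }
  expect_error(phasi_name("t", "tx-1", 1), "must not contain")
})

test_that("trigger selection enforces length, 5' U and target evidence", {
  mirnas <- data.frame(
    mirna_id = c("t22u", "t22u-notarget", "t21u", "t22a"),
    mature_seq = c(paste0("T", strrep("ACGTG", 4), "C"),   # 22 nt, 5' U
                   paste0("T", strrep("GTACG", 4), "A"),
                   paste0("T", strrep("ACGTG", 4)),        # 21 nt
                   paste0("A", strrep("ACGTG", 4), "C")),  # 22 nt, 5' A
    stringsAsFactors = FALSE)
  calls <- data.frame(mirna_id = c("t22u", "t21u", "t22a"))
  tr <- select_triggers(mirnas, calls)
  expect_equal(tr$mirna_id, "t22u")
  tr2 <- select_triggers(mirnas, calls,
                         pipeline_config(require_trigger_5pU = FALSE))
  expect_setequal(tr2$mirna_id, c("t22u", "t22a"))
})

test_that("register quantification requires exact catalog support", {
  set.seed(43)
  tx <- random_dna(150)
  ph <- enumerate_phases(tx, 40, trigger_id = "trig",
                         transcript_id = "Cs1g00010")
  supported <- ph$sequence[c(1, 3)]
  reads <- list(leaf = data.frame(sequence = c(supported, random_dna(21)),
                                  count = c(10L, 8L, 5L)))
  cat <- tpm_normalize(collapse_and_filter(reads))
  qp <- quantify_phases(ph, cat)
  expect_equal(qp$reported$k, c(1L, 3L))
  expect_equal(qp$reported$name[1], "trig-Cs1g00010-1")
  expect_true(all(qp$reported$tpm_leaf > 0))
  expect_equal(sum(qp$diagnostics$supported), 2L)
  expect_equal(nrow(qp$diagnostics), nrow(ph))
})

test_that("TAS flagging needs a trigger call, registers, and non-coding status", {
  triggers <- data.frame(mirna_id = "trig", mature_seq = strrep("TA", 11))
  calls <- data.frame(mirna_id = "trig",
                      transcript_id = c("ncA", "codB", "ncC"))
  phas <- data.frame(trigger_id = "trig",
                     transcript_id = c(rep("ncA", 9), rep("codB", 9), "ncC"),
                     k = c(1:9, 1:9, 1L))
  coding <- data.frame(transcript_id = c("ncA", "codB", "ncC"),
                       coding = c(FALSE, TRUE, FALSE))
  tas <- flag_candidate_tas(triggers, calls, phas, coding)
  expect_true(tas$candidate_tas[tas$transcript_id == "ncA"])
  expect_false(tas$candidate_tas[tas$transcript_id == "codB"])  # coding
  expect_false(tas$candidate_tas[tas$transcript_id == "ncC"])   # 1 register
})

test_that("phasiRNA target calling carries trigger provenance", {
  res <- get_full_result()
  sim <- get_full_sim()
  ph <- sim$truth$phasing
  expect_true(nrow(res$phasi_calls) > 0)
  expect_true(all(res$phasi_calls$trigger_id %in%
                    res$triggers$mirna_id))
  # the planted phasiRNA target is recovered as category I
  t <- sim$truth$targets
  t7 <- t[grepl("_phase", t$mirna), ]
  got <- res$phasi_calls[res$phasi_calls$transcript_id == t7$transcript_id &
                           abs(res$phasi_calls$cleavage_site -
                                 t7$cleavage_site) <= 1, ]
  expect_true(any(got$category == "I"))
  # empty phasiRNA list gives an empty result
  empty <- call_phasi_targets(res$phasirnas[0, ], res$tplots)
  expect_equal(nrow(empty), 0L)
})
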