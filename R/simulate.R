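## Synthetic-data generators: genome with planted hairpin precursors and SSR
## tracts, transcriptome with planted cleavage targets, per-tissue collapsed
## sRNA libraries (24-nt-dominant background plus planted matures and stars),
## degradome libraries with category I/II/III signals, and a 22-nt-triggered
## 21-nt phasing cascade. Every generator is deterministic given its seed and
## emits a ground-truth manifest for parameter-recovery tests.

SRDK_TISSUES <- c("leaf", "flower", "fruit")

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Background read-length distribution: 24-nt dominant, as in plant sRNAomes.
BG_LENGTHS <- c(21, 22, 23, 24, 18, 19, 20, 25, 26, 27, 28, 29, 30)
BG_LENGTH_PROBS <- c(0.15, 0.10, 0.15, 0.45, rep(0.15 / 9, 9))

# Loop inserts for SSR-bearing precursors: C/T-only units cannot base pair,
# so the tract stays in the terminal loop. The first is the 45-nt (CTT)15.
SSR_LOOP_PLAN <- list(c("CTT", 15L), c("TTC", 5L), c("CTT", 4L),
                      c("TCT", 6L), c("CTT", 3L), c("TTC", 4L))

# Reference names recycled for planted known miRNAs (the first is the 22-nt
# 5'U phasing trigger).
KNOWN_REF_IDS <- c("csi-miR3954a", "csi-miR164", "csi-miR166j", "csi-miR396c",
                   "csi-miR482a", "csi-miR159", "csi-miR171", "csi-miR169c")

#' Simulate a genome with planted miRNA hairpins and SSR tracts
#'
#' Hairpin precursors are planted as perfect reverse-complement-palindromic
#' arms (stem well above 16 bp) around a loop; a stated subset carries an SSR
#' tract in the loop, always including one (CTT)15 (45 nt). Placements are
#' uniform at random and non-overlapping; one known precursor is planted on
#' the minus strand. The first hairpin is a 22-nt 5'U phasing trigger.
#'
#' @param n_chrom,chrom_len Number and length (nt) of chromosomes.
#' @param n_hairpins Hairpins to plant (`>= n_ssr_hairpins`). When 8 or more,
#'   the last two are planted at sub-threshold abundance (and must never be
#'   recovered).
#' @param n_ssr_hairpins Hairpins whose loop carries an SSR tract.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param arm_len Stem arm length (nt).
#' @return list with `genome` (named character), `truth` (list with `mirnas`
#'   and `ssrs` manifests) and the call parameters.
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_len = 50000L,
                            n_hairpins = 12L, n_ssr_hairpins = 4L,
                            seed = 1L, arm_len = 90L) {
  if (n_hairpins < n_ssr_hairpins || n_ssr_hairpins < 0)
    stop("need n_hairpins >= n_ssr_hairpins >= 0", call. = FALSE)
  set.seed(seed + 11L)
  chroms <- setNames(vapply(seq_len(n_chrom), function(i) rand_dna(chrom_len),
                            ""), paste0("chr", seq_len(n_chrom)))
  mirnas <- list()
  ssrs <- list()
  occupied <- lapply(chroms, function(x) cbind(start = integer(),
                                               end = integer()))
  n_known <- min(length(KNOWN_REF_IDS), ceiling(n_hairpins / 2))
  pad <- 400L
  for (i in seq_len(n_hairpins)) {
    is_trigger <- i == 1L
    is_known <- i <= n_known
    expressed <- !(n_hairpins >= 8L && i > n_hairpins - 2L)
    has_ssr <- n_ssr_hairpins > 0L && i >= 2L && i <= n_ssr_hairpins + 1L
    mature_len <- if (is_trigger) 22L else 21L
    m1 <- 21L
    m2 <- m1 + mature_len - 1L

    arm5 <- strsplit(rand_dna(arm_len), "")[[1]]
    arm5[(arm_len - 2L):arm_len] <- c("G", "G", "G")  # blocks SSR extension
    if (is_trigger) arm5[m1] <- "T"                   # 5' uridine
    arm5 <- paste(arm5, collapse = "")
    if (has_ssr) {
      plan <- SSR_LOOP_PLAN[[((i - 2L) %% length(SSR_LOOP_PLAN)) + 1L]]
      loop <- strrep(plan[1], as.integer(plan[2]))
      ssr_unit <- plan[1]; ssr_reps <- as.integer(plan[2])
    } else {
      loop <- rand_dna(12L)
      ssr_unit <- NA_character_; ssr_reps <- NA_integer_
    }
    prec <- paste0(arm5, loop, revcomp(arm5))
    P <- nchar(prec)
    strand <- if (i == 2L && n_hairpins >= 2L) "-" else "+"

    placed <- FALSE
    for (try in seq_len(1000L)) {
      ci <- sample(seq_len(n_chrom), 1L)
      pos <- sample(seq_len(chrom_len - P - pad), 1L) + pad %/% 2L
      occ <- occupied[[ci]]
      if (nrow(occ) && any(pos - pad <= occ[, "end"] &
                           pos + P + pad >= occ[, "start"])) next
      insert <- if (strand == "+") prec else revcomp(prec)
      chroms[[ci]] <- paste0(substr(chroms[[ci]], 1L, pos - 1L), insert,
                             substr(chroms[[ci]], pos + P, chrom_len))
      occupied[[ci]] <- rbind(occ, cbind(start = pos, end = pos + P - 1L))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("capacity error: cannot place ", n_hairpins,
           " non-overlapping hairpins", call. = FALSE)

    mature <- substr(prec, m1, m2)
    star1 <- P - m2 + 3L; star2 <- P - m1 + 3L
    star <- substr(prec, star1, star2)
    g <- function(a, b) {  # precursor coords -> genomic coords
      if (strand == "+") c(pos + a - 1L, pos + b - 1L)
      else c(pos + P - b, pos + P - a)
    }
    gm <- g(m1, m2); gs <- g(star1, star2); gp <- g(1L, P)
    hp_id <- sprintf("hp%02d", i)
    mirnas[[i]] <- data.frame(
      hp_id = hp_id,
      ref_id = if (is_known) KNOWN_REF_IDS[i] else NA_character_,
      is_known = is_known, is_trigger = is_trigger, expressed = expressed,
      mature_seq = mature, star_seq = star,
      chrom = names(chroms)[ci], strand = strand,
      precursor_start = gp[1], precursor_end = gp[2],
      mature_start = gm[1], mature_end = gm[2],
      star_start = gs[1], star_end = gs[2],
      loop_unit = ssr_unit, loop_reps = ssr_reps,
      stringsAsFactors = FALSE)
    if (has_ssr) {
      gl <- g(arm_len + 1L, arm_len + nchar(loop))
      ssrs[[length(ssrs) + 1L]] <- data.frame(
        hp_id = hp_id, unit = ssr_unit, repeat_number = ssr_reps,
        length = nchar(loop), chrom = names(chroms)[ci], strand = strand,
        start = gl[1], end = gl[2], stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    mirnas = if (length(mirnas)) do.call(rbind, mirnas) else NULL,
    ssrs = if (length(ssrs)) do.call(rbind, ssrs) else
      data.frame(hp_id = character(), unit = character(),
                 repeat_number = integer(), length = integer(),
                 chrom = character(), strand = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE))
  list(genome = chroms, truth = truth,
       params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                     n_hairpins = n_hairpins,
                     n_ssr_hairpins = n_ssr_hairpins, seed = seed,
                     arm_len = arm_len))
}

# Per-tissue abundance patterns cycled over expressed planted miRNAs (the
# trigger takes the first). Includes >4-fold pairs (the 10x leaf/fruit pair),
# a tissue-absent case, and moderate enrichments.
ABUNDANCE_PATTERNS <- list(
  c(leaf = 300, flower = 280, fruit = 260),
  c(leaf = 200, flower = 40,  fruit = 40),
  c(leaf = 40,  flower = 40,  fruit = 400),
  c(leaf = 60,  flower = 150, fruit = 60),
  c(leaf = 100, flower = 100, fruit = 100),
  c(leaf = 80,  flower = 80,  fruit = 0),
  c(leaf = 120, flower = 50,  fruit = 50),
  c(leaf = 40,  flower = 200, fruit = 40),
  c(leaf = 50,  flower = 50,  fruit = 160),
  c(leaf = 90,  flower = 90,  fruit = 90))
SUBTHRESHOLD_PATTERNS <- list(c(leaf = 2, flower = 1, fruit = 0),
                              c(leaf = 2, flower = 2, fruit = 2))

#' Simulate per-tissue collapsed sRNA libraries
#'
#' Background reads follow a 24-nt-dominant length distribution (65% drawn
#' from the genome, the rest unmappable); planted matures receive the
#' manifest's per-tissue counts (including >4-fold tissue pairs and
#' sub-threshold plants) and star reads at `star_fraction` of the mature
#' count.
#'
#' @param sim Result of [simulate_genome()].
#' @param tissues Subset of `c("leaf","flower","fruit")`.
#' @param depth Approximate total read count per tissue (>= 1000).
#' @param seed Integer seed.
#' @param ncrna Optional named character vector of non-coding RNA references;
#'   when given, reads sampled from them are spiked in.
#' @param star_fraction Star-read fraction of the mature count.
#' @return list with `libraries` (named list of `sequence`/`count`
#'   data.frames) and `abundance` (planted manifest counts per tissue).
#' @export
simulate_srna_libraries <- function(sim, tissues = SRDK_TISSUES,
                                    depth = 50000L, seed = 1L,
                                    ncrna = NULL, star_fraction = 0.1) {
  if (!length(tissues) || !all(tissues %in% SRDK_TISSUES))
    stop("unknown tissue label: tissues must be among ",
         paste(SRDK_TISSUES, collapse = ", "), call. = FALSE)
  if (depth < 1000) stop("depth must be at least 1000", call. = FALSE)
  set.seed(seed + 33L)
  genome <- sim$genome
  mir <- sim$truth$mirnas

  # manifest counts
  ab <- list()
  if (!is.null(mir)) {
    i_exp <- 0L; i_sub <- 0L
    for (r in seq_len(nrow(mir))) {
      if (mir$expressed[r]) {
        i_exp <- i_exp + 1L
        pat <- ABUNDANCE_PATTERNS[[(i_exp - 1L) %% length(ABUNDANCE_PATTERNS) + 1L]]
      } else {
        i_sub <- i_sub + 1L
        pat <- SUBTHRESHOLD_PATTERNS[[(i_sub - 1L) %% length(SUBTHRESHOLD_PATTERNS) + 1L]]
      }
      ab[[r]] <- data.frame(hp_id = mir$hp_id[r], tissue = names(pat),
                            mature_count = as.integer(pat),
                            star_count = as.integer(ceiling(star_fraction * pat)),
                            stringsAsFactors = FALSE)
    }
  }
  abundance <- if (length(ab)) do.call(rbind, ab) else
    data.frame(hp_id = character(), tissue = character(),
               mature_count = integer(), star_count = integer(),
               stringsAsFactors = FALSE)

  # shared background pool; per-read counts average ~6.4 across tissues
  # (geometric mean 8, 80% presence), so this sizes the pool such that the
  # emitted library totals approximate `depth`
  n_bg <- max(50L, round(depth / 7))
  lens <- sample(BG_LENGTHS, n_bg, replace = TRUE, prob = BG_LENGTH_PROBS)
  from_genome <- runif(n_bg) < 0.65
  chrom_lens <- nchar(genome)
  bg_seq <- character(n_bg)
  for (i in seq_len(n_bg)) {
    if (from_genome[i]) {
      ci <- sample(seq_along(genome), 1L)
      pos <- sample(chrom_lens[ci] - lens[i], 1L)
      s <- substr(genome[[ci]], pos, pos + lens[i] - 1L)
      if (runif(1) < 0.5) s <- revcomp(s)
      bg_seq[i] <- s
    } else {
      bg_seq[i] <- rand_dna(lens[i])
    }
  }
  planted_seqs <- if (!is.null(mir)) c(mir$mature_seq, mir$star_seq) else character()
  bg_seq <- setdiff(unique(bg_seq), planted_seqs)
  n_bg <- length(bg_seq)

  nc_seq <- character(0)
  if (!is.null(ncrna) && length(ncrna)) {
    for (i in seq_len(20L)) {
      ri <- sample(seq_along(ncrna), 1L)
      w <- sample(20:24, 1L)
      if (nchar(ncrna[[ri]]) <= w) next
      pos <- sample(nchar(ncrna[[ri]]) - w, 1L)
      nc_seq <- c(nc_seq, substr(ncrna[[ri]], pos, pos + w - 1L))
    }
    nc_seq <- setdiff(unique(nc_seq), c(planted_seqs, bg_seq))
  }

  libraries <- list()
  for (t in tissues) {
    present <- runif(n_bg) < 0.8
    counts <- (1L + stats::rgeom(n_bg, 1 / 8)) * present
    df <- data.frame(sequence = bg_seq, count = as.integer(counts),
                     stringsAsFactors = FALSE)
    if (length(nc_seq)) {
      df <- rbind(df, data.frame(sequence = nc_seq,
                                 count = 4L + stats::rpois(length(nc_seq), 6),
                                 stringsAsFactors = FALSE))
    }
    if (!is.null(mir)) {
      at <- abundance[abundance$tissue == t, , drop = FALSE]
      at <- at[match(mir$hp_id, at$hp_id), , drop = FALSE]
      df <- rbind(df,
                  data.frame(sequence = mir$mature_seq,
                             count = at$mature_count, stringsAsFactors = FALSE),
                  data.frame(sequence = mir$star_seq,
                             count = at$star_count, stringsAsFactors = FALSE))
    }
    df <- df[df$count > 0L, , drop = FALSE]
    agg <- rowsum(df$count, group = df$sequence, reorder = FALSE)
    libraries[[t]] <- data.frame(sequence = rownames(agg),
                                 count = as.integer(agg[, 1]),
                                 stringsAsFactors = FALSE)
  }
  list(libraries = libraries, abundance = abundance)
}

#' Simulate a transcriptome with planted cleavage targets
#'
#' Plants reverse-complement target sites for the expressed planted miRNAs:
#' the trigger targets a non-coding transcript (the candidate TAS gene, with
#' intended category I), most other targets are category I, one is category
#' II (a decoy position will out-peak it) and one category III. One phased
#' siRNA (register 7 of the trigger cascade) also receives a category-I
#' target on a coding transcript.
#'
#' @param sim Result of [simulate_genome()].
#' @param n_transcripts,transcript_len Transcriptome dimensions.
#' @param seed Integer seed.
#' @param phase_length Phasing register length (nt).
#' @param n_registers Planted cascade registers K.
#' @return list with `transcripts` (named character), `coding_status`,
#'   and `truth` additions (`targets`, `phasing`).
#' @export
simulate_transcripts <- function(sim, n_transcripts = 12L,
                                 transcript_len = 1000L, seed = 1L,
                                 phase_length = 21L, n_registers = 9L) {
  set.seed(seed + 22L)
  stopifnot(n_transcripts >= 3L, transcript_len >= 600L)
  ids <- sprintf("Cs%dg%05d", rep(1:9, length.out = n_transcripts),
                 seq_len(n_transcripts) * 10L)
  tx <- setNames(vapply(seq_len(n_transcripts),
                        function(i) rand_dna(transcript_len), ""), ids)
  mir <- sim$truth$mirnas
  targets <- list()
  phasing <- NULL
  if (!is.null(mir)) {
    exp_mir <- mir[mir$expressed, , drop = FALSE]
    n_t <- min(nrow(exp_mir), n_transcripts - 1L)
    site_start <- 301L
    for (j in seq_len(n_t)) {
      m <- exp_mir[j, ]
      L <- nchar(m$mature_seq)
      cat_int <- if (j == min(6L, n_t) && n_t >= 6L) "II"
                 else if (j == min(7L, n_t) && n_t >= 7L) "III" else "I"
      txid <- ids[j]
      site <- revcomp(m$mature_seq)
      tx[[txid]] <- paste0(substr(tx[[txid]], 1L, site_start - 1L), site,
                           substr(tx[[txid]], site_start + L, transcript_len))
      cleavage <- site_start + L - 10L
      targets[[length(targets) + 1L]] <- data.frame(
        mirna = m$hp_id, ref_id = m$ref_id, transcript_id = txid,
        site_start = site_start, cleavage_site = cleavage,
        category = cat_int, stringsAsFactors = FALSE)
      if (m$is_trigger) {
        if (cleavage + phase_length * n_registers - 1L > transcript_len)
          stop("capacity error: ", n_registers,
               " registers do not fit in the transcript", call. = FALSE)
        phasing <- list(trigger = m$hp_id, ref_id = m$ref_id,
                        transcript_id = txid, cleavage_site = cleavage,
                        K = n_registers)
      }
    }
    # a phasiRNA (register 7, or the last register) gets its own target
    if (!is.null(phasing) && n_transcripts > n_t + 1L) {
      k7 <- min(7L, phasing$K)
      st <- phasing$cleavage_site + phase_length * (k7 - 1L)
      ph_seq <- substr(tx[[phasing$transcript_id]], st, st + phase_length - 1L)
      txid <- ids[n_t + 1L]
      site <- revcomp(ph_seq)
      tx[[txid]] <- paste0(substr(tx[[txid]], 1L, 300L), site,
                           substr(tx[[txid]], 301L + phase_length,
                                  transcript_len))
      targets[[length(targets) + 1L]] <- data.frame(
        mirna = sprintf("%s_phase%d", phasing$trigger, k7),
        ref_id = NA_character_, transcript_id = txid,
        site_start = 301L, cleavage_site = 301L + phase_length - 10L,
        category = "I", stringsAsFactors = FALSE)
      phasing$phasi_k <- k7
      phasing$phasi_seq <- ph_seq
      phasing$phasi_target <- txid
    }
  }
  coding <- data.frame(transcript_id = ids, coding = TRUE,
                       stringsAsFactors = FALSE)
  if (!is.null(phasing))
    coding$coding[coding$transcript_id == phasing$transcript_id] <- FALSE
  list(transcripts = tx, coding_status = coding,
       truth = list(targets = if (length(targets)) do.call(rbind, targets)
                    else NULL,
                    phasing = phasing))
}

#' Simulate per-tissue degradome libraries (20-nt 5' tags)
#'
#' Background tags are drawn uniformly over transcript positions (plus a
#' fraction of unmappable tags); planted cleavage signals receive
#' `signal_to_noise` tag counts, with background peaks capped at a quarter of
#' that so category-I signals are strict maxima by construction. Category-II
#' plants get a decoy position with 1.8x the signal; category-III plants get
#' a 2-count signal under a high decoy.
#'
#' @param txsim Result of [simulate_transcripts()].
#' @param tissues Tissues to emit.
#' @param depth Approximate tag total per tissue; `0` gives empty libraries.
#' @param signal_to_noise Planted signal tag count (> 0).
#' @param seed Integer seed.
#' @return Named list (per tissue) of `sequence`/`count` data.frames.
#' @export
simulate_degradome <- function(txsim, tissues = SRDK_TISSUES,
                               depth = 3000L, signal_to_noise = 20,
                               seed = 1L) {
  if (signal_to_noise <= 0)
    stop("signal_to_noise must be positive", call. = FALSE)
  set.seed(seed + 55L)
  tx <- txsim$transcripts
  targets <- txsim$truth$targets
  tag_len <- 20L
  out <- list()
  for (t in tissues) {
    if (depth == 0L) {
      out[[t]] <- data.frame(sequence = character(), count = integer(),
                             stringsAsFactors = FALSE)
      next
    }
    bg_cap <- max(1L, floor(signal_to_noise / 4))
    n_tags <- max(10L, round(depth * 0.8 / 2))
    rows <- list()
    poscnt <- lapply(tx, function(s) integer(nchar(s)))
    for (i in seq_len(n_tags)) {
      ti <- sample(seq_along(tx), 1L)
      n <- nchar(tx[[ti]])
      pos <- sample(n - tag_len, 1L)
      cnt <- 1L + stats::rgeom(1L, 0.5)
      room <- bg_cap - poscnt[[ti]][pos]
      if (room <= 0L) next
      cnt <- min(cnt, room)
      poscnt[[ti]][pos] <- poscnt[[ti]][pos] + cnt
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(tx[[ti]], pos, pos + tag_len - 1L),
        count = cnt, stringsAsFactors = FALSE)
    }
    n_un <- max(5L, round(depth * 0.2 / 1.5))
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = vapply(seq_len(n_un), function(i) rand_dna(tag_len), ""),
      count = 1L + stats::rpois(n_un, 0.5), stringsAsFactors = FALSE)
    if (!is.null(targets)) {
      for (r in seq_len(nrow(targets))) {
        txid <- targets$transcript_id[r]
        cleave <- targets$cleavage_site[r]
        n <- nchar(tx[[txid]])
        if (cleave + 2L * tag_len > n)
          stop("planted target too close to the transcript 3' end",
               call. = FALSE)
        sig <- as.integer(ceiling(signal_to_noise))
        plant <- switch(targets$category[r],
          I = data.frame(pos = cleave, count = sig),
          II = data.frame(pos = c(cleave, cleave + 97L),
                          count = c(sig, as.integer(ceiling(1.8 * sig)))),
          III = data.frame(pos = c(cleave, cleave + 97L),
                           count = c(2L, as.integer(ceiling(1.5 * sig)))))
        for (p in seq_len(nrow(plant))) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = substr(tx[[txid]], plant$pos[p],
                              plant$pos[p] + tag_len - 1L),
            count = plant$count[p], stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    agg <- rowsum(df$count, group = df$sequence, reorder = FALSE)
    out[[t]] <- data.frame(sequence = rownames(agg),
                           count = as.integer(agg[, 1]),
                           stringsAsFactors = FALSE)
  }
  out
}

#' Simulate the 22-nt-triggered phasing cascade
#'
#' Emits 21-nt reads at registers `c + 21(k-1)`, `k = 1..K`, on the trigger
#' target's 3' cleavage fragment (each above the count filter), plus the
#' trigger's cleavage tag for the degradome.
#'
#' @param txsim Result of [simulate_transcripts()] (must carry a planted
#'   trigger).
#' @param tissues Tissues to emit.
#' @param seed Integer seed.
#' @param phase_length Register length (nt).
#' @return list with `srna` and `degradome` additions (named per-tissue
#'   lists) and `registers` (k, start, end, sequence).
#' @export
simulate_phasing_cascade <- function(txsim, tissues = SRDK_TISSUES,
                                     seed = 1L, phase_length = 21L) {
  ph <- txsim$truth$phasing
  if (is.null(ph)) stop("no planted trigger in the manifest", call. = FALSE)
  set.seed(seed + 66L)
  seq <- txsim$transcripts[[ph$transcript_id]]
  n <- nchar(seq)
  K <- ph$K
  if (ph$cleavage_site + phase_length * K - 1L > n)
    stop("capacity error: K registers do not fit in the transcript",
         call. = FALSE)
  starts <- ph$cleavage_site + phase_length * (seq_len(K) - 1L)
  registers <- data.frame(k = seq_len(K), start = starts,
                          end = starts + phase_length - 1L,
                          sequence = substring(seq, starts,
                                               starts + phase_length - 1L),
                          stringsAsFactors = FALSE)
  base <- c(leaf = 12L, flower = 10L, fruit = 5L)
  srna <- list(); degradome <- list()
  for (t in tissues) {
    srna[[t]] <- data.frame(sequence = registers$sequence,
                            count = rep(base[[t]], K),
                            stringsAsFactors = FALSE)
    degradome[[t]] <- data.frame(
      sequence = substr(seq, ph$cleavage_site, ph$cleavage_site + 19L),
      count = 5L, stringsAsFactors = FALSE)
  }
  list(srna = srna, degradome = degradome, registers = registers)
}

#' Simulate non-coding RNA references
#'
#' @param n Number of reference sequences.
#' @param seed Integer seed.
#' @return Named character vector (rRNA/tRNA/snRNA/snoRNA-style identifiers).
#' @export
simulate_ncrna <- function(n = 6L, seed = 1L) {
  set.seed(seed + 44L)
  kinds <- rep(c("rRNA", "tRNA", "snRNA", "snoRNA"), length.out = n)
  setNames(vapply(seq_len(n), function(i) rand_dna(sample(80:200, 1L)), ""),
           sprintf("%s%d", kinds, seq_len(n)))
}

merge_read_sets <- function(a, b) {
  df <- rbind(a, b)
  agg <- rowsum(df$count, group = df$sequence, reorder = FALSE)
  data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset
#'
#' Runs all generators under one master seed (each derives a fixed sub-seed,
#' so components can be regenerated independently), merges the phasing
#' cascade into the sRNA and degradome libraries, and optionally writes the
#' standard file set (`genome.fa`, `transcripts.fa`, `mirna_ref.fa`,
#' `ncrna.fa`, `<tissue>.srna.fa`, `<tissue>.degradome.fa`, truth manifests).
#'
#' @param outdir Optional output directory (created if needed).
#' @param tissues Tissues to simulate.
#' @param n_chrom,chrom_len,n_hairpins,n_ssr_hairpins,arm_len Genome
#'   parameters ([simulate_genome()]).
#' @param n_transcripts,transcript_len Transcriptome parameters.
#' @param srna_depth,degradome_depth Library depths per tissue.
#' @param signal_to_noise Degradome signal strength.
#' @param n_registers Planted phased registers K.
#' @param with_cascade Plant the phasing cascade (needs a trigger).
#' @param seed Master seed.
#' @return list with `genome`, `transcripts`, `coding_status`, `mirna_ref`,
#'   `ncrna`, `libraries`, `degradome`, `truth` (mirnas, ssrs, targets,
#'   phasing, abundance, registers) and `files` (when written).
#' @export
simulate_dataset <- function(outdir = NULL, tissues = SRDK_TISSUES,
                             n_chrom = 2L, chrom_len = 50000L,
                             n_hairpins = 12L, n_ssr_hairpins = 4L,
                             arm_len = 90L, n_transcripts = 12L,
                             transcript_len = 1000L, srna_depth = 50000L,
                             degradome_depth = 3000L, signal_to_noise = 20,
                             n_registers = 9L, with_cascade = TRUE,
                             seed = 1L) {
  gsim <- simulate_genome(n_chrom, chrom_len, n_hairpins, n_ssr_hairpins,
                          seed, arm_len)
  txsim <- simulate_transcripts(gsim, n_transcripts, transcript_len, seed,
                                n_registers = n_registers)
  ncrna <- simulate_ncrna(seed = seed)
  lsim <- simulate_srna_libraries(gsim, tissues, srna_depth, seed,
                                  ncrna = ncrna)
  degradome <- simulate_degradome(txsim, tissues, degradome_depth,
                                  signal_to_noise, seed)
  registers <- NULL
  libraries <- lsim$libraries
  if (with_cascade && !is.null(txsim$truth$phasing)) {
    casc <- simulate_phasing_cascade(txsim, tissues, seed)
    registers <- casc$registers
    for (t in tissues) {
      libraries[[t]] <- merge_read_sets(libraries[[t]], casc$srna[[t]])
      if (nrow(degradome[[t]]))
        degradome[[t]] <- merge_read_sets(degradome[[t]], casc$degradome[[t]])
    }
  }
  mir <- gsim$truth$mirnas
  mirna_ref <- character(0)
  if (!is.null(mir)) {
    known <- mir[mir$is_known, , drop = FALSE]
    mirna_ref <- setNames(known$mature_seq, known$ref_id)
  }
  set.seed(seed + 77L)
  mirna_ref <- c(mirna_ref,
                 setNames(c(rand_dna(21L), rand_dna(21L)),
                          c("csi-miR9991", "csi-miR9992")))
  res <- list(genome = gsim$genome, transcripts = txsim$transcripts,
              coding_status = txsim$coding_status, mirna_ref = mirna_ref,
              ncrna = ncrna, libraries = libraries, degradome = degradome,
              truth = c(gsim$truth, txsim$truth,
                        list(abundance = lsim$abundance,
                             registers = registers)),
              params = list(seed = seed, tissues = tissues))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    write_fasta(res$genome, fp("genome.fa"))
    write_fasta(res$transcripts, fp("transcripts.fa"))
    write_fasta(res$mirna_ref, fp("mirna_ref.fa"))
    write_fasta(res$ncrna, fp("ncrna.fa"))
    for (t in tissues) {
      write_collapsed_srna(libraries[[t]], fp(paste0(t, ".srna.fa")))
      write_collapsed_srna(degradome[[t]], fp(paste0(t, ".degradome.fa")))
    }
    write_tsv(res$coding_status, fp("coding_status.tsv"))
    if (!is.null(res$truth$mirnas))
      write_tsv(res$truth$mirnas, fp("truth_mirnas.tsv"))
    write_tsv(res$truth$ssrs, fp("truth_ssrs.tsv"))
    if (!is.null(res$truth$targets))
      write_tsv(res$truth$targets, fp("truth_targets.tsv"))
    write_tsv(res$truth$abundance, fp("truth_abundance.tsv"))
    res$files <- list.files(outdir, full.names = TRUE)
  }
  res
}
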