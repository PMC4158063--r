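## Degradome (PARE) target calling: T-plots, plant complementarity penalty
## scoring, cleavage validation opposite miRNA position 10/11, and category
## I/II/III confidence classification.

#' Build T-plots from degradome tags
#'
#' Each tag is matched exactly against the sense strand of every transcript;
#' its 5' position increments the transcript's position-count vector at every
#' transcript where it matches (multi-matching tags count in every T-plot).
#'
#' @param tags_by_library Named list (per library) of data.frames with
#'   `sequence` and `count` (e.g. [read_collapsed_srna()] on a degradome
#'   FASTA).
#' @param transcripts Transcripts: data.frame from [read_fasta()] or named
#'   character vector.
#' @return An `srdk_tplots` object: list with `plots[[library]][[transcript]]`
#'   (integer vector over transcript positions), `transcript_length`, and
#'   `stats` (per-library tag accounting with mRNA-matched percentages).
#' @export
build_tplots <- function(tags_by_library, transcripts) {
  if (is.data.frame(transcripts))
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  transcripts <- setNames(canonical_dna(transcripts), names(transcripts))
  tx_set <- Biostrings::DNAStringSet(transcripts)
  tlen <- setNames(nchar(transcripts), names(transcripts))
  plots <- list()
  stats <- list()
  for (lib in names(tags_by_library)) {
    tags <- tags_by_library[[lib]]
    tags$sequence <- canonical_dna(tags$sequence)
    mat <- lapply(tlen, function(n) integer(n))
    matched <- logical(nrow(tags))
    if (nrow(tags)) {
      widths <- nchar(tags$sequence)
      for (w in sort(unique(widths))) {
        idx <- which(widths == w)
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$sequence[idx]))
        for (ti in seq_along(tx_set)) {
          tx <- names(tx_set)[ti]
          m <- Biostrings::matchPDict(pd, tx_set[[ti]])
          cnt <- S4Vectors::elementNROWS(m)
          for (k in which(cnt > 0L)) {
            starts <- IRanges::start(m[[k]])
            mat[[tx]][starts] <- mat[[tx]][starts] + tags$count[idx[k]]
            matched[idx[k]] <- TRUE
          }
        }
      }
    }
    plots[[lib]] <- mat
    total <- sum(tags$count)
    mt <- sum(tags$count[matched])
    stats[[lib]] <- data.frame(
      library = lib, total_tags = total, unique_tags = nrow(tags),
      matched_total = mt, matched_unique = sum(matched),
      pct_matched_total = if (total > 0) 100 * mt / total else NA_real_,
      pct_matched_unique = if (nrow(tags) > 0)
        100 * sum(matched) / nrow(tags) else NA_real_,
      stringsAsFactors = FALSE)
    log_stage(paste0("build_tplots[", lib, "]"), nrow(tags), sum(matched))
  }
  structure(list(plots = plots, transcript_length = tlen,
                 transcripts = transcripts,
                 stats = do.call(rbind, stats)),
            class = "srdk_tplots")
}

# Penalty lookup: rows = miRNA base, cols = transcript base (both 5'->3', DNA
# alphabet). Perfect complement scores 0; G:U wobble (miRNA G opposite
# transcript T, or miRNA T opposite transcript G) scores the wobble penalty;
# everything else is a mismatch.
penalty_lookup <- function(config) {
  b <- c("A", "C", "G", "T")
  P <- matrix(config$mismatch_penalty, 4, 4, dimnames = list(b, b))
  P["A", "T"] <- 0; P["T", "A"] <- 0; P["G", "C"] <- 0; P["C", "G"] <- 0
  P["G", "T"] <- config$wobble_penalty
  P["T", "G"] <- config$wobble_penalty
  P
}

core_weights <- function(L) ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)

#' Score a miRNA--target-site alignment
#'
#' Ungapped plant-target complementarity penalty: per miRNA position, 0 for a
#' Watson-Crick pair, `wobble_penalty` (0.5) for a G:U wobble, and
#' `mismatch_penalty` (1) for a mismatch; positions 2-13 from the miRNA 5'
#' end are double-weighted. miRNA position `i` is paired with site position
#' `L - i + 1` (the site is the transcript window, given 5' to 3').
#'
#' @param mirna_seq Mature miRNA sequence.
#' @param site_seq Transcript window of the same length, 5' to 3'.
#' @param config An [pipeline_config()] object.
#' @return list with `penalty` and `alignment` (one symbol per miRNA
#'   position: `|` match, `o` G:U wobble, `x` mismatch).
#' @export
score_alignment <- function(mirna_seq, site_seq, config = pipeline_config()) {
  m <- strsplit(canonical_dna(mirna_seq), "")[[1]]
  s <- strsplit(canonical_dna(site_seq), "")[[1]]
  if (length(m) != length(s))
    stop("alignment error: site length differs from miRNA length ",
         "(gapped alignment is disabled)", call. = FALSE)
  L <- length(m)
  P <- penalty_lookup(config)
  opp <- s[L - seq_len(L) + 1L]
  per_pos <- P[cbind(m, opp)]
  symbols <- ifelse(per_pos == 0, "|",
                    ifelse(per_pos == config$wobble_penalty, "o", "x"))
  list(penalty = sum(per_pos * core_weights(L)),
       alignment = paste(symbols, collapse = ""))
}

# Vectorized penalty over all windows of a transcript for one miRNA.
scan_penalties <- function(m_chars, t_chars, P, weights) {
  L <- length(m_chars)
  ns <- length(t_chars) - L + 1L
  if (ns < 1L) return(numeric(0))
  pen <- numeric(ns)
  for (i in seq_len(L)) {
    opp <- t_chars[seq_len(ns) + (L - i)]
    pen <- pen + weights[i] * P[cbind(rep(m_chars[i], ns), opp)]
  }
  pen
}

#' Classify a cleavage site into category I, II or III
#'
#' Category I: the tag count at the cleavage site is the unique maximum of
#' the transcript's T-plot. Category II: the site is a clear peak --- at
#' least `peak_fraction` of the transcript maximum --- but not the unique
#' maximum (a shared maximum is category II). Category III: everything else.
#'
#' @param position_counts Integer vector of tag 5'-end counts per transcript
#'   position (a T-plot row).
#' @param cleavage_site 1-based transcript position of the cleavage signal.
#' @param peak_fraction Clear-peak fraction (default 0.5).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_category <- function(position_counts, cleavage_site,
                              peak_fraction = 0.5) {
  if (all(position_counts == 0))
    stop("no degradome evidence: all-zero T-plot", call. = FALSE)
  stopifnot(cleavage_site >= 1, cleavage_site <= length(position_counts))
  cc <- position_counts[cleavage_site]
  mx <- max(position_counts)
  if (cc == mx && sum(position_counts == mx) == 1L) return("I")
  if (cc >= peak_fraction * mx) return("II")
  "III"
}

#' Call miRNA targets from degradome T-plots
#'
#' For every query x transcript window with complementarity penalty at or
#' below `penalty_threshold`, the predicted cleavage position is the
#' transcript nucleotide opposite miRNA position 10 (5'-counted). A call is
#' emitted iff the T-plot carries at least one tag within 1 nt of that
#' position (the reported site is the maximum-count position in that window,
#' accommodating cleavage opposite nucleotide 10 or 11), and is classified
#' with [classify_category()]. Calls are reported per library.
#'
#' @param queries data.frame with `mirna_id` and `sequence` (mature miRNAs or
#'   phased siRNAs).
#' @param tplots An `srdk_tplots` object.
#' @param config An [pipeline_config()] object.
#' @return data.frame of target calls: `library`, `mirna_id`,
#'   `transcript_id`, `site_start`, `cleavage_site`, `cleavage_count`,
#'   `transcript_max`, `category`, `penalty`, `alignment`.
#' @export
call_targets <- function(queries, tplots, config = pipeline_config()) {
  stopifnot(inherits(tplots, "srdk_tplots"))
  empty <- data.frame(library = character(), mirna_id = character(),
                      transcript_id = character(), site_start = integer(),
                      cleavage_site = integer(), cleavage_count = integer(),
                      transcript_max = integer(), category = character(),
                      penalty = numeric(), alignment = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(queries)) return(empty)
  P <- penalty_lookup(config)
  tx_chars <- lapply(tplots$transcripts, function(s) strsplit(s, "")[[1]])
  rows <- list()
  for (q in seq_len(nrow(queries))) {
    mseq <- canonical_dna(queries$sequence[q])
    m_chars <- strsplit(mseq, "")[[1]]
    L <- length(m_chars)
    w <- core_weights(L)
    for (tx in names(tx_chars)) {
      pen <- scan_penalties(m_chars, tx_chars[[tx]], P, w)
      ok <- which(pen <= config$penalty_threshold)
      if (!length(ok)) next
      for (lib in names(tplots$plots)) {
        counts <- tplots$plots[[lib]][[tx]]
        if (all(counts == 0)) next
        for (s in ok) {
          cleave <- s + L - 10L
          win <- intersect((cleave - 1L):(cleave + 1L),
                           seq_along(counts))
          if (!length(win) || all(counts[win] == 0)) next
          site <- win[which.max(counts[win])]
          # prefer the canonical position on count ties
          if (counts[cleave] == max(counts[win]) && cleave %in% win)
            site <- cleave
          al <- score_alignment(mseq,
                                substr(tplots$transcripts[[tx]], s, s + L - 1L),
                                config)
          rows[[length(rows) + 1L]] <- data.frame(
            library = lib, mirna_id = queries$mirna_id[q],
            transcript_id = tx, site_start = s, cleavage_site = site,
            cleavage_count = counts[site],
            transcript_max = max(counts),
            category = classify_category(counts, site, config$peak_fraction),
            penalty = pen[s], alignment = al$alignment,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  # one call per (library, miRNA, transcript, site): keep the best alignment
  key <- paste(res$library, res$mirna_id, res$transcript_id, res$cleavage_site)
  res <- res[order(key, res$penalty), , drop = FALSE]
  res <- res[!duplicated(paste(res$library, res$mirna_id, res$transcript_id,
                               res$cleavage_site)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize target calls per category and library
#'
#' @param calls data.frame from [call_targets()].
#' @return data.frame with `library`, `category`, `n_targets` (distinct
#'   transcript-miRNA pairs) per category.
#' @export
summarize_targets <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(library = character(), category = character(),
                      n_targets = integer(), stringsAsFactors = FALSE))
  }
  key <- unique(calls[, c("library", "category", "mirna_id", "transcript_id")])
  agg <- aggregate(list(n_targets = key$mirna_id),
                   by = list(library = key$library, category = key$category),
                   FUN = length)
  agg[order(agg$library, agg$category), , drop = FALSE]
}

#' @importFrom stats aggregate
NULL
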