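## miRNA discovery: mismatch-tolerant matching against reference matures,
## novel calls from hairpin-validated genomic loci, isoform pairs, and
## genome distribution.

# Candidate precursor windows around a genomic hit. A mature miRNA sits near
# one end of its precursor, so the two asymmetric windows (long flank on one
# side, short on the other) are tried along with the symmetric window; the
# first window whose fold passes the structural criteria is kept.
precursor_windows <- function(start, end, chrom_len, config) {
  f <- config$flank_for_precursor
  s <- config$flank_short
  w <- rbind(c(start - s, end + f),
             c(start - f, end + s),
             c(start - f, end + f))
  w[, 1] <- pmax(w[, 1], 1L)
  w[, 2] <- pmin(w[, 2], chrom_len)
  unique(w)
}

# Fold one candidate window and compute hairpin metrics for the mature read.
# Returns NULL when the window does not look like a hairpin.
eval_hairpin_window <- function(chrom_seq, hit_start, hit_end, strand,
                                wstart, wend, min_loop = 3L) {
  wseq <- substr(chrom_seq, wstart, wend)
  if (strand == "+") {
    m1 <- hit_start - wstart + 1L
  } else {
    wseq <- revcomp(wseq)
    m1 <- wend - hit_end + 1L
  }
  m2 <- m1 + (hit_end - hit_start)
  struct <- fold_rna(wseq, min_loop = min_loop)
  metrics <- try(hairpin_metrics(struct, c(m1, m2)), silent = TRUE)
  if (inherits(metrics, "try-error")) return(NULL)
  list(struct = struct, metrics = metrics, precursor = wseq,
       m1 = m1, m2 = m2, wstart = wstart, wend = wend)
}

# Trim an accepted window to the hairpin proper (duplex span plus margin),
# refold, and return the final locus geometry, or NULL if the trimmed
# precursor no longer passes.
trim_and_refold <- function(ev, margin = 15L) {
  met <- ev$metrics
  lo <- max(1L, min(ev$m1, met$star_interval[1]) - margin)
  hi <- min(nchar(ev$precursor), max(ev$m2, met$star_interval[2]) + margin)
  prec <- substr(ev$precursor, lo, hi)
  m1 <- ev$m1 - lo + 1L
  m2 <- ev$m2 - lo + 1L
  struct <- fold_rna(prec)
  metrics <- try(hairpin_metrics(struct, c(m1, m2)), silent = TRUE)
  if (inherits(metrics, "try-error")) return(NULL)
  list(struct = struct, metrics = metrics, precursor = prec,
       m1 = m1, m2 = m2, offset = lo - 1L)
}

# Genomic interval of a position range inside the (possibly minus-strand)
# window [wstart, wend].
window_to_genomic <- function(wstart, wend, strand, lo, hi) {
  if (strand == "+") c(wstart + lo - 1L, wstart + hi - 1L)
  else c(wend - hi + 1L, wend - lo + 1L)
}

structural_pass <- function(metrics, config) {
  !is.null(metrics) &&
    metrics$duplex_mismatches <= config$max_duplex_mismatches &&
    metrics$max_asym_bulge <= config$max_asym_bulge &&
    metrics$mature_paired_fraction >= config$min_mature_paired_fraction
}

# Ungapped comparison of a read to a reference mature: substitutions, plus
# the length difference when the shorter sequence is slid within the longer.
# Inf when the length difference exceeds the slide allowance.
slide_mismatches <- function(read, ref, max_len_diff = 2L) {
  lr <- nchar(read); lf <- nchar(ref)
  d <- abs(lr - lf)
  if (d > max_len_diff) return(Inf)
  long <- if (lr >= lf) read else ref
  short <- if (lr >= lf) ref else read
  sc <- strsplit(short, "")[[1]]
  best <- Inf
  for (off in 0:d) {
    wc <- strsplit(substr(long, off + 1L, off + nchar(short)), "")[[1]]
    best <- min(best, sum(sc != wc))
  }
  best + d
}

mirna_locus_row <- function(mirna_id, locus_id, status, mature_seq, tr,
                            chrom, strand, wstart, wend) {
  g_pre <- window_to_genomic(wstart, wend, strand,
                             1L + tr$offset, tr$offset + nchar(tr$precursor))
  g_mat <- window_to_genomic(wstart, wend, strand,
                             tr$m1 + tr$offset, tr$m2 + tr$offset)
  data.frame(mirna_id = mirna_id, locus_id = locus_id, status = status,
             arm = tr$metrics$arm, mature_seq = mature_seq,
             star_seq = tr$metrics$star_seq, chrom = chrom, strand = strand,
             precursor_start = g_pre[1], precursor_end = g_pre[2],
             mature_start = g_mat[1], mature_end = g_mat[2],
             precursor_seq = tr$precursor, dot_bracket = tr$struct$dot_bracket,
             mature_paired_fraction = tr$metrics$mature_paired_fraction,
             duplex_mismatches = tr$metrics$duplex_mismatches,
             max_asym_bulge = tr$metrics$max_asym_bulge,
             loop_size = tr$metrics$loop_size,
             stringsAsFactors = FALSE)
}

#' Match catalog sequences against reference mature miRNAs
#'
#' A catalog sequence is assigned to the reference mature with the fewest
#' mismatches, provided the penalty (substitutions plus length overhang under
#' ungapped sliding) does not exceed `known_max_mismatch`; ties are broken by
#' reference order. Each assignment additionally requires a genomic locus
#' whose surrounding window folds into a stem-loop containing the mature
#' outside the terminal loop.
#'
#' @param catalog An `srdk_catalog` after [map_to_genome()].
#' @param reference Reference matures: data.frame from [read_fasta()] or a
#'   named character vector (RNA or DNA alphabet).
#' @param genome Genome as given to [map_to_genome()].
#' @param config An [pipeline_config()] object.
#' @return A miRNA locus table (one row per genomic locus) with a
#'   `ref_mismatches` column; zero rows when nothing matches.
#' @export
match_known <- function(catalog, reference, genome,
                        config = pipeline_config()) {
  stopifnot(inherits(catalog, "srdk_catalog"))
  if (is.null(catalog$genome_hits)) stop("run map_to_genome() first", call. = FALSE)
  if (is.data.frame(reference)) reference <- setNames(reference$sequence,
                                                      reference$id)
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  genome <- setNames(canonical_dna(genome), names(genome))
  out <- empty_loci()
  out$ref_mismatches <- integer()
  if (!length(reference)) {
    warning("empty miRNA reference: no known miRNAs can be assigned")
    return(out)
  }
  reference <- setNames(canonical_dna(reference), names(reference))
  rows <- list()
  cand <- which(catalog$annotation != "ncRNA")
  mapped <- unique(catalog$genome_hits$seq_index)
  cand <- intersect(cand, mapped)
  for (i in cand) {
    seq <- catalog$sequences[i]
    pen <- vapply(reference, slide_mismatches, 0, read = seq)
    best <- which.min(pen)
    if (!is.finite(pen[best]) || pen[best] > config$known_max_mismatch) next
    hits <- catalog$genome_hits[catalog$genome_hits$seq_index == i, ,
                                drop = FALSE]
    n_loc <- 0L
    for (h in seq_len(nrow(hits))) {
      chrom <- hits$chrom[h]
      wins <- precursor_windows(hits$start[h], hits$end[h],
                                nchar(genome[[chrom]]), config)
      for (w in seq_len(nrow(wins))) {
        ev <- eval_hairpin_window(genome[[chrom]], hits$start[h], hits$end[h],
                                  hits$strand[h], wins[w, 1], wins[w, 2])
        if (is.null(ev)) next
        if (ev$metrics$mature_paired_fraction <
            config$min_mature_paired_fraction) next
        tr <- trim_and_refold(ev)
        if (is.null(tr)) next
        if (tr$metrics$mature_paired_fraction <
            config$min_mature_paired_fraction) next
        n_loc <- n_loc + 1L
        id <- names(reference)[best]
        row <- mirna_locus_row(id, sprintf("%s-%d", id, n_loc), "known",
                               seq, tr, chrom, hits$strand[h],
                               ev$wstart, ev$wend)
        row$ref_mismatches <- as.integer(pen[best])
        rows[[length(rows) + 1L]] <- row
        break
      }
    }
  }
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Predict novel miRNAs from hairpin-validated genomic loci
#'
#' Considers every unassigned, genome-mapped catalog sequence of 20-24 nt.
#' For each genomic hit, candidate precursor windows are folded; a locus is
#' accepted when the mature lies outside the terminal loop with at most
#' `max_duplex_mismatches` unpaired positions and `max_asym_bulge` asymmetry,
#' and the catalog contains a read matching the computed miRNA* interval
#' (within a 1-nt shift) in at least one library. Identifiers `csi-miRN##`
#' are assigned in discovery order (descending total count); identical mature
#' sequences at multiple loci share one identifier with locus suffixes.
#'
#' @param catalog An `srdk_catalog` after [map_to_genome()].
#' @param genome Genome as given to [map_to_genome()].
#' @param config An [pipeline_config()] object.
#' @param exclude Mature sequences already assigned (e.g. known miRNAs).
#' @return A miRNA locus table; zero rows allowed.
#' @export
predict_novel <- function(catalog, genome, config = pipeline_config(),
                          exclude = character()) {
  stopifnot(inherits(catalog, "srdk_catalog"))
  if (is.null(catalog$genome_hits)) stop("run map_to_genome() first", call. = FALSE)
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  genome <- setNames(canonical_dna(genome), names(genome))
  lens <- nchar(catalog$sequences)
  cand <- which(catalog$annotation == "unannotated" &
                lens >= 20L & lens <= 24L &
                !(catalog$sequences %in% canonical_dna(exclude)) &
                seq_along(catalog$sequences) %in% catalog$genome_hits$seq_index)
  cand <- cand[order(-rowSums(catalog$counts[cand, , drop = FALSE]),
                     catalog$sequences[cand])]
  seq_set <- catalog$sequences
  consumed <- character(0)
  rows <- list()
  next_id <- 1L
  # Prescreen: folding is only attempted where some nearby catalog read could
  # plausibly be the miRNA* (an ungapped antiparallel duplex with the
  # candidate reaching L - max_duplex_mismatches - max_asym_bulge pairs).
  # The folded structure still decides; this only skips hopeless windows.
  gh <- catalog$genome_hits
  lens_all <- nchar(catalog$sequences)
  star_pool <- gh[lens_all[gh$seq_index] >= 19L &
                    lens_all[gh$seq_index] <= 25L, , drop = FALSE]
  pool_key <- paste(star_pool$chrom, star_pool$strand)
  reach <- config$flank_for_precursor + 40L
  has_star_partner <- function(i, hit_chrom, hit_strand, hit_start) {
    near <- star_pool[pool_key == paste(hit_chrom, hit_strand) &
                        star_pool$seq_index != i &
                        abs(star_pool$start - hit_start) <= reach, ,
                      drop = FALSE]
    if (!nrow(near)) return(FALSE)
    need <- nchar(catalog$sequences[i]) - config$max_duplex_mismatches -
      config$max_asym_bulge
    for (r in unique(near$seq_index)) {
      if (.duplex_pairs_cpp(catalog$sequences[i], catalog$sequences[r],
                            4L) >= need) return(TRUE)
    }
    FALSE
  }
  for (i in cand) {
    seq <- catalog$sequences[i]
    if (seq %in% consumed) next
    hits <- catalog$genome_hits[catalog$genome_hits$seq_index == i, ,
                                drop = FALSE]
    id <- NULL
    n_loc <- 0L
    for (h in seq_len(nrow(hits))) {
      chrom <- hits$chrom[h]
      if (!has_star_partner(i, chrom, hits$strand[h], hits$start[h])) next
      wins <- precursor_windows(hits$start[h], hits$end[h],
                                nchar(genome[[chrom]]), config)
      for (w in seq_len(nrow(wins))) {
        ev <- eval_hairpin_window(genome[[chrom]], hits$start[h], hits$end[h],
                                  hits$strand[h], wins[w, 1], wins[w, 2])
        if (is.null(ev) || !structural_pass(ev$metrics, config)) next
        tr <- trim_and_refold(ev)
        if (is.null(tr) || !structural_pass(tr$metrics, config)) next
        # miRNA* evidence: a catalog read consistent with the computed star
        # interval, allowing a 1-nt placement shift.
        si <- tr$metrics$star_interval
        shifts <- -1:1
        star_seqs <- vapply(shifts, function(d) {
          substr(tr$precursor, si[1] + d, si[2] + d)
        }, "")
        star_seqs <- star_seqs[nchar(star_seqs) == si[2] - si[1] + 1L]
        star_hit <- star_seqs[star_seqs %in% seq_set]
        if (!length(star_hit)) next
        if (is.null(id)) {
          id <- sprintf("csi-miRN%02d", next_id)
          next_id <- next_id + 1L
        }
        n_loc <- n_loc + 1L
        rows[[length(rows) + 1L]] <-
          mirna_locus_row(id, sprintf("%s-%d", id, n_loc), "novel", seq, tr,
                          chrom, hits$strand[h], ev$wstart, ev$wend)
        consumed <- c(consumed, star_hit)
        break
      }
    }
  }
  if (!length(rows)) {
    out <- empty_loci()
    out$ref_mismatches <- integer()
    return(out)
  }
  res <- do.call(rbind, rows)
  res$ref_mismatches <- NA_integer_
  rownames(res) <- NULL
  res
}

#' Attach per-library expression to a miRNA locus table
#'
#' @param loci miRNA locus table.
#' @param catalog A TPM-normalized `srdk_catalog`.
#' @return The loci with `count_<lib>` and `tpm_<lib>` columns.
#' @export
loci_expression <- function(loci, catalog) {
  idx <- match(loci$mature_seq, catalog$sequences)
  for (l in colnames(catalog$counts)) {
    loci[[paste0("count_", l)]] <- ifelse(is.na(idx), 0L,
                                          catalog$counts[idx, l])
    if (!is.null(catalog$tpm))
      loci[[paste0("tpm_", l)]] <- ifelse(is.na(idx), 0, catalog$tpm[idx, l])
  }
  loci
}

#' Find isoform pairs sharing a precursor
#'
#' Loci whose precursor intervals overlap on the same chromosome and strand
#' are treated as residing on one precursor; every pair of distinct mature
#' loci on such a precursor is reported with its separation (distance from
#' the end of the earlier mature to the start of the later one) and arm
#' labels.
#'
#' @param loci miRNA locus table.
#' @return data.frame with `locus_a`, `locus_b`, `mirna_a`, `mirna_b`,
#'   `separation`, `arm_a`, `arm_b`, `precursor_span`.
#' @export
find_isoform_pairs <- function(loci) {
  empty <- data.frame(locus_a = character(), locus_b = character(),
                      mirna_a = character(), mirna_b = character(),
                      separation = integer(), arm_a = character(),
                      arm_b = character(), precursor_span = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(loci) < 2L) return(empty)
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$precursor_start,
                                                loci$precursor_end),
                               strand = loci$strand)
  comp <- GenomicRanges::findOverlaps(gr, gr)
  # connected components via union-find over overlap pairs
  parent <- seq_len(nrow(loci))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(comp)) {
    a <- find(S4Vectors::queryHits(comp)[k])
    b <- find(S4Vectors::subjectHits(comp)[k])
    if (a != b) parent[b] <- a
  }
  groups <- vapply(seq_len(nrow(loci)), find, 0L)
  rows <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2L) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      if (loci$mature_start[a] == loci$mature_start[b] &&
          loci$mature_end[a] == loci$mature_end[b]) next
      first <- if (loci$mature_start[a] <= loci$mature_start[b]) a else b
      second <- if (first == a) b else a
      rows[[length(rows) + 1L]] <- data.frame(
        locus_a = loci$locus_id[first], locus_b = loci$locus_id[second],
        mirna_a = loci$mirna_id[first], mirna_b = loci$mirna_id[second],
        separation = loci$mature_start[second] - loci$mature_end[first],
        arm_a = loci$arm[first], arm_b = loci$arm[second],
        precursor_span = max(loci$precursor_end[idx]) -
          min(loci$precursor_start[idx]) + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Genome distribution of miRNA precursors
#'
#' Counts precursor loci per fixed-size chromosome bin and flags bins
#' containing two or more loci (co-located family members).
#'
#' @param loci miRNA locus table.
#' @param bin_size Bin width in nt.
#' @return data.frame with `chrom`, `bin_start`, `bin_end`, `n_loci`,
#'   `mirna_ids`, `colocated`.
#' @export
genome_distribution <- function(loci, bin_size = 100000L) {
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  if (!nrow(loci)) {
    return(data.frame(chrom = character(), bin_start = integer(),
                      bin_end = integer(), n_loci = integer(),
                      mirna_ids = character(), colocated = logical(),
                      stringsAsFactors = FALSE))
  }
  bin <- (loci$precursor_start - 1L) %/% bin_size
  key <- paste(loci$chrom, bin)
  out <- do.call(rbind, lapply(unique(key), function(k) {
    idx <- which(key == k)
    data.frame(chrom = loci$chrom[idx[1]],
               bin_start = bin[idx[1]] * bin_size + 1L,
               bin_end = (bin[idx[1]] + 1L) * bin_size,
               n_loci = length(idx),
               mirna_ids = paste(sort(unique(loci$mirna_id[idx])),
                                 collapse = ","),
               colocated = length(idx) >= 2L,
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$bin_start), , drop = FALSE]
}
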