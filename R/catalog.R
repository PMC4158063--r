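#' Collapse and filter small-RNA libraries
#'
#' Builds the unique-sequence catalog underlying all downstream stages. Low
#' quality reads (containing `N` or with length outside `read_len_range`) are
#' removed, and a sequence is retained for a library only if its count in
#' that library reaches `min_read_count`. Sequences failing the threshold in
#' every library are dropped from the catalog.
#'
#' @param reads Named list (one element per library) of data.frames with
#'   columns `sequence` and `count`, e.g. from [read_collapsed_srna()] or
#'   [collapse_fastq()].
#' @param config An [pipeline_config()] object.
#' @return An object of class `srdk_catalog`: list with `sequences`
#'   (character), `counts` (integer matrix, sequences x libraries), `tpm`
#'   (filled by [tpm_normalize()]), `annotation`, `genome_hits`, `stats`
#'   (library accounting: raw, clean, unique, genome-matched) and
#'   `length_hist` (per-library unique-sequence length fractions).
#' @export
collapse_and_filter <- function(reads, config = pipeline_config()) {
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("reads must be a named list: one element per library", call. = FALSE)
  libs <- names(reads)
  rng <- config$read_len_range
  per_lib <- lapply(reads, function(df) {
    stopifnot(all(c("sequence", "count") %in% names(df)))
    df$sequence <- canonical_dna(df$sequence)
    df
  })
  total_raw <- vapply(per_lib, function(df) sum(df$count), 0)
  # Quality filter: N-containing or out-of-range lengths are low quality.
  per_lib <- lapply(per_lib, function(df) {
    len <- nchar(df$sequence)
    keep <- len >= rng[1] & len <= rng[2] & !grepl("N", df$sequence, fixed = TRUE)
    df <- df[keep, , drop = FALSE]
    agg <- rowsum(df$count, group = df$sequence, reorder = FALSE)
    data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
               stringsAsFactors = FALSE)
  })
  all_seqs <- unique(unlist(lapply(per_lib, `[[`, "sequence"), use.names = FALSE))
  counts <- matrix(0L, nrow = length(all_seqs), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (l in libs) {
    idx <- match(per_lib[[l]]$sequence, all_seqs)
    counts[idx, l] <- per_lib[[l]]$count
  }
  # Per-library abundance threshold.
  counts[counts < config$min_read_count] <- 0L
  keep <- rowSums(counts) > 0L
  log_stage("collapse_and_filter", length(all_seqs), sum(keep))
  all_seqs <- all_seqs[keep]
  counts <- counts[keep, , drop = FALSE]

  total_clean <- colSums(counts)
  unique_clean <- colSums(counts > 0L)
  stats <- data.frame(library = libs,
                      total_raw = as.numeric(total_raw),
                      total_clean = as.numeric(total_clean),
                      unique_clean = as.integer(unique_clean),
                      matched_genome_total = NA_real_,
                      matched_genome_unique = NA_integer_,
                      pct_matched_total = NA_real_,
                      pct_matched_unique = NA_real_,
                      stringsAsFactors = FALSE)
  lens <- nchar(all_seqs)
  length_hist <- do.call(rbind, lapply(libs, function(l) {
    present <- counts[, l] > 0L
    if (!sum(present)) {
      return(data.frame(library = l, length = integer(), fraction = numeric()))
    }
    tab <- table(lens[present])
    data.frame(library = l, length = as.integer(names(tab)),
               fraction = as.numeric(tab) / sum(present),
               stringsAsFactors = FALSE)
  }))
  structure(list(sequences = all_seqs, counts = counts, tpm = NULL,
                 annotation = rep("unannotated", length(all_seqs)),
                 genome_hits = NULL, stats = stats,
                 length_hist = length_hist),
            class = "srdk_catalog")
}

#' @export
print.srdk_catalog <- function(x, ...) {
  cat("srdk catalog:", length(x$sequences), "unique sequences,",
      ncol(x$counts), "libraries\n")
  print(x$stats)
  invisible(x)
}

# Group sequences by width and run fn(pdict, width_indices) for each group.
.by_width <- function(seqs, fn) {
  widths <- nchar(seqs)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    fn(pd, idx)
  }
  invisible(NULL)
}

#' Flag catalog sequences matching non-coding RNA references
#'
#' A sequence is flagged `ncRNA` iff it occurs as an exact substring of any
#' reference non-coding RNA, on either strand. Flagged sequences are excluded
#' from miRNA discovery but keep their counts in the library statistics.
#'
#' @param catalog An `srdk_catalog`.
#' @param ncrna Reference set: data.frame from [read_fasta()], named character
#'   vector, or `NULL`/empty for no flags.
#' @return The catalog with updated `annotation`.
#' @export
annotate_ncrna <- function(catalog, ncrna = NULL) {
  stopifnot(inherits(catalog, "srdk_catalog"))
  if (is.data.frame(ncrna)) ncrna <- setNames(ncrna$sequence, ncrna$id)
  if (is.null(ncrna) || !length(ncrna)) return(catalog)
  refs <- Biostrings::DNAStringSet(canonical_dna(ncrna))
  subjects <- c(refs, Biostrings::reverseComplement(refs))
  flagged <- logical(length(catalog$sequences))
  .by_width(catalog$sequences, function(pd, idx) {
    hits <- Biostrings::vcountPDict(pd, subjects)
    flagged[idx[rowSums(hits) > 0L]] <<- TRUE
  })
  catalog$annotation[flagged] <- "ncRNA"
  log_stage("annotate_ncrna", length(flagged), sum(!flagged))
  catalog
}

#' Map catalog sequences to a genome by exact match
#'
#' Records perfect-match hits on both strands and fills the genome-matched
#' columns of the library statistics (percentage of unique sequences and of
#' total clean reads with at least one genomic hit).
#'
#' @param catalog An `srdk_catalog`.
#' @param genome Genome: data.frame from [read_fasta()], named character
#'   vector, or `DNAStringSet`.
#' @return The catalog with `genome_hits` (data.frame `seq_index`, `sequence`,
#'   `chrom`, `start`, `end`, `strand`) and updated `stats`.
#' @export
map_to_genome <- function(catalog, genome) {
  stopifnot(inherits(catalog, "srdk_catalog"))
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(canonical_dna(genome))
  hits <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    fwd <- genome[[ci]]
    rev <- Biostrings::reverseComplement(fwd)
    L <- length(fwd)
    .by_width(catalog$sequences, function(pd, idx) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") fwd else rev
        m <- Biostrings::matchPDict(pd, subj)
        cnt <- S4Vectors::elementNROWS(m)
        for (k in which(cnt > 0L)) {
          ir <- m[[k]]
          s <- IRanges::start(ir); e <- IRanges::end(ir)
          if (strand == "-") {
            s2 <- L - e + 1L; e2 <- L - IRanges::start(ir) + 1L
            s <- s2; e <- e2
          }
          hits[[length(hits) + 1L]] <<- data.frame(
            seq_index = idx[k], sequence = catalog$sequences[idx[k]],
            chrom = chrom, start = s, end = e, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    })
  }
  gh <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq_index = integer(), sequence = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  gh <- gh[order(gh$seq_index, gh$chrom, gh$start), , drop = FALSE]
  rownames(gh) <- NULL
  catalog$genome_hits <- gh
  matched <- seq_along(catalog$sequences) %in% gh$seq_index
  st <- catalog$stats
  for (r in seq_len(nrow(st))) {
    l <- st$library[r]
    present <- catalog$counts[, l] > 0L
    st$matched_genome_unique[r] <- sum(present & matched)
    st$matched_genome_total[r] <- sum(catalog$counts[present & matched, l])
    st$pct_matched_unique[r] <-
      if (sum(present)) 100 * st$matched_genome_unique[r] / sum(present) else NA
    st$pct_matched_total[r] <-
      if (st$total_clean[r] > 0) 100 * st$matched_genome_total[r] / st$total_clean[r] else NA
  }
  catalog$stats <- st
  log_stage("map_to_genome", length(matched), sum(matched))
  catalog
}

#' TPM-normalize a catalog
#'
#' `tpm = count / total_clean x 10^6` per library ("tags per million" digital
#' expression).
#'
#' @param catalog An `srdk_catalog` (after [collapse_and_filter()]).
#' @return The catalog with its `tpm` matrix filled.
#' @export
tpm_normalize <- function(catalog) {
  stopifnot(inherits(catalog, "srdk_catalog"))
  totals <- catalog$stats$total_clean[match(colnames(catalog$counts),
                                            catalog$stats$library)]
  if (any(totals == 0))
    stop("undefined normalization: a library has zero clean reads",
         call. = FALSE)
  catalog$tpm <- sweep(catalog$counts, 2, totals, "/") * 1e6
  catalog
}

#' Per-sequence TPM of a catalog as a data.frame
#'
#' @param catalog A TPM-normalized `srdk_catalog`.
#' @return data.frame with `sequence` and one TPM column per library.
#' @export
catalog_tpm_table <- function(catalog) {
  stopifnot(!is.null(catalog$tpm))
  out <- data.frame(sequence = catalog$sequences, stringsAsFactors = FALSE)
  for (l in colnames(catalog$tpm)) out[[paste0("tpm_", l)]] <- catalog$tpm[, l]
  out
}

#' Compare expression between tissues
#'
#' For each sequence and tissue, the fold change is the tissue's TPM divided
#' by the maximum TPM among the other tissues (the denominator is floored at
#' a 0.5 TPM pseudocount to avoid division by zero). Classes: tissue-enriched
#' (fold change above `fold_change_threshold`), strongly enriched (above
#' `strong_fold_change`), tissue-absent (zero TPM in a tissue, positive
#' elsewhere; takes precedence over fold-change classes), and highly
#' expressed (maximum TPM above `high_tpm`).
#'
#' @param catalog A TPM-normalized `srdk_catalog`.
#' @param tissues Libraries to compare (default: all; at least two).
#' @param config An [pipeline_config()] object.
#' @return data.frame with per-tissue TPM and fold-change columns plus
#'   `enriched_in`, `strongly_enriched_in`, `absent_in`, `highly_expressed`
#'   and a single precedence-resolved `class` column.
#' @export
compare_tissues <- function(catalog, tissues = colnames(catalog$counts),
                            config = pipeline_config()) {
  stopifnot(inherits(catalog, "srdk_catalog"))
  if (is.null(catalog$tpm)) stop("run tpm_normalize() first", call. = FALSE)
  if (length(tissues) < 2L)
    stop("tissue comparison needs at least two tissues", call. = FALSE)
  if (!all(tissues %in% colnames(catalog$tpm)))
    stop("unknown tissue label", call. = FALSE)
  tpm <- catalog$tpm[, tissues, drop = FALSE]
  n <- nrow(tpm)
  fc <- matrix(NA_real_, n, length(tissues),
               dimnames = list(NULL, tissues))
  for (t in seq_along(tissues)) {
    others <- tpm[, -t, drop = FALSE]
    omax <- apply(others, 1, max)
    fc[, t] <- tpm[, t] / pmax(omax, 0.5)
  }
  enr <- apply(fc, 1, function(v) {
    i <- which(v > config$fold_change_threshold)
    if (length(i)) tissues[i[1]] else ""
  })
  strong <- apply(fc, 1, function(v) {
    i <- which(v > config$strong_fold_change)
    if (length(i)) tissues[i[1]] else ""
  })
  absent <- apply(tpm, 1, function(v) {
    if (all(v == 0)) return("")
    paste(tissues[v == 0], collapse = ",")
  })
  high <- apply(tpm, 1, max) > config$high_tpm
  cls <- ifelse(nzchar(absent), paste0("absent:", absent),
         ifelse(nzchar(strong), paste0("strongly_enriched:", strong),
         ifelse(nzchar(enr), paste0("enriched:", enr),
         ifelse(high, "highly_expressed", "none"))))
  out <- data.frame(sequence = catalog$sequences, stringsAsFactors = FALSE)
  for (t in tissues) out[[paste0("tpm_", t)]] <- tpm[, t]
  for (t in tissues) out[[paste0("fc_", t)]] <- fc[, t]
  out$enriched_in <- enr
  out$strongly_enriched_in <- strong
  out$absent_in <- absent
  out$highly_expressed <- high
  out$class <- cls
  out
}
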