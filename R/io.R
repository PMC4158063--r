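#' Coordinate conversions
#'
#' All coordinates persisted by this package (GFF3, BED columns after import,
#' TSV reports) are 1-based inclusive. These helpers convert between that
#' convention and 0-based half-open offsets for callers that need them.
#'
#' @param start,end Interval in 1-based inclusive coordinates.
#' @return `to_zero_based()` returns a list with `start` (0-based) and `end`
#'   (exclusive); `to_one_based()` is its inverse.
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = start - 1L, end = end)
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = start + 1L, end = end)
}

# Canonical internal alphabet is DNA: U -> T, uppercase.
canonical_dna <- function(x) chartr("uU", "tT", toupper(x))

# Display alphabet for RNA-facing outputs.
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Read a FASTA file
#'
#' Sequences are stored internally over the DNA alphabet: `U` is converted to
#' `T` and case is normalized, so RNA and DNA inputs compare equal. Record
#' order is preserved. Malformed headers or empty sequences raise an error
#' naming the offending line.
#'
#' @param path Path to a FASTA file (alphabet `A,C,G,T,U,N`, any case).
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  is_hdr <- startsWith(trimws(lines), ">")
  if (!is_hdr[nonblank[1]])
    stop("FASTA format error at line ", nonblank[1],
         ": expected a '>' header", call. = FALSE)
  hdr_idx <- which(is_hdr)
  bad_hdr <- hdr_idx[trimws(lines[hdr_idx]) == ">"]
  if (length(bad_hdr))
    stop("FASTA format error at line ", bad_hdr[1], ": empty header",
         call. = FALSE)
  bounds <- c(hdr_idx, length(lines) + 1L)
  ids <- character(length(hdr_idx))
  desc <- character(length(hdr_idx))
  seqs <- character(length(hdr_idx))
  for (r in seq_along(hdr_idx)) {
    h <- sub("^>", "", trimws(lines[hdr_idx[r]]))
    ids[r] <- sub("\\s.*$", "", h)
    desc[r] <- ifelse(grepl("\\s", h), sub("^\\S+\\s+", "", h), "")
    body <- lines[seq(hdr_idx[r] + 1L, bounds[r + 1L] - 1L, length.out =
                        max(0L, bounds[r + 1L] - hdr_idx[r] - 1L))]
    s <- paste(trimws(body), collapse = "")
    if (!nzchar(s))
      stop("FASTA format error at line ", hdr_idx[r],
           ": record '", ids[r], "' has an empty sequence", call. = FALSE)
    if (grepl("[^ACGTUNacgtun]", s))
      stop("FASTA format error at line ", hdr_idx[r] + 1L,
           ": illegal character in sequence of '", ids[r], "'", call. = FALSE)
    seqs[r] <- canonical_dna(s)
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or data.frame with `id` and `sequence`.
#' @param path Output path.
#' @param rna Write in the RNA display alphabet (`U` for `T`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$id)
  s <- if (rna) as_rna(seqs) else canonical_dna(seqs)
  set <- Biostrings::BStringSet(s)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

parse_count_header <- function(ids) {
  cnt <- rep(NA_integer_, length(ids))
  mx <- regexpr("_x(\\d+)$", ids)
  cnt[mx > 0L] <- as.integer(sub("^_x", "", regmatches(ids, mx)))
  mc <- regexpr("count=(\\d+)", ids)
  use <- mc > 0L & is.na(cnt)
  vals <- rep(NA_character_, length(ids))
  vals[mc > 0L] <- regmatches(ids, mc)
  cnt[use] <- as.integer(sub("count=", "", vals[use]))
  cnt
}

#' Read a collapsed small-RNA FASTA file
#'
#' Accepts the two common count dialects: a `_xN` suffix on the identifier
#' (`>r1_x5`) or a `count=N` token in the header. Duplicate sequences are
#' merged by summing their counts.
#'
#' @param path Path to a collapsed FASTA file.
#' @return A data.frame with columns `sequence` and `count` (count >= 1).
#' @export
read_collapsed_srna <- function(path) {
  rec <- read_fasta(path)
  if (!nrow(rec)) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  hdr <- trimws(paste(rec$id, rec$description))
  counts <- parse_count_header(hdr)
  if (anyNA(counts)) {
    bad <- rec$id[which(is.na(counts))[1]]
    stop("collapsed FASTA format error: header of '", bad,
         "' carries no parsable count (expected '_xN' or 'count=N')",
         call. = FALSE)
  }
  agg <- rowsum(counts, group = rec$sequence, reorder = FALSE)
  data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
             stringsAsFactors = FALSE)
}

#' Write a collapsed small-RNA FASTA file
#'
#' Emits the `_xN` count dialect (`>t1_x12`).
#'
#' @param reads data.frame with `sequence` and `count`.
#' @param path Output path.
#' @param prefix Identifier prefix.
#' @return `path`, invisibly.
#' @export
write_collapsed_srna <- function(reads, path, prefix = "t") {
  stopifnot(all(c("sequence", "count") %in% names(reads)))
  ids <- sprintf("%s%d_x%d", prefix, seq_len(nrow(reads)),
                 as.integer(reads$count))
  write_fasta(setNames(reads$sequence, ids), path)
  invisible(path)
}

#' Collapse a FASTQ file to unique read counts
#'
#' Convenience entry point for libraries delivered as raw FASTQ; an optional
#' 3' adaptor prefix is clipped before collapsing.
#'
#' @param path FASTQ path.
#' @param adaptor Optional 3' adaptor: the read is truncated at its first
#'   occurrence.
#' @return A data.frame with `sequence` and `count`.
#' @export
collapse_fastq <- function(path, adaptor = NULL) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- canonical_dna(as.character(set))
  if (!is.null(adaptor) && nzchar(adaptor)) {
    pos <- regexpr(canonical_dna(adaptor), seqs, fixed = TRUE)
    clip <- pos > 0
    seqs[clip] <- substr(seqs[clip], 1L, pos[clip] - 1L)
  }
  seqs <- seqs[nzchar(seqs)]
  tab <- table(seqs)
  data.frame(sequence = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

empty_loci <- function() {
  data.frame(mirna_id = character(), locus_id = character(),
             status = character(), arm = character(),
             mature_seq = character(), star_seq = character(),
             chrom = character(), strand = character(),
             precursor_start = integer(), precursor_end = integer(),
             mature_start = integer(), mature_end = integer(),
             precursor_seq = character(), dot_bracket = character(),
             stringsAsFactors = FALSE)
}

#' Write miRNA loci to GFF3
#'
#' Each locus becomes a `miRNA_primary_transcript` feature (the precursor) and
#' a child `miRNA` feature (the mature). Coordinates are 1-based inclusive.
#'
#' @param loci miRNA locus table, as returned by [match_known()] or
#'   [predict_novel()].
#' @param path Output path.
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   validate intervals.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path, seqlengths = NULL) {
  if (nrow(loci)) {
    if (any(loci$precursor_start < 1) ||
        any(loci$precursor_start > loci$precursor_end))
      stop("invalid precursor interval", call. = FALSE)
    if (!is.null(seqlengths)) {
      lim <- seqlengths[loci$chrom]
      if (any(is.na(lim)) || any(loci$precursor_end > lim))
        stop("locus interval outside its sequence length", call. = FALSE)
    }
  }
  if (!nrow(loci)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  pre <- GenomicRanges::GRanges(
    loci$chrom,
    IRanges::IRanges(loci$precursor_start, loci$precursor_end),
    strand = loci$strand)
  S4Vectors::mcols(pre)$type <- "miRNA_primary_transcript"
  S4Vectors::mcols(pre)$ID <- loci$locus_id
  S4Vectors::mcols(pre)$Name <- loci$mirna_id
  mat <- GenomicRanges::GRanges(
    loci$chrom,
    IRanges::IRanges(loci$mature_start, loci$mature_end),
    strand = loci$strand)
  S4Vectors::mcols(mat)$type <- "miRNA"
  S4Vectors::mcols(mat)$ID <- paste0(loci$locus_id, "_mature")
  S4Vectors::mcols(mat)$Name <- loci$mirna_id
  S4Vectors::mcols(mat)$Parent <- loci$locus_id
  gr <- c(pre, mat)
  S4Vectors::mcols(gr)$source <- "srdk"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read miRNA loci from GFF3
#'
#' Inverse of [write_gff3()]: restores the interval columns of the locus
#' table (sequence-level columns are not stored in GFF3).
#'
#' @param path GFF3 path.
#' @return data.frame with `locus_id`, `mirna_id`, `chrom`, `strand`,
#'   `precursor_start`, `precursor_end`, `mature_start`, `mature_end`.
#' @export
read_gff3_loci <- function(path) {
  gr <- try(rtracklayer::import(path, format = "gff3"), silent = TRUE)
  if (inherits(gr, "try-error") || !length(gr)) {
    return(data.frame(locus_id = character(), mirna_id = character(),
                      chrom = character(), strand = character(),
                      precursor_start = integer(), precursor_end = integer(),
                      mature_start = integer(), mature_end = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- as.data.frame(gr)
  pre <- df[df$type == "miRNA_primary_transcript", ]
  mat <- df[df$type == "miRNA", ]
  mat_parent <- vapply(mat$Parent, function(p) as.character(p)[1], "")
  idx <- match(pre$ID, mat_parent)
  data.frame(locus_id = pre$ID, mirna_id = pre$Name,
             chrom = as.character(pre$seqnames),
             strand = as.character(pre$strand),
             precursor_start = pre$start, precursor_end = pre$end,
             mature_start = mat$start[idx], mature_end = mat$end[idx],
             stringsAsFactors = FALSE)
}

#' Write SSR loci to BED6
#'
#' @param ssrs SSR table (see [detect_ssrs()]) with genomic columns `chrom`,
#'   `start`, `end`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ssrs, path) {
  if (!nrow(ssrs)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(ssrs$chrom,
                               IRanges::IRanges(ssrs$start, ssrs$end),
                               strand = ssrs$strand)
  S4Vectors::mcols(gr)$name <- sprintf("(%s)%d", ssrs$unit, ssrs$repeat_number)
  S4Vectors::mcols(gr)$score <- ssrs$repeat_number
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read SSR loci back from BED6
#'
#' @param path BED path written by [write_bed()].
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `unit`,
#'   `repeat_number`.
#' @export
read_bed_ssrs <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      unit = character(), repeat_number = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             unit = sub("^\\((.*)\\)\\d+$", "\\1", nm),
             repeat_number = as.integer(sub("^\\(.*\\)", "", nm)),
             stringsAsFactors = FALSE)
}

#' Write / read a tab-separated report table
#'
#' All report tables carry a fixed header line and are round-trip stable.
#'
#' @param df data.frame to persist.
#' @param path File path.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` returns a
#'   data.frame.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# Reverse complement over the canonical DNA alphabet (plain strings).
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

# Stage logging: input vs surviving record counts, mirroring library
# accounting tables.
log_stage <- function(stage, n_in, n_out, verbose = getOption("srdk.verbose", FALSE)) {
  if (isTRUE(verbose))
    message(sprintf("[srdk] %-20s in=%d out=%d", stage, n_in, n_out))
  invisible(NULL)
}
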