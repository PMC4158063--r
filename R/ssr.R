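## Simple sequence repeat (SSR) detection, co-localization with miRNA
## precursors, and repeat-unit composition summaries.
##
## Reporting rules (shared with the brute-force oracle used in tests):
##   * a run is a maximal tandem repeat of a 1-6 nt unit: it cannot be
##     extended by one full unit on either side;
##   * the unit must be primitive (not itself a repetition of a shorter
##     unit), so a (CTCT)n run is reported as (CT)2n, never as CTCT;
##   * a run strictly contained within another detected run is suppressed
##     (rotated-phase sub-runs of a longer tract);
##   * a run is reported iff its repeat number reaches the per-unit-length
##     threshold. Units are reported on the given strand, uncanonicalized.

ssr_class_names <- c(`1` = "mono", `2` = "di", `3` = "tri",
                     `4` = "tetra", `5` = "penta", `6` = "hexa")

#' Unit-length class of a repeat unit
#'
#' @param unit Repeat unit string(s), 1-6 nt.
#' @return Character vector in `mono`, `di`, `tri`, `tetra`, `penta`, `hexa`.
#' @export
ssr_unit_class <- function(unit) {
  unname(ssr_class_names[as.character(nchar(unit))])
}

# TRUE iff the unit is primitive (its minimal period equals its length).
is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (unit == strrep(substr(unit, 1L, d), k / d)) return(FALSE)
  }
  TRUE
}

#' Detect simple sequence repeats in one sequence
#'
#' Reports all maximal tandem repeats of primitive 1-6 nt units meeting the
#' per-unit-length repeat thresholds, suppressing runs strictly contained in
#' another run. Coordinates are 1-based inclusive on the given strand.
#'
#' @param sequence A single sequence (DNA or RNA alphabet).
#' @param min_repeats Named integer vector mapping unit length (`"1"`..`"6"`)
#'   to the minimum repeat number (see [pipeline_config()]).
#' @return data.frame with `start`, `end`, `unit`, `unit_len`,
#'   `repeat_number`, `length`, `class`.
#' @export
detect_ssrs <- function(sequence,
                        min_repeats = pipeline_config()$ssr_min_repeats) {
  seq <- canonical_dna(sequence)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(), unit = character(),
                      unit_len = integer(), repeat_number = integer(),
                      length = integer(), class = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ch <- strsplit(seq, "")[[1]]
  cand <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    eq <- ch[seq_len(n - k)] == ch[(k + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= k)) {
      p <- starts[j]
      L <- r$lengths[j] + k           # length of the period-k region
      for (c in p:(p + k - 1L)) {
        reps <- (L - (c - p)) %/% k
        if (reps < 2L) next
        unit <- substr(seq, c, c + k - 1L)
        if (!is_primitive_unit(unit)) next
        cand[[length(cand) + 1L]] <- c(start = c, end = c + k * reps - 1L,
                                       k = k, reps = reps)
      }
    }
  }
  if (!length(cand)) return(empty)
  m <- do.call(rbind, cand)
  # suppress runs strictly contained in another candidate run
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    inside <- m[, "start"] <= m[i, "start"] & m[, "end"] >= m[i, "end"] &
      (m[, "end"] - m[, "start"] > m[i, "end"] - m[i, "start"])
    if (any(inside)) keep[i] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  thr <- min_repeats[as.character(m[, "k"])]
  m <- m[m[, "reps"] >= thr, , drop = FALSE]
  if (!nrow(m)) return(empty)
  out <- data.frame(start = as.integer(m[, "start"]),
                    end = as.integer(m[, "end"]),
                    unit = substring(seq, m[, "start"],
                                     m[, "start"] + m[, "k"] - 1L),
                    unit_len = as.integer(m[, "k"]),
                    repeat_number = as.integer(m[, "reps"]),
                    length = as.integer(m[, "end"] - m[, "start"] + 1L),
                    stringsAsFactors = FALSE)
  out$class <- ssr_unit_class(out$unit)
  out <- out[order(out$start, out$unit_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect SSRs across a genome, both strands
#'
#' @param genome data.frame from [read_fasta()], named character vector, or
#'   `DNAStringSet`.
#' @param min_repeats See [detect_ssrs()].
#' @return data.frame as [detect_ssrs()] plus `chrom` and `strand`; minus
#'   strand units are reported in minus-strand orientation with coordinates
#'   on the plus strand.
#' @export
detect_ssrs_genome <- function(genome,
                               min_repeats = pipeline_config()$ssr_min_repeats) {
  if (is.data.frame(genome)) genome <- setNames(genome$sequence, genome$id)
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  rows <- list()
  for (chrom in names(genome)) {
    fwd <- canonical_dna(genome[[chrom]])
    n <- nchar(fwd)
    plus <- detect_ssrs(fwd, min_repeats)
    if (nrow(plus)) {
      plus$chrom <- chrom; plus$strand <- "+"
      rows[[length(rows) + 1L]] <- plus
    }
    minus <- detect_ssrs(revcomp(fwd), min_repeats)
    if (nrow(minus)) {
      s <- n - minus$end + 1L; e <- n - minus$start + 1L
      minus$start <- s; minus$end <- e
      minus$chrom <- chrom; minus$strand <- "-"
      rows[[length(rows) + 1L]] <- minus
    }
  }
  if (!length(rows)) {
    out <- detect_ssrs("A", min_repeats)
    out$chrom <- character(); out$strand <- character()
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-localize SSRs with pre-miRNA loci
#'
#' An SSR occurrence is co-localized iff its interval overlaps a precursor
#' interval by at least 1 nt on the same strand.
#'
#' @param ssrs Genomic SSR table from [detect_ssrs_genome()].
#' @param loci miRNA locus table.
#' @return list with `occurrences` (SSR rows plus `locus_id`, `mirna_id`; one
#'   row per SSR x precursor overlap) and `precursors` (distinct precursors
#'   hit).
#' @export
colocalize_ssrs <- function(ssrs, loci) {
  empty_occ <- cbind(ssrs[0, , drop = FALSE],
                     data.frame(locus_id = character(),
                                mirna_id = character(),
                                stringsAsFactors = FALSE))
  if (!nrow(ssrs) || !nrow(loci)) {
    return(list(occurrences = empty_occ,
                precursors = loci[0, c("locus_id", "mirna_id"), drop = FALSE]))
  }
  gs <- GenomicRanges::GRanges(ssrs$chrom,
                               IRanges::IRanges(ssrs$start, ssrs$end),
                               strand = ssrs$strand)
  gl <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$precursor_start,
                                                loci$precursor_end),
                               strand = loci$strand)
  ov <- GenomicRanges::findOverlaps(gs, gl, minoverlap = 1L,
                                    ignore.strand = FALSE)
  if (!length(ov)) {
    return(list(occurrences = empty_occ,
                precursors = loci[0, c("locus_id", "mirna_id"), drop = FALSE]))
  }
  occ <- ssrs[S4Vectors::queryHits(ov), , drop = FALSE]
  occ$locus_id <- loci$locus_id[S4Vectors::subjectHits(ov)]
  occ$mirna_id <- loci$mirna_id[S4Vectors::subjectHits(ov)]
  rownames(occ) <- NULL
  pre <- unique(loci[unique(S4Vectors::subjectHits(ov)),
                     c("locus_id", "mirna_id"), drop = FALSE])
  rownames(pre) <- NULL
  list(occurrences = occ, precursors = pre)
}

#' Summarize SSR repeat units
#'
#' Builds the per-unit frequency table and composition statistics either from
#' a co-localized occurrence list or from a pre-tabulated `(unit, class,
#' count)` table (summary-only mode for published censuses).
#'
#' @param x data.frame: either SSR occurrences (with a `unit` column) or a
#'   tabulated census with `unit`, `class`, `count`.
#' @return list of class `srdk_ssr_summary`: `units` (unit, class, count,
#'   RNA-display unit), `classes` (per-class totals and percentages), `total`,
#'   `modal_unit`, `modal_unit_rna`, `modal_count`. Empty input yields
#'   `total = 0` and an `undefined` flag.
#' @export
summarize_ssr_units <- function(x) {
  if (!nrow(x)) {
    return(structure(list(units = data.frame(), classes = data.frame(),
                          total = 0L, modal_unit = NA_character_,
                          modal_unit_rna = NA_character_,
                          modal_count = NA_integer_, undefined = TRUE),
                     class = "srdk_ssr_summary"))
  }
  if ("count" %in% names(x)) {
    units <- data.frame(unit = canonical_dna(x$unit),
                        count = as.integer(x$count),
                        stringsAsFactors = FALSE)
    units <- aggregate(count ~ unit, data = units, FUN = sum)
  } else {
    tab <- table(canonical_dna(x$unit))
    units <- data.frame(unit = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  }
  units$class <- ssr_unit_class(units$unit)
  units$unit_rna <- as_rna(units$unit)
  units <- units[order(nchar(units$unit), units$unit), , drop = FALSE]
  rownames(units) <- NULL
  total <- sum(units$count)
  cls <- aggregate(count ~ class, data = units, FUN = sum)
  cls$pct <- round(100 * cls$count / total, 1)
  cls <- cls[order(match(cls$class, ssr_class_names)), , drop = FALSE]
  rownames(cls) <- NULL
  best <- which.max(units$count)
  structure(list(units = units[, c("unit", "unit_rna", "class", "count")],
                 classes = cls, total = total,
                 modal_unit = units$unit[best],
                 modal_unit_rna = units$unit_rna[best],
                 modal_count = units$count[best], undefined = FALSE),
            class = "srdk_ssr_summary")
}

#' @export
print.srdk_ssr_summary <- function(x, ...) {
  cat("SSR unit summary:", x$total, "occurrences\n")
  if (!x$undefined) {
    print(x$classes)
    cat("modal unit:", x$modal_unit, "(", x$modal_unit_rna, "), count",
        x$modal_count, "\n")
  }
  invisible(x)
}

#' Composition percentage of a subset of unit-length classes
#'
#' @param summary An `srdk_ssr_summary`.
#' @param classes Class names to pool (e.g. `c("di", "tri")`).
#' @return Percentage of all occurrences in the pooled classes, rounded to
#'   one decimal.
#' @export
ssr_composition_pct <- function(summary, classes = c("di", "tri")) {
  stopifnot(inherits(summary, "srdk_ssr_summary"))
  if (summary$undefined) return(NA_real_)
  sub <- sum(summary$classes$count[summary$classes$class %in% classes])
  round(100 * sub / summary$total, 1)
}

#' Read a tabulated SSR unit census
#'
#' A three-column TSV (`unit`, `class`, `count`) such as the census of SSRs
#' co-localized with sweet-orange pre-miRNAs shipped in
#' `inst/extdata/ssr_unit_counts_sweet_orange.tsv`.
#'
#' @param path TSV path.
#' @return data.frame with `unit`, `class`, `count`.
#' @export
read_ssr_unit_counts <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("unit", "class", "count") %in% names(df)))
  df
}
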