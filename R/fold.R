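#' Fold an RNA/DNA sequence by base-pair maximization
#'
#' Predicts a nested secondary structure maximizing the number of base pairs
#' (Watson-Crick plus G:U wobble) with a minimum hairpin loop of `min_loop`
#' unpaired nucleotides. The dynamic program is exact for this objective and
#' the traceback is deterministic: within any interval the leftmost base is
#' paired to the smallest admissible partner achieving the optimum. This
#' folder is dependency-free and sufficient to verify stem-loop precursor
#' criteria; `folder` accepts a plug-in returning a dot-bracket string (for
#' example a wrapper around a thermodynamic folder) for users who want
#' minimum-free-energy structures instead.
#'
#' @param sequence A single sequence over `A,C,G,T,U,N` (either case). `N`
#'   never pairs.
#' @param min_loop Minimum unpaired nucleotides in a hairpin loop.
#' @param folder Optional function `function(sequence)` returning a
#'   dot-bracket string of the same length; when supplied it replaces the
#'   internal folder.
#' @return An object of class `srdk_structure`: a list with `sequence`
#'   (canonical DNA alphabet), `dot_bracket`, `pair_count`, `partner`
#'   (integer vector, `NA` where unpaired) and `loops` (data.frame of hairpin
#'   loop intervals).
#' @export
fold_rna <- function(sequence, min_loop = 3L, folder = NULL) {
  stopifnot(length(sequence) == 1L)
  seq <- canonical_dna(sequence)
  if (grepl("[^ACGTN]", seq))
    stop("illegal character in sequence", call. = FALSE)
  if (nchar(seq) > 600L)
    stop("sequence longer than 600 nt; fold windows, not chromosomes",
         call. = FALSE)
  db <- if (is.null(folder)) {
    .nussinov_cpp(seq, as.integer(min_loop))
  } else {
    folder(sequence)
  }
  if (nchar(db) != nchar(seq))
    stop("dot-bracket length does not match sequence", call. = FALSE)
  partner <- dot_bracket_partners(db)
  structure(
    list(sequence = seq, dot_bracket = db,
         pair_count = sum(!is.na(partner)) %/% 2L,
         partner = partner, loops = hairpin_loops(partner)),
    class = "srdk_structure")
}

#' @export
print.srdk_structure <- function(x, ...) {
  cat(as_rna(x$sequence), "\n", x$dot_bracket, "  (", x$pair_count,
      " pairs)\n", sep = "")
  invisible(x)
}

#' Write a structure in Vienna dot-bracket text format
#'
#' Two lines per record: RNA sequence and dot-bracket string.
#'
#' @param struct An `srdk_structure`.
#' @param path Output path (or connection).
#' @param id Record identifier.
#' @return `path`, invisibly.
#' @export
write_dot_bracket <- function(struct, path, id = "seq") {
  writeLines(c(paste0(">", id), as_rna(struct$sequence), struct$dot_bracket),
             path)
  invisible(path)
}

# Partner table from a dot-bracket string; errors on unbalanced brackets.
dot_bracket_partners <- function(db) {
  chars <- strsplit(db, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (chars[i] != ".") {
      stop("illegal dot-bracket character '", chars[i], "'", call. = FALSE)
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  partner
}

# Hairpin loops: pairs (i, j) with no paired position strictly inside.
hairpin_loops <- function(partner) {
  res <- data.frame(start = integer(), end = integer(), size = integer())
  opens <- which(!is.na(partner) & partner > seq_along(partner))
  for (i in opens) {
    j <- partner[i]
    if (j - i > 1L && all(is.na(partner[(i + 1L):(j - 1L)]))) {
      res <- rbind(res, data.frame(start = i, end = j, size = j - i - 1L))
    }
  }
  res
}

#' Hairpin metrics for a mature miRNA within a folded precursor
#'
#' Computes the structural quantities that the miRNA annotation criteria are
#' stated in: the fraction of mature positions that are base paired, the
#' number of unpaired (mismatched) mature positions in the miRNA/miRNA*
#' duplex, the largest asymmetric bulge within the duplex, the miRNA* (star)
#' interval implied by the canonical 2-nt 3' overhang duplex geometry, the
#' terminal loop size of the stem carrying the mature, and the arm (5p/3p).
#'
#' @param struct An `srdk_structure` for the candidate precursor.
#' @param mature_interval Integer vector `c(start, end)`, 1-based inclusive
#'   positions of the mature within the precursor.
#' @return A list of class `srdk_hairpin_metrics` with fields
#'   `mature_paired_fraction`, `duplex_mismatches`, `max_asym_bulge`,
#'   `star_interval`, `star_seq`, `loop_size`, `loop_interval`, `arm`,
#'   `precursor_length`.
#' @export
hairpin_metrics <- function(struct, mature_interval) {
  stopifnot(inherits(struct, "srdk_structure"), length(mature_interval) == 2L)
  n <- nchar(struct$sequence)
  m1 <- as.integer(mature_interval[1]); m2 <- as.integer(mature_interval[2])
  if (m1 < 1L || m2 > n || m1 > m2)
    stop("mature interval outside the precursor", call. = FALSE)
  partner <- struct$partner
  mpos <- m1:m2
  paired <- !is.na(partner[mpos])
  loops <- struct$loops
  if (!any(paired)) {
    in_loop <- nrow(loops) > 0 && any(loops$start < m1 & loops$end > m2)
    if (in_loop)
      stop("not a hairpin: mature maps into the terminal loop", call. = FALSE)
    stop("not a hairpin: mature maps to an unpaired region", call. = FALSE)
  }

  # Inferred partner of any mature position, extrapolated antiparallel from
  # the nearest paired mature position.
  infer_partner <- function(p) {
    q <- mpos[paired][which.min(abs(mpos[paired] - p))]
    partner[q] + (q - p)
  }
  s_a <- infer_partner(m2 - 2L)
  s_b <- infer_partner(m1) + 2L
  star <- sort(c(s_a, s_b))
  star <- pmin(pmax(star, 1L), n)
  if (star[1] <= m2 && star[2] >= m1)
    stop("not a hairpin: star interval overlaps the mature", call. = FALSE)

  pp <- mpos[paired]
  mism <- sum(!paired)
  asym <- 0L
  if (length(pp) > 1L) {
    for (t in seq_len(length(pp) - 1L)) {
      gm <- pp[t + 1L] - pp[t] - 1L
      gs <- abs(partner[pp[t]] - partner[pp[t + 1L]]) - 1L
      asym <- max(asym, abs(gm - gs))
    }
  }

  # Terminal loop of the stem carrying the mature: the hairpin loop nested
  # inside the innermost mature pair.
  qin <- pp[which.min(abs(partner[pp] - pp))]
  lo <- min(qin, partner[qin]); hi <- max(qin, partner[qin])
  cand <- loops[loops$start >= lo & loops$end <= hi, , drop = FALSE]
  if (nrow(cand)) {
    cand <- cand[which.max(cand$size), ]
    loop_interval <- c(cand$start + 1L, cand$end - 1L)
    loop_size <- cand$size
  } else {
    loop_interval <- c(NA_integer_, NA_integer_)
    loop_size <- NA_integer_
  }
  arm <- if (!is.na(loop_interval[1]) && m2 < loop_interval[1]) "5p"
         else if (!is.na(loop_interval[2]) && m1 > loop_interval[2]) "3p"
         else if (median(partner[pp]) > m2) "5p" else "3p"

  structure(list(
    mature_paired_fraction = mean(paired),
    duplex_mismatches = as.integer(mism),
    max_asym_bulge = as.integer(asym),
    star_interval = as.integer(star),
    star_seq = substr(struct$sequence, star[1], star[2]),
    loop_size = loop_size,
    loop_interval = loop_interval,
    arm = arm,
    precursor_length = n
  ), class = "srdk_hairpin_metrics")
}

#' @importFrom stats median
NULL

#' Thermodynamic folding through an external RNAfold binary
#'
#' A plug-in for [fold_rna()]'s `folder` argument that shells out to the
#' ViennaRNA `RNAfold` program for minimum-free-energy structures. The
#' internal base-pair-maximization folder is sufficient for the stem-loop
#' annotation criteria, but MFE structures are needed for fine loop geometry
#' (for example, how a (CUU)n tract in the loop widens it as n grows).
#'
#' @param binary Name or path of the RNAfold executable.
#' @return A function `function(sequence) -> dot-bracket string`, suitable for
#'   `fold_rna(seq, folder = fold_vienna())`.
#' @export
fold_vienna <- function(binary = "RNAfold") {
  if (Sys.which(binary) == "")
    stop("RNAfold binary not found on PATH", call. = FALSE)
  function(sequence) {
    out <- system2(binary, c("--noPS"), input = as_rna(canonical_dna(sequence)),
                   stdout = TRUE)
    db <- sub("\\s.*$", "", out[2])
    if (is.na(db) || nchar(db) != nchar(sequence))
      stop("RNAfold returned no structure", call. = FALSE)
    db
  }
}
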