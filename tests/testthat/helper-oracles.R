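# Independent oracles, implemented without reference to the package internals.

# Exhaustive maximum base-pair count over all nested structures (min hairpin
# loop 3, G:U allowed). Plain recursion, no memoization; for sequences <= 14.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(toupper(chartr("u", "T", chartr("U", "T", seq))), "")[[1]]
  can <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && (b == "A" || b == "G")) ||
      (a == "G" && (b == "C" || b == "T")) || (a == "C" && b == "G")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can(ch[i], ch[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + if (k < j) rec(k + 1L, j) else 0L
        if (v > best) best <- v
      }
    }
    best
  }
  n <- length(ch)
  if (n < min_loop + 2L) return(0L)
  rec(1L, n)
}

# Brute-force maximal tandem repeat scan over every (position, unit length)
# pair, with the same reporting rules the detector documents: primitive
# units, full-unit maximality both sides, strict-containment suppression,
# per-unit-length thresholds.
oracle_ssrs <- function(seq, min_repeats) {
  s <- toupper(chartr("U", "T", seq))
  n <- nchar(s)
  sub <- function(a, b) substr(s, a, b)
  cand <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    for (i in seq_len(n - 2L * k + 1L)) {
      unit <- sub(i, i + k - 1L)
      prim <- TRUE
      if (k > 1L) {
        for (d in seq_len(k - 1L)) {
          if (k %% d == 0L &&
              unit == strrep(substr(unit, 1L, d), k / d)) prim <- FALSE
        }
      }
      if (!prim) next
      r <- 1L
      while (i + k * (r + 1L) - 1L <= n &&
             sub(i + k * r, i + k * (r + 1L) - 1L) == unit) r <- r + 1L
      if (r < 2L) next
      if (i - k >= 1L && sub(i - k, i - 1L) == unit) next       # left-extendable
      if (i + k * (r + 1L) - 1L <= n &&
          sub(i + k * r, i + k * (r + 1L) - 1L) == unit) next   # (defensive)
      cand[[length(cand) + 1L]] <- c(start = i, end = i + k * r - 1L,
                                     k = k, reps = r)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      repeat_number = integer(), stringsAsFactors = FALSE))
  }
  m <- unique(do.call(rbind, cand))
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (any(m[, "start"] <= m[i, "start"] & m[, "end"] >= m[i, "end"] &
            (m[, "end"] - m[, "start"]) > (m[i, "end"] - m[i, "start"])))
      keep[i] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  m <- m[m[, "reps"] >= min_repeats[as.character(m[, "k"])], , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      repeat_number = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(start = as.integer(m[, "start"]),
                    end = as.integer(m[, "end"]),
                    unit = substring(s, m[, "start"],
                                     m[, "start"] + m[, "k"] - 1L),
                    repeat_number = as.integer(m[, "reps"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, nchar(out$unit)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Independent per-position recomputation of the target-alignment penalty.
oracle_penalty <- function(mirna, site) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(mirna, "")[[1]]
  t <- rev(strsplit(site, "")[[1]])  # opposite base for miRNA position i
  total <- 0
  for (i in seq_along(m)) {
    p <- if (comp[[m[i]]] == t[i]) 0
         else if ((m[i] == "G" && t[i] == "T") ||
                  (m[i] == "T" && t[i] == "G")) 0.5
         else 1
    if (i >= 2 && i <= 13) p <- 2 * p
    total <- total + p
  }
  total
}

# Naive genome mapper: exact substring scan on both strands.
oracle_map <- function(read, genome) {
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  }
  hits <- 0L
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    for (q in c(read, rc(read))) {
      p <- gregexpr(q, g, fixed = TRUE)[[1]]
      hits <- hits + sum(p > 0)
    }
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
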