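## Phased secondary siRNA (phasiRNA) prediction: 22-nt trigger selection,
## 21-nt register enumeration downstream of validated cleavage sites,
## quantification from the sRNA catalog, naming, and target calling.

#' Select phasing-trigger miRNAs
#'
#' Triggers are miRNAs of exactly `trigger_length` (22 nt), optionally with a
#' 5' uridine, that have at least one degradome-validated target call.
#'
#' @param mirnas miRNA table with `mirna_id` and `mature_seq` (e.g. a locus
#'   table from [match_known()] / [predict_novel()]).
#' @param calls Target calls from [call_targets()].
#' @param config An [pipeline_config()] object.
#' @return data.frame with `mirna_id` and `mature_seq`, one row per trigger.
#' @export
select_triggers <- function(mirnas, calls, config = pipeline_config()) {
  uniq <- unique(mirnas[, c("mirna_id", "mature_seq")])
  keep <- nchar(uniq$mature_seq) == config$trigger_length
  if (config$require_trigger_5pU)
    keep <- keep & startsWith(canonical_dna(uniq$mature_seq), "T")
  keep <- keep & uniq$mirna_id %in% calls$mirna_id
  out <- uniq[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate 21-nt phased registers downstream of a cleavage site
#'
#' Register k spans transcript positions `c + phase_length*(k-1)` to
#' `c + phase_length*k - 1` (0-based offsets from the cleavage site `c`, the
#' first nucleotide of the 3' cleavage fragment). Only complete windows are
#' emitted, in order k = 1, 2, ...
#'
#' @param transcript_seq Transcript sequence.
#' @param cleavage_site 1-based position of the first nucleotide of the 3'
#'   cleavage fragment.
#' @param config An [pipeline_config()] object (supplies `phase_length`).
#' @param trigger_id,transcript_id Optional identifiers stamped onto the
#'   result for downstream naming.
#' @return data.frame with `k`, `start`, `end` (1-based inclusive) and
#'   `sequence`; zero rows when no complete window fits.
#' @export
enumerate_phases <- function(transcript_seq, cleavage_site,
                             config = pipeline_config(),
                             trigger_id = NA_character_,
                             transcript_id = NA_character_) {
  seq <- canonical_dna(transcript_seq)
  n <- nchar(seq)
  pl <- config$phase_length
  if (cleavage_site < 1L || cleavage_site > n)
    stop("cleavage site outside the transcript", call. = FALSE)
  if (cleavage_site + pl - 1L > n) {
    return(data.frame(trigger_id = character(), transcript_id = character(),
                      k = integer(), start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  starts <- seq.int(cleavage_site, n - pl + 1L, by = pl)
  data.frame(trigger_id = trigger_id, transcript_id = transcript_id,
             k = seq_along(starts), start = starts, end = starts + pl - 1L,
             sequence = substring(seq, starts, starts + pl - 1L),
             stringsAsFactors = FALSE)
}

#' Name a phased siRNA / parse a phased siRNA name
#'
#' The convention is `trigger-transcript-k`: for example the name of the
#' ninth register triggered by `csi-miR3954a` on `Cs1g09635.1` is
#' `csi-miR3954a-Cs1g09635.1-9`. Trigger identifiers may themselves contain
#' dashes; transcript identifiers must not.
#'
#' @param trigger_id,transcript_id,k Name components.
#' @return `phasi_name()` returns the composite name; `parse_phasi_name()`
#'   returns a list with `trigger_id`, `transcript_id`, `k`.
#' @export
phasi_name <- function(trigger_id, transcript_id, k) {
  if (any(grepl("-", transcript_id, fixed = TRUE)))
    stop("transcript identifiers must not contain '-'", call. = FALSE)
  paste(trigger_id, transcript_id, k, sep = "-")
}

#' @rdname phasi_name
#' @param name A composite phasiRNA name.
#' @export
parse_phasi_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) < 3L) stop("not a phasiRNA name: ", name, call. = FALSE)
  list(trigger_id = paste(parts[seq_len(length(parts) - 2L)], collapse = "-"),
       transcript_id = parts[length(parts) - 1L],
       k = as.integer(parts[length(parts)]))
}

#' Quantify phased registers from the sRNA catalog
#'
#' A register is read-supported iff a catalog sequence exactly equals the
#' window sequence (sense strand). Supported registers are named and carry
#' per-library TPM; unsupported registers are retained in the diagnostics
#' table only.
#'
#' @param phases data.frame from [enumerate_phases()] (with `trigger_id` and
#'   `transcript_id` stamped).
#' @param catalog A TPM-normalized `srdk_catalog`.
#' @return list with `reported` (supported registers: `name`, coordinates,
#'   `sequence`, per-library TPM) and `diagnostics` (all registers with a
#'   `supported` flag).
#' @export
quantify_phases <- function(phases, catalog) {
  stopifnot(inherits(catalog, "srdk_catalog"))
  if (is.null(catalog$tpm)) stop("run tpm_normalize() first", call. = FALSE)
  diag <- phases
  if (!nrow(phases)) {
    diag$supported <- logical(0)
    diag$name <- character(0)
    rep <- diag
    for (l in colnames(catalog$tpm)) {
      rep[[paste0("count_", l)]] <- integer(0)
      rep[[paste0("tpm_", l)]] <- numeric(0)
    }
    return(list(reported = rep, diagnostics = diag))
  }
  idx <- match(phases$sequence, catalog$sequences)
  diag$supported <- !is.na(idx)
  diag$name <- phasi_name(phases$trigger_id, phases$transcript_id, phases$k)
  rep <- diag[diag$supported, , drop = FALSE]
  ridx <- idx[diag$supported]
  for (l in colnames(catalog$tpm)) {
    rep[[paste0("count_", l)]] <- catalog$counts[ridx, l]
    rep[[paste0("tpm_", l)]] <- catalog$tpm[ridx, l]
  }
  rownames(rep) <- NULL
  list(reported = rep, diagnostics = diag)
}

#' Call targets of phased siRNAs
#'
#' Identical contract to [call_targets()] with phasiRNAs as queries; the
#' output is annotated with the trigger of each phasiRNA.
#'
#' @param phasirnas `reported` table from [quantify_phases()].
#' @param tplots An `srdk_tplots` object.
#' @param config An [pipeline_config()] object.
#' @return Target-call data.frame with an extra `trigger_id` column.
#' @export
call_phasi_targets <- function(phasirnas, tplots,
                               config = pipeline_config()) {
  if (!nrow(phasirnas)) {
    out <- call_targets(data.frame(mirna_id = character(),
                                   sequence = character()), tplots, config)
    out$trigger_id <- character(0)
    return(out)
  }
  queries <- data.frame(mirna_id = phasirnas$name,
                        sequence = phasirnas$sequence,
                        stringsAsFactors = FALSE)
  calls <- call_targets(queries, tplots, config)
  calls$trigger_id <- vapply(calls$mirna_id,
                             function(n) parse_phasi_name(n)$trigger_id, "")
  calls
}

#' Flag candidate TAS (phasiRNA-spawning) transcripts
#'
#' A transcript is a candidate TAS gene iff it is targeted by a selected
#' 22-nt trigger, carries at least `phase_min_registers` read-supported
#' phased registers, and is annotated non-coding or is unannotated.
#'
#' @param triggers data.frame from [select_triggers()].
#' @param calls Target calls of the triggers ([call_targets()]).
#' @param phasirnas `reported` table from [quantify_phases()].
#' @param coding_status Optional data.frame with `transcript_id` and `coding`
#'   (logical; `NA` = unannotated). Transcripts absent from the table are
#'   treated as unannotated.
#' @param config An [pipeline_config()] object.
#' @return data.frame with `transcript_id`, `trigger_id`, `n_registers`,
#'   `coding`, `candidate_tas`.
#' @export
flag_candidate_tas <- function(triggers, calls, phasirnas,
                               coding_status = NULL,
                               config = pipeline_config()) {
  empty <- data.frame(transcript_id = character(), trigger_id = character(),
                      n_registers = integer(), coding = logical(),
                      candidate_tas = logical(), stringsAsFactors = FALSE)
  if (!nrow(triggers) || !nrow(calls)) return(empty)
  tc <- unique(calls[calls$mirna_id %in% triggers$mirna_id,
                     c("mirna_id", "transcript_id")])
  if (!nrow(tc)) return(empty)
  rows <- lapply(seq_len(nrow(tc)), function(r) {
    n_reg <- 0L
    if (nrow(phasirnas)) {
      n_reg <- length(unique(phasirnas$k[
        phasirnas$trigger_id == tc$mirna_id[r] &
        phasirnas$transcript_id == tc$transcript_id[r]]))
    }
    coding <- NA
    if (!is.null(coding_status)) {
      m <- match(tc$transcript_id[r], coding_status$transcript_id)
      if (!is.na(m)) coding <- coding_status$coding[m]
    }
    data.frame(transcript_id = tc$transcript_id[r],
               trigger_id = tc$mirna_id[r], n_registers = n_reg,
               coding = coding,
               candidate_tas = n_reg >= config$phase_min_registers &&
                 (is.na(coding) || !coding),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predict phased siRNAs for all selected triggers
#'
#' For every degradome-validated cleavage site of every trigger, enumerates
#' the 21-nt registers on the 3' cleavage fragment and quantifies them from
#' the catalog.
#'
#' @param triggers data.frame from [select_triggers()].
#' @param calls Target calls from [call_targets()].
#' @param transcripts Named transcript sequences (or [read_fasta()] table).
#' @param catalog A TPM-normalized `srdk_catalog`.
#' @param config An [pipeline_config()] object.
#' @return list with `reported` and `diagnostics` tables (see
#'   [quantify_phases()]).
#' @export
predict_phasirnas <- function(triggers, calls, transcripts, catalog,
                              config = pipeline_config()) {
  if (is.data.frame(transcripts))
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  transcripts <- setNames(canonical_dna(transcripts), names(transcripts))
  reported <- list(); diagnostics <- list()
  tcalls <- calls[calls$mirna_id %in% triggers$mirna_id, , drop = FALSE]
  sites <- unique(tcalls[, c("mirna_id", "transcript_id", "cleavage_site")])
  for (r in seq_len(nrow(sites))) {
    ph <- enumerate_phases(transcripts[[sites$transcript_id[r]]],
                           sites$cleavage_site[r], config,
                           trigger_id = sites$mirna_id[r],
                           transcript_id = sites$transcript_id[r])
    qp <- quantify_phases(ph, catalog)
    reported[[length(reported) + 1L]] <- qp$reported
    diagnostics[[length(diagnostics) + 1L]] <- qp$diagnostics
  }
  bindf <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  proto <- quantify_phases(enumerate_phases("ACGT", 4L, config), catalog)
  list(reported = bindf(reported, proto$reported),
       diagnostics = bindf(diagnostics, proto$diagnostics))
}
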