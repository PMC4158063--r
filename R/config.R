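#' Pipeline configuration
#'
#' Builds the configuration object shared by all pipeline stages. Every
#' threshold of the analysis is collected here so that a run is fully
#' described by one object (serializable to/from YAML).
#'
#' @param min_read_count Minimum per-library count for a collapsed read to be
#'   retained in that library (reads below it are treated as noise).
#' @param read_len_range Length-2 integer vector, inclusive range of read
#'   lengths (nt) kept after quality filtering.
#' @param known_max_mismatch Maximum penalty (substitutions plus length
#'   overhang) allowed when matching reads to reference mature miRNAs.
#' @param penalty_threshold Maximum complementarity penalty score for a
#'   miRNA--transcript alignment to be considered a candidate target site.
#' @param peak_fraction Fraction of the transcript-maximum tag count a
#'   cleavage signal must reach to count as a "clear peak" (category II).
#' @param phase_length Register length (nt) of phased secondary siRNAs.
#' @param trigger_length Mature length (nt) required of phasing triggers.
#' @param require_trigger_5pU Require a 5' uridine on trigger miRNAs.
#' @param phase_min_registers Minimum number of read-supported registers for
#'   a transcript to be flagged as a candidate TAS gene.
#' @param fold_change_threshold TPM fold change above which a sequence is
#'   called tissue-enriched.
#' @param strong_fold_change TPM fold change above which a sequence is called
#'   strongly enriched.
#' @param high_tpm TPM above which a sequence is called highly expressed.
#' @param ssr_min_repeats Named integer vector mapping repeat-unit length
#'   ("1".."6") to the minimum repeat number reported by the SSR detector.
#' @param flank_for_precursor Genomic flank (nt) folded on the far side of a
#'   candidate mature read when extracting precursor windows.
#' @param flank_short Genomic flank (nt) on the near side of the candidate
#'   precursor windows.
#' @param max_duplex_mismatches Maximum unpaired mature positions tolerated in
#'   the miRNA/miRNA* duplex of an accepted hairpin.
#' @param max_asym_bulge Maximum asymmetric bulge (nt) tolerated in the duplex.
#' @param min_mature_paired_fraction Minimum fraction of mature positions that
#'   must be base paired in the precursor structure.
#' @param star_fraction Star-read abundance, as a fraction of the mature
#'   count, emitted by the synthetic-data generator.
#' @param mismatch_penalty,wobble_penalty,gap_penalty Per-position alignment
#'   penalties (the 5'-proximal core, positions 2-13, is double-weighted).
#' @param rng_seed Integer seed used by the simulators.
#'
#' @return An object of class `srdk_config` (a validated named list).
#' @export
pipeline_config <- function(min_read_count = 3L,
                            read_len_range = c(18L, 30L),
                            known_max_mismatch = 2L,
                            penalty_threshold = 7,
                            peak_fraction = 0.5,
                            phase_length = 21L,
                            trigger_length = 22L,
                            require_trigger_5pU = TRUE,
                            phase_min_registers = 3L,
                            fold_change_threshold = 2,
                            strong_fold_change = 4,
                            high_tpm = 10,
                            ssr_min_repeats = c(`1` = 8L, `2` = 4L, `3` = 3L,
                                                `4` = 3L, `5` = 3L, `6` = 2L),
                            flank_for_precursor = 200L,
                            flank_short = 20L,
                            max_duplex_mismatches = 4L,
                            max_asym_bulge = 2L,
                            min_mature_paired_fraction = 0.6,
                            star_fraction = 0.1,
                            mismatch_penalty = 1,
                            wobble_penalty = 0.5,
                            gap_penalty = 2,
                            rng_seed = 1L) {
  cfg <- list(
    min_read_count = as.integer(min_read_count),
    read_len_range = as.integer(read_len_range),
    known_max_mismatch = as.integer(known_max_mismatch),
    penalty_threshold = as.numeric(penalty_threshold),
    peak_fraction = as.numeric(peak_fraction),
    phase_length = as.integer(phase_length),
    trigger_length = as.integer(trigger_length),
    require_trigger_5pU = isTRUE(require_trigger_5pU),
    phase_min_registers = as.integer(phase_min_registers),
    fold_change_threshold = as.numeric(fold_change_threshold),
    strong_fold_change = as.numeric(strong_fold_change),
    high_tpm = as.numeric(high_tpm),
    ssr_min_repeats = setNames(as.integer(ssr_min_repeats),
                               names(ssr_min_repeats)),
    flank_for_precursor = as.integer(flank_for_precursor),
    flank_short = as.integer(flank_short),
    max_duplex_mismatches = as.integer(max_duplex_mismatches),
    max_asym_bulge = as.integer(max_asym_bulge),
    min_mature_paired_fraction = as.numeric(min_mature_paired_fraction),
    star_fraction = as.numeric(star_fraction),
    mismatch_penalty = as.numeric(mismatch_penalty),
    wobble_penalty = as.numeric(wobble_penalty),
    gap_penalty = as.numeric(gap_penalty),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "srdk_config"
  cfg
}

validate_config <- function(cfg) {
  num <- c("min_read_count", "penalty_threshold",
           "peak_fraction", "phase_length", "trigger_length",
           "phase_min_registers", "fold_change_threshold",
           "strong_fold_change", "high_tpm", "flank_for_precursor",
           "flank_short", "min_mature_paired_fraction", "star_fraction",
           "mismatch_penalty", "wobble_penalty", "gap_penalty")
  for (f in num) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  for (f in c("known_max_mismatch", "max_duplex_mismatches",
              "max_asym_bulge")) {
    if (cfg[[f]] < 0) stop("config field '", f, "' must be >= 0", call. = FALSE)
  }
  rng <- cfg$read_len_range
  if (length(rng) != 2L || any(rng <= 0) || rng[1] > rng[2])
    stop("read_len_range must be positive with min <= max", call. = FALSE)
  if (!all(as.character(1:6) %in% names(cfg$ssr_min_repeats)))
    stop("ssr_min_repeats must name unit lengths '1'..'6'", call. = FALSE)
  if (any(cfg$ssr_min_repeats <= 0))
    stop("ssr_min_repeats must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the package defaults; unknown fields
#' are rejected.
#'
#' @param path Path to a YAML file.
#' @return An `srdk_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  defaults <- formals(pipeline_config)
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$ssr_min_repeats))
    vals$ssr_min_repeats <- unlist(vals$ssr_min_repeats)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config An `srdk_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "srdk_config"))
  out <- unclass(config)
  out$ssr_min_repeats <- as.list(out$ssr_min_repeats)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.srdk_config <- function(x, ...) {
  cat("srdk pipeline configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-28s %s\n", f, paste(x[[f]], collapse = " ")))
  }
  invisible(x)
}
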