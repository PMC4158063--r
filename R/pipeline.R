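#' Read a dataset directory
#'
#' Loads the standard file set written by [simulate_dataset()] (or assembled
#' by hand): `genome.fa`, `transcripts.fa`, `mirna_ref.fa`, optional
#' `ncrna.fa`, per-tissue `<tissue>.srna.fa` and `<tissue>.degradome.fa`,
#' optional `coding_status.tsv`.
#'
#' @param dir Directory path.
#' @return list in the shape expected by [run_pipeline()].
#' @export
read_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  need <- c("genome.fa", "transcripts.fa", "mirna_ref.fa")
  for (f in need) if (!file.exists(fp(f)))
    stop("dataset file missing: ", f, call. = FALSE)
  as_named <- function(df) setNames(df$sequence, df$id)
  srna_files <- list.files(dir, pattern = "\\.srna\\.fa$")
  tissues <- sub("\\.srna\\.fa$", "", srna_files)
  if (!length(tissues)) stop("no <tissue>.srna.fa files found", call. = FALSE)
  libraries <- lapply(setNames(tissues, tissues), function(t) {
    read_collapsed_srna(fp(paste0(t, ".srna.fa")))
  })
  degradome <- list()
  for (t in tissues) {
    f <- fp(paste0(t, ".degradome.fa"))
    if (file.exists(f)) degradome[[t]] <- read_collapsed_srna(f)
  }
  list(genome = as_named(read_fasta(fp("genome.fa"))),
       transcripts = as_named(read_fasta(fp("transcripts.fa"))),
       mirna_ref = as_named(read_fasta(fp("mirna_ref.fa"))),
       ncrna = if (file.exists(fp("ncrna.fa")))
         as_named(read_fasta(fp("ncrna.fa"))) else NULL,
       coding_status = if (file.exists(fp("coding_status.tsv")))
         read_tsv(fp("coding_status.tsv")) else NULL,
       libraries = libraries, degradome = degradome)
}

#' Run the full analysis pipeline
#'
#' Catalog construction (collapse, quality/abundance filter, ncRNA
#' exclusion, genome mapping, TPM), known/novel miRNA discovery, SSR
#' detection and co-localization, degradome T-plots and target calling with
#' category classification, trigger selection and phasiRNA prediction with
#' their own target calls, candidate-TAS flagging, tissue comparison,
#' isoform pairs and genome distribution.
#'
#' @param data Dataset list ([read_dataset()] or [simulate_dataset()]).
#' @param config An [pipeline_config()] object.
#' @return list with the catalog and every stage's result table.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  catalog <- collapse_and_filter(data$libraries, config)
  catalog <- annotate_ncrna(catalog, data$ncrna)
  catalog <- map_to_genome(catalog, data$genome)
  catalog <- tpm_normalize(catalog)

  known <- match_known(catalog, data$mirna_ref, data$genome, config)
  exclude <- unique(c(known$mature_seq, known$star_seq))
  novel <- predict_novel(catalog, data$genome, config, exclude = exclude)
  loci <- rbind(known, novel)
  loci <- loci_expression(loci, catalog)
  catalog$annotation[catalog$sequences %in% known$mature_seq] <- "known_miRNA"
  catalog$annotation[catalog$sequences %in% novel$mature_seq] <- "novel_miRNA"

  ssrs <- detect_ssrs_genome(data$genome, config$ssr_min_repeats)
  coloc <- colocalize_ssrs(ssrs, loci)
  ssr_summary <- summarize_ssr_units(coloc$occurrences)

  tplots <- build_tplots(data$degradome, data$transcripts)
  queries <- unique(loci[, c("mirna_id", "mature_seq")])
  names(queries) <- c("mirna_id", "sequence")
  calls <- call_targets(queries, tplots, config)

  triggers <- select_triggers(loci, calls, config)
  phasi <- predict_phasirnas(triggers, calls, data$transcripts, catalog,
                             config)
  if (nrow(phasi$reported))
    catalog$annotation[catalog$sequences %in% phasi$reported$sequence &
                         catalog$annotation == "unannotated"] <- "phased_siRNA"
  phasi_calls <- call_phasi_targets(phasi$reported, tplots, config)
  tas <- flag_candidate_tas(triggers, calls, phasi$reported,
                            data$coding_status, config)

  comparison <- if (ncol(catalog$counts) >= 2L)
    compare_tissues(catalog, config = config) else NULL

  list(catalog = catalog, known = known, novel = novel, loci = loci,
       ssrs = ssrs, colocalized = coloc, ssr_summary = ssr_summary,
       tplots = tplots, target_calls = calls,
       target_summary = summarize_targets(calls),
       triggers = triggers, phasirnas = phasi$reported,
       phasi_diagnostics = phasi$diagnostics, phasi_calls = phasi_calls,
       tas_candidates = tas, comparison = comparison,
       isoform_pairs = find_isoform_pairs(loci),
       distribution = genome_distribution(loci),
       config = config)
}

#' Write the standard report files for a pipeline result
#'
#' @param result list from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param seqlengths Optional chromosome lengths for GFF3 validation.
#' @return The output paths, invisibly.
#' @export
write_pipeline_reports <- function(result, outdir, seqlengths = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(outdir, f)
  cat_tab <- data.frame(sequence = result$catalog$sequences,
                        length = nchar(result$catalog$sequences),
                        annotation = result$catalog$annotation,
                        stringsAsFactors = FALSE)
  for (l in colnames(result$catalog$counts)) {
    cat_tab[[paste0("count_", l)]] <- result$catalog$counts[, l]
    cat_tab[[paste0("tpm_", l)]] <- result$catalog$tpm[, l]
  }
  write_tsv(cat_tab, fp("catalog.tsv"))
  write_tsv(result$catalog$stats, fp("stats.tsv"))
  write_tsv(result$catalog$length_hist, fp("lengths.tsv"))
  loci_flat <- result$loci[, setdiff(names(result$loci),
                                     c("precursor_seq", "dot_bracket"))]
  write_tsv(loci_flat, fp("mirna_catalog.tsv"))
  write_gff3(result$loci, fp("mirna_loci.gff3"), seqlengths)
  write_tsv(result$isoform_pairs, fp("isoform_pairs.tsv"))
  write_tsv(result$distribution, fp("distribution.tsv"))
  write_tsv(result$target_calls, fp("target_calls.tsv"))
  write_tsv(result$target_summary, fp("category_summary.tsv"))
  write_tsv(result$phasirnas, fp("phasirnas.tsv"))
  write_tsv(result$phasi_calls, fp("phasi_targets.tsv"))
  write_tsv(result$tas_candidates, fp("tas_candidates.tsv"))
  write_bed(result$ssrs, fp("ssrs.bed"))
  write_tsv(result$colocalized$occurrences, fp("colocalized.tsv"))
  if (!result$ssr_summary$undefined)
    write_tsv(result$ssr_summary$units, fp("unit_summary.tsv"))
  if (!is.null(result$comparison))
    write_tsv(result$comparison, fp("fold_changes.tsv"))
  tp <- result$tplots
  tp_rows <- list()
  for (lib in names(tp$plots)) {
    for (tx in names(tp$plots[[lib]])) {
      v <- tp$plots[[lib]][[tx]]
      nz <- which(v > 0L)
      if (!length(nz)) next
      tp_rows[[length(tp_rows) + 1L]] <- data.frame(
        library = lib, transcript_id = tx, position = nz, count = v[nz],
        stringsAsFactors = FALSE)
    }
  }
  if (length(tp_rows)) write_tsv(do.call(rbind, tp_rows), fp("tplots.tsv"))
  invisible(list.files(outdir, full.names = TRUE))
}

#' Score recovery of planted features
#'
#' Compares a pipeline result against the ground-truth manifest of a
#' simulated dataset: fraction of expressed planted miRNAs recovered
#' (mature sequence found among called loci), fraction of planted category-I
#' targets recalled as category I at the planted site (within 1 nt),
#' fraction of planted phased registers reported, whether the planted
#' non-coding TAS transcript is flagged, and whether any sub-threshold plant
#' leaked through.
#'
#' @param result list from [run_pipeline()].
#' @param data Simulated dataset with its `truth` manifest.
#' @return list of recovery statistics.
#' @export
score_recovery <- function(result, data) {
  truth <- data$truth
  mir <- truth$mirnas
  out <- list()
  if (!is.null(mir)) {
    called <- unique(result$loci$mature_seq)
    exp <- mir[mir$expressed, , drop = FALSE]
    out$n_planted <- nrow(exp)
    out$n_recovered <- sum(exp$mature_seq %in% called)
    out$mirna_recovery <- out$n_recovered / max(1L, out$n_planted)
    sub <- mir[!mir$expressed, , drop = FALSE]
    out$subthreshold_leaked <- sum(sub$mature_seq %in% called)
  }
  tg <- truth$targets
  if (!is.null(tg)) {
    cat1 <- tg[tg$category == "I", , drop = FALSE]
    calls <- rbind(
      result$target_calls[, c("mirna_id", "transcript_id",
                              "cleavage_site", "category")],
      result$phasi_calls[, c("mirna_id", "transcript_id",
                             "cleavage_site", "category")])
    hit <- logical(nrow(cat1))
    for (r in seq_len(nrow(cat1))) {
      m <- calls$transcript_id == cat1$transcript_id[r] &
        abs(calls$cleavage_site - cat1$cleavage_site[r]) <= 1L &
        calls$category == "I"
      # restrict to the planted miRNA's called identifier when known
      mi <- match(cat1$mirna[r], mir$hp_id)
      if (!is.na(mi)) {
        ids <- result$loci$mirna_id[result$loci$mature_seq ==
                                      mir$mature_seq[mi]]
        if (length(ids)) m <- m & calls$mirna_id %in% ids
      }
      hit[r] <- any(m)
    }
    out$n_cat1_planted <- nrow(cat1)
    out$n_cat1_recovered <- sum(hit)
    out$cat1_recovery <- mean(hit)
  }
  ph <- truth$phasing
  if (!is.null(ph) && !is.null(truth$registers)) {
    ids <- result$loci$mirna_id[result$loci$mature_seq ==
                                  mir$mature_seq[mir$hp_id == ph$trigger]]
    rep <- result$phasirnas
    found <- vapply(seq_len(ph$K), function(k) {
      any(rep$k == k & rep$transcript_id == ph$transcript_id &
            rep$trigger_id %in% ids &
            rep$sequence == truth$registers$sequence[k])
    }, TRUE)
    out$n_registers_planted <- ph$K
    out$n_registers_recovered <- sum(found)
    out$register_recovery <- mean(found)
    out$tas_flagged <- any(result$tas_candidates$candidate_tas &
                             result$tas_candidates$transcript_id ==
                               ph$transcript_id)
  }
  out
}
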