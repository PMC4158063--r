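---
title: "Methods: small-RNA cataloguing, miRNA discovery, degradome target
  calling, phasiRNA prediction and SSR co-localization in srdk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the srdk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`srdk` re-implements, as a tested and reusable pipeline, the computational
core of a genome-wide small-RNA / degradome analysis of the kind performed
for sweet orange (*Citrus sinensis*) leaf, flower and fruit tissues: building
a catalog of collapsed small-RNA reads, annotating known and novel miRNAs
from stem-loop precursors, validating their targets with degradome (PARE)
tags, predicting 21-nt phased secondary siRNAs (phasiRNAs) triggered by
22-nt miRNAs, and intersecting precursors with simple sequence repeats
(SSRs). This vignette explains the models and procedures, the parameters
that matter, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

## The small-RNA catalog

Libraries arrive as collapsed FASTA (unique sequence + count; the `_xN` and
`count=N` header dialects are both accepted) or as FASTQ to be collapsed.
Two filters define the "clean" catalog:

* **quality** — reads containing `N` or outside `read_len_range`
  (default 18–30 nt) are discarded. Length is the only quality proxy
  available for collapsed input; base-quality filtering belongs upstream.
* **abundance** — a sequence is kept *per library* only if its count in that
  library reaches `min_read_count` (default 3, the usual "counts below 3 are
  noise" rule). A sequence below threshold in every library leaves the
  catalog entirely. Raising the threshold can only shrink the catalog
  (tested as a monotonicity property).

Sequences are stored internally over the DNA alphabet (U→T, uppercased) so
RNA and DNA inputs compare equal; RNA-facing outputs convert on write. All
persisted coordinates are 1-based inclusive (GFF3 convention); helpers
`to_zero_based()` / `to_one_based()` convert at the API boundary.

Expression is normalized as TPM, `count / total_clean × 10⁶` per library, so
each library's TPM column sums to one million over the catalog (tested
exactly). Cross-tissue comparison computes, per sequence and tissue, the
fold change against the maximum TPM of the other tissues. The denominator is
floored at a 0.5 TPM pseudocount — a floor rather than an addend, so that
clean ratios like 25/5 = 5 are reported exactly while division by zero is
impossible. Classes: enriched (>2×), strongly enriched (>4×), tissue-absent
(zero TPM in a tissue, positive elsewhere; absence takes precedence over
fold-change labels because a ratio against zero is not meaningful), and
highly expressed (>10 TPM).

Non-coding RNA exclusion is an exact-substring rule: a read is flagged
`ncRNA` iff it occurs verbatim (either strand) inside a user-supplied
rRNA/tRNA/snRNA/snoRNA reference; flagged reads are excluded from miRNA
discovery but retained in the accounting tables. Genome mapping is
perfect-match only, on both strands, with all hits of multi-mapping reads
kept — matching the "perfect matches with the genome" accounting that
produces the matched-fraction rows of a library characteristics table.

## Hairpin folding

Precursor validation needs secondary structure. The internal folder
maximizes the number of base pairs (Watson–Crick plus G:U wobble) over all
nested structures with a minimum hairpin loop of 3 nt — a Nussinov-style
dynamic program, exact for this objective, dependency-free and fast (Rcpp).

Base-pair maximization is heavily degenerate: many different structures
attain the maximal count. An arbitrary tie-break (for example, always pairing
the leftmost base with its smallest admissible partner) can return a
structure in which a perfect 90-bp stem is shredded into count-equivalent
fragments — a (CUU)ₙ loop, whose C/U bases can always re-pair one-for-one
against arm G/A bases once stem pairs are opened, makes this failure mode
systematic. `srdk` therefore resolves ties lexicographically: first the pair
count (still the exact maximum, and verified against an exhaustive
enumeration oracle for all sequences up to 14 nt), then the number of
stacked pairs, with the traceback preferring helix continuation. This keeps
helices contiguous, is deterministic, and makes the terminal loop of a
(CUU)ₙ-loop hairpin come out at exactly 3n nt — strictly increasing in n,
the qualitative behaviour expected of such precursors.

For users who want thermodynamic (MFE) structures, `fold_rna()` accepts any
plug-in returning a dot-bracket string; `fold_vienna()` wraps the ViennaRNA
`RNAfold` binary.

`hairpin_metrics()` evaluates a mature placement within a folded precursor:
paired fraction, unpaired (mismatched) duplex positions, the largest
asymmetric bulge (difference of opposing unpaired runs between consecutive
paired mature positions), the terminal loop of the stem carrying the mature,
the arm (5p/3p), and the miRNA\* interval implied by canonical Dicer
geometry — the star pairs mature positions `m₁..m₂−2` and extends 2 nt past
the partner of `m₁` (2-nt 3′ overhangs on both duplex ends). A mature that
falls wholly into the terminal loop, or whose implied star would overlap it,
is rejected as "not a hairpin".

## Known and novel miRNAs

**Known** assignment compares each catalog sequence against a
reference set of mature miRNAs, ungapped, with the shorter sequence slid
within the longer when lengths differ by at most 2 nt; the penalty is
substitutions plus the length difference, and at most `known_max_mismatch`
(default 2, the "two or fewer mismatches" convention) is allowed, ties going
to the earlier reference entry. An assignment additionally requires a
genomic locus whose surrounding window folds into a stem-loop containing the
mature outside the terminal loop — sequence similarity alone does not make a
miRNA.

**Novel** prediction considers every unassigned, genome-mapped 20–24-nt
read. Around each genomic hit three candidate windows are folded: two
asymmetric ones (long flank on one side, `flank_short` = 20 nt on the
other) and the symmetric one. Matures sit near one end of their precursor,
so one asymmetric window usually contains the whole hairpin with little
flanking sequence; a long symmetric window around a short hairpin invites
the degenerate-tie problem above. The default `flank_for_precursor` is
200 nt so that a window can contain precursors beyond 350 nt — documented
long precursors reach that size, and a 150-nt flank demonstrably cannot span
them (it already fails for a 225-nt precursor whose 45-nt loop pushes the
star 164 nt past the mature).

A window is accepted when the mature is outside the terminal loop with at
most `max_duplex_mismatches` (4) unpaired positions and `max_asym_bulge`
(2), **and** the catalog contains a read matching the computed miRNA\*
interval within a 1-nt shift, in at least one library (any library suffices
by default; the requirement is configurable). Accepted windows are trimmed
to the duplex span plus a 15-nt margin and refolded; the trimmed hairpin is
the reported precursor. Star evidence is the decisive specificity filter: in
background-only simulations it reduces false loci to zero.

For speed, folding is only attempted where some nearby catalog read could
plausibly be the star — the best ungapped antiparallel duplex between the
candidate and each read mapping within reach must reach
`L − max_duplex_mismatches − max_asym_bulge` pairs. This prescreen is a
performance device; the folded structure still makes the decision.

Identifiers `csi-miRN##` are assigned in discovery order (descending total
count); identical matures at several loci share an identifier with locus
suffixes. Multi-mapping is deliberate: a perfect palindromic precursor
yields the same mature on both strands and both loci are reported. Isoform
pairs are found by grouping loci with overlapping precursor intervals;
separation is the distance from the earlier mature's end to the later one's
start (two matures at offsets 10–31 and 226–247 are 195 nt apart). Genome
distribution bins precursors per chromosome (default 100-kb bins) and flags
bins holding two or more loci.

## Degradome targets

Degradome tags (20-nt 5′ signatures of uncapped cleavage products) are
matched exactly against transcript sense strands; each tag's 5′ position
increments the transcript's **T-plot**, at every transcript it matches.

Candidate sites are scored with the standard plant complementarity penalty:
per miRNA position, 0 for a Watson–Crick pair, 0.5 for a G:U wobble, 1 for a
mismatch, with positions 2–13 from the miRNA 5′ end double-weighted; the
alignment is ungapped (sites must match the miRNA length; a gap penalty
constant exists in the configuration for completeness but gapped alignment
is disabled). Sites with penalty ≤ `penalty_threshold` (default 7) are
candidates. RISC cleaves opposite miRNA positions 10/11, so the expected tag
position is the transcript base opposite position 10; a call is emitted iff
at least one tag lies within ±1 nt of it (the reported site is the
highest-count position in that window, which absorbs the 10-vs-11
ambiguity), and is classified:

* **I** — the site count is the *unique* maximum of the T-plot;
* **II** — not the maximum, but a clear peak: at least `peak_fraction`
  (default 0.5) of the maximum. A shared maximum is II, because "most
  abundant" is read as unique;
* **III** — everything else.

Category is monotone in the site count (a site never drops from I to III as
its count grows; tested on an enumerated grid). The penalty arithmetic is
property-tested against an independent per-position recomputation.

## Phased secondary siRNAs

Triggers are miRNAs of exactly `trigger_length` (22 nt), by default with a
5′ U (`require_trigger_5pU`; the 5′-U requirement is exposed because it is
typical of documented triggers but not proven universal), and with at least
one degradome-validated target call. Registers are enumerated from the first
nucleotide of the 3′ cleavage fragment in exact `phase_length` = 21-nt
steps: register k spans `c + 21(k−1) … c + 21k − 1` (so k = 9 starts at
c + 168); only complete windows count, and near-phased reads are not
rescued. A register is *reported* iff a catalog sequence equals its window
exactly (sense strand; an antisense mode offset by the 2-nt overhang is a
documented possible extension, not implemented because the procedure being
reproduced quantified the target strand). Names follow
`trigger-transcript-k` (`csi-miR3954a-Cs1g09635.1-9` is the ninth register
on Cs1g09635.1 triggered by csi-miR3954a) and parse back uniquely because
transcript identifiers contain no dash. No phasing score statistic is
computed: register membership plus read support is the whole criterion, and
reported phasiRNAs are fed back through the degradome machinery to call
their own targets with trigger provenance.

A transcript is flagged as a candidate TAS (phasiRNA-spawning) gene iff a
selected trigger targets it, at least `phase_min_registers` (3) registers
are read-supported, and it is annotated non-coding or not annotated at all.

## SSRs and co-localization

The detector reports all maximal tandem repeats of primitive 1–6-nt units:
a run must not be extendable by one full unit on either side, its unit must
not itself be a repetition of a shorter unit (a (CUCU)ₙ tract is reported as
(CU)₂ₙ), runs strictly contained in another run are suppressed (these are
rotated-phase sub-runs of the same tract), and the repeat number must reach
the per-unit-length thresholds (defaults mono 8, di 4, tri 3, tetra 3,
penta 3, hexa 2 — MISA-like, with tri = 3 so that a (CUU)₃ tract inside a
precursor still counts). Units are reported on the scanned strand without
canonicalization, because the downstream census distinguishes, for example,
CT from TC. Containment suppression is applied before thresholding so that
lowering a threshold can only add runs (tested). The detector is verified
against a brute-force every-position scanner on random 5-kb sequences.

An SSR co-localizes with a precursor iff their intervals overlap by ≥ 1 nt
on the same strand. `summarize_ssr_units()` builds the per-unit census
(count, class, RNA display) either from detected occurrences or from a
pre-tabulated unit/class/count table; a transcription of the published
census of SSRs co-localized with sweet-orange pre-miRNAs ships in
`inst/extdata/ssr_unit_counts_sweet_orange.tsv`, and pooling its di- and
trinucleotide classes reproduces the published 77.6% share with modal unit
UA (count 12).

## The synthetic dataset

`simulate_dataset()` builds a fully self-contained toy study with a
ground-truth manifest, used by the parameter-recovery tests and the
acceptance script. What it emulates, and the values chosen where only the
qualitative shape is documented:

* **Genome** (2 × 50 kb by default): hairpins planted as perfect
  reverse-complement-palindromic 90-nt arms around a loop, placed uniformly
  without overlap; 12 hairpins, of which 6 carry known reference names (the
  first is the 22-nt 5′U trigger), one sits on the minus strand, 4 carry
  C/U-only SSR loops — always including one (CUU)₁₅ (45 nt) — and the last
  2 are planted below the count filter and must never be recovered. C/U-only
  loop units cannot pair internally, so the tract stays in the terminal
  loop; the three arm bases flanking the loop are fixed to G so the tract
  cannot extend into the stem and its unit phase is unambiguous.
* **sRNA libraries** (≈50,000 reads per tissue): background lengths follow a
  categorical distribution with mode 24 nt ({21: 0.15, 22: 0.10, 23: 0.15,
  24: 0.45, other 18–30: 0.15}); 65% of background reads are genomic
  windows, the rest unmappable; per-read counts are geometric (mean ≈ 8), so
  a realistic fraction falls under the count filter. Planted matures get
  fixed per-tissue counts covering uniform, enriched (>2×), strongly
  enriched (>4×), tissue-absent and a 40-vs-400 ten-fold pair; stars are
  emitted at 10% of the mature count (star_fraction), quantifying the
  qualitative "stars are rarer than matures".
* **Transcriptome** (12 × 1 kb): reverse-complement target sites planted at
  position 301; the trigger targets a non-coding transcript (the TAS
  candidate), one target is category II, one category III, the rest
  category I; register 7 of the cascade gets its own category-I target on a
  coding transcript.
* **Degradome** (≈3,000 tags per tissue): uniform background tags with
  per-position counts capped at a quarter of the signal; planted signals
  carry `signal_to_noise` (default 20) counts, so category-I sites are
  strict maxima by construction; category-II decoys carry 1.6 × the signal
  (keeping the signal a clear ≥ 50% peak), category-III sites carry 2 counts
  under a high decoy.
* **Cascade**: K = 9 registers at exact 21-nt steps with counts well above
  the filter in every tissue, plus the trigger's cleavage tag.

Each generator sets a fixed offset of the master seed, so components are
independently regenerable and identical seeds give byte-identical files.

What passing recovery tests shows: the pipeline's rules are implemented
faithfully and are mutually consistent (planted signals pass exactly the
filters they were designed to pass, and pure background does not). What it
does not show: performance on real libraries — real precursors have
imperfect, bulged stems that base-pair maximization folds less cleanly than
MFE, real degradomes have structured (not uniform) background, sequencing
error and adaptor artefacts are not modelled, and the real transcriptome's
repeat structure can multiply map both tags and reads. The headline counts
of any particular real study (numbers of known/novel miRNAs, per-tissue
target counts, co-localized precursor counts) are data-dependent and are not
reproduction targets at this scale.

## Problem sizes and runtime

The default synthetic study (two 50-kb chromosomes, three tissues, ≈50k
reads and ≈3k degradome tags per tissue) runs through the full pipeline in
about half a minute on one core; the test suite, including a full-scale and
a background-only run plus the folding and SSR oracles (500 short sequences;
50 × 5 kb), completes in under three minutes. `scripts/acceptance.R`
recomputes the worked examples, oracle agreement rates and recovery
statistics from scratch in about a minute and a half.

## Known limitations

* The folder ignores thermodynamics; duplex-adjacent geometry is exact for
  clean stems but approximate for heavily bulged precursors (plug in
  `fold_vienna()` when MFE parity matters).
* Gapped miRNA–target alignments are not scored; one-nt bulged sites are
  missed by design.
* Antisense phasing registers and two-hit trigger geometries are out of
  scope; single-hit, 3′-directed phasing only.
* The SSR detector reports rotated units of odd-length tails of a tract as
  separate runs when they genuinely cannot be extended; censuses built on
  different maximality conventions may differ slightly.
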