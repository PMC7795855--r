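---
title: "Methods: ceRNA network inference in plantcerna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference in plantcerna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantcerna)
```

## The problem

Plant transcriptomes respond to abiotic stress at every RNA layer: coding
mRNAs, long non-coding RNAs (lncRNAs), circular RNAs (circRNAs) and
microRNAs (miRNAs). Under the competing endogenous RNA (ceRNA) hypothesis,
transcripts that carry binding sites for the same miRNA compete for its
limited pool, so a lncRNA or circRNA acting as a miRNA "sponge" can
indirectly de-repress the miRNA's mRNA targets. plantcerna implements the
full inference chain for a two-tissue, two-condition (control `ck` versus
salt-treated `st`), three-replicate design: class-specific differential
expression (DE) at fixed cutoffs, annotation filters for lncRNAs and
circRNAs, plant-style miRNA target prediction in two modes, degradome
(PARE) validation of cleavage, and assembly of a correlation-filtered,
miRNA-centric bipartite network.

Every stage is also exercised against a synthetic whole-transcriptome
generator that plants known DE features, known cleavage and mimic sites,
known degradome peaks and known ceRNA triplets, and records them in a
machine-readable truth table, so recovery is a testable property rather
than an anecdote.

## Differential expression

Abundances are normalized as FPKM (gene-like features; fragments per
kilobase per million mapped fragments) and CPM (miRNAs). A pseudo-count of
10^-6 is added *only where logs are taken*, never stored, so linear-space
statistics are undistorted.

Calls come from a negative-binomial (NB) exact test on per-group summed
normalized counts:

* Samples within a tissue are normalized by median-of-ratios size factors
  (each sample's median ratio to the per-feature geometric-mean reference,
  computed over features expressed in all samples). This estimator is
  robust to composition shifts, which matter in small feature sets where a
  substantial fraction of features move; total-count scaling is biased
  there.
* Per-feature dispersion \(\phi\) (variance \(= \mu + \phi\mu^2\)) is
  estimated by the method of moments within each condition group, with the
  squared-mean denominator debiased by \(m^2 - v/k\) (at \(k = 3\)
  replicates the naive denominator is noticeably inflated), averaged
  across groups, clipped at 0, and shrunk 50/50 toward the across-feature
  median.
* The two-sided p-value conditions on the total of the two group sums:
  each group sum of \(k\) iid NB counts has size \(k/\phi\); the
  conditional distribution over splits is enumerated and all outcomes with
  probability at most that of the observed split are summed (the
  "small-p" two-sided rule). In the \(\phi \to 0\) limit this reduces
  exactly to the conditional binomial test with p = 1/2, which the test
  suite uses as an independent oracle (`stats::binom.test`, agreement to
  10^-6).

Calls are class-specific and mirror common fixed-cutoff practice:
gene-like features require raw p < 0.05 and |log2FC| strictly greater
than 1; miRNAs require p < 0.05 and fold change of at least 1.5 in either
direction (|log2FC| >= log2 1.5, inclusive). Raw p-values are used for
filtering (no FDR step); `relax_threshold_mode()` re-filters an existing
result at p < 0.1 without recomputation, for tissues that yield no
candidate ceRNAs at the strict cutoff, and flags the relaxation in all
downstream outputs. `delta_delta_ct()` provides the companion 2^-ddCt
relative-quantification utility for qPCR follow-up.

Calibration, measured by the test suite and the acceptance script: with no
planted DE at dispersion 0.1 the empirical type-I error at alpha = 0.05
stays within [0.02, 0.08] (the test is mildly anti-conservative because
3-replicate dispersion estimates are noisy; with the true dispersion
supplied it is slightly conservative, ~0.045). With planted |log2FC| = 2
at means >= 100, over 95% of planted features are called in the planted
direction.

## lncRNA, circRNA and miRNA annotation

**lncRNAs.** A transcript is retained iff it is >= 200 nt, has no
same-strand exonic overlap with a known mRNA (antisense overlappers are
retained, the standard convention), and has low coding potential. External
coding-potential classifiers are deliberately out of scope; the built-in
stand-in is "longest forward-frame ORF < 300 nt", a deterministic,
dependency-free rule that the synthetic generator exercises from both
sides (mRNAs are built around ORFs >= 300 nt, lncRNAs rejection-sampled to
stay below). A precomputed coding table can be supplied to honour external
scores instead.

**circRNAs.** Back-splice discovery is out of scope; given annotated
circular spans, `classify_circrna()` assigns exactly one locus type:
`exon` (span overlaps >= 1 exon of a same-strand transcript), else
`intron` (fully inside a same-strand transcript and touching no exon),
else `intergenic`.

**Cis targets.** `assign_cis_targets()` pairs each lncRNA with every
coding gene within 100 kb. Distance is the gap width between genomic spans
(overlapping or book-ended spans count as 0, the GenomicRanges
convention); the sign is negative when the lncRNA lies upstream in the
gene's orientation. A brute-force all-pairs scan is the test oracle.

**miRNA catalogue.** Small RNA reads are length-filtered to 18-25 nt. A
read matching a reference mature of the same length with at most 3
mismatches (Hamming distance; "no indels" makes unequal lengths
incomparable, so only same-length references are considered) is `known`.
Otherwise the read is located exactly on the genome and its +/-200-nt
window is folded by `hairpin_check()`; a passing stem-loop makes it
`novel`, anything else is dropped. Summary statistics (length histogram,
5' nucleotide composition per length) expose the canonical
DICER-LIKE signature: 21-mers dominated by 5' U, 24-mers by 5' A — which
the generator plants as an exact rule.

**Hairpin heuristic.** Thermodynamic folding is out of scope. The
stand-in scans every arm/loop/arm split (loop 3-150 nt) of the window; in
a fold whose loop is flanked by last-left-arm base \(c\) and
first-right-arm base \(d\), base \(i\) pairs with \(c + d - i\), so the
paired fraction of the mature depends only on the antidiagonal sum
\(s = c + d\) and the scan is linear in the window length. A split passes
when the mature pairs (Watson-Crick or G:U) at >= 85% of its positions.
The threshold was calibrated by Monte-Carlo before being frozen: because
the scan maximizes over hundreds of loop placements, per-placement
thresholds as low as 60% are passed by essentially all random windows
(random pairing probability is 6/16 per base), while 0.85 holds the
false-pass rate of random 421-nt windows below 1%, comfortably under the
5% design bound the test suite asserts. Planted perfect hairpins pair at
100%, so sensitivity is unaffected.

## Target prediction

Plant miRNAs direct cleavage through near-perfect complementarity, which
makes direct complementarity scanning viable. `align_duplex()` computes
the antiparallel pairing of a candidate window against the miRNA; every
position is labelled WC, G:U or mismatch.

**Cleavage mode** admits no bulges (window length = miRNA length). The
score sums mismatch = 1 and G:U = 0.5, doubled at miRNA positions 2-13; a
site is accepted iff the score is <= 4.0 *and* positions 10-11 are
Watson-Crick — the scissile site, between the bases paired to miRNA
positions 10 and 11, must be paired for slicing. The predicted cleavage
position is the target base paired to miRNA position 10 (the 5' end of
the 3' cleavage fragment). These constants stand in for unpublished
parameterizations of the usual web tools and are all exposed as
arguments. Monte-Carlo calibration in the test suite shows random 21-mers
accept fewer than 0.05 sites per 2-kb random transcript.

**Mimic mode** implements endogenous target mimicry: a non-cleavable site
that sequesters the miRNA. The rules are: (I) exactly one bulge, on the
target (ncRNA) side, inserted at a middle position of the miRNA; (II)
outside the middle, at most 4 mismatch units (mismatch = 1, G:U = 0.5)
with no run of more than 2 consecutive mismatches; (III) no bulge
anywhere else. "Middle" is fixed at miRNA positions 9-11 — insertion
between the bases paired to 9-10 or 10-11 — because the canonical
scissile site lies between 10 and 11 and reported mimics bulge there; the
bulge length is bounded at 1-4 nt (3 nt is the canonical case). G:U pairs
count half toward the rule-II budget but do not extend a mismatch run
(they are stable pairs; the run rule targets true helix disruptions).
All of these are configurable.

`scan_transcript()` slides every admissible window, with a vectorized
fast path, deduplicates overlapping cleavage windows by keeping the best
score per predicted cleavage position, and treats circRNAs as circular by
scanning the doubled sequence and deduplicating hits by modular position,
so sites straddling the back-splice junction are found. mRNAs are scanned
in cleavage mode; lncRNAs and circRNAs in both modes, with the mode
recorded per hit — which transcript classes count as ceRNA candidates in
which mode is left to the user's interpretation downstream. An exhaustive
enumeration of all admissible pairings is the oracle for the aligner.

## Degradome validation

Degradome (PARE) tags are 5' ends of uncapped RNA fragments; a sharp tag
peak at the base paired to miRNA position 10 is direct evidence of guided
cleavage. `map_tags()` places each tag's 20-nt 5' prefix at every exact
sense-strand match, splitting multi-mapping tags 1/k across their k
positions (degradome tags are short and high quality, so exact prefix
matching replaces alignment). `validate_sites()` turns a predicted site
into a `CleavageEvent` iff the tag abundance at the predicted position is
positive, and classifies it:

| category | rule (x = abundance at the site) |
|---|---|
| 0 | x > 1, equals the transcript maximum, maximum unique |
| 1 | x > 1, equals a shared maximum |
| 2 | x > 1, below the maximum but above the median |
| 3 | x > 1 and at most the median |
| 4 | x <= 1 (fractional multi-map weights classify here) |

The median is taken over positions with at least one tag, the common
degradome-tool convention (configurable). An independently coded
classifier is the test oracle. A binomial enrichment p-value (>= observed
count at one position under a uniform null) is attached for reference
only and is never used as a filter. Degradome libraries are pooled across
conditions per tissue, so degradome evidence is treated as
condition-agnostic. `tplot_table()`/`plot_tplot()` emit the per-position
T-plot surface with validated sites flagged.

## Network assembly

`build_network()` assembles one network per tissue; tissues are processed
independently. Nodes are DE features only. An edge miRNA -> ceRNA is
retained iff:

a. a predicted site exists (cleavage or mimic, recorded on the edge);
b. Pearson correlation between the miRNA and the ceRNA, computed on
   log2(normalized abundance + 10^-6) over the six within-tissue samples,
   is <= -0.7;
c. (optional, on by default) at least one other retained ceRNA of the
   same miRNA correlates with it at >= +0.7 — the competing-pair
   condition that encodes the expected sign structure of a functioning
   ceRNA module: ceRNAs positively correlated with each other, each
   negatively with the shared miRNA.

With n = 6 samples, rank correlations are too coarse, hence Pearson; the
0.7 default is a documented design choice, exposed as `r_threshold`, not
a claim about any particular published analysis. Constant series have
undefined correlation and are flagged and excluded rather than filtered.
Degradome-verified edges are flagged; node attributes carry feature class
and DE direction. `negative_pairs()` produces the companion table of
(DE miRNA, DE mRNA) cleavage-target pairs with opposite directions and a
Y/N degradome flag, and the package ships a transcribed 33-row published
reference table of such pairs whose marginals (16 leaf, 17 root, 11
degradome-confirmed) the test suite and acceptance script recompute.
Networks export losslessly to GraphML (via igraph) and TSV.

## The synthetic generator

`simulate_cerna_study()` builds, deterministically under a seed: a random
two-chromosome genome; mRNAs with planted ORFs >= 300 nt across 1-3 exons
on both strands; lncRNAs of 200-1000 nt rejection-sampled to ORF < 300;
circRNAs of all three locus types; 21-nt (5' U) and 24-nt (5' A) miRNAs;
one cleavage site per miRNA written into an mRNA 3' UTR (exact reverse
complement with 0-1 planted mismatches outside positions 10-11, written
back into the genome so sequence extraction stays consistent); mimic
sites (reverse complement with a 1-4 nt bulge between the bases paired to
positions 10-11) in lncRNAs and one intergenic circRNA; NB count matrices
with planted DE; and a degradome table with `peak_reads` tags at each
planted cleavage position over Poisson background.

Study conditions (the generator defaults) and the reasoning behind the
genuinely open choices:

* 2 tissues x 2 conditions x 3 replicates; 30 mRNAs, 15 lncRNAs, 5
  circRNAs, 20 miRNAs, 8 ceRNA triplets; library size 10^6; NB dispersion
  0.1 (no noise model is dictated by real libraries, so a single shared
  dispersion — the simplest model under which fixed DE cutoffs are
  meaningful — is used and documented as a stand-in); degradome peaks of
  50 reads over 0.01 background.
* Planted DE is |log2FC| = 2 for ordinary features. Triplet members are
  planted at |log2FC| = 4 with a small shared per-sample latent factor
  (sd 0.25 log2; ceRNAs load +1, the miRNA -1). The correlation filter
  operates on n = 6 samples, where the sampling noise of Pearson r is
  large: a design analysis shows that at separation 2 a genuinely planted
  correlation fails the |r| >= 0.7 filter in several percent of cases,
  while at separation 4 the failure rate is ~10^-4. The stronger planting
  keeps "planted correlation" meaningful under the default filter and is
  well within fold changes reported for strongly stress-responsive
  miRNAs and transcripts.
* Planted directions alternate out of phase with tissue so each tissue
  receives a balanced mix of up- and down-planted features; size-factor
  normalization assumes most features are unchanged, and a 50-feature
  transcriptome makes that assumption fragile enough without adding a
  systematic per-tissue skew.
* Correlation is induced structurally — condition effect plus the shared
  latent factor on the means — never by post-hoc shaping of realized
  counts, so counts stay integer and marginally NB.

What the generator does *not* emulate: read-level sequencing (no FASTQ,
no error model, no adapters), alignment and assembly artifacts,
transcript-length biases in FPKM, isomiR heterogeneity, cross-feature
correlation beyond the planted triplets, and real genomic base
composition. Passing recovery tests therefore demonstrates the *logic* of
the pipeline — filters, scoring rules, category tables, network
conditions — on data satisfying its assumptions, not performance on real
libraries.

## Numerical choices and degenerate inputs

* Genomic coordinates are 1-based inclusive everywhere (GFF convention);
  transcript positions are 1-based from the 5' end; all pairing logic is
  in RNA space, with conversion at the I/O boundary.
* Ties at cutoffs: p < alpha strict; gene-like |log2FC| > 1 strict;
  miRNA fold change >= 1.5 inclusive — mirroring the usual phrasing of
  each rule.
* Alignment tie-breaks: leftmost bulge insertion point, then shortest
  bulge; overlapping cleavage windows keep the best score per cleavage
  position.
* Zero totals (empty libraries) and missing replicates are errors; empty
  DE sets produce an empty network with a warning, not an error;
  constant expression series are flagged undefined rather than
  correlated.
* The coding-potential rule treats an AUG with no in-frame stop as an
  ORF running to the last complete codon.
* Test problem sizes: five synthetic studies (seeds 1-5) for recovery
  properties; 2000 null features for type-I calibration (4000 in the
  acceptance script); 20 seeds x 100 features for power; 100 random
  duplexes, 1000 random degradome profiles and a 15x20 feature grid for
  the oracle-equivalence checks. These sizes give stable Monte-Carlo
  estimates while keeping the default suite quick.

## Known limitations

* The DE test is mildly anti-conservative (empirical type-I ~0.07 at
  alpha 0.05) because 3-replicate moment dispersion estimates are noisy
  even after shrinkage; analyses needing strict error control should use
  the relaxed/strict thresholds as screens, as the fixed-cutoff design
  intends.
* The coding-potential and hairpin stand-ins are deliberately simple;
  both accept external results (a coding table; a different
  `min_pairing`) where stronger tools are available.
* Cleavage scoring constants are a documented parameterization, not a
  reimplementation of any specific published tool.
* Degradome evidence is condition-agnostic because libraries are pooled
  per tissue; condition-specific validation would be more informative but
  is not representable in this design.
* With n = 6, the correlation filter is a coarse screen; r_threshold
  trades sensitivity against false edges and should be reported with any
  downstream result.
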