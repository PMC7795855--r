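# plantcerna

Inference of competing endogenous RNA (ceRNA) networks from plant
whole-transcriptome profiles, for researchers studying how mRNAs, lncRNAs,
circRNAs and miRNAs jointly respond to a stress contrast (control `ck`
versus treated `st`, two tissues, three replicates).

Under the ceRNA hypothesis, transcripts sharing miRNA response elements
compete for a common miRNA pool, so a lncRNA or circRNA can de-repress an
mRNA by sequestering their shared miRNA. The package implements the full
inference chain:

* **Differential expression** — FPKM/CPM quantification and a
  negative-binomial exact test on per-group summed, median-of-ratios
  normalized counts, with per-feature moment dispersion shrunk 50/50 to
  the across-feature median. Fixed cutoffs: p < 0.05 and |log2FC| > 1 for
  gene-like features, p < 0.05 and fold change ≥ 1.5 for miRNAs, plus a
  relaxed p < 0.1 re-filtering mode.
* **Annotation** — lncRNA identification (≥ 200 nt, no same-strand mRNA
  exon overlap, longest ORF < 300 nt), circRNA locus typing
  (exon/intron/intergenic), 100-kb cis-target pairing, and a known/novel
  miRNA catalogue (≤ 3 mismatches to a reference mature, or an exact
  genomic locus whose ±200-nt window folds into a stem-loop).
* **Target prediction** — antiparallel duplex scanning in two modes.
  Cleavage: penalty ≤ 4 (mismatch 1, G:U 0.5, doubled at positions 2–13)
  with Watson–Crick pairing required at positions 10–11. Target mimicry:
  exactly one 1–4 nt target-side bulge between the bases paired to miRNA
  positions 9–11, at most 4 non-middle mismatch units, no run of > 2
  mismatches. circRNAs are scanned circularly across the back-splice
  junction.
* **Degradome (PARE) validation** — exact-prefix tag mapping with 1/k
  multi-map splitting, cleavage-site categories 0–4 relative to the
  transcript's maximum and covered-position median, and T-plot tables.
* **Network assembly** — per tissue, edges miRNA → ceRNA kept when a site
  exists, Pearson r on log2(normalized + 1e-6) over the six samples is
  ≤ −0.7, and (optionally) some competing ceRNA of the same miRNA
  correlates at ≥ +0.7; degradome-verified edges flagged; GraphML/TSV
  export; negative miRNA–mRNA pair tables.
* **Synthetic data** — a deterministic generator
  (`simulate_cerna_study()`) that emits genome, annotations, miRNAs with
  planted cleavage/mimic sites, counts with planted DE and correlation
  structure, degradome peaks, and a truth table, so every stage has a
  planted-truth recovery test.

See the methods vignette (`vignettes/plantcerna-methods.Rmd`) for the
model, parameter rationale and limitations.

## Worked example

```r
library(plantcerna)

study <- simulate_cerna_study(seed = 1)
study
#> cerna_study (seed 1): 30 mRNA, 15 lncRNA, 5 circRNA, 20 miRNA;
#> 20 planted cleavage sites, 8 mimic sites, 8 ceRNA triplets

results <- run_cerna_pipeline(study)
glance(results$networks$root)
#> # A tibble: 1 × 10
#>   tissue n_nodes n_mirna n_mrna n_lncrna n_circrna n_edges n_degradome_verified
#> 1 root        12       4      4        3         1       8                    4

tidy(results$networks$root)
#> # A tibble: 8 × 7
#>   mirna_id cerna_id   cerna_class tissue      r mode     degradome_verified
#> 1 mir002   lnc002     lncRNA      root   -0.919 mimic    FALSE
#> 2 mir002   mrna002.t1 mRNA        root   -0.983 cleavage TRUE
#> 3 mir004   lnc004     lncRNA      root   -0.967 mimic    FALSE
#> 4 mir004   mrna004.t1 mRNA        root   -0.946 cleavage TRUE
#> ...
```

Each root-tissue miRNA hub connects its cleaved mRNA target
(degradome-verified, solid edge in `autoplot()`) and its sponge lncRNA or
circRNA (mimic mode): the two ceRNAs of each hub correlate positively
with each other and negatively (r ≤ −0.7) with the miRNA, which is the
ceRNA signature the network filter screens for. `results$negative_pairs`
lists DE miRNA–mRNA cleavage pairs with opposite directions and a Y/N
degradome flag, and the packaged published reference table of such pairs
reproduces its printed marginals:

```r
negative_pair_marginals(read_negative_pair_table())
#> # A tibble: 1 × 3
#>   n_leaf n_root n_degradome_confirmed
#> 1     16     17                    11
```

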