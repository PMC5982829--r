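---
title: "Screening for putative cis-regulatory lncRNA/coding gene pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for putative cis-regulatory lncRNA/coding gene pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cispair)
```

## The screening problem

Long non-coding RNAs (lncRNAs) can regulate nearby protein-coding genes in
*cis* — classic examples include antisense transcripts that silence their
overlapping partner and lncRNAs that recruit chromatin modifiers to a locus.
Across a large tumor cohort, a lncRNA that represses a neighboring coding
gene should show a *negative* expression correlation with it within each
cancer type. Negative correlations are the interesting signal here: positive
correlations between close neighbors arise generically from shared chromatin
domains and transcriptional ripple effects, which is why closely spaced
coding/coding pairs show the same positive skew.

`cispair` implements this screen end to end:

1. **Pairing.** Every coding gene is an anchor; every lncRNA (and, as a
   control, every other coding gene) whose span falls within a window of
   25/50/100 kb of the anchor span forms a pair. Orientation is classified
   into six geometric classes (antisense/sense overlap, divergent, convergent,
   sense upstream/downstream). Same-strand lncRNAs within 5 kb of a coding
   gene are flagged as likely alternative-polyadenylation (APA) artifacts —
   un-annotated 3' extensions of the coding transcript — and excluded.
   A within-chromosome shuffle of gene placements provides the randomized
   baseline for proximity statistics.
2. **Per-cancer screen.** Counts are CPM-normalized per sample (plain
   library-size scaling, no TMM — the screen is rank-based, so any
   per-sample monotone scaling choice is immaterial to rho). Genes with
   ≥ 1 CPM in ≥ 3 samples of a cancer type are testable there. For each pair
   and cancer type, Spearman's rho is computed across samples, with
   Benjamini–Hochberg adjustment within each
   (cancer type × partner class × window) family and significance at
   adjusted *P* < 1e-5. No threshold is placed on rho itself: with hundreds
   of samples per cancer type, a stringent *P* cut-off retains weakly but
   consistently correlated pairs whose expression is also shaped by somatic
   mutations and copy number.
3. **Set construction.** A pair whose rho is negative in the majority of its
   testable cancer types and significantly negative in at least one becomes
   part of the LCN set (lncRNA/coding negative) or CCN (coding/coding);
   LCP/CCP are defined symmetrically. Significant correlations of the
   opposite sign do not veto membership — a pair can be repressed in some
   tissue contexts and co-activated in others.
4. **Characterization.** Candidate sets are profiled by Tau expression
   specificity, exonic sequence conservation, gene-category enrichment,
   subcellular localization (RCI), and coupling between lncRNA expression
   and coding-promoter methylation.

## Statistics and numerical choices

**Spearman rho and its p-value.** rho is the Pearson correlation of midranks;
the two-sided p-value uses the t-approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\) degrees of freedom, which is
accurate at the cohort sizes the screen targets (hundreds of samples). A
perfect correlation returns the numeric floor rather than zero. Pairs with
fewer than 10 samples, or with constant expression, are skipped — rank
p-values below that size are unstable.

**Majority rule.** "Majority of cancers" is counted over *testable* cancer
types (both genes pass the expression filter), not over the whole cohort: a
pair unexpressed in a cancer type cannot vote either way.
`label_pairs(majority = "all")` provides the stricter whole-cohort
denominator.

**BH families.** The family choice is per cancer type, per partner class,
per window, matching the per-cancer presentation of the results;
`screen_pairs(family = "global")` collapses this to one family per partner
class and window.

**Tau.** For a profile of per-cancer-type mean CPM values
\(x_1,\dots,x_n\), \(\tau = \sum_i (1-\hat x_i)/(n-1)\) with
\(\hat x_i = x_i/\max_j x_j\). Tau is 0 for a flat profile and 1 when exactly
one group is nonzero, in both raw-CPM and (default) `log2(x+1)` modes; the
log mode is the standard choice because raw CPM lets a single dominant
tissue mask graded expression elsewhere. Tau is undefined (an error) for
all-zero profiles and for fewer than two groups; `tau_table()` reports `NA`
there.

**Conservation.** The per-gene score is the base-weighted mean of a per-base
track over the union of the gene's exons; bases without track coverage score
0 but stay in the denominator. For lncRNAs, bases shared with any coding exon
are subtracted first, so that a lncRNA overlapping a conserved coding exon is
not credited with the coding gene's constraint.

**Promoter methylation.** Among a coding gene's TSS probes (`TSS200` ∪
`TSS1500`), the probe with the highest mean beta within the cancer type
represents the TSS (ties break to the lexicographically smaller probe id;
the alternative readings of "maximum value" — per-sample maximum or maximum
variance — were considered and rejected as less stable). The coupling
statistic is Spearman's rho between lncRNA CPM and that probe's beta over
matched samples, BH-adjusted per cancer type at 0.05; a pair is *positively
coupled* when rho > 0 in the majority of its testable cancer types, the
signature of repression via promoter methylation (lncRNA up → methylation
up → coding gene down).

**Intervals.** All coordinates are 0-based half-open (BED convention); GTF
input is converted on read. Window pairing admits a partner when its span
intersects the anchor span extended by the window on both sides, i.e. when
the boundary gap is strictly smaller than the window; overlapping spans pair
at distance 0. The shuffle null redraws each gene's start uniformly within
its chromosome, keeping length and strand, and permits overlaps (a
rejection-sampling no-overlap mode exists but is off by default, matching
the behavior of the standard interval-shuffling tools).

## The synthetic cohort

Real inputs for this screen are a multi-thousand-sample tumor compendium, a
reference gene annotation, a conservation track, 450K methylation arrays and
a localization atlas. The generator in `sim_config()`/`simulate_cohort()`
emulates all of them at desk scale with a ground-truth manifest, so every
stage is testable without downloads.

Default study conditions: 3 chromosomes × 10 Mb; 300 coding + 300 lncRNA
genes; 4 cancer types × 200 samples; 40 planted repressor pairs (half
methylation-mediated) at a target population Spearman of −0.5; 60
shared-domain positive pairs; 20 APA decoys; 10 distal (> 100 kb) negative
controls; 40 single-cancer-specific genes; 15 cell lines in the RCI table.

Counts are negative binomial with gene dispersions in 0.1–0.4 (TCGA-like
overdispersion — a Poisson model would make the screen's p-values look
better than they are on real data) and log-normal library factors. Each
planted pair shares a per-sample standard-normal latent activity \(z\):
the lncRNA's log-mean gains \(+\gamma z\) and the coding gene's
\(-\gamma z\) (repressors), or both gain \(+a z\) (shared-domain pairs).
For mediated repressors the coding gene's TSS-probe betas gain
\(+\delta z\) on the logit scale, producing the lncRNA-up/methylation-up/
coding-down signature. The loadings (\(\gamma = a = 0.57\),
\(\delta = 0.5\)) were calibrated once by simulation against the realized
median pair Spearman; the calibration curve ships at
`inst/extdata/gamma_calibration.tsv` and a test re-simulates one point of it.

What the generator does **not** emulate: batch structure, tumor purity,
copy-number and mutation effects on expression, distance-decaying chromatin
domains spanning many genes, and isoform-level structure. Passing the
recovery tests therefore demonstrates that the pipeline's inference machinery
is correct under its stated noise model — not that real-tumor confounders
are handled.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg, "cohort")
pc <- pipeline_config(
  gtf = cohort$paths$gtf, cohort_index = cohort$paths$cohort_index,
  chrom_sizes = cohort$paths$chrom_sizes,
  conservation = cohort$paths$conservation,
  meth_index = cohort$paths$meth_index,
  probe_manifest = cohort$paths$probe_manifest,
  rci = cohort$paths$rci, seed = 1)
run <- run_all(pc, "results")
print(run)
evaluate_recovery(run, cohort$truth)
```

On the default conditions the run recovers all 40 planted repressors as LCN
with no false discoveries, and flags all 20 mediated repressors as
positively methylation-coupled (these numbers are recomputed by the
acceptance suite; see `tests/testthat/test-acceptance.R`).

## Test problem sizes

The suite exercises: oracle equivalence of window pairing against an O(n²)
scan on 500 genes; Spearman against a brute-force midrank-Pearson oracle on
200 random vectors; BH against an independent step-up; Fisher's exact test
against exhaustive hypergeometric enumeration on small-margin tables;
conservation against a per-base loop. Parameter recovery runs the full
default cohort (4 × 200 samples); null calibration runs 20 reduced
all-independent cohorts (60 + 60 genes, 2 × 100 samples) and requires an
empty LCN set in ≥ 95% of seeds. These sizes were chosen as the smallest
that give the recovery and calibration checks adequate power.

## Known limitations

* Correlation is not causation twice over: an LCN label is a hypothesis
  about *cis*-regulation, and even a planted-data-perfect pipeline inherits
  every confounder of correlational screens on real tumors (shared
  regulators, copy-number co-variation, purity).
* The distance between genes is measured between span boundaries, not TSSs;
  promoter-centric analyses may prefer TSS distances.
* The screen is gene-level; antisense pairs with isoform-specific overlap
  are treated by their merged gene spans.
* `read_gtf()` expects the GENCODE attribute dialect (`gene_id`,
  `gene_type`/`gene_biotype`); the biotype-to-class mapping is configuration
  (`default_biotype_map()`), because annotation releases disagree on which
  biotypes constitute the lncRNA class.
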