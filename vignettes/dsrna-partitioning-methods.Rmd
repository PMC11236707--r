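---
title: "Methods: sense-antisense dsRNA formation and nucleo-cytoplasmic RNA partitioning"
author: "dsRNAtools"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsRNAtools)
```

# Scope and rationale

In budding yeast, many mRNAs have an overlapping antisense long non-coding
RNA (asRNA) transcribed from the opposite strand. When both strands are
present they can hybridize into a double-stranded RNA (dsRNA), and dsRNA
formation is associated with preferential nuclear export: transcripts prone
to duplex formation accumulate in the cytoplasm. `dsRNAtools` implements the
computational side of this analysis as a reusable pipeline:

1. **Pairing** — identify opposite-strand sense-antisense transcript pairs
   from a stranded annotation (mRNA plus the yeast lncRNA classes SUT, CUT,
   XUT).
2. **Enrichment statistics** — per-transcript compartment enrichment from
   strand-specific counts with a negative-binomial (NB) Wald test and
   Benjamini-Hochberg (BH) correction, for three contrasts: cytoplasmic
   fraction vs total lysate, dsRNA-specific J2 immunoprecipitation eluate vs
   unbound, and stress vs control.
3. **Classification** — three-way nucleo-cytoplasmic distribution calls,
   J2 enrichment calls, ten RNAi-seq dsRNA-propensity groups, and the
   ssRNA/dsRNA validation-target rules.
4. **Coverage, structure, imaging** — percentile-binned gene-body coverage
   profiles by lncRNA class, differential dimethyl-sulfate (DMS) reactivity
   between strains, and smFISH nuclear/cytoplasmic signal arithmetic.
5. **Integration** — the summary quantities that tie the layers together
   (distribution percentages by biotype, propensity-localization rank
   correlation, asRNA-ratio localization bins, stress co-induction
   percentage, and the export-receptor footprint arithmetic).

Because the primary datasets of such a study are large sequencing
experiments, the package ships a synthetic-data generator with known ground
truth so every stage — and the recovery of the latent quantities — is
testable end to end at desk scale.

# Sense-antisense pairing

Transcripts are stranded genomic intervals (0-based half-open internally;
GTF input is converted on read, BED passes through). Multi-exon features are
collapsed to their genomic span: the analysis operates on transcript-level
coordinates, not exon structure.

A pair is emitted when an mRNA and an opposite-strand partner on the same
chromosome overlap by at least a minimum *overlap fraction* (default 0.5,
inclusive). The fraction's denominator is genuinely ambiguous in
BEDTools-style overlap filters; we resolve it as **the antisense
transcript's length** because asRNAs are typically the shorter partner and
the pairing question is asRNA-centric ("how much of this asRNA can base-pair
with its mRNA?"). `find_pairs(denominator=)` switches to sense-relative,
either-qualifies, or reciprocal conventions.

For class-level analyses, SUTs/XUTs/CUTs are kept only when they do not
overlap a transcript of a *different* lncRNA class on the same strand; both
members of a conflicting overlap are dropped. We read "other types" as the
lncRNA classes only — an mRNA overlap does not disqualify a lncRNA, since
mRNA overlap is the defining feature of an asRNA.

# The NB Wald enrichment test

Counts $K_{ij}$ are normalized by median-of-ratios size factors $s_j$
(median over reference rows of $K_{ij}$ divided by the row geometric mean,
rescaled to geometric mean 1). For a two-condition contrast with per-gene
per-condition means $\mu_1, \mu_2$ and NB variance $\mu + \alpha\mu^2$:

* $\log_2\mathrm{FC} = \log_2(\hat\mu_1/\hat\mu_2)$,
* $\mathrm{SE}^2 = \left[\left(1/\hat\mu_1 + \hat\alpha\right)/n_1 +
  \left(1/\hat\mu_2 + \hat\alpha\right)/n_2\right]/(\ln 2)^2$
  (delta method on the NB Fisher information),
* Wald $z = \log_2\mathrm{FC}/\mathrm{SE}$, two-sided p from the standard
  normal, BH adjustment across tested transcripts.

This is a deliberately minimal pipeline — no fold-change shrinkage and no
independent filtering — so its guarantees are calibration-based rather than
a numerical match to any specific DE package (one of which is nevertheless
used as an independent cross-check in the test suite).

**Dispersion moderation.** Gene-wise method-of-moments dispersion estimates
pooled within condition have only $n_1+n_2-2 = 4$ residual degrees of
freedom at the default 3 vs 3 design; plugging them raw into a
normal-reference Wald statistic produces a $t_4$-like null and a ~12%
rejection rate at nominal 5%. We therefore moderate each gene-wise estimate
toward the across-gene mean with prior weight $d_0 = 10$:
$\tilde\alpha_g = (d_0\bar\alpha + 4\,\hat\alpha_g)/(d_0 + 4)$,
which restores the empirical type-I error to ~0.05 (verified in the
acceptance suite on a 2000-gene null across five seeds). `nb_wald_test`
also exposes `dispersion = "gene"` (raw) and `"common"` (one pooled value).
Negative moment estimates floor at the Poisson limit and all dispersions at
$10^{-8}$.

**Degenerate inputs.** When a condition's fitted mean is exactly zero, a
pseudo-mean of 0.5 normalized counts is substituted for that condition only
and the transcript is flagged (`zero_guard`); the log2 fold change stays
finite. Low-count filtering keeps transcripts whose mean raw count across
the contrast's samples is strictly above 40, applied per contrast (the
filter's scope is not fixed by convention; per-contrast keeps each
comparison self-contained).

# Classification rules

* **Distribution calls:** cytoplasmic if `padj < alpha` and
  `log2fc > lfc_min`; nuclear if `padj < alpha` and `log2fc < -lfc_min`;
  otherwise not significant. Defaults `alpha = 0.05`, `lfc_min = 0` (no
  fold-change cut-off beyond significance). The same rule with labels
  enriched/depleted serves the J2 eluate-vs-unbound contrast; "J2-enriched"
  means `padj < 0.05` and `log2fc > 0` there.
* **Propensity groups:** the log2(RNAi/WT) density ratio is binned into ten
  groups $-5..-1, 1..5$; positive group $k$ covers $[k-1, k)$ with group 5
  open-ended above 4, mirrored on the negative side. The labels skip 0 but
  the values do not: a ratio of exactly 0 falls in group 1 by the half-open
  convention (configurable in the sense that the boundary behaviour is a
  documented property of `floor`).
* **Validation targets:** dsRNA targets need asRNA RPKM above the mRNA's,
  a positive propensity group, and J2 enrichment; ssRNA targets need an
  asRNA below 1:100 of the mRNA, a negative group, and no J2 enrichment.

# Coverage profiles, DMS deltas, smFISH arithmetic

Gene bodies are split into 100 equal-width bins in transcript orientation
(reversed for minus-strand features); the bin value is the mean per-base
depth. Transcripts shorter than the bin count sample a representative base
per bin (bases repeat; documented, not an error). Aggregates are bin-wise
means per class after excluding same-strand overlapping features among the
aggregated classes, then max-normalized (`sum`/`none` available).

The DMS structural-change score is the mutant minus wild-type summary of
per-nucleotide reactivity. The upstream description mixes "summed" and
"average"; we default to the **mean** because raw sums scale with transcript
length and would confound the per-group comparison, and expose
`stat = "sum"` for the literal reading.

smFISH measurements follow the imaging convention: corrected signal =
integrated density − area × mean(background readings); negative corrected
signals are kept and flagged rather than clamped. The cytoplasmic signal is
total − nuclear; the reported total is reconstructed as nuclear +
cytoplasmic so that conservation holds bit-exactly (the reconstruction can
differ from the measured corrected total by one floating-point ulp).

# Integration summaries

Spearman correlations use mid-ranks (average ranks on ties). The
asRNA-ratio localization summary bins mRNAs by asRNA:mRNA expression ratio
with decade edges $0, 0.01, 0.1, 1, \infty$ — not fixed by any convention,
so chosen as the natural decades around the "equal or higher" boundary at
ratio 1 — plus a dedicated `no_asRNA` bin; the statistic per bin is the mean
cytoplasm:total log2 fold change. The stress summary takes mRNAs
significantly up in stress whose paired asRNA is significantly changed, and
reports the percentage with asRNA log2FC > 0; "significantly changed"
reuses the global `alpha`.

The export-receptor footprint converts a titration observation into a
window length: a substrate of length $L$ saturated at $E$-fold molar excess
binds one heterodimer per $L/E$ bases, so a window holding $u$ units spans
$\lfloor u \cdot L / E \rfloor$ bases. With the published inputs (36-bp
duplex saturated at 10-fold excess) this gives two heterodimers per 7 bp of
dsRNA, versus one per 7 nt of ssRNA (36 nt, 5-fold excess):

```{r footprint}
binding_footprint(36, 10, 2)
binding_footprint(36, 5, 1)
```

# The synthetic-data generator

`simulate_annotation` places mRNAs (500-2000 bp) on alternating strands of
one linear chromosome, with inter-gene gaps sized so that asRNA overhangs
never touch a neighbouring gene. With probability `p_antisense` (default
0.5) an mRNA gets an opposite-strand asRNA anchored at its 3' end —
initiating downstream of the gene and running antisense into the gene body —
with class weights favouring XUT (0.5/0.3/0.2 for XUT/SUT/CUT) and an
overlap fraction of its own length drawn from `overlap_fraction_range`
(default [0.5, 1], so every generated asRNA is recoverable at the default
pairing threshold).

`simulate_experiment` then draws, per transcript:

* true mean expression $\mu$, log-normal (default median 200, sdlog 1);
  asRNA means are the sense mean times a log-normal ratio with **median**
  `asrna_ratio_mean` (default 0.1 — asRNAs about 10-fold lower, the
  empirical regime that motivates the asymmetry between strands);
* duplex propensity $\pi_{ds} = \min(1, \mu_{partner}/\mu_{own}) \cdot
  f_{overlap}$, and 0 for unpaired transcripts. The molar-ratio bound is
  applied per strand: an asRNA 10-fold below its mRNA can be almost fully
  sequestered in duplex while only ~10% of the mRNA is — which is exactly
  the asymmetry the J2 experiments exhibit (most asRNAs enriched, a
  minority of mRNAs);
* cytoplasmic fraction $f_{cyto} =
  \mathrm{logistic}(\mathrm{logit}(f_0) + \delta\,\pi_{ds})$ with baseline
  $f_0 = 0.4$ and coupling $\delta = 2$ (a latent, deterministic link — the
  generator's ground-truth invariant);
* counts $\sim \mathrm{NB}(\ell_j \mu w, \alpha)$ with dispersion
  $\alpha = 0.05$ (typical bulk RNA-seq biological variability), three
  replicates per condition, per-sample library factors from
  `library_size_range`, and condition weights $w$: 1 (total), $f_{cyto}$
  (cytoplasm), $\pi_{ds}$ (J2 eluate), $1-\pi_{ds}$ (J2 unbound);
* a stress condition in which 20% of mRNAs are induced
  (log2FC $\sim N(2, 0.5)$) and their asRNAs co-induced with probability
  0.95 (repressed otherwise) — emulating the coordinated stress response of
  both strands;
* RNAi/WT densities with $\log_2(\mathrm{RNAi/WT}) = 5\,\pi_{ds} +
  N(0, 0.75)$, spanning the ten propensity groups;
* per-nucleotide DMS reactivities, wild type $\sim \Gamma(1, 2)$ and mutant
  $= \mathrm{wt} + 0.3\,\pi_{ds} + N(0, 0.05)$ clamped at 0 — more duplex,
  more nucleotides freed when the duplex is resolved;
* strand-specific coverage: uniform body coverage $\propto \mu$ plus
  duplex-proportional extra coverage over the overlap region (degradation
  products concentrate where the duplex forms).

All draws flow from the single configured seed (the caller's RNG state is
saved and restored), so identical configurations are byte-identical on
disk.

**What the generator does not emulate.** Read-level artifacts (GC bias,
positional bias, multimapping), exon structure and splice isoforms,
chromosome structure beyond one linear contig, transcript-intrinsic
localization variation beyond the duplex coupling, and the single-cell
co-occurrence layer. Passing recovery tests therefore demonstrates that the
statistical machinery recovers the latent structure it assumes — not that
real libraries satisfy those assumptions.

# Problem sizes and runtime choices

The test suite runs the null-calibration check at 2000 genes × 5 seeds, the
power check at 2000 genes (500 enriched), the recovery property at the
default 500 genes across seeds 1-10, and the brute-force pairing oracle on
100 random annotations of 100-1000 transcripts — sizes at which every
property is measurable with comfortable margin on a single CPU. The power
check supplies unit size factors because its libraries are generated at
equal depth and a one-sided 25% enriched fraction would otherwise bias the
median-of-ratios normalization — a known limitation of median-based
normalization, not of the test.

# Known limitations

* The NB test supports one factor with two levels; no GLM designs.
* Dispersion moderation uses a single global prior weight, not an
  empirical-Bayes fit of the prior.
* Pairing is span-based; exon-aware overlap would change fractions for
  heavily spliced transcripts (irrelevant in yeast, where introns are
  rare).
* The generator's coupling of localization to duplex propensity is
  deterministic by construction; real transcripts have duplex-independent
  localization determinants, so real-data correlations will be lower than
  the synthetic recovery ceiling.
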