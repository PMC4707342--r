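---
title: "Methods: multi-omics discrimination of uterine leiomyosarcoma"
author: "myomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics discrimination of uterine leiomyosarcoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomics)
```

## The problem

Uterine leiomyosarcoma (LMS) is a rare, aggressive malignancy of the
myometrium that is hard to distinguish preoperatively — and sometimes
histologically — from the extremely common benign leiomyoma (LM).
`myomics` implements, as a tested and reusable pipeline, the array-based
multi-omics analysis that separates the two tumor types and normal
myometrium (NM) at the molecular level, on three axes:

1. **Chromosomal-abnormality burden** from SNP-array log R ratio (LRR)
   and B-allele frequency (BAF) tracks. Malignant samples carry extensive
   copy-number change and copy-neutral loss of heterozygosity (CN-LOH);
   benign samples carry little.
2. **Expression signatures and tissue-specific markers** from a
   four-group (NM/LM/LMS/cell-line) microarray comparison.
3. **Genome-wide DNA methylation** from 450K-style beta values:
   malignant samples are globally hypomethylated outside CpG islands and
   focally hypermethylated at polycomb-target-like promoters, and a
   two-sided beta filter yields candidate marker loci quantifiable by
   COBRA (combined bisulfite restriction analysis).

Every stage consumes plain probe-level TSV matrices. A synthetic-data
module generates all four modalities with planted, machine-readable truth
so that each stage — and the pipeline end to end — is testable without any
external download.

## CNV burden

### Model and segmentation

LRR is modelled per chromosome as a piecewise-constant signal plus
Gaussian noise. `segment_lrr()` minimises

$$\mathrm{RSS} + \lambda \cdot \#\{\text{breakpoints}\}$$

subject to every segment containing at least `min_probes` (default 2)
probes. The optimum is found *exactly* by an $O(n^2)$ optimal-partitioning
dynamic program over candidate previous changepoints. We deliberately
chose an exact program over a greedy binary-segmentation heuristic: it is
in the same piecewise-constant model class as the sparse-Bayesian CNV
callers used on real genotyping arrays, but its output provably equals an
exhaustive search over breakpoint placements, which makes the
segmentation oracle-checkable in the test suite (and it is, against full
enumeration on small tracks).

The penalty defaults to $10\hat\sigma^2$ with $\hat\sigma$ estimated
robustly from the median absolute successive difference of the LRR
($\hat\sigma = \mathrm{median}|\Delta x| / (0.6745\sqrt2)$), so that a
breakpoint must explain clearly more than noise-level variance. The
penalty is floored at a tiny positive value so that zero-noise input
yields exactly one segment per chromosome (ties between equal-cost
segmentations are otherwise possible at $\lambda = 0$).

### States, CN-LOH and the burden ratio

Segment states are called by strict LRR thresholds (`gain_t = +0.10`,
`loss_t = -0.15`; a segment exactly at a threshold stays neutral). The
thresholds are deliberately permissive so that mosaic events — whose LRR
shift is attenuated by the fraction of aberrant cells — are still caught.

CN-LOH is a BAF phenomenon at normal copy number: `detect_cnloh()` looks
for maximal runs of at least `min_run = 50` informative probes spanning
at least `min_span = 3` Mb in which no probe has BAF strictly inside the
heterozygous band (0.15, 0.85). Runs are searched only in copy-neutral
territory; the same BAF pattern inside a gain or loss is by definition
not copy-neutral. Adjacent neutral segments are merged into maximal
neutral extents before scanning — a neutral-to-neutral segmentation
boundary (which the penalized fit occasionally produces under noise) must
not break a genuine homozygous run in half and push both halves under the
span floor.

The per-sample **burden ratio** is the fraction of the probed autosomal
genome in an aberrant state: bp in gain-or-loss segments plus bp in
CN-LOH calls, over the per-chromosome first-to-last-probe extent, sex
chromosomes excluded. Intervals are probe-delimited and 1-based inclusive
internally; BED export converts to 0-based half-open.

## Expression markers

Raw intensities are quantile-normalized (every column gets the per-rank
mean of the input columns; ties share their rank mean), then
log2-transformed. The selection funnel mirrors standard microarray
practice, and every threshold is strict:

1. per-probe one-way ANOVA across the four groups, Benjamini–Hochberg
   step-up over all tested probes, keep $q < 0.05$;
2. keep probes with linear fold change $> 2$ or $< 0.5$ in LMS-vs-NM or
   LM-vs-NM (fold change is computed on linear-scale group means of the
   normalized intensities; "fold change" is a linear-scale quantity,
   so the linear reading was adopted);
3. drop probes without a gene symbol and collapse to one probe per
   symbol, keeping the largest $|\log_2 \mathrm{FC}|$ over the named
   contrasts (ties: lexicographically smaller probe id).

The row-wise F statistic is computed vectorised (between/within mean
squares); a row with zero between- and within-group variance is given
$p = 1$ by convention, and a perfectly separated row with zero
within-group variance $p = 0$.

**Tissue-specific markers** use the flag/intensity filter: a probe is
specific to a class $C$ of groups iff it is flagged present *and* has
normalized log2 intensity $> 6$ in every sample of every group in $C$,
and is flagged absent *or* $\le 6$ in every sample outside $C$. The exact
conjunction (AND inside, OR outside) is this package's declared
interpretation of a present/absent + intensity filter; it makes the
all-on probe set and the all-off probe set markers of no class.

**Per-sample DE counts** compare each non-reference sample to the mean
of the NM group (ratio $> 2$ up, $< 0.5$ down, strict). The "commonly
regulated" fraction of a group is the intersection of its samples' DE
probe sets over their union — the union denominator is the package's
choice where a Venn percentage would otherwise be ambiguous.

## Methylation analysis

Beta values follow the array convention
$\beta = M/(U + M + 100)$, bounded in $[0, 1)$ by the offset. QC removes
a probe when *any* sample has detection $P > 0.05$ or a blank beta; this
any-sample reading was chosen because a single genome-wide surviving
probe count shared by all downstream analyses is what a per-analysis QC
cannot provide.

Differential methylation between two groups is the difference of group
mean betas, $\Delta\beta$, with strict calls:
hyper iff $\Delta\beta > 0.2$, hypo iff $\Delta\beta < -0.2$. Calls are
tabulated against the manifest in two partitions — six gene feature
groups (TSS200, TSS1500, 5'UTR/first exon, body, 3'UTR, intergenic) and
three CGI relations (island, shore/shelf within 4 kb, open sea) — with
percentages over each category's QC-passed probe count. Because the
manifest assigns exactly one feature group (precedence TSS200 > TSS1500
> 5'UTR/first exon > body > 3'UTR > intergenic) and one CGI relation per
probe, category counts always sum to the grand total.

**Regions** bin two or more same-direction probes falling in the same
feature group of the same gene; the region spans the first to last member
probe. Region direction requires every member probe to individually pass
the $\Delta\beta$ threshold — the package bins already-classified probes
and does not reproduce any region-level test statistic.

**Marker selection** is two-sided and strict: $\beta > 0.6$ in every
sample of one group and $\beta < 0.1$ in every sample of the other.
`promoter_refine()` keeps genes with at least two passing probes in
TSS1500/TSS200 — the pattern of a promoter CpG island fully methylated in
one tumor type and unmethylated in the other, which is what a
bisulfite-PCR assay can interrogate cheaply.

`geneset_overlap()` reports the count and fraction of a reference gene
set (e.g. polycomb/SUZ12 targets) among differentially methylated genes.

## COBRA quantification

The methylation index converts band intensities to molar fractions
before forming the ratio, because a long fragment binds proportionally
more intercalating dye than a short one:

$$\mathrm{index} = \frac{\mathrm{cut}/246}
 {\mathrm{cut}/246 + \mathrm{uncut}/413} \times 100\,\%$$

with the 246 bp cut (methylated) and 413 bp uncut fragment lengths of
the LINE1 amplicon as defaults. The index is invariant to common
rescaling of both intensities. A standard curve fitted by ordinary least
squares to control mixtures (raw = slope × true + intercept) is inverted
to correct the raw index, clamping to [0, 100]. A linear curve was
chosen because bisulfite-PCR bias over a 0–100% ladder is smooth and a
two-parameter model can be inverted stably from the five-point ladders
typically run; nothing in the interface precludes refitting with more
points.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the package is validated under:

* **Design**: 3 NM + 3 LM + 3 LMS tissue samples, plus 3 cell lines.
* **SNP arrays**: 4 chromosomes × 800 probes at 10 kb spacing.
  Genotypes Hardy–Weinberg at allele frequency 0.5. LRR noise sd 0.15
  (typical post-normalization genotyping-array noise); BAF noise is a
  fifth of that, so a noiseless request is noiseless in both metrics.
  Full-clonality shifts +0.40 (gain) and −0.55 (loss), scaled by the
  mosaic fraction $f$; heterozygous BAF splits by $f/(4-2f)$ — an
  approximation shared between gain and loss that is exact for loss
  (at $f = 1$ it degenerates to the homozygous 0/1 split) — and CN-LOH
  re-draws a fraction $f$ of heterozygous probes from near 0/1 at
  unchanged LRR. The default planted burdens are 0.70/0.75/0.80 for the
  LMS samples and 0.01/0.04/0.08 for LM, inside the ranges the package
  is meant to discriminate.
* **Expression**: 4000 probes, baseline log2 ~ N(8, 1), per-cell noise
  sd 0.25; planted group-restricted fold changes (LMS: 250 probes ×4,
  150 probes ×0.3; LM: 60 ×3, 40 ×0.4; cell lines 80 ×3, scaled with
  matrix size) and planted on/off marker probes (45 LMS, 4 NM, 1 LM,
  4 NM/LM — the class sizes the marker filter is expected to produce).
  Flags are present exactly when raw log2 intensity exceeds 6, so
  absent flags co-occur with near-background intensity by construction.
* **Methylation**: manifest of 300 gene models × 14 probes; baseline
  beta drawn by CGI relation (islands Beta(2,8), shores Beta(5,5), open
  sea Beta(8,3) — the canonical 450K bimodality). Noise is additive
  Gaussian (sd 0.3) on the *logit* of the target beta, which keeps betas
  in range without truncation artifacts. M/U intensities are
  reconstructed so `compute_beta()` returns the noisy beta exactly.
  0.5% of cells get a failing detection P. The default scenario plants
  LMS hypomethylation graded by CGI class (−0.40 on 28% of open sea,
  −0.40 on 17% of shores/shelves, −0.35 on 4.6% of islands),
  island-promoter hypermethylation (+0.40) at a third of a 60-gene
  polycomb-like reference set, milder symmetric LM changes (3% / 2%),
  and two promoter marker genes forced to baseline 0.03 with +0.80
  planted in LMS and LM respectively.
* **COBRA**: true methylated fractions around 0.75 for NM/LM and
  0.45–0.55 for LMS, observed through a slope 0.9 / intercept 10 linear
  distortion with 1 percent-point band noise, plus a 0/25/50/75/100%
  control ladder under the same distortion.

One top-level seed drives everything; each generator and each sample
gets a deterministically derived child stream, so adding one modality
never perturbs another and identical configurations are byte-identical.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: scanner physics and batch effects; probe
cross-hybridization and SNP-in-probe artifacts; correlated noise along
the genome; subclonal mixtures beyond a single mosaic fraction per
segment; the empirical (rather than planted) correlation structure
between promoter methylation and expression; and real annotation
complexity (multi-gene probes are given a single feature by precedence,
by construction). Recovery rates measured here are upper bounds on real
data.

## Numerical choices and degenerate inputs

* Segmentation tie-breaks: the dynamic program takes the first argmin,
  and the penalty floor makes the single-segment fit strictly preferred
  on constant input. Tracks shorter than `2 * min_probes` are returned
  as one segment.
* ANOVA degenerate rows: $p = 1$ when both variance components vanish,
  $p = 0$ when only the within-group component does.
* Quantile normalization ties share their rank mean.
* Beta markers, fold changes, $\Delta\beta$, state thresholds: all
  strict inequalities; boundary values are excluded everywhere.
* Empty inputs: an empty track segments to an empty frame; an empty
  reference gene set, an empty sample, and a config referencing missing
  files are errors raised before any work is done.
* `correct_index()` clamps to [0, 100]; a raw index below the curve
  intercept maps to 0 rather than a negative level.

## Problem sizes

The default synthetic study (12 samples; 3,200 SNP probes per sample;
4,000 expression probes; 4,200 methylation probes) runs the full
pipeline in a few seconds. The test suite's simulation-based checks use
20 seeds for burden recovery (ten planted levels), 100 seeds for
breakpoint localisation, 200 random instances for the segmentation
oracle, and 20 seeds for the BH null control; these sizes give binomial
standard errors comfortably below the margins being asserted while
keeping the whole suite under a minute.

## Limitations

* The burden ratio depends on segmentation resolution near breakpoints
  (probe-delimited intervals); on real arrays with uneven probe spacing
  the bp-weighted and probe-weighted burdens can differ.
* No mosaic-fraction point estimation is attempted beyond the planted
  truth; BAF deconvolution of subclone mixtures is out of scope.
* The marker filters are exact threshold rules; they inherit the
  arbitrariness of the thresholds (intensity 6, beta 0.6/0.1) and
  different candidates appear under different settings, so all
  thresholds are configurable and echoed into the run log.
* Ontology/enrichment annotation of the exported gene lists and BED
  files is delegated to external tools; the package only produces the
  inputs those tools consume.
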