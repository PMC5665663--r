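---
title: "Depth-of-coverage CNV calling on targeted panels: models and design"
author: "panelcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-of-coverage CNV calling on targeted panels: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcnv)
```

# Scope and model

`panelcnv` detects whole-exon copy number variants (CNVs) from the
per-target mean depth of coverage (DOC) of a high-coverage targeted
sequencing panel. The motivating application is *LDLR* in familial
hypercholesterolemia, where a fifth of pathogenic alleles in some founder
populations are whole-exon deletions (most famously the ~15 kb
promoter–exon 1 French-Canadian deletion) and where clinical validation
against MLPA on 388 patients reported 38 carriers and perfect
sensitivity/specificity for the DOC approach.

The generative assumption is simple: on a panel sequenced to mean depth
$\mu$ (~300×), the coverage of sample $s$ at target $t$ is approximately

$$ d_{st} \approx \mu \cdot \ell_s \cdot g_t \cdot \frac{c_{st}}{2} \cdot
   \varepsilon_{st}, $$

where $\ell_s$ is a library-size factor, $g_t$ a target-specific capture
efficiency (dominated by GC content), $c_{st}$ the local copy number, and
$\varepsilon_{st}$ multiplicative noise. Everything in the workflow is
aimed at cancelling $\ell_s$ and $g_t$ so that the copy-number term is the
only systematic signal left.

## Matched reference selection

Controls are matched per test sample because $g_t$ drifts with capture
chemistry and batch: the best estimate of a sample's diploid expectation
is the samples that look most like it. The distance is the mean symmetric
absolute percent difference over targets,
$\mathrm{pd}(a,b) = \tfrac{100}{T}\sum_t |a_t-b_t| / \big((a_t+b_t)/2\big)$,
after scaling the candidate control onto the test profile by the median
depth ratio. Two properties motivated the pairwise scaling (rather than
cohort-level size factors computed over the whole pool): each control's
distance depends only on that pair, so enlarging the pool with poorly
matching controls can never reorder the existing ranking; and the
distance becomes purely a *shape* comparison, insensitive to sequencing
yield. The `k = 30` best controls are kept (pool of at least ~100
recommended); a mean percent difference above 20% flags the sample as
poorly matched. On this package's 19-target single-gene panel a carrier
of a large CNV (5+ targets) can legitimately trip the flag — a 5-target
heterozygous deletion alone contributes $5/19 \times 67\% \approx 18\%$ —
so the flag is advisory run metadata, never a reason to suppress a call.

## Normalization

*Library size.* Median-of-ratios factors against a geometric-mean
pseudo-reference (the DESeq construction, computed over targets covered in
every sample), rescaled to median 1. The median makes the factor robust to
a CNV occupying a minority of targets, which total-count scaling is not.

*GC bias.* Targets are binned by GC fraction (bin width 0.05); each bin's
correction is the ratio of the bin's median control depth to the global
median control depth, estimated from the matched controls only and applied
to test and controls alike. Bins with fewer than two targets get no
correction. After division, every sample is rescaled to its pre-correction
median depth, so the correction reshapes the profile across GC without
touching overall depth. A binned-median curve was chosen over a smoother
(loess) because at 19–~2000 target panel scale it is transparent,
monotone-free, and directly testable; the simulator's bias is a smooth
unimodal factor peaking at GC 0.45, and on simulated biased cohorts the
binned correction reduces the regression slope of depth on GC by well over
five-fold (asserted in the test suite).

*Mappability.* No alignability track is computed; targets whose matched
controls show a coefficient of variation above 0.3 are down-weighted to
0.5, and a user-supplied weight file can force any weight in $[0,1]$,
with 0 excluding the target from evidence entirely. Control-cohort
variability is the observable consequence of poor mappability on capture
panels, which is why it serves as the proxy.

## Per-target metrics and the second anchoring pass

The two published evidence metrics are the ratio
$r_t = s_t / \overline{\mathrm{ref}_t}$ and the z-score
$z_t = (s_t - \overline{\mathrm{ref}_t}) / \mathrm{sd}(\mathrm{ref}_t)$
(sd with $n-1$; the test sample never enters the reference statistics).
Diploid targets sit at $r \approx 1$, heterozygous deletions at
$\approx 0.5$, duplications at $\approx 1.5$.

On a single-gene panel one correction proved necessary: a CNV spanning
several of the 19 targets drags the sample's median-of-ratios size factor
toward itself (the median is an order statistic; with 5 of 19 targets at
1.5× the median shifts several percent), deflating or inflating *every*
ratio. `targetMetrics()` therefore re-anchors: after a first pass, the
median ratio over diploid-looking targets ($|r-1| \le 0.15$, requiring at
least a third of the panel) rescales the sample, and metrics are
recomputed. This is the iterative-normalization idea standard in
exome-CNV callers, reduced to two passes. The residual limitation is
fundamental: an event covering most of the gene (beyond roughly
two-thirds of targets) would defeat any within-gene normalization; in
practice the panel this models carries 73 genes and normalizes across all
of them, and the largest published *LDLR* event spans 7 of 19 targets.

*VAF evidence.* Heterozygous-SNP allele fractions inside a target carry
orthogonal copy-number information: any site near 0.5 means both
haplotypes are present (evidence against deletion); sites near 1/3 or 2/3
are the balance of a het site on a triploid segment (evidence for
duplication). The bands — 0.40–0.60 "het", 0.25–0.40 and 0.60–0.75
"duplication-like" — are not published values; they were chosen once to
separate 1/2 from 1/3 and 2/3 under binomial sampling at the ≥20-read
site depth the extractor enforces (at depth 100 the standard deviation of
an observed fraction is ~0.05, so the band edges sit ~2 sd from both
hypotheses; at 300× panels most sites are far deeper).

## State assignment, segmentation, filtration

Per target the posterior over {diploid, het deletion, hom deletion,
duplication} is proportional to
$\pi_k \, \mathcal{N}(r_t \mid \mu_k, \sigma)^{w_t} \cdot v$, with
$\mu = (1, 0.5, 0.02, 1.5)$, emission sd $\sigma = 0.08$, priors
$\pi = (0.97, 0.015, 0.0025, 0.0125)$, target weight $w_t$, and VAF term
$v$ that divides both deletion states by 4 when the target's VAF class is
*against deletion* and multiplies the duplication state by 4 when it is
*supports duplication*. Choices worth recording:

* the homozygous-deletion mean is 0.02 rather than 0 so the Gaussian
  likelihood stays proper at nonzero noise;
* $\sigma = 0.08$ matches the ratio spread observed in the simulator's
  default regime (~6% coefficient of variation plus reference-mean
  noise) and keeps the diploid/het-del decision boundary near $r=0.70$
  once the priors are folded in — deliberately close to the published
  filtration threshold;
* the VAF multiplier 4 is a tunable surrogate for an unpublished
  weighting; it shifts borderline posteriors without overriding a clear
  coverage signal;
* the prior mass on non-diploid states (3%) reflects that even in an FH
  referral cohort any *given* target is overwhelmingly diploid.

Segmentation merges maximal runs of adjacent targets (panel indices
differing by exactly 1, same gene) sharing a non-diploid state. There is
no transition model and no bridging across a discordant or excluded
target: what the validation design actually gates on is the filtration
step, and run-merging keeps event boundaries exactly interpretable.
Event-level metrics are arithmetic means over the run, the convention
used in the published per-event table.

Filtration applies the published, mutually inclusive thresholds:
deletions pass iff mean ratio ≤ 0.7 **and** mean z ≤ −5.0; duplications
iff mean ratio ≥ 1.30 **and** mean z ≥ 5.0. A deletion event containing a
mid-band VAF site is demoted with reason `vaf_contradiction`. Duplications
are reported as "dup" without a copy-number estimate: at incrementally
higher copy numbers the expected ratios (2.0, 2.5, …) compress relative
to noise, so the degree of amplification is deliberately not inferred.

# The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions for every end-to-end result in the package:

* per-target total base coverage is negative binomial with mean
  $\mu \, \ell_s \, g_t \, (c_{st}/2) \, \ell en_t$ and dispersion 0.004
  (variance $= m + 0.004\,m^2$, i.e. ~6.3% CV at panel depths, Poisson as
  dispersion → 0) — the overdispersion typical of capture panels;
* library factors are lognormal with log-sd 0.1; the GC factor is
  $\exp(-b\,(gc_t-0.45)^2/(2\cdot 0.1^2))$ with default strength
  $b = 0.3$ shared across samples (a per-sample jitter is available);
* implants place copy number 0, 1 or 3 over contiguous label spans;
  duplications are simulated at CN = 3 only, mirroring the method's
  refusal to grade amplification;
* het-SNP VAFs are binomial at the realized target depth with expectation
  0.5 (diploid), 0 or 1 with equal probability (het deletion — one
  haplotype lost), or 1/3 / 2/3 (duplication); hemizygously silent and
  homozygously deleted targets emit nothing; density is Poisson with mean
  1 site per target;
* `table2Cohort()` reproduces the published validation design: 388
  samples of which 38 carry exactly the published event types and spans
  and 350 are diploid, plus a separately seeded 100-sample control pool.

The mean depth (300×), cohort size (388/350/38) and control-pool size
(>100) are the published study conditions; dispersion, library-size sd and
GC strength are not published and were fixed once at values a capture
panel at this depth plausibly shows — dispersion 0.004 in particular
gives per-target z-scores for heterozygous deletions centred near −8,
the middle of the published per-event range (−5.4 to −15.9).

What the simulator does **not** emulate: inter-target correlation beyond
the shared sample and GC factors (real batch structure is richer), probe
dropout, allele-specific capture bias, mosaic or fractional copy numbers,
and breakpoints (the panel sequences no introns, so events are whole-exon
by construction). Passing tests on simulated data therefore demonstrate
the pipeline's correctness and its behaviour under the *assumed* noise
model, not clinical performance on real libraries — the original
patient-level validation data are not public and are not reproduced here
except through the published per-event table and count summaries.

The MLPA arm simulates one normal control per seven study samples
(rounded up), three replicate measurements per sample (the assay is run
at least in duplicate in practice; three gives the Welch test stable
degrees of freedom), lognormal probe levels, 4% replicate noise and 10%
sample-level signal variation, with gene probes scaled by $c/2$.
Normalization is intra-sample (each gene probe over the mean of the 12
reference probes) then inter-sample (over the control-sample mean), one
of the normalization modes the standard fragment-analysis software
offers. Classification requires both a threshold crossing (ratio < 0.75
loss, > 1.33 gain) and Welch $P < 0.05$ against the controls; with a
single control sample it degrades, documented, to ratio-only. Confidence
intervals are reported informally but never feed the class decision.

# Concordance statistics

`contingency()` compares per-sample CNV status (at least one passing
event in the gene under test) between two call sets over an identical
sample universe; sensitivity and specificity are reported in percent with
`NA` when a denominator is zero. `chiSquare()` is the Pearson statistic
without continuity correction (Yates available by flag), reported as
inapplicable rather than an error when a marginal is zero.
`summarizeCalls()` counts multi-exon events over *numbered* exons only —
the promoter target is a target but not an exon, which is what makes the
published "13 spanned multiple exons" reproducible (promoter–exon 1
events are single-exon). One published count is knowingly discrepant: the
text reports exon 6 affected in 6 of 38 patients, but only 5 of the 38
published spans include exon 6; the summary reports the recomputed 5.

# Numerical and testing choices

Degenerate inputs are defined, not exceptional: a zero reference mean
marks a target uninformative (no ratio), zero reference sd likewise (no
z), dual-zero targets drop out of the percent difference, an all-zero
profile is an error naming the sample, and weight-0 targets disappear
from evidence and break segmentation runs (gaps are never bridged).
Posterior normalization is enforced to $10^{-9}$; ties in reference
selection break by pool order so calls are bit-reproducible; all
randomness flows through a single integer seed per simulation.

Problem sizes in the test suite were chosen to keep the default run a few
minutes on one core while leaving the statistical assertions
well-powered: the depth-convergence check uses 400 samples × 19 targets,
metric-centering uses 60 samples against a 40-control pool (>1100 target
draws), the brute-force matching oracle runs on random pools up to
n = 200, the MLPA recovery property is checked over 20 seeds, and the
end-to-end twin cohort runs at the full published size (388 + 100
samples) once in the acceptance suite.

# Known limitations

* Whole-gene (or near-whole-gene) events on a *single-gene* coverage
  matrix defeat within-gene normalization; multi-gene panels are the
  intended input for such cases.
* Breakpoints are not estimated (intronic sequence is absent from the
  panel) and duplication copy number is not graded.
* The Bayesian state model is a per-target naive-Bayes surrogate for an
  unpublished proprietary model; the published ratio/z filtration gate,
  which *is* fully specified, is the decisive step, and the per-target
  model only has to be good enough to hand segmentation the right
  argmax states.
* MLPA simulation abstracts the assay to multiplicative probe signals;
  electropherogram artefacts, probe-site SNPs under ligation sites, and
  partial-exon events are out of scope.
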