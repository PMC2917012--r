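---
title: "cnascan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cnascan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnascan)
```

# Scope

`cnascan` analyzes cohorts of array-based DNA copy-number profiles of the
kind produced by BAC aCGH platforms for amplifier-type tumor genomes —
HER2-positive breast cancer being the motivating case. A profile is a
vector of per-probe log2 tumor/reference ratios; the package segments
these profiles, calls ordinal copy-number states, scores cohort-level
recurrence, delineates amplicon cores, detects firestorm amplification
patterns, summarizes the altered genome fraction, and integrates matched
expression data through permutation-calibrated dosage correlation. A
synthetic cohort generator with a complete truth ledger backs every stage
with recoverable ground truth.

Coordinates are 1-based inclusive everywhere; interval lengths are
`end - start + 1`. Missing probe values are propagated, never imputed.

# Segmentation

Each chromosome is segmented by circular binary segmentation: among all
circular arcs of the probe sequence, the arc maximizing the two-sample
t statistic between arc and complement defines a candidate split, accepted
when its permutation p-value falls below `alpha` (default 0.01), and the
resulting pieces are segmented recursively. The permutation reference
distribution is obtained by randomly permuting the probe values within the
piece and recording the maximal arc statistic; values are exchangeable
under the no-change null, and a pure rotation would preserve any step
signal and leave the test powerless, so full random permutations are used.
P-values use the add-one estimator `(b + 1) / (B + 1)`, which cannot be
zero. The permutation loop stops as soon as the estimate can no longer
fall below `alpha`; because the exceedance count only grows, this early
stop reproduces the full-run decision exactly. The pruning/undo heuristics
of the original segmentation literature are omitted; the explicit
minimum-probe policy below plays that role here.

Segments with fewer than `min_probes_keep` probes (default 4, matching
BAC-array practice where sub-4-probe segments are not interpreted) are
merged into the adjacent segment with the closest mean; the merged mean is
probe-weighted, so every reported mean remains the mean over member
probes and the segment partition of non-missing probes is preserved.

Technical replicates are merged by per-probe averaging after
normalization, ignoring missing values.

# State calling

Gain and loss are sample-adaptive: the profile is smoothed with a 250-kb
window (mean of probes whose centers fall within ±125 kb; a median option
exists since either convention is defensible), and the thresholds are
±`k`·s with `k = 2` and s the MAD-based robust scale (1.4826 × median
absolute deviation) of the non-missing smoothed values. The MAD resists
the planted or real aberrations that occupy a minority of the genome; at
least 50 values are required for a stable estimate. Fixed thresholds
define the top of the ladder: amplification at segmented log2 ratio
≥ 0.5 and high-level amplification at ≥ 1.0 in the HER2-cohort mode, or
strictly > 0.8 in the reference-cohort mode used for assembled comparison
data sets. Adaptive thresholds are compared strictly (`m > gain_thr`,
`m < loss_thr`): an all-zero profile has zero thresholds and must call
every probe normal, which a non-strict comparison would violate. The five
states form one ordinal ladder — loss < normal < gain < amplification <
high-level amplification — so amplified probes count as gained wherever
gain frequencies are tallied, and the fraction of genome altered
decomposes exactly as `fga_total = fga_gain + fga_loss` over non-missing
probes.

The pericentromeric (CEP17-style) call averages the segmented values of
the three probes closest to the centromere on each arm and reports
amplification when either triple reaches the 0.5 threshold.

# Amplicon delineation and firestorms

The shortest region of overlap (SRO) of an amplification anchored at a
locus is the genomic intersection, over all carriers (samples whose
anchor-overlapping probes all reach the required state), of the maximal
state-qualified probe run containing the anchor: `[max of run starts,
min of run ends]`. Recurrent high-level amplification peaks are plateaus
of locally maximal per-probe carrier frequency exceeding 2\% of the
cohort, reported as the SRO of the plateau's carriers; plateaus tie-break
leftmost for stable output. Co-amplification between two peaks is the
shared-carrier count divided by the smaller carrier count (symmetric) or
by the row peak's count (asymmetric matrix form); the symmetric value is
always the larger of the two asymmetric ones. Mutual exclusivity or
co-occurrence is tested by a two-sided Fisher exact test on the 2×2
carrier table, with a Haldane-corrected sample odds ratio flagged whenever
a cell is zero.

A firestorm call on a chromosome arm requires at least three peaks — runs
of consecutive high-level-amplification probes spanning at least four
probes ("larger than three") — each adjacent pair separated by at least
one probe strictly below the amplification state, with the maximum
center-to-center distance between adjacent peaks below half the arm
length. "Maximum inter-peak distance" is read as the maximum over
adjacent pairs; a pairwise-maximum variant is available since the phrase
admits both readings. The separation clause uses the amplification
threshold (0.5), not merely sub-high-level, reflecting "non-amplified"
separation.

HER2/TOP2A classification applies to samples whose HER2-locus segmented
mean reaches 0.5: co-amplified when the TOP2A locus (700 kb telomeric)
also reaches 0.5, TOP2A-deleted when it falls at or below the sample's
adaptive loss threshold (no fixed loss cutoff exists for these data), and
TOP2A-neutral otherwise.

# Recurrence significance

The recurrence score at marker m in direction gain is
`G_m = Σ_s max(0, min(x_ms, cap) − gain_thr_s)` over samples, with
`cap = 2` log2 units bounding single-sample dominance; loss is symmetric.
The null distribution cyclically shifts each sample's whole-genome
contribution vector by an independent uniform offset — preserving each
sample's autocorrelation and alteration burden while destroying
cross-sample positional alignment — and pools all marker-level null values
over `n_permutations` draws (a deliberately simple stand-in for the
semi-exact convolution null of the original method; the pooled form
matches desk-scale runtime and q-value resolution `1/(B·M)`). Add-one
p-values are Benjamini–Hochberg adjusted across markers; regions are
maximal runs of markers with q below 0.25. When every marker scores zero
— the typical null cohort after thresholding — the permutations are
skipped and all q are 1.

The peak of a region is the contiguous plateau of maximal G containing
the argmax, with a leave-one-sample-out tolerance: markers whose G lies
within one sample's contribution (taken at the argmax marker) of the
maximum belong to the plateau. Segmentation at `alpha = 0.01` gives
roughly 1\% of carriers a spurious breakpoint inside a shared amplicon,
and a strict plateau would then collapse to the fragment favored by one
sample's noise; robustifying peak boundaries against single-sample
fluctuation is standard in this method family, and the tolerance is
derived from the data rather than fixed. Peel-off zeroes the
chromosome-level contributions of the samples that feed a detected peak,
recomputes G and (against the original pooled null) q, and iterates; each
iteration strictly reduces total G, so termination is guaranteed.

Region–covariate association uses Welch's t-test (a pooled-variance
option exists; the two-level clinical contrasts here rarely justify equal
variances) on per-sample region-average log2 ratios, BH-adjusted across
regions at an FDR of 0.05, requiring at least three samples per level.
Cohort-versus-cohort frequency comparison tests each region's 2×2
altered-versus-not table by Fisher's exact test with Bonferroni
adjustment, and requires a shared probe grid — profiles from different
platforms are first remapped to a common 100-kb pseudo-probe grid, each
bin taking the mean of the segment covering its center.

# Expression–dosage integration

Each gene is matched to the probe whose center is nearest the gene
midpoint on the same chromosome. Genes with expression SD at or below 0.5
are excluded (low-variance transcripts cannot carry a detectable dosage
signal and dilute the multiple-testing budget). Pearson correlation
between expression and the matched probe's segmented log2 ratio is
compared against a pooled permutation null: each draw permutes the
copy-number sample labels once for all genes (preserving gene–gene
structure) and the null correlations are pooled across genes — the pooled
form yields a single cohort-level cutoff; a per-gene null is available
through the same machinery. Significance is one-sided positive by
default, since dosage effects are directional, with BH adjustment at 0.05;
the 95th-percentile null cutoff is also reported. Under independence the
closed-form attenuated correlation
`r = β·σ_cn / sqrt(β²σ_cn² + σ_ε²)` links the generator's slope β, the
copy-number spread, and the expression noise; the test suite verifies the
observed correlations against this form.

# The synthetic cohort generator

The generator's defaults define the package's reference conditions: four
chromosomes of 150/110/80/50 Mb (≈390 Mb) with 1-Mb centromeres at 40\%
of each length, tiled at 100-kb probe spacing (≈3,900 probes); Gaussian
per-probe noise of SD 0.15 log2 units around piecewise-constant event
sums (no published noise model exists for BAC ratios, so Gaussian noise
is an explicit assumption); events compose additively in log2 space so
ground truth stays invertible. Event classes cover broad arm-level
gains/losses, focal amplicons whose carriers extend a shared driver
interval by independent exponential distances (creating SRO structure),
multi-peak firestorm arms, pericentromeric gains spanning the probe
triples nearest the centromere, and HER2-amplicon variants realizing the
three TOP2A classes via two driver loci 700 kb apart. The expression
block gives a configurable gene fraction (default 30\%) a linear dosage
term with slope 0.8 and noise SD 0.5 on log2 expression, mirroring the
strength of dosage effects reported for amplifier cohorts. Metadata
covariates (ER, LN, grade, ploidy, size, age) draw from realistic
marginals and can be linked to a planted event. Everything is
deterministic given the seed, and the truth ledger records every realized
interval, carrier, and responsive gene for replay.

What the generator does not emulate: breakage–fusion–bridge mechanics,
tumor purity and ploidy mixtures, allele-specific copy number, wave/GC
artifacts, and platform-specific probe response. Passing tests therefore
demonstrate correctness of the algorithms under an idealized noise model,
not performance on raw clinical arrays.

# Problem sizes and numerical choices

Validation suites run at sizes chosen for a desk machine: null
calibration of the recurrence scan uses 50-sample cohorts on the full
≈3,900-probe default grid; the planted-amplicon power check uses
200-sample cohorts on a 1-Mb grid (the probe density is not part of the
tested condition); cohort-scale segmentation inside these sweeps uses the
configuration minimum of 100 split-test permutations, which leaves the
accept/reject rule's operating characteristics unchanged (the add-one
decision at `alpha = 0.01` has the same false-split rate at B = 100 and
B = 1000), while single-profile checks use the default 1,000. Degenerate
inputs are handled explicitly: constant vectors segment to one piece;
an all-missing chromosome yields zero segments with a warning; zero
expression variance excludes a gene; zero-carrier peaks are errors; ties
in plateau detection resolve leftmost.

# Known limitations

The segmentation is a faithful but simplified CBS — no hybrid tail
approximation, no undo step — so very long chromosomes segment more
slowly than in the optimized reference implementations. The recurrence
null is pooled across markers; markers with atypical marginal behavior
(e.g. near chromosome ends) share the genome-wide null. The FGA "gain"
component counts amplifications through the ordinal ladder; cohorts
defined with disjoint state classes would need the states recoded.
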