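---
title: "Methods: clone-based bisulfite amplicon methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-based bisulfite amplicon methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclone)
```

## The assay and its data

epiclone analyses the classical clone-based bisulfite design: a promoter
region is PCR-amplified from bisulfite-converted genomic DNA, the
amplicons are cloned, and 7–10 individual clones per fish are sequenced.
Each clone is a single DNA molecule, so its pattern of methylation
states across the assayed CpG loci is a true molecular haplotype (an
*epiallele*), not an average. The motivating application is
temperature-dependent sex determination in European sea bass, where
methylation of the gonadal aromatase (*cyp19a*) promoter differs
between sexes and rises in females exposed to high temperature during
early development.

Everything is anchored on a `PromoterAssay`: the sense-strand amplicon
sequence plus a declared, ordered panel of CpG loci labelled by
TSS-relative position (signed integers, no position 0; −1 abuts +1).
The panel is declarative rather than scanned from the sequence because
real assays interrogate a chosen subset of the CG dinucleotides in the
region — the packaged *cyp19a* fixture has seven loci (−431, −56, −49,
−33, −13, +9, +60). The fixture amplicon itself is synthetic (the
study's sequence is not public): it reproduces the locus count, the
label spacing, and a realistic non-CpG cytosine density (113 non-CpG
Cs), and contains no CG outside the declared panel. Only the sense
strand is modelled; clones sequenced in the reverse orientation are
recognised by reverse-complementing, but each clone contributes one
call vector.

## Methylation calling and conversion QC

Calling is a gapless anchored comparison in bisulfite space. The clone
must have the amplicon length; at reference positions that are not C
the clone must match, and the fraction of mismatches at those
unambiguous positions must not exceed a tolerance (default 0.05 —
generous for Sanger-sequenced clones while rejecting mispriming
products). Reference C positions accept either C or T. At each
declared locus, C means methylated, T unmethylated, anything else
missing.

Per clone, the bisulfite conversion efficiency is the fraction of
covered non-CpG cytosines read as T. A non-CpG C is a C not followed
by G; a C belonging to an *undeclared* CG dinucleotide is excluded from
both the call set and the conversion denominator, since its methylation
state is unknown and it carries no conversion signal. No clone is
excluded on conversion grounds by default — efficiencies are reported
as QC, and a `minConversion` filter exists for users who want a cutoff.

Per-fish means are computed as the mean over loci of the per-locus
means (M/(M+U), ignoring missing calls). Equal locus weighting was
chosen over pooling all calls because per-position averages are the
primary reported quantity in this design; with complete balanced data
the two coincide, and the pooled mean is also reported alongside.

## The synthetic-data generator

Because no raw clone data were deposited with the study, the generator
is a first-class module: every downstream stage is validated on data
whose truth is known. It emulates the study design, with defaults set
once from the published conditions:

* **Classes and sizes** — females and males at low and high temperature
  with 14, 8, 15 and 15 fish and 10 clones per fish
  (`studyGeneratorConfig()`); per-CpG methylation probabilities whose
  across-site averages equal the published class means (37.1%, 53.9%,
  77.0%, 85.3%).
* **Within-fish correlation** — a shared fish-level random intercept on
  the log-odds scale, `logit(theta[i,j]) = logit(p[g,j]) + u_i`,
  `u_i ~ N(0, sigma_fish^2)`. The study shows clear fish-to-fish spread
  but states no variance model; a single `sigma_fish = 0.5` for all
  sites is a parsimonious fixture choice, flagged as such.
* **All-or-none epialleles** — with probability `rho` (default 0.5) a
  clone is drawn fully methylated (probability = the fish's mean
  propensity) or fully unmethylated. Site-independent Bernoulli draws
  alone cannot reproduce the strong bimodality of observed pattern
  tables, where all-M and all-U dominate.
* **Conversion failure** — each non-CpG C escapes conversion with
  probability `epsilon` (default 0.0202, the study's estimated failure
  rate).
* **Sequencing error and dropout** — available, both defaulting to 0;
  the study reports no error model and sequences both strands.

Probabilities at 0 or 1 are clamped to `[1e-6, 1 - 1e-6]` before the
logit. One consequence of taking the logit-normal model literally: the
class-mean of fish propensities is not exactly the configured `p`
(Jensen's inequality contributes a bias of roughly one percentage point
at p ≈ 0.8 with `sigma_fish = 0.5`). The recovery checks account for
this by testing at the tolerance of the published means, not by
re-calibrating the generator.

What the generator does **not** emulate: PCR amplification-efficiency
bias beyond the all-or-none proxy, chimeric clones, strand-specific
conversion artefacts, and linkage between neighbouring amplicons.
Passing tests therefore demonstrate correctness of the computations
under a plausible data-generating process, not robustness to every
artefact of real libraries.

## Epiallele analysis

With L loci there are 2^L possible patterns (128 for the seven-locus
panel). Clones with any missing call are excluded from pattern
analysis — a partial pattern is not a pattern — but still contribute to
per-locus means. A pattern is eligible for testing when its total count
is at least 5 × (number of classes): the expected-count-of-5 rule under
equal allocation, which is how the rule is stated for four groups
(total ≥ 20). Expected counts in the test itself are proportional to
each class's complete-clone total, which reduces to equal allocation
when classes are balanced (as they approximately are at 10 clones per
fish).

The per-pattern test is a goodness-of-fit chi-square of the pattern's
class counts against those expectations (df = classes − 1). The
alternative reading — an r×c independence test across all patterns —
was rejected because results in this design are reported pattern by
pattern. No multiple-testing correction is applied by default (raw
per-pattern p-values are the reported convention here); a Bonferroni
option exists.

Per-fish pattern diversity (distinct complete patterns among a fish's
clones, at most min(clones, 2^L)) is the PCR-bias diagnostic: diversity
collapsing towards 1 would indicate that the PCR amplified one epiallele
preferentially.

## AMOVA and fixation indices

Methylation haplotypes are binary vectors; the distance is Hamming,
which on 0/1 data equals squared Euclidean distance — there is no
substitution model to weight, so no transition/transversion scheme.
The hierarchy is clones within fish (populations) within treatment
classes (groups). Sums of squares come from pairwise squared distances
aggregated at fish level; variance components use the standard
unbalanced-design coefficient equations, and may be negative (they are
estimates, not parameters). Phi_CT, Phi_SC and Phi_ST follow.

The *reported* Fst is Phi_CT — differentiation among classes with fish
as populations — because the comparison of interest is between
treatment classes and because this statistic can take the small
negative values that appear in published tables of this kind. Phi_ST
is reported alongside. When the total variance is zero the statistics
are returned as 0 with a `monomorphic` flag rather than NaN.

Significance is by permutation with the add-one rule
p = (1 + #{perm ≥ observed}) / (1 + nPerm), so p is never exactly 0.
For Phi_CT whole fish are permuted among classes, preserving class
sizes: fish, not clones, are the independent sampling units, and
permuting clones would treat pseudo-replicates as replicates. For
Phi_ST clones are permuted among fish. The study's methods text
describes the significance rule in an inverted form ("less than 5% of
pseudo-replicates higher … not significant"); the standard convention
is implemented (significant when the tail mass at or above the observed
statistic is below alpha), and this discrepancy is deliberately
documented here. Fewer than 20 distinct permutations triggers an
"underpowered" warning. Single-locus runs use length-1 haplotypes and
admit clones that are incomplete elsewhere.

## Group statistics and the sex threshold

All statistics on methylation proportions are computed on the arcsine
square-root scale (radians). The two-way sex × temperature ANOVA uses
Type-II sums of squares for the unbalanced cells; the t-test is the
pooled-variance Student's form (Welch behind a flag), matching the
declared analysis; Tukey's HSD with a compact letters display covers
the 2×2 cell means. The sex-ratio comparison is a Pearson chi-square
without continuity correction.

The sex-classification threshold is built from the 95% confidence
intervals of each sex's mean on the transformed scale: the threshold is
the back-transformed midpoint between the female CI upper bound and
the male CI lower bound. The exact construction behind the published
67% value is not stated in this level of detail anywhere, so this
definition is declared and validated by bracketing: thresholds from
simulations at the published group means should fall in [0.60, 0.75]
in at least 90% of runs, which the acceptance suite checks over 200
runs. If the two CIs overlap, the midpoint of the means is used and an
`overlap` flag is raised. Classification is strict: mean < threshold
is female, the boundary goes to male. Because the transform is
strictly increasing, classifying on either scale gives identical
labels.

## Expression and presumptive sexing

Relative quantification is the standard 2^(−ΔΔCt) model with
amplification efficiency fixed at perfect doubling. ΔCt is the mean
target Ct minus mean reference Ct over replicates; the calibrator is
the fish with the highest ΔCt (lowest expression), ties broken by
smallest fish id so the choice is deterministic; the calibrator's RQ
is exactly 1 by construction.

Presumptive sexing replaces the original SPSS "two-step" clustering
with exact one-dimensional 2-means on log2(RQ): for a 1-D two-group
split the optimal partition is a threshold, so all n−1 splits are
scored and the best taken — deterministic, no initialisation, no
restarts. The cluster with higher mean expression is presumptive
female, always. Clustering is done within each temperature group
(pooled mode available), mirroring the per-treatment classification of
the original design. Groups with fewer than 4 fish or no expression
spread are left `unassigned` with a warning. The mean silhouette width
is reported as a separation diagnostic.

## Numerical and degenerate-input conventions

* Probabilities are clamped to `[1e-6, 1 - 1e-6]` before logits.
* SS additivity holds to 1e-9 relative (enforced by the result class).
* Constant ANOVA responses return F = 0, p = 1 with a `degenerate`
  attribute; zero pooled variance with unequal means is an error.
* Pattern-table ordering: total descending, ties lexicographic.
* All stochastic stages require an explicit seed; reruns are
  byte-identical.

## Validation design and problem sizes

The test suite validates the AMOVA decomposition against an
independent oracle that computes sums of squares from per-site
centroid deviations (never from pairwise distances) on exhaustive toy
sets of up to 12 haplotypes, to 1e-9. Permutation calibration uses
2,000 null datasets of 16 fish × 5 clones at 199 permutations each,
checking uniformity of p (Kolmogorov–Smirnov) and the type-I error at
alpha = 0.05. Group-mean recovery runs 100 seeded simulations of 15
fish × 10 clones per class; threshold bracketing runs 200 simulations
of the full 52-fish study design. These sizes give Monte-Carlo
standard errors comfortably below the tolerances being tested while
keeping the default check fast.

## Known limitations

* Gapless alignment: clones with indels relative to the amplicon are
  rejected rather than realigned — appropriate for clone sequencing of
  a known amplicon, not for general WGBS/RRBS data.
* One call vector per clone; forward/reverse read reconciliation is
  assumed done upstream.
* The generator's fish effect is shared across sites; site-specific
  random effects are not modelled.
* The threshold construction assumes roughly symmetric, separated sex
  distributions on the transformed scale; with heavy overlap the
  flagged fallback is a descriptive midpoint, not a calibrated
  classifier boundary.
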