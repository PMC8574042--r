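---
title: "Methods: interpretable fuzzy-rule enhancer prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable fuzzy-rule enhancer prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Enhancers carry a combinatorial histone-modification code, but the
classifiers usually trained on that code are opaque. `enhancerRules`
instead learns a small set of human-readable IF/THEN rules — for example
*IF H3K4me1 is high AND H4K16ac is high THEN enhancer* — that map binned,
min-max-normalized ChIP enrichment signals to an enhancer probability.

The genome is tiled into fixed-width bins (default 10 bp). Each mark's
signal is aggregated per bin (coverage-weighted mean by default; the
aggregator is pluggable because upstream smoothing makes the choice
nearly irrelevant) and normalized to [0, 1]. Reporter-assay peaks provide
the binary labels: peaks are expanded to 400 bp around their midpoints
(never shrunk), and a bin is labeled enhancer if it overlaps an expanded
peak by at least 1 bp. A stratified sample (defaults to up to one million
bins, preserving the enhancer:non-enhancer ratio to within one bin per
class) is split into train and test sets.

### Interval type-2 fuzzy sets

Each mark is described by three linguistic terms — low, medium, high —
anchored at the mark's empirical 25th/50th/75th percentiles. Crisp
boundaries sit midway between adjacent anchors; an `overlap` fraction
(default 0.3) widens the linear ramps around each boundary, and a `fou`
fraction (default 0.3) shifts the trapezoid outward/inward into an upper
and a lower membership function. The gap between the two (the footprint
of uncertainty) encodes that the low/medium/high boundaries are
themselves uncertain. With `fou = 0` the sets degenerate to ordinary
type-1 trapezoids, and inference provably reduces to the type-1
computation (a regression test checks this against an independent
implementation to 1e-12).

### Inference

A rule has 1–3 antecedents over distinct marks and an enhancer or
non-enhancer consequent. Firing is the minimum t-norm over antecedent
memberships, applied separately to the lower and upper bound. Per class,
dominance-weighted firing strengths are summed, each interval is
type-reduced to its midpoint, and the enhancer probability is the
enhancer aggregate divided by the total. When nothing fires the
probability is 0.5 — deliberate ignorance, below the 0.8 calling
threshold so silent bins are never called enhancers. *Dominance* is the
rule-quality weight: confidence × support of the rule on training data,
scaled to [0, 10] within each consequent class (per-class scaling stops
the majority class's huge support from drowning out enhancer rules).
These are the simplest widely used Mamdani-style choices; all are
isolated behind the inference functions.

### Rule induction

A seeded evolutionary search optimizes a rule list under hard caps of 50
rules and 3 antecedents per rule (enforced by repair). Candidate rules
are harvested from the data: every singleton and mark-pair linguistic
pattern (consequent assigned by lift over the class prior) plus rules
read off individual training bins. The scalar fitness is
`w_acc * balanced accuracy − w_rules * (rules/50) − w_ant *
(antecedents/150)` with defaults (1, 0.02, 0.01); balanced accuracy is
used because enhancer bins are a few percent of the genome.

Three practical devices matter more than the genetic operators
themselves:

* **Cross-fitted fitness.** With label noise, a fixed set of flipped
  labels can be partially memorized: rule sets gained apparent accuracy
  by covering the specific noise bins. Dominance is therefore estimated
  on one stratified half of the fitness subsample and balanced accuracy
  scored on the other, which removes that incentive.
* **Greedy seeding and memetic pruning.** A set-cover seed (start from
  the strongest enhancer rule, repeatedly add the candidate with the best
  fitness gain) puts coordinated individuals into the initial population;
  the per-generation best is additionally pruned by testing the removal
  of each rule. Without these the search reliably stalled in a local
  optimum of broad background guards well below the attainable optimum.
* **Pool injection.** Every ten generations, fresh candidate rules are
  read off bins the current best individual misclassifies.

Population 100 and 200 generations are the package defaults, sized for
desk-scale runs; tests and the acceptance suite use smaller,
early-stopping configurations and say so. Partition anchors can also be
jittered by mutation, so the low/medium/high boundaries are trained per
mark rather than fixed.

### Region calling

Bins with probability ≥ 0.8 form candidate regions; neighbouring
candidates within 100 bp are merged when the mean probability over their
member bins (gap bins excluded from the mean, included in the span) is
strictly above 0.8, iterated left-to-right to a fixpoint so the result
does not depend on scan order. Regions are classed by size — fragment
(< 50 bp, excluded downstream by default), enhancer (50 bp–1 kb),
super-enhancer (> 1 kb) — and, against a reference set, by origin:
common (≥ 1 bp overlap with the reference), putative (no overlap), or
reference-only. The evaluation threshold for classifier metrics (0.5) is
deliberately distinct from the 0.8 calling threshold: the former is an
operating point for confusion-matrix statistics, the latter a
high-confidence cutoff for genomic intervals.

### Contacts, expression, profiles

Promoters are the 250 bp upstream of each TSS (strand-aware, clipped at
chromosome ends). Contact records carry observed/expected ratios; a
record is enriched at ratio ≥ 2 by default — the upstream contact
caller's cutoff is not something this package can infer, so it is an
explicit, mandatory parameter. A region is *proximal* when within 5 kb of
a promoter and also holding distal enriched contacts, *proximal_only*
without such contacts, *distal_only* when beyond 5 kb but contacting a
promoter through an enriched record, else *neither*. Linked expression is
the maximum FPKM over contacted (and, for proximal regions, nearby)
genes; a region counts as expressed above FPKM 1 (configurable; log
transforms are applied only downstream, never stored).

Signal profiles are sampled at bin resolution ±5 kb around region
centers, rows sorted largest region first. Winsorization zeroes negative
entries and caps at the 95th percentile of positive entries before
rescaling to [0, 1] (stranded signal is rescaled per sign onto [−1, 1]).
The cap uses the inverse-ECDF (type 1) quantile — an order statistic —
which makes the transform exactly idempotent; an interpolated quantile
would shrink the matrix a little on every application. Per-region body
scores use the linearly interpolated (type 7) 95th percentile, the common
default, and group comparisons use two-sided Mann-Whitney U tests.

The eRNA directionality score is `log10((P + c) / (N + c))` where P and N
sum the plus-strand and minus-strand magnitudes over 500 bp windows
placed 500 bp outside both region borders. Summing both strands over both
windows (rather than pairing plus with downstream only) makes the score
exactly antisymmetric under a strand swap, which the test suite checks;
with divergent transcription the two conventions agree. The pseudocount
`c` defaults to 1 signal unit to keep the ratio finite at zero coverage;
noise-free tests pass `c = 0` so planted ratios give exact scores.
Regions with total flanking signal below 1 are non-transcribed; otherwise
|score| ≤ 0.5 is bidirectional. TAD-border proximity is a 2 kb gap
distance.

## The synthetic world

The generator states a fully seeded world with planted ground truth; its
defaults are commitments, not dials:

* **Genome**: two 1 Mb autosome-like chromosomes, 10 bp bins, 8 marks.
* **Enhancers**: 50 regions per Mb, widths 200–1000 bp, at least 1 kb
  apart. Rationale: reporter assays in fly cell lines annotate thousands
  of enhancers of median size a few hundred bp across a ~120 Mb genome —
  tens of regions per Mb, a few percent of bases. (At a much sparser
  density a 5% label-flip rate leaves labeled positives ~90% noise and no
  label-driven objective can rank rules; that regime is documented, not
  silently avoided.)
* **Rules**: two planted enhancer rules — high H3K4me1 with either high
  H4K16ac or high H3K18ac — plus a low-H3K4me1 non-enhancer rule.
* **Signals**: background is uniform on [0, 1] per mark, conditioned so
  no planted enhancer rule fires at ≥ 0.5; inside an enhancer the
  assigned rule's antecedent marks are drawn on the lower-membership
  plateau, so the rule fires exactly before noise. Gaussian noise
  (sd 0.05) is added and clipped; 5% of labels are flipped.
* **Contacts/expression/eRNA**: each enhancer contacts one gene's
  promoter with probability 0.8 (scores in [2, 8], so planted links
  always pass the enrichment cutoff); promoters contact random background
  with probability 0.05; linked genes draw lognormal FPKM (meanlog 2),
  unlinked genes are zero-inflated; stranded transcription puts
  plus-signal downstream and minus-signal upstream of each enhancer with
  a configurable plus:minus ratio.

Two generator subtleties are load-bearing. First, conditioning the
background must not warp the marginals: redrawing whole bins depletes the
upper tail of marks shared between planted rules, and the learner's
quantile-anchored partitions then stop matching the planted geometry.
Only one antecedent of the offending rule is redrawn per iteration,
preferring the mark shared by the fewest rules. Second, the planted
partitions are re-anchored at the empirical quantiles of the conditioned
background (iterated three times) before signals are planted, so
"anchored at the data's quartiles" — the learner's definition — is also
the truth's definition. The re-anchored rules are returned as ground
truth.

What a green test establishes: that the pipeline recovers planted
combinatorial structure from bounded, noisy, imbalanced data with
realistic region geometry. What it does not establish: performance on
real chromatin data, whose signals are spatially autocorrelated,
cross-correlated between marks, and probe-biased in ways this generator
deliberately does not model.

## Numerical choices and degenerate inputs

* Min-max normalization of a constant track yields all zeros (no
  information, no division by zero); such marks are excluded from rule
  search with a warning.
* Probabilities are clipped to [0, 1] by construction; features outside
  [0, 1] are clipped with a warning.
* Merging uses strict "mean > threshold" and a ≤ 100 bp gap; a combined
  mean of exactly 0.8 does not merge, while a single bin at exactly 0.8
  is a candidate ("0.8 or higher").
* Classification uses strict "probability > threshold", so the ignorance
  default of 0.5 maps to non-enhancer at the default operating point.
* Ties in AUC use midranks.
* All stochastic stages draw from seeds derived from one master seed with
  a 32-bit linear map; reruns are byte-identical.

## Open choices resolved here

The inference internals of the commercial platform this class of model
descends from are unpublished, so min/sum/midpoint/ratio above are this
package's own, documented choices; equivalence with any particular
platform's probabilities is not claimed. The quantitative definition of
rule dominance is likewise unpublished; confidence × support reproduces
its ordinal use (filtering "dominance ≥ 3" rules) without claiming the
same scale. Whether peak expansion was midpoint- or summit-anchored, and
whether region merging was iterated, are unstated upstream; this package
centers on midpoints and iterates to a fixpoint, both switchable. The
pipeline configuration file is JSON rather than YAML because no YAML
parser is assumed at runtime.

## Known limitations

The evolutionary search is stochastic; different seeds can return
different (equally fit) rule bases, and only the antecedent structure of
strong planted rules is expected to be stable. Balanced accuracy against
noisy labels is bounded far below 1 when label noise swamps a rare
positive class — recovery must then be judged against ground truth,
which only synthetic data provides. Hi-C matrix normalization, TAD
calling, motif enrichment and chromatin-state model fitting are upstream
of this package and out of scope.
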