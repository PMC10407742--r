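---
title: "Benchmarking variant effect predictors with DMS and clinical variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variant effect predictors with DMS and clinical variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsbench)
```

## The problem

A variant effect predictor (VEP) maps an amino acid substitution to a
score meant to reflect its damage. Evaluating VEPs against clinical
databases is haunted by two circularities: predictors trained on the very
labels they are tested on (type 1), and gene-level label skew leaking
into variant-level performance (type 2). Deep mutational scanning (DMS)
sidesteps both: it measures a functional score for most substitutions in
a protein, with no knowledge of clinical annotation. `dmsbench`
implements a benchmarking framework built on that idea, with two
tournaments and a shared significance machinery.

## The pairwise tournament model

The unit of comparison is a *pair of methods on one protein, restricted
to the variants both score*. This restriction is the methodological core:
VEP coverage varies (nucleotide-level methods only reach
single-nucleotide-change missense; alignment-based methods skip poorly
aligned regions), and a method must never be penalised or rewarded for
variants its rival cannot see.

* Correlation benchmark: for predictors $i, j$ and DMS scores $d$, let
  $V$ be the variants scored by $i$, $j$, and $d$. If $|V| \ge$
  `min_shared` (default 10, mirroring the clinical benchmark's shared-set
  rule), compute Spearman's $\rho(i, d)$ and $\rho(j, d)$ on $V$ (average
  ranks for ties); the larger wins one point, ties give half a point each.
* Clinical benchmark: identical structure with AUROC (or AUBPRC) over the
  pathogenic/benign variants shared by the pair, requiring at least 10
  shared pathogenic and 10 shared benign variants.

A method's per-protein rank score is points over comparisons
participated; the overall rank score is the unweighted mean across
proteins in which it was compared. Two exact invariants follow from the
tie rule and are tested: summed points equal executed comparisons, and a
full round robin has mean rank score exactly $1/2$. Because only rank
statistics are used, the tournament is invariant to any strictly
increasing transform of any method's scores.

Undefined correlations (fewer than three complete pairs, or a constant
ranked vector) propagate as missing and drop the comparison for both
sides; they are never scored zero, which would punish a method for a
degenerate subset.

### Orientation

Score scales point in both directions in the wild (for DMS fitness
scores, high usually means tolerated). Orientation is always *declared*,
never inferred, and normalisation is by negation — an order-reversing
map, which is all a rank statistic can detect. The shift rescaling
`modified_score()` (score minus its maximum) is also provided for
convention compatibility; it is order-preserving, so every downstream
number is identical either way. An opt-in repair (`auto_orient()`,
`flip_inverse` in the driver) inverts entries whose AUROC under the
declared orientation falls below 0.5, with a loud warning; it is off by
default because silently rescuing a mis-declared input usually masks an
upstream error. An AUROC of exactly 0.5 is never flipped.

### Classification metrics

AUROC is computed as the Mann–Whitney statistic (ties half credit), which
is exactly the concordant-pair probability and is insensitive to class
balance. Average precision is the recall-weighted mean of precision over
a descending threshold sweep, tied scores forming a single threshold. The
balanced variant
$$\mathrm{AUBPRC} = \frac{\mathrm{AUPRC}\,(1-\pi)}{\mathrm{AUPRC}\,(1-\pi) + (1-\mathrm{AUPRC})\,\pi},$$
with $\pi$ the pathogenic fraction, is a strictly increasing transform of
AUPRC for fixed $\pi$, equals it at $\pi = 1/2$, and can be read as the
PR-AUC on balanced classes. Both the pair-counting identity and the
AUBPRC closed forms are enforced against exhaustive oracles in the tests.

## Supporting procedures

**Representative assay.** When several DMS assays exist for a protein,
the one with the highest *median* $|\rho|$ against all predictors
represents the protein — the median keeps a few extreme predictors from
driving the choice. Ties break lexicographically (logged), making reruns
deterministic.

**Coverage filter.** Assays scoring under 5% of the $19 L$ possible
substitutions are excluded before anything else; such sparse maps make
shared-variant sets unstable.

**SNV-reachable mode.** Restricting to substitutions reachable by one
nucleotide change levels the field between nucleotide-level and
protein-level predictors; the remaining gaps are filled with each
predictor's most benign per-protein score, under the assumption that
missing regions are mostly poorly conserved. With a coding sequence the
reachable set is codon-specific; without one it falls back to the union
over all standard-code codons of the reference residue — a documented
superset of the transcript-specific set, the honest choice when the
transcript is unknown. Stop gains are never emitted; only missense is in
scope.

**Scanning-window filter.** Regions where *no* predictor tracks the DMS
data make comparisons there uninformative. A 20-residue window slides one
residue at a time (stride 1 is the maximal-information reading of a
scanning window; terminal windows are not padded); the window statistic
is the mean over predictors of the in-window DMS correlation (a predictor
needs ≥ 3 shared variants to contribute; empty windows are excluded from
the summary). Windows falling strictly more than one standard deviation
below the mean have their central 10 residues marked, and marked cores
from overlapping windows are unioned. Strict inequality means a
constant-agreement protein (σ = 0) loses nothing. The three analysis
modes — baseline, SNV+imputation, window-filtered — are explicit driver
flags and are never combined implicitly.

**Label assembly.** The putatively benign class is population-database
derived and may contain variants independently reported pathogenic;
those are removed from the benign side only. Eligibility (≥ 10
pathogenic and ≥ 10 benign per protein, thresholds inclusive) gates the
clinical benchmark; the best-ranking DMS set per protein represents
"DMS" in the cross-protein summary. Upstream database filters
(review-status stars, population-database internal quality flags) are the
user's responsibility and documented constants only; no allele-frequency
filtering of the benign set is applied by default, since rare benign
variants are precisely the decision problem VEPs face in practice.

Per-entry headline metrics are always reported on the entry's *full*
labelled coverage, tournaments always on *pairwise-shared* subsets; the
two appear side by side and are never mixed.

## Bootstrap significance

Rank differences between similar methods are often resampling noise. Per
replicate, the correlation bootstrap resamples the variant rows of each
protein's DMS-joined panel with replacement (within protein, preserving
the per-protein comparison structure — the resampling unit is the score
pair per variant); the classification bootstrap resamples pathogenic and
benign sets independently, so no replicate can empty a class. The full
tournament, including overall averaging, is recomputed each time.
Outranking counts convert to one-sided P-values $p = 1 - c/B$, matching
the directional "outranks" question; no multiple-testing correction is
applied. Exact copies of a method tie in every replicate, so neither ever
outranks the other — ties are accounted separately rather than split.
RNG streams are derived per replicate from the master seed, so results
are bit-identical across reruns and would survive parallelisation.

## The synthetic benchmark generator

The generator exists so every stage can be validated against known ground
truth without any external download. It emulates:

* **Fitness landscapes** — per protein, a damage value for all $19 L$
  substitutions: a smoothly varying positional severity (moving-average
  Gaussian process, window 9, giving the positive lag-1 autocorrelation
  real mutational landscapes show and the window filter needs), plus a
  per-residue exchange component (weight 0.45) and i.i.d. scatter (0.35),
  standardised to unit variance.
* **DMS assays** — fitness plus Gaussian noise on a binomial coverage
  subset, emitted on a fitness-like (higher = benign) scale. The default
  noise sd 0.92 follows from requiring two independent assays of one
  protein to correlate at $\rho \approx 1/(1+\sigma^2) \approx 0.54$, the
  middle of the moderate-reproducibility band real assay pairs occupy.
  Default coverage 0.8.
* **Predictors** — Gaussian copula: fitness is rank-transformed to
  normal scores and mixed with independent noise at Pearson weight
  $r = 2\sin(\pi \rho_s / 6)$, the bivariate-normal value whose Spearman
  correlation equals the target, so the realised rank correlation
  converges to the injected one (verified to ±0.02 at $n = 10^4$).
  Coverage masks and SNV-only restriction apply after the copula. The
  default grid injects 0.9/0.75/0.6/0.45/0.3.
* **Clinical labels** — pathogenic drawn from the top-quantile damage
  tail (default 0.25), benign from the remainder, 50+50 per protein,
  each label flipped with probability 0.1 by default. Because the pools
  occupy disjoint damage ranges, a noiseless predictor's expected AUROC
  under symmetric flip noise $p$ is exactly $1 - p$, which the tests
  exploit. A `benign_only` mode keeps the pathogenic class clean and
  contaminates only the benign slots with truly damaging variants,
  mimicking the one-sided noise of population databases.

All randomness flows from one master seed through named substreams per
artifact, so the same seed reproduces files byte for byte and changing
one component (say, the labels) leaves the others untouched.

What the generator does *not* emulate: sequence evolution, alignment
depth, structural context, gene-level label imbalance, or correlated
errors between predictors built on shared alignments. Passing the
recovery tests therefore shows the *machinery* is correct and powerful
enough at the simulated signal strengths — not that any particular real
predictor ranking is right.

## Numerical and design choices

* Ties: average ranks (Spearman), half credit (AUROC), single threshold
  (average precision), half a point (tournament wins) — chosen so the
  conservation invariants hold exactly.
* Tie-breaks in selections (representative assay, best DMS) are
  lexicographic and logged: determinism over cleverness.
* Degenerate inputs: fewer than three shared variants, constant ranked
  vectors, sub-threshold shared label counts, and proteins shorter than
  the window are all *skipped with a record* (or an error where the
  result would be meaningless), never silently zeroed.
* `min_shared = 10` for correlation comparisons mirrors the clinical
  10+10 shared rule; both are configurable.
* Score tables serialise at 17 significant digits so a write/read cycle
  reproduces doubles bit for bit.
* Problem sizes in the validation suite (five proteins of ~1000 variants
  for correlation recovery, ten proteins of 50+50 labels for
  classification recovery, 100 seeds each, B = 200 bootstrap) were chosen
  as the smallest sizes at which the injected orderings are comfortably
  identifiable, keeping the full suite in the low minutes on one CPU.

## Known limitations

* The fallback (no-CDS) SNV universe is a superset of any real
  transcript's; canonical-transcript resolution is the user's problem,
  by design.
* Overall rank scores weight proteins equally regardless of variant
  count; no meta-combination of predictors is attempted.
* Bootstrap P-values are one-sided and uncorrected; with many methods,
  borderline calls should be read accordingly.
* The concordance between the two benchmarks on synthetic data reflects
  a single latent quality axis by construction; on real data the two
  benchmarks measure genuinely different things and their agreement is
  an empirical finding, not a guarantee.
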