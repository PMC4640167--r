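---
title: "Information-gain detection of transcription factor binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-gain detection of transcription factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmotif)
```

## The model

`sigmotif` detects short DNA motifs by measuring how much a candidate
sequence *disturbs* a trained motif model, rather than how well it matches
a per-position score. The training input is a set $M$ of $I$ aligned
binding sites of common length $L$ over $\{A, C, G, T\}$; the method is
designed for the small $I$ (5–50) typical of curated binding-site
collections, where higher-order models (HMMs, Bayesian networks) cannot be
estimated reliably.

Two parametric summaries are computed at a Rényi order $q > 0$:

$$H_q(p) = \frac{1}{1-q}\log_2 \sum_{x} p_x^{\,q}, \qquad
  R_q = 1 - \frac{H_q}{\log_2 4},$$

the per-position redundancy profile (information content normalized to
$[0,1]$), and

$$D_q(i,j) = \frac{1}{q-1}\log_2 \sum_{x,y} P_{xy}^{\,q}\,Q_{xy}^{\,1-q},
  \qquad Q = p_i \otimes p_j,$$

the pairwise Rényi divergence between each joint symbol distribution and
the product of its own marginals — a parametric generalization of mutual
information that is zero exactly when two positions vary independently.
The order $q$ tunes the sensitivity of both measures to rare versus
common symbols; it is restricted to $(0, 2]$ because larger orders
amplify sampling noise in the redundancy signal faster than they add
contrast.

For a candidate $s$, both summaries are re-estimated on
$S = M \cup \{s\}$ (the candidate contributes one count) and folded into
two scalar *information-gain* features,

$$\rho = \Big|\sum_i R_q^{M_i}\,\gamma_i\Big|^{-1},\qquad
  \eta = \Big|\sum_i |R_q^{M_i}|\,\omega_i\Big|^{-1},$$

with $\gamma_i = |R_q^{M_i} - R_q^{S_i}|$ and
$\omega_i = |D_q^{M_i} - D_q^{S_i}|$. True sites leave the model nearly
unchanged and land at large $(\rho, \eta)$; background windows erode
conserved positions and dilute couplings, landing low. A quadratic
discriminant (class-conditional Gaussians over the $(\rho,\eta)$ plane)
draws the decision boundary; its continuous log-posterior difference is
the scan score.

### Assumptions

* Sites are already aligned and gap-free; no de-novo discovery.
* Dependence is modelled at pair level only; triplet and higher
  interactions are ignored.
* Background sequence is homogeneous at the scale of a scan; the
  discriminant's negative class is drawn from the supplied background.

## Design choices at the open points

Several pieces of the procedure are underdetermined by the general recipe
above; the package resolves them as follows.

**Redundancy form.** $R_q = 1 - H_q/H_{max}$ (ratio form) rather than the
difference $H_{max} - H_q$: it is dimensionless and bounded in $[0,1]$,
which keeps $\rho$ and $\eta$ scale-free across motif lengths.

**$q = 1$.** The closed forms are singular at $q = 1$; the package serves
the analytic Shannon/mutual-information limit there instead of an epsilon
offset, so validation grids may include 1 exactly.

**Per-position divergence aggregate.** $D_q^{M_i}$ is read as the sum of
row $i$ of the divergence matrix restricted to the screened pairs
(diagonal excluded). Unscreened pairs contribute nothing to $\eta$,
matching the screening rationale below.

**Zero conventions.** $0\log 0 = 0$ and $0^q = 0$: zero-probability cells
contribute nothing to either measure. Divergence cells with $P_{xy} = 0$
contribute zero regardless of $Q$; a zero $Q$ cell can only occur where
$P$ is also zero because $Q$ is built from $P$'s own marginals. Tiny
negative floating-point residues of the divergence are clamped to 0, and
entropies to $[0, 2]$.

**Denominator floor.** A candidate identical to a fully conserved
consensus makes the inner sums of $\rho, \eta$ exactly zero (so does an
empty screened-pair set for $\eta$). Sums below $\varepsilon = 10^{-12}$
are floored, capping the features at $1/\varepsilon$; this preserves
ranking without infinities and is configurable (`epsilon`).

**Screening threshold.** Plug-in divergence estimates are biased upward
at finite $I$; position pairs count as correlated only above that bias.
The default estimate is the 95th percentile of a seeded permutation null
(1,000 draws of two independent columns of length $I$, scored with the
training pseudocount). The null columns are drawn from *uniform*
marginals — the maximum-entropy case, whose bias is largest — making the
threshold conservative for conserved positions; this deliberately favours
screening precision over recall. The Miller–Madow analytic bias
$(|X|-1)(|Y|-1)/(2I\ln 2)$ bits is available as a fast alternative for
$q$ near 1, and a fixed numeric threshold can be supplied directly.

**Pseudocount.** 0.5 per count cell (Jeffreys-style), added to the
$4$-cell position counts and the $16$-cell pair counts alike, keeping all
probabilities strictly positive at $I$ as small as 5. Exact toy
calculations use 0.

**QDA details.** The two-class Gaussian discriminant is fitted with
unbiased ($n-1$) covariance estimates and empirical class priors; a ridge
`regularization` is added to the covariance diagonals. The strict default
0 raises an error on singular fits; the pipelines pass `NULL`, which
chooses $10^{-8}$ of the mean feature variance (floored at $10^{-12}$) —
necessary because $\eta$ is constant whenever no pair passes screening.
A score of exactly 0 is labelled genomic, favouring specificity.

**Candidate weighting.** The candidate joins $S$ with weight 1 (counts
$I + 1$); no weighting scheme is applied.

**ν and model selection.** Leave-one-out cross-validation scores each
fold by ROC AUC (rank/midrank estimator, identical to the trapezoidal
area); the selected $q$ maximizes $\nu_{auc} = \mu_{auc}(1-\sigma_{auc})$
where $\sigma_{auc}$ is by convention here the *population variance* of
the fold AUCs ("sd" is selectable, and the report echoes the choice).
Negative windows are drawn once per grid point and shared across folds,
which makes the selected $q$ invariant to the order of the training
sequences. Within each fold the discriminant is fitted on the $I-1$
training sites against `negatives_per_positive` (default 10) background
windows per positive. The AUC comparison utility for paired per-motif
results wraps the standard signed-rank test.

**Coordinates.** Positions are 1-based in models and reports; intervals
in BED output are 0-based half-open, with the conversion centralized in
the writers. Scans over both strands score the reverse complement of each
window with the same model and report the better-scoring strand; strand
ties go to `+`. Windows containing non-ACGT symbols are skipped and
counted, not scored.

## The lookup library

Scanning recomputes $(\rho, \eta)$ at every offset of a long sequence.
The $\gamma$ part needs only $L \times 4$ precomputed "redundancy after
appending symbol $x$ at position $i$" values; the $\omega$ part needs,
for each screened pair, only the $16$ possible post-append divergences
(one per symbol combination at the pair). Both tables are built once at
training time, reducing the per-window cost from $O(L^2)$ divergence
evaluations to indexed reads over the screened pairs. This is a pure
optimization: the test suite asserts bit-level agreement (within
$10^{-9}$, observed 0) between the lookup path and naive recomputation
over ten full 1,500-nt scans, and the equivalence holds by construction
for any input.

## What the synthetic generator emulates

`motif_spec()`/`sample_motif_set()` generate aligned sets with a
per-position conservation profile (consensus probability in $(0.25, 1]$;
0.25 would be background) and optional coupled position pairs: with
probability `coupling` the second position copies the first (identity
partner map), otherwise it draws independently. The identity map was
chosen because it yields a closed-form target joint — a diagonal-inflated
mixture — against which generator tests can assert exactly.
`sample_background()` provides i.i.d. or order-1 Markov background, and
`plant_motifs()` embeds seeded, non-overlapping motif realizations with a
BED ground truth. Defaults mirror the regime of curated TFBS collections
(motif lengths around 6–25, 9–44 sites).

The generator emulates conservation, pairwise coupling and composition —
the three properties the detector actually consumes. It does **not**
emulate promoter grammar, CpG islands, repeats, soft-masking, alignment
error, or non-stationary background; a pass on synthetic data therefore
demonstrates the statistical machinery under its stated assumptions, not
performance on genomic data, which additionally depends on alignment
quality and background inhomogeneity.

## Study conditions used by the test suite

The statistical checks run at fixed, seeded desk-scale conditions chosen
once:

* *Metric accuracy*: 1,000 randomized distributions/joints (including
  sparse and near-degenerate ones), $q \in (0, 2]$, against an
  independent compensated-summation oracle; observed error $< 10^{-13}$.
* *Screening recovery*: 3 planted coupled pairs, coupling 0.9, $I = 50$,
  $L = 12$, conservation 0.7 — mid-range conservation, because position
  pairs must vary to carry covariation — 20 seeds.
* *Complexity regimes*: $L = 4$ with both disjoint pairs coupled,
  conservation 0.4, $I = 30$, 8 coupling levels × 10 seeds. Realized
  complexity spans $C \approx 0.06$–$0.22$: with disjoint pairs and
  pseudocount smoothing the average pairwise divergence cannot approach
  its theoretical ceiling, but the full regime reversal (entropy-only
  better at the low end, divergence-only at the high end, gap increasing
  with $C$) is reproduced within that span.
* *Detection power*: $I = 20$, $L = 10$, conservation 0.92 versus i.i.d.
  background (held-out AUC $\ge 0.95$; observed $\approx 0.998$), and a
  background-only null (AUC $\approx 0.5$), 10 seeds each.

## Known limitations

* Only pairwise dependence is modelled; a motif whose structure is purely
  third-order would look independent to the screen.
* The $\eta$ feature is uninformative (capped constant) when no pair
  passes screening; the discriminant then works on $\rho$ alone, which is
  the intended degenerate behaviour but means the "full" detector equals
  the entropy-only detector on independent motifs.
* Feature values are inverses of small sums and therefore heavy-tailed;
  the QDA Gaussian assumption is a pragmatic approximation, serviceable
  because only the induced ranking and boundary matter.
* Scan scores are discriminant values, not calibrated p-values; threshold
  choice is left to the ROC operating point.
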