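---
title: "Methods: differential PPIN rewiring, effector competition, and information flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential PPIN rewiring, effector competition, and information flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppirewire)
```

`ppirewire` compares the protein–protein interaction network (PPIN) around a
bait panel between two cellular conditions ("hi" and "lo", e.g. high and low
oncogenic KRAS dosage) from replicate-level SILAC ratio tables. This
vignette documents the statistical models, the tunable parameters, the
synthetic-data generator, and the numerical and design decisions, in that
order. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Interaction scoring model

A *QuantTable* row is one log2 heavy/light ratio for a (bait, prey) pair in
one MS run (one biological x technical replicate of one pulldown). Three
tables enter the pipeline: bait pulldowns per condition, empty-vector
controls per condition, and direct hi-vs-lo comparisons per bait.

**Normalisation.** Reverse-labelled runs are sign-flipped to the forward
orientation, then every run's ratio set is median-centred to zero. Centring
is per MS run — per (bait, condition, replicate) — rather than per pooled
experiment, because the mixing error that centring removes is a property of
an individual run. This presumes most quantified proteins in a run are not
enriched, which holds when pulldowns quantify a large co-purification
background (see the generator section).

**Enrichment over controls.** Technical replicates are averaged into their
biological replicate first, so the test sample size is the number of
biological replicates and pseudo-replication is avoided. Each prey is then
tested with a one-sided Welch *t*-test of pulldown versus control log2
ratios. Empty-vector runs only quantify background binders, so most true
preys have no matched control rows; those are tested against the pooled
control ratio distribution of the same condition, which estimates the same
null (background ratios centred on zero). The reported effect is
`mean(pulldown) - mean(control)`.

**Significance A.** The outlier statistic for a log2 fold-change `r` within
a set of fold-changes uses percentile-based robust z-scores:
`z = (r - q50)/(q84.13 - q50)` above the median and
`z = (q50 - r)/(q50 - q15.87)` below, with
`sig_a = 0.5 erfc(z / sqrt(2)) = 1 - pnorm(z)`. The 84.13/15.87 percentiles
are the one-sigma quantiles of a Gaussian, so for Gaussian input `z` is an
ordinary z-score; for heavy-tailed input the percentile spread is robust to
the outliers being tested. `sig_a` is 0.5 at the median and decreases with
outlyingness on either side. By default percentiles are estimated within
each bait experiment (each bait's ratio distribution is its own null);
pooling across baits is a switch, and bait experiments with fewer than 10
preys fall back to the pooled distribution with a warning.

**Degenerate inputs.** A *t*-test cannot be formed from zero-variance
replicates; the P value is then set by the sign of the difference (1 for no
difference, 0 for a perfect separation in the tested direction) instead of
propagating NaN. Similarly, when a percentile spread of the fold-change
distribution collapses to zero (a point mass at the median, as in noise-free
data), significance A uses the limiting robust z — 0 at the median, infinite
off a fully degenerate side, the informative side's spread when only one
side is degenerate — and errors only when every value is identical. These
limits make the pipeline exact on noise-free data: planted rewiring is then
recovered without error, which the test suite checks.

**Filtering and rewiring.** Network membership requires the joint gate
*P* ≤ `p_max` and significance A ≤ `sig_a_max` (defaults 0.05/0.05, raw).
No multiple-testing correction is applied at these gates: the conjunction of
two correlated but distinct criteria is the pipeline's false-positive
control, and the joint false-positive rate on null preys is bounded by each
gate's level (the test suite verifies the realised false-rewiring rate stays
under the 5% ceiling). A second step removes preys retained for more than
`contaminant_max_frequency` (default 0.5) of all baits — a protein enriched
in a majority of unrelated pulldowns is treated as a nonspecific binder —
plus an optional user exclusion list. This frequency rule is the package's
own false-positive step; it stands in for bespoke upstream QC procedures
that processed-data consumers cannot reproduce.

An edge of the hi/lo union is *rewired* only if the direct hi-vs-lo
comparison (two-sided one-sample *t* against 0, plus significance A over the
bait experiment's fold-changes) passes the same joint gate. Rewired edges
present in one network only are gains/losses (`hi_only`/`lo_only`); rewired
edges in both are `shared_up_hi`/`shared_up_lo` by the sign of the
fold-change; everything else — including single-network edges without
statistical support — is `unchanged`. The five categories partition the
union, and relabelling hi as lo mirrors the categories exactly (significance
A is invariant under global negation because the percentile spreads swap
sides).

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions of a 95-bait differential EGFR-pathway screen:

| parameter | default | meaning |
|---|---|---|
| `n_baits` | 95 | bait panel size |
| `preys_per_bait` | 33 | Poisson mean of true preys per bait |
| `frac_hi_only`, `frac_lo_only`, `frac_shift` | 0.143, 0.092, 0.074 | planted category fractions of the edge union, matching the proportions of gained, lost and shifted interactions at full scale |
| `n_bio`, `n_tech` | 3, 2 | replicate design; label swap alternates with the biological replicate |
| `noise_sd` | 0.3 | per-replicate log2 ratio noise (log2 units) |
| `run_offset_sd` | 0.2 | per-run mixing offset removed by normalisation |
| `effect_gain` | 4 | absolute hi-vs-lo log2 effect of gained/lost edges |
| `effect_shift_range` | [2, 4] | absolute effects of shifted edges |
| `detect_miss_prob` | 0.9 | probability an absent edge leaves no trace in that condition's table |
| `n_background` | 300 | background preys quantified per pulldown at ratio ≈ 0 |
| `n_contaminants`, `contaminant_rate` | 100, 0.05 | nonspecific binder pool and its appearance probability per pulldown |

Preys live in one global namespace and are assigned by preferential
attachment (`new_prey_prob` controls hub strength), so shared hub preys and
a heavy-tailed degree distribution arise naturally. Gains and losses are
modelled as large finite log2 shifts (±4) rather than infinities, because
presence/absence in AP-MS manifests as detection-limited ratios; this keeps
one statistical machinery applicable to every category. Shifted edges split
their effect across the two conditions with the weaker side floored at +0.5
log2 enrichment, so a shifted interaction remains a detectable interaction
on both sides. An edge absent from a condition is usually missing from that
condition's table (probability `detect_miss_prob`) and otherwise appears at
near-zero enrichment, mimicking stochastic peptide detection.

Two defaults deserve justification. *Background size*: significance A and
median centring both assume a mostly-null ratio distribution; real pulldowns
quantify hundreds of background proteins alongside a few dozen true
interactors, and `n_background = 300` reproduces that regime. With a
background comparable in size to the true interactor set, the empirical
percentiles are contaminated by genuine enrichment and the statistic loses
its meaning — an instructive failure mode, not a usable setting. *Empty
vector contaminant rate*: the frequency of nonspecific binders in controls
is a free parameter (0.05 per pulldown) chosen so controls contain a handful
of quantified proteins per run, as typical.

What the generator does not emulate: peptide-level effects (missed
cleavages, shared peptides, intensity-dependent variance), ratio compression,
correlated biological replicates, and batch structure beyond the per-run
offset. Passing recovery tests therefore demonstrates the statistical
machinery is correct under the design's idealised noise model, not that real
data meet that model.

## Networks and topology

Networks are undirected spoke models: bait–prey edges only, since AP-MS
gives neither direction nor direct prey–prey evidence, and no matrix-model
inflation is performed. Duplicate rows collapse to one edge keeping the
better P value. Betweenness is Brandes', normalised by `(n-1)(n-2)/2`;
clustering is the local triangle fraction; average path length is taken over
the largest component (augmented singleton nodes are retained in the graph
but excluded from path statistics). Scale-freeness is fitted by least
squares of `log10 P(k)` on `log10 k` over degrees with nonzero counts — the
convention of the interactive network-analysis tools this mirrors —
with maximum-likelihood fitting available as `method = "mle"`; the log–log
fit is the default for comparability, not statistical superiority. Bait
ranking counts incident rewired edges, ties broken lexicographically for
reproducibility.

## Effector competition model

Effectors compete for the single effector-binding site of active KRAS. At
equilibrium the free KRAS concentration `r` is the unique root of
`g(r) = r (1 + sum E_i / (K_i + r)) - R_T` on `(0, R_T]`; `g` is strictly
increasing with `g(0) < 0 <= g(R_T)`, so bracketed bisection cannot fail,
and Newton polishing (derivative `1 + sum E_i K_i/(K_i + r)^2 >= 1`)
converges to a relative conservation residual below 1e-12. Only the fixed
point is solved: rate constants are not inputs, and the steady state is what
the dose-response analyses need. Complexes follow as
`C_i = r E_i/(K_i + r)`.

Classification is by `K_i` against the active-KRAS abundance; `K_i` exactly
equal to the abundance is labelled low-affinity (boundary convention: at the
boundary the site is at most half-occupied, the sub-saturated regime).
Bound-fraction fold-change between doses is non-decreasing in `K_i` — the
low-affinity > high-affinity dose-sensitivity prediction — which the test
suite verifies over 1000 random effector sets. The default catalogue is
illustrative and user-replaceable; no literature concentrations are
hard-coded as ground truth. AP-MS sensitivity scores are mean log
fold-changes over a pathway's measured preys, log2 by default (consistent
with SILAC ratios) with a natural-log option, compared to model ranks by
Spearman correlation.

## Information flow

The channel model scores nodes by expected visits of a damped random walk
from the source, conditioned on absorption at any sink before dissipation.
With `P` the row-stochastic transition operator (uniform over neighbours by
default; confidence weighting is available but off because no weighting
scheme is privileged), `d = 0.85` the damping factor, and `Q = d P`
restricted to transient nodes: visits are the source row of `(I - Q)^{-1}`,
the absorption probability solves `h = d (P_sink 1 + P_transient h)`, and
the conditioned score is `visits * h(v)/h(s)`. Sinks form one absorbing
class; per-sink attribution comes from the absorption split, which sums to
exactly 1 after conditioning (a tested invariant). Initial placement counts
as one visit, so the source scores at least 1. Cross-network comparison uses
each node's share of total network flow, because raw visit counts are not
comparable between networks of different size; raw scores are also reported.
Differential thresholds are a >2-fold share change for any node and ≥20%
for sink transcription factors. The implementation is a dense linear solve;
its correctness standard is an independent Monte-Carlo oracle (one million
simulated damped walks reproduce conditioned scores within 2% in the
acceptance suite), not numeric agreement with any particular legacy tool.

## Enrichment

The upper-tail hypergeometric probability `p(X >= k)` is computed via the
log-space stable distribution function and checked against exhaustive draw
enumeration for every background size up to 12. The enrichment background
defaults to the assayed-protein universe of the relevant table, never the
whole proteome. Complex coverage flags complexes with at least 70% of
members present (inclusive) and more than 60% of *present* members rewired
(exclusive); using present members as the rewired denominator is the
conservative reading, and the full member list is a switch. No correction is
applied inside single tests; `adjust_enrichment()` provides
Benjamini–Hochberg for batches.

## Problem sizes and verification

The test suite runs synthetic screens of 6–20 baits (a few hundred union
edges) and the acceptance script adds one full-scale 95-bait screen plus a
~500-edge calibration run (15 baits x 33 preys, noise 0.3, planted effects
≥ 2 log2 units, rewiring concentrated on three designated baits) for
precision/recall and bait-ranking recovery. These sizes were chosen so every
oracle comparison — exhaustive hypergeometric enumeration, brute-force
shortest-path metrics on ≤ 8 nodes, the one-effector quadratic, the
Monte-Carlo walk oracle — runs comfortably while exercising the same code
paths as the full design.

## Known limitations

- The pipeline consumes processed ratio tables; peptide-to-protein
  inference, run-level intensity normalisation and imputation are out of
  scope.
- The two-step false-positive filter's second step is a frequency rule, a
  documented stand-in for bespoke QC of the original processing chain.
- The rewiring gates are raw thresholds by design; users wanting FDR control
  across edges should apply `adjust_enrichment()`-style correction to the
  direct-comparison P values and tighten `ppi_thresholds()` accordingly.
- Exact category labels (gain versus shift) depend on detection: a strongly
  shifted edge whose weak side falls below detection is reported as a gain,
  which is a property of the data, not recoverable by the statistics.
- Information-flow results depend on the chosen source, sinks and damping;
  the automatic selection (best-connected shared bait, highest-degree shared
  reachable non-bait nodes) is a convenience for synthetic runs, and real
  analyses should supply a biologically motivated `flow_config()`.
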