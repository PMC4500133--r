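---
title: "Methods: linking co-expression topology to metabolic gene essentiality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking co-expression topology to metabolic gene essentiality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netflux)
```

# Overview

`netflux` implements an integrative workflow for microbial systems
biology: given (i) a gene-by-condition expression compendium, (ii) a
constraint-based metabolic model with gene–protein–reaction (GPR) rules,
and (iii) an optional gene-to-function map, it asks whether genes that
are *topologically central* in the co-expression network are also
*functionally essential* in the metabolic network.

The pipeline has four stages:

1. **Co-expression network inference** — mutual information (MI) between
   all gene pairs, standardized per gene against its own MI background
   (the CLR scheme), with a leave-2-conditions-out bootstrap; pairs whose
   Z-score reaches 4.5 in at least 375 of 500 iterations become edges.
2. **Topology** — connected components, four centralities (degree,
   eigenvector, betweenness, harmonic closeness), a max-normalized
   combined score, and the *topologically important* (TI) flag: the top
   50% of the combined score among non-isolated genes.
3. **Flux simulation** — per condition, a flux distribution estimated by
   expression-weighted flux minimization; every single-gene knockout
   simulated by a linearized minimization-of-metabolic-adjustment (MOMA)
   step plus a biomass-maximization lethality test; genes binned into
   Group 1 (no effect), Group 2 (altered relative fluxes), Group 3 (no
   growth in at least one condition). Groups 2–3 are *functionally
   important* (FI).
4. **Integration** — the TI × FI cross-classification (TF / Tf / Ft),
   Fisher-exact functional enrichment, and a Monte Carlo randomization
   comparing each group's mean centrality with same-size random gene
   sets.

# The co-expression stage

## MI estimation

The default estimator is the smoothed-histogram (B-spline) estimator:
each gene's `log2(x+1)` values are rank-scaled and spread over 10 bins
with order-3 B-spline weights, and MI is computed from the resulting
fractional joint counts. This is the estimator used by the original CLR
network-inference program, and the choice matters at compendium sizes of
a few dozen conditions: with hard equal-frequency binning
(`estimator = "plugin"`, also provided), the MI estimate's sampling noise
at `m ~ 40` conditions is of the same order as the spread of the per-gene
background, which caps per-gene Z-scores near 3 — below the conventional
4.5 edge threshold — no matter how strongly a pair is actually
co-expressed. The soft estimator roughly halves that noise and restores
the intended meaning of the threshold. Constant rows (e.g., unexpressed
genes) have zero MI against everything by construction.

## Per-gene standardization and the pair score

For gene *i*, `z_i(j)` standardizes `MI_ij` against the mean and standard
deviation of row *i* (diagonal excluded). Two pair-score combiners are
available:

* `combine = "clr"` (default): `sqrt(max(0, z_i)^2 + max(0, z_j)^2)` —
  the canonical CLR score;
* `combine = "min"`: `min(z_i(j), z_j(i))` — stricter, requiring the
  edge to be exceptional from both sides.

The default follows the canonical program for the same reason as the
estimator choice: at `m ~ 40`, a single gene's z-score is bounded by the
MI estimator's own sampling noise, so the min rule stalls well below the
conventional 4.5 cutoff even for near-perfectly correlated pairs, while
the canonical combination — which adds the two views in quadrature —
separates them cleanly (the recovery test in the acceptance suite
exercises exactly this regime). Both combiners are exposed; switching to
`"min"` reproduces the stricter rule.

## Bootstrap edge calling

Each of `n_boot = 500` iterations removes `drop_per_iter = 2` conditions
uniformly at random (without replacement within an iteration, one RNG
stream across iterations), recomputes MI and Z, and increments a support
counter for every pair at `Z >= 4.5` (closed boundary). Edges require
support in at least `support_min = 375` iterations. Support counts are
reproducible given the seed, and edge calling commutes with gene
permutation.

# Centralities on disconnected graphs

Co-expression networks at these thresholds are highly fragmented, so all
measures are defined on disconnected graphs:

* **degree** — adjacency row sums;
* **eigenvector** — dominant eigenpair of the whole adjacency matrix;
  the Perron vector lives on the component with the largest spectral
  radius and is zero elsewhere; computed by power iteration on `A + I`
  (the unit shift prevents oscillation on bipartite components, whose
  adjacency spectrum is symmetric), normalized to unit Euclidean length,
  residual `max|lambda e - A e|` kept below 1e-8;
* **betweenness** — geodesic pair dependencies (Brandes accumulation)
  over unordered pairs, endpoints excluded, unreachable pairs
  contributing zero, no normalization;
* **closeness** — the harmonic form `sum_j 1/g_ij` (with `1/Inf = 0`),
  which stays finite and informative when the graph is disconnected —
  the classical reciprocal-of-sum form would be zero for every node.

The combined score divides each measure by its maximum over genes and
averages; a measure that is identically zero on the graph (betweenness
on a union of cliques, for instance) carries no ranking information and
is dropped from the average rather than diluting it. Isolated genes have
all-zero centralities, are excluded from the per-measure maxima, and are
never TI; among the rest, the TI cut is the closed upper half at the
linearly interpolated median of the combined score (ties at the
threshold are included, so a fully tied graph is all-TI). A per-measure
TI mode (`per_measure = TRUE`) flags the top fraction of each individual
measure separately and reports each set without attempting to intersect
or union them.

# Flux estimation and knockouts

## Expression-weighted flux minimization

Reaction expression is the GPR evaluated numerically over the
condition's expression values — AND is `min` (limiting subunit), OR is
`max` (isozymes); genes missing from the expression matrix are imputed
at the condition median with a warning; reactions without a GPR are
"unmapped". Weights are `w_r = 1 - e_hat_r` with `e_hat_r` the mapped
expression min–max scaled to [0, 1] within the condition; unmapped
reactions get `w_r = 1`, and a flat expression profile degenerates to
the unweighted (parsimonious) minimization. The LP

    min sum_r w_r |v_r|   s.t.  S v = 0 (internal metabolites),
                                lb <= v <= ub,  v_biomass >= growth_floor

is linearized by forward/reverse flux splitting. `growth_floor`
(default 1, arbitrary units) anchors the otherwise scale-free solution;
every downstream comparison is biomass-normalized, so its exact value
only sets units. External metabolites are excluded from the balance, so
boundary reactions act as exchanges without special-casing.

## Knockouts

A knockout disables all reactions whose GPR evaluates FALSE with that
gene absent (boolean semantics, distinct from the numeric mapping). Two
LPs are solved per knockout:

* **lethality** — maximize mutant biomass; lethal iff the maximum falls
  below `growth_tol = 1e-6` times the parent biomass flux. MOMA alone
  cannot distinguish "no growth" from "reduced growth", hence the
  separate test.
* **adjustment** — minimize the L1 distance to the parent flux vector
  (the linear recast of the classically quadratic MOMA objective; the
  quadratic original is out of scope) under the knocked-out bounds.

Flux change is judged on biomass-normalized vectors at
`flux_tol = 1e-6` (sup-norm); anchoring the mutant to the parent vector
also suppresses spurious "changes" from LP alternate optima. If the
mutant cannot grow, relative distributions are incomparable and any
nonzero adjustment counts as a change.

Group rules: Group 3 = lethal somewhere; Group 2 = not Group 3 but
flux-changing somewhere; Group 1 = neither. The classifier also reports
how many Group-3 genes are lethal under every condition.

## The LP solver

No linear-programming package is available in the target R environment,
so the package ships a small dense two-phase simplex (Bland's rule,
tableau form, basis re-solve for accuracy) adequate for the tens of
variables these models produce. It is validated in the test suite
against vertex-enumeration on random LPs and against an independent
dense solver (`scipy.optimize.linprog`) on the flux problems themselves.

## Condition PCA

Condition-level flux vectors (biomass-normalized) are summarized by
mean-centered PCA; the "number of distinct flux profiles" is the number
of transitive equivalence classes of conditions at Euclidean distance
below `cluster_tol = 1e-4`. The tolerance is on normalized fluxes, i.e.
two conditions are merged only when their flux distributions are
identical to roughly four decimal digits per reaction.

# Integration statistics

The TI × FI cross-classification assigns TF (both), Tf (TI only),
Ft (FI only) or neither; by construction `|TF| + |Tf| = |TI|` and
`|TF| + |Ft| = |FI|`. Enrichment per functional category uses the
one-sided hypergeometric upper tail (Fisher's exact test for
enrichment) on the 2-by-2 table of set membership against category
membership; raw p-values are reported with a significance flag at 0.05
(a Benjamini–Hochberg column is available but off by default, since the
primary outputs are raw Fisher p-values). The direction is "higher than
the genome-wide percentage" — a depleted category can only reach p = 1.

The randomization compares a group's mean (optionally median) centrality
against `n_draws = 5000` same-size uniform draws without replacement
from the full universe — isolated, zero-centrality genes included, since
group membership includes them. Empirical p-values use the add-one
correction `p = (1 + #{null >= obs}) / (n_draws + 1)`, bounded away from
zero, with the depletion tail reported alongside.

# Synthetic data: what it emulates, and what it does not

## Expression

The generator plants co-expression modules in an otherwise independent
background: module genes share a per-condition latent factor (a common
regulatory driver), with gene-specific baselines and amplitudes, additive
Gaussian measurement noise, and truncation at zero to respect
RPKM-like semantics. The module's correlation parameter is calibrated to
be the *realized* pairwise correlation of the generated rows (the factor
share is inflated to compensate for the additive noise, capped at the
attainable maximum), so "correlation 0.95" means 0.95 on the data.
Defaults — baseline 100, amplitude 25% of baseline, noise 5% of
baseline — put the truncation four standard deviations below the mean,
where it almost never binds.

For the 100-gene recovery benchmark the planted module has 5 genes, the
scale of a small bacterial operon. The size matters for a reason worth
stating: CLR standardizes each gene's MI against its own row, assuming
true partners are a negligible fraction of that row. In a genome-scale
network a regulon is well under 1% of the background; in a 100-gene
benchmark a 10-gene module is 10% of every member's background and
visibly inflates the background standard deviation, degrading all
CLR variants. Five genes in one hundred is both realistic and inside the
regime the method was designed for.

What the generator does **not** emulate: read-count noise
(over-dispersion, library-size effects), condition covariance structure,
overlapping regulons, or anti-correlated modules. A green recovery test
therefore establishes that the inference machinery works in its intended
regime, not that it would reconstruct a real compendium's network.

## Metabolic models

Three topologies around an uptake → conversions → biomass skeleton:
a linear chain (every chain gene essential), parallel redundant routes
(route genes non-lethal but flux-altering), and a branched backbone with
a zero-bounded appendix (its gene silent). Ground-truth phenotype labels
are computed at generation time by *stoichiometric reachability* — not
linear programming — so the flux module is validated against a genuinely
independent oracle: a gene is lethal iff disabling its reactions
disconnects every stoichiometric route from medium to biomass, silent
iff its reactions cannot carry flux in the wild type, flux-altering
otherwise.

One subtlety: a redundant route's knockout only *manifests* as a flux
change if the route carries flux in some condition. The companion
expression generator therefore rotates route dominance across
conditions (as pathway usage shifts with environment in real data),
which guarantees each non-silent route is active somewhere and makes
the reachability labels and the LP-based group calls coincide —
exactly the property the recovery test asserts.

# Numerical choices

* simplex pivot tolerance 1e-9; Bland's rule for determinism and
  anti-cycling; the final basic solution re-solved from the basis matrix;
* steady-state residual required below 1e-9 on accepted flux states;
* eigenvector power iteration to 1e-10 on the iterate, residual checked
  at 1e-8; dominant-eigenvalue ties across components (e.g., two
  isomorphic components) converge to a valid vector in the dominant
  eigenspace — the residual criterion is the defining contract there;
* equal-frequency binning uses `ties.method = "min"`, keeping tied RPKM
  values (zeros especially) in one bin and making constant genes
  MI-silent; bin count `max(2, floor(sqrt(m)))` for the plug-in
  estimator, 10 B-spline bins (order 3) for the default;
* empirical p-values are add-one corrected; Fisher tests use the exact
  hypergeometric tail, not a chi-square approximation;
* quantile for the TI cut is the linear-interpolation (type 7) quantile
  with a closed upper boundary.

# Known limitations

* The simplex is dense and unsuited to genome-scale models with
  thousands of reactions; the scope here is small and synthetic models.
  The bootstrap, by contrast, handles hundreds of genes comfortably.
* MOMA is linear (L1); the quadratic original would distribute
  adjustment differently among alternate optima.
* The SBML reader/writer covers the subset this package emits
  (L3 + fbc-style bounds, GPRs, boundary species), not arbitrary SBML.
* Eigenvector centrality reports the global dominant eigenvector; genes
  outside the dominant component receive exact zeros, which is the
  intended convention but means the measure carries no information
  within smaller components.
* With `n_draws` randomization draws the smallest attainable p-value is
  `1/(n_draws + 1)`; group-size-1 nulls are heavily discrete.
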