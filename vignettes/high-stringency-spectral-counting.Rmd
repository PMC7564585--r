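---
title: "High-stringency spectral counting, NSAF quantitation, and the same-same PQ-FDR threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-stringency spectral counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccount)
library(dplyr)
```

## The problem

Spectral counting infers a protein's abundance from the number of
peptide-to-spectrum matches attributed to it in a run. It is simple and
widely used, but low-abundance proteins and small replicate numbers make
raw counts noisy, and search engines emit many identifications that are
not reproducible across replicates. `speccount` implements a two-part
answer: a stringency filter that keeps only reproducibly identified
proteins, and a permutation analysis that converts biological replicates
of a single condition into an empirical multiple-testing threshold.

## Minimum spectral counting

For each state (condition), replicate CSVs are collated by the union of
protein identifiers, absences coded as zero counts. A protein is
*high-stringency* in a state when

1. its count is positive in **every** replicate of that state, and
2. its replicate-summed raw count is at least `min_spc` (default 5).

The experiment-wide high-stringency inventory is the union of the
per-state qualifying sets: a protein reproducibly identified in *at least
one* state is retained, so proteins that vanish under treatment are not
lost. Both rules are evaluated within each state separately. The
unfiltered union ("All Proteins") is carried through the entire pipeline
in parallel so users can see why a protein of interest did not reach high
stringency.

Raising `min_spc` can only shrink the high-stringency set (a property the
test suite checks), and proteins injected into a single replicate can
never qualify.

## NSAF

Within one replicate, the normalised spectral abundance factor of protein
$k$ is

$$\mathrm{NSAF}_k = \frac{\mathrm{SpC}_k / L_k}{\sum_j \mathrm{SpC}_j / L_j}$$

with $L$ the molecular weight as supplied by the search engine. Molecular
weight enters only as a relative length proxy: any global unit factor
(Da vs kDa) cancels, so no unit conversion is attempted. The denominator
always runs over the replicate's full All Proteins basis, so NSAF values
are comparable between the two stringency streams; per replicate they sum
to 1 over that basis (tolerance 1e-9 in the tests).

**Zero handling.** A protein absent from a replicate has count 0 and an
undefined log. We substitute a configurable pseudocount (default 0.5
counts) in the numerator only — the denominator uses raw counts, which
preserves the sum-to-1 identity — so lnNSAF and t-tests are defined for
proteins missing from part of one state. The substitution is deliberately
visible in the statistics: a protein hit by dropout gets a strongly
deviant lnNSAF in that replicate, which inflates its within-group variance
and makes its test conservative rather than anticonservative.

Statistics and PCA run on the natural log of NSAF; fold changes are
reported in log2 of the ratio of group mean NSAF (treatment over control),
matching the conventional volcano-plot axes.

## Two-state comparison

Shared proteins are tested with a two-sided pooled-variance Student's
t-test on lnNSAF (Welch available via `var_equal = FALSE`). Degenerate
zero-variance inputs return p = 1 when the group means are equal and the
p = 0 limit otherwise. Without a derived threshold, significance is
p < `alpha` (default 0.05) with no fold-change gate; direction comes from
the sign of the log2 fold change.

"Unique to a state" is judged against the *other state's All Proteins
list*, not its high-stringency set: a protein that is high-stringency in
the control but seen at low stringency in the treatment is tested as
shared, and only proteins with no trace at all in the other state are
declared unique. This keeps borderline proteins in the tested set and
makes the unique lists mean "genuinely unobserved".

Swapping the control and treatment labels mirrors UP and DOWN, negates
every fold change, and leaves p-values unchanged — a property test in the
suite.

## Same-same permutation analysis and the PQ-FDR

With six replicates of a state, there are $\binom{6}{3}/2 = 10$
non-redundant ways to split them into two triplets. Comparing the two
halves of the same biological state with the full BH-modified testing
machinery measures how often the pipeline calls a difference where none
exists: the percentage of proteins with BH-adjusted value at or below a
threshold Q is the *protein-quantitation FDR* at Q. The curve is evaluated
on the grid Q = 0, 0.01, ..., 1, averaged over the ten partitions within
each six-replicate state, then across states (when both states carry six
replicates, both contribute; with only one six-replicate state its average
alone is the grand average). The reported threshold Q\* is the largest
grid point whose grand-average PQ-FDR is at or below the target (default
1%), refined by linear interpolation between the bracketing grid points —
the sub-grid refinement is why Q\* is generally not a multiple of 0.01. A
largest-grid-point rule without interpolation is available by reading the
curve directly. If even Q = 0.01 overshoots the target, Q\* = 0 is
returned with a warning. The two-state comparison is then re-classified
with q ≤ Q\* in place of p < 0.05, yielding the refined
upregulated/downregulated/unchanged/combined tables.

Proteins entering the same-same tests are the state's high-stringency set
with the MSC rules applied across all six replicates (presence in all six,
sum over all six), which is stricter than per-triplet qualification but
identical for every partition, keeping the ten curves comparable.

BH adjustment itself is the standard step-up procedure (delegated to
`stats::p.adjust`); the test suite checks it against an independently
written step-up oracle to 1e-12 on a thousand random vectors.

## Workflow routing and outputs

`plan_run()` routes on the file inventory alone: a single state yields the
two data-quality tables per state; two or more states add the comparison
tables and figures (proportional Venn, volcano, top-20 heatmap, p-value
histograms, inter-state PCAs of lnNSAF and spectral counts); when every
state has exactly six replicates the same-same outputs (PQ-FDR curves and
plot, combinatorial PCAs, refined BH-classified tables) are enabled on
top. With more than two states, each treatment is compared pairwise
against the control (the first state, or `--control`). `write_bundle()`
materialises everything under class-grouped subfolders with a
machine-readable `run_log.yaml`, and `bundle_outputs()` zips the tree
reproducibly (sorted member order, fixed row/column ordering in every
CSV).

Figure payloads are exactly the tables the underlying operations return —
rendering adds no computation — so every figure is recomputable from the
output CSVs. The volcano y-axis is $-\log_{10} p$ (the conventional
negation), the heatmap shows per-protein z-scored lnNSAF by default (raw
lnNSAF optional) with proteins ranked by p-value, ties broken by absolute
fold change then identifier, and the Venn is an exact-area two-circle
layout: radii proportional to the square root of each set size and centre
distance solved numerically so the lens area equals the shared count.
PCA treats replicates as observations and proteins as variables,
protein-centred and unscaled, since its role here is replicate-level
quality control.

## Input dialects

The input contract is a CSV per replicate named `{state}-{R#}.csv`
(the state label may contain hyphens; the token after the last hyphen is
the replicate number) holding identifiers, spectral counts, scores and
molecular weights. Column names differ by engine, so a YAML registry
(`inst/extdata/dialects.yaml`) maps each supported engine's documented
export columns onto the four canonical fields; detection is by
case-insensitive presence of the full signature in the header. The
registry is data, not code — engines change export formats across
versions, and users can point `dialect_registry()` at an edited copy.
Duplicate identifiers within a file (e.g. one row per protein-group
member) are merged by summing counts and keeping the best score, in the
direction the registry declares per engine (GPM's log(e) is better when
smaller). Rows with missing or non-positive molecular weight are dropped
with a warning.

## The synthetic data generator

`spc_design()` / `simulate_dataset()` emulate the input contract with
known ground truth: per-protein mean counts are log-normal across the
inventory (`baseline_meanlog = log(30)`, `baseline_sdlog = 0.8`),
per-replicate counts are negative binomial around the (possibly
fold-changed) mean with `dispersion = 25` — replicate coefficients of
variation of roughly 25–35% on top of counting noise, the
technical-replicate regime of reproducibly identified spectral-count
proteins — or Poisson for a clean null. Differential expression is
planted on `de_fraction` (default 0.2) of proteins at
`de_fold_change` (default 4), directions split evenly; dropout
(default 0.05 per cell) zeroes a sampled cell, and zero-count rows are
omitted from the written CSV exactly as a search engine omits an
unidentified protein, exercising the pseudocount pathway end to end.
Generation is fully seeded and byte-reproducible.

The defaults encode a deliberate power calibration: with three replicates
per group a pooled t-test has 4 degrees of freedom, and recovering 4-fold
changes with sensitivity above 0.9 — the regression guard the test suite
enforces — requires replicate lnNSAF standard deviations below roughly
0.35. Noisier settings (e.g. negative binomial size 4, CVs above 50%) cap
sensitivity near 0.55 regardless of abundance, which is a statement about
3-replicate designs rather than about the pipeline. Dropout is the other
power ceiling: each affected cell inflates that protein's variance via the
pseudocount, so at 2% cell dropout about 11% of proteins lose most of
their power; the power checks therefore use "low dropout" (0.005), and the
null-calibration checks use dropout 0 so they isolate t-test calibration.

What the generator does **not** emulate: protein-group ambiguity and
shared peptides, abundance-dependent identification probability (dropout
is uniform), correlated replicates (batch effects), or realistic score
distributions (scores are nominal fillers). Passing tests therefore show
the pipeline's logic and calibration under a well-behaved generative
model, not performance on any particular instrument's data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
inventories of 40–300 proteins, 20–50 Monte-Carlo repeats. These sizes
give binomial standard errors well inside the asserted bands (e.g. the
null p < 0.05 fraction is checked at 0.05 ± 0.015 over 50 repeats of 200
proteins) while keeping any single test file under a minute. NSAF
sum-to-1 is asserted to 1e-9; BH against the oracle to 1e-12; PQ-FDR
curves are exact counts, so monotonicity is asserted without tolerance.
Ties in the heatmap ranking are broken by descending absolute fold change
and then by identifier so the selection is total and deterministic. All
row and column orders in written outputs are fixed (identifier-ascending,
replicate-ascending), making bundles byte-comparable across runs.

## Known limitations

- Shared or distributed NSAF across protein groups is not implemented;
  each identifier row is treated as one protein.
- No mixed-stringency stream: a protein satisfying one MSC rule but not
  both is excluded from the high-stringency analysis (it remains in All
  Proteins).
- The t-tests are unmoderated; with three replicates per group, variance
  estimates are noisy, and the same-same threshold partly compensates at
  the inventory level rather than per protein.
- Same-same analysis requires exactly six replicates in a state; states
  with other replicate counts contribute comparisons only.
- Dropout handling by pseudocount substitution is conservative by
  construction; heavily dropout-affected proteins are more likely to land
  in UNCHANGED than to be false calls.
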