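# speccount

High-stringency spectral counting and NSAF quantitation for label-free
shotgun proteomics.

`speccount` takes the low-stringency protein identification CSVs exported
by PSM search engines (GPM/X!Tandem, MetaMorpheus, Proteome Discoverer),
filters them into a reproducible high-stringency inventory, quantifies with
normalised spectral abundance factors, tests for differential expression
between a control and one or more treatment states, and — when six
replicates per state are available — derives an empirical
Benjamini-Hochberg significance threshold from a same-same permutation
analysis. It is written for proteomics labs doing spectral-count
quantitation who want the whole control-vs-treatment workflow, including
figures and output tables, from a single function call.

## The method

**Minimum spectral counting (MSC).** A protein enters the high-stringency
set of a state when it is identified (spectral count > 0) in *every*
replicate of that state and its replicate-summed raw count reaches a
threshold (default 5). Random noise identifications are, by definition, not
reproducible, so this removes most of them; the unfiltered union is kept in
parallel as the "All Proteins" stream for transparency.

**NSAF quantitation.** Within each replicate, a protein's abundance is

    NSAF_k = (SpC_k / L_k) / Σ_j (SpC_j / L_j)

where SpC is the spectral count and L the molecular weight (a length
proxy; the ratio is invariant to the unit). NSAF values sum to 1 per
replicate; statistics run on lnNSAF. Zero counts receive a small
pseudocount (default 0.5) in the numerator only, so lnNSAF stays defined
for proteins missing from some replicates.

**Differential expression.** Shared proteins are compared with a two-sided
pooled-variance Student's t-test on lnNSAF, fold changes are reported as
log2(mean treatment NSAF / mean control NSAF), and every protein is
classified UP / DOWN / UNCHANGED / UNIQUE-to-a-state. "Unique" means truly
unobserved in the other state's All Proteins list; a low-stringency
sighting keeps the protein in the tested set.

**Same-same permutation threshold.** With six replicates per state, each
state's replicates are split into the 10 non-redundant 3-vs-3 partitions.
Any protein called differentially expressed between two halves of the same
biological state is a false discovery at the protein-quantitation level
(PQ-FDR). Per partition, BH-adjusted t-tests are evaluated along a
threshold grid Q = 0, 0.01, ..., 1; the resulting PQ-FDR curves are
averaged within state and then across states, and the threshold Q* at
which the grand-average PQ-FDR is 1% replaces the flat 0.05 cut-off in a
re-classification of the comparison.

## Worked example

The package ships a fixed 20-protein, two-state × three-replicate dataset
exercising every classification pathway:

```r
library(speccount)

dir <- file.path(tempdir(), "example")
worked_example(dir)                     # writes {state}-{R#}.csv files

bundle <- run_pipeline(dir, out = file.path(tempdir(), "results.zip"))
#> speccount run (comparison): control x3, treatment x3
#> 2 comparison table(s), 8 figure(s)

cmp <- bundle$comparisons[["treatment_vs_control.high_stringency"]]
glance(cmp)
#> # A tibble: 1 x 11
#>   control treatment stream    n_tested  n_up n_down n_unchanged ...
#> 1 control treatment high_str…       16     2      1          13
dplyr::filter(tidy(cmp), category != "UNCHANGED")
#> # A tibble: 5 x 8
#>   protein log2_fold_change   p_value category
#> 1 P02                -1.86   1.37e-4 DOWN
#> 2 P03                 2.01   1.90e-4 UP
#> 3 P07                   NA        NA UNIQUE_CONTROL
#> 4 P08                   NA        NA UNIQUE_TREATMENT
#> 5 P10                 1.05   4.03e-5 UP
```

Of the 20 proteins, 16 are testable at high stringency: P02 drops ~3.6-fold
(DOWN), P03 and P10 rise (UP), P07/P08 are seen in only one state
(UNIQUE), and the rest are UNCHANGED. The zip bundle contains the
data-quality tables, the per-category CSVs for both stringency streams,
and the figures (Venn, volcano, heatmap, p-value histograms, PCAs).

With six replicates per state the same run adds the PQ-FDR analysis:

```r
sim <- simulate_dataset(spc_design(states = c(control = 6, treatment = 6)),
                        dir = "simdata")
bundle <- run_pipeline("simdata")
bundle$samesame$threshold$q_star   # empirical BH threshold at 1% PQ-FDR
autoplot(bundle$samesame)          # PQ-FDR vs Q curve
```

A thin command-line wrapper is installed at
`system.file("cli", "speccount", package = "speccount")` with `run` and
`simulate` subcommands mirroring `run_pipeline()` and
`simulate_dataset()`.

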