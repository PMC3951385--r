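# qpcrstab

Reference-gene stability analysis for RT-qPCR normalization, end to end:
from raw amplification data to a defensible choice of housekeeping genes
and a quantitative picture of how much that choice moves your results.

## The problem

Relative quantification by RT-qPCR divides every target-gene measurement by
a normalization factor built from *reference* (housekeeping) genes. If those
references are not actually stable across the tissues and treatments in the
experiment, every downstream fold change inherits their wobble. Candidate
references therefore have to be validated per organism and per experimental
design — typically a panel of ~10 candidates measured over all conditions,
ranked by two complementary stability algorithms, and trimmed to the
smallest sufficient set.

`qpcrstab` implements that whole workflow as pipeable, data-frame-first R
functions:

* **Efficiency-corrected quantification.** Each well's starting quantity is
  back-calculated from its threshold cycle Ct, amplification efficiency E
  and threshold fluorescence R_Ct as

  R₀ = R_Ct · (1 + E)^(−Ct)

  with E fitted per well by log-linear regression over the best
  exponential-phase window of the raw fluorescence trace (or supplied per
  primer from a Ct-table export). Wells with outlying efficiencies are
  flagged by a Bonferroni-corrected studentized-residual test on the
  one-way ANOVA model across replicate groups.
* **Stepwise pairwise-variation ranking (geNorm-style).** A gene's M value
  is its average standard deviation of pairwise log₂ expression ratios with
  all other candidates; the least stable gene is removed iteratively until
  a tied most-stable pair remains. The pairwise variation V_n/V_n+1 between
  successive normalization factors, with the conventional 0.15 cutoff,
  gives the optimal number of reference genes.
* **Intra/inter-group decomposition (NormFinder-style).** Per gene and
  sample group, the systematic between-group difference d and within-group
  variance σ² are estimated after removing per-sample effects; the
  stability value ρ combines shrunken |d| with the intra-group sampling
  error, and an exhaustive pair search finds the best two-gene combination
  (opposite-sign group biases cancel).
* **Normalization and comparison.** Geometric-mean normalization factors,
  target-gene normalization, and per-sample percent differences between
  competing reference-gene choices.
* **Synthetic experiments with known truth.** A generator emulating a
  multi-tissue + multi-stress plant design (10 conditions × 3 biological ×
  3 technical replicates, 11 candidate references spanning Ct 21–27 with
  per-gene dispersions from under 1 to ~5 cycles, 7 condition-responsive
  target genes), so every stage is testable without instrument data.

## Worked example

```r
library(qpcrstab)

sim   <- simulate_experiment(sim_config(), seed = 1)
wells <- quantify_ct_table(sim$ct[sim$ct$role == "reference", ],
                           sim$efficiencies) |>
  detect_outliers()
rq    <- relative_quantities(wells)

fit <- genorm(rq)
fit
#> Reference gene stability ranking (stepwise pairwise variation)
#>   11 genes x 30 samples; V cutoff 0.15
#>   Most stable (tied pair): U2AF / eIF-4a
#>   Recommended number of reference genes: 2

tidy(fit)
#> # A tibble: 11 x 4
#>   gene    rank     m eliminated_round
#> 1 U2AF     1.5 0.285               10
#> 2 eIF-4a   1.5 0.285               10
#> 3 FTSH4    3   0.391                9
#> 4 UBQ6     4   0.448                8
#> # ...

nf <- normfinder(rq, groups = sim$annotation)
nf
#> Reference gene stability (intra/inter-group variance decomposition)
#>   11 genes x 30 samples (grouped)
#>   Best gene: U2AF (rho = 0.067)
#>   Best pair: eIF-4a + U2AF (combined rho = 0.049)
```

Both algorithms converge on the two candidates simulated as tightest
(`U2AF`, `eIF-4a`) and agree that the least stable gene is `TUB6`, the
candidate given strong stress-specific expression shifts. The M values are
the per-gene average pairwise log₂-ratio SDs at elimination (lower = more
stable); ρ combines each gene's between-group bias with its within-group
sampling error.

How much does the reference choice matter? The per-sample percent
difference between two normalization factors equals the relative difference
it induces in every normalized expression value:

```r
compare_normalizations(data.frame(sample = "flooding_1", nf = 1.24e-8),
                       data.frame(sample = "flooding_1", nf = 8.50e-9))
#>       sample     nf_a    nf_b pct_difference
#> 1 flooding_1 1.24e-08 8.5e-09       31.45161
```

i.e. two defensible reference pairs whose NFs differ by these amounts shift
every normalized value by ~31%.

`run_pipeline()` chains the full analysis (quantification, both rankings on
the standard sample subsets — all / abiotic / tissue / leaf+stem —,
normalization-strategy comparison) and writes CSV/JSON artifacts plus a run
manifest; `inst/cli/qpcrstab.R` exposes the same steps as shell
subcommands (`simulate`, `quantify`, `rank-genorm`, `rank-normfinder`,
`report`).

## Package layout

| Path | Contents |
| --- | --- |
| `R/quantify.R` | Ct determination, efficiency fitting, R₀, outlier screen, calibrated relative quantities |
| `R/genorm.R` | pairwise SDs, M values, stepwise ranking, NFs, V series, cutoff rule |
| `R/normfinder.R` | sample-effect removal, variance decomposition, ρ, best pair |
| `R/normalize.R` | target normalization, NF comparison, multi-subset validation report |
| `R/simdata.R` | synthetic experiment generator and ground truth |
| `R/io.R`, `R/plots.R` | CSV/JSON readers & writers, pipeline orchestration, autoplot methods |
| `vignettes/reference-gene-stability.Rmd` | methods: models, assumptions, tuning parameters, limitations |
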