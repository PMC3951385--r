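---
title: "Methods: reference-gene stability analysis for RT-qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-gene stability analysis for RT-qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

`qpcrstab` validates candidate reference (housekeeping) genes for RT-qPCR
normalization. This vignette is the package's account of the underlying
models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices a careful user should know about.

## 1. Efficiency-corrected quantification

### Model

A well's fluorescence during the exponential phase grows as
$F(c) = R_0 (1+E)^c$, where $R_0$ is the starting fluorescence
(proportional to starting template), $E$ the per-cycle amplification
efficiency ($E = 1$: perfect doubling), and $c$ the cycle. At the
threshold cycle $C_t$ the fluorescence equals the threshold $R_{C_t}$, so

$$R_0 = R_{C_t}\,(1+E)^{-C_t}.$$

`quantify_traces()` estimates all three quantities per well:

1. **Baseline correction.** The mean fluorescence of cycles 3–8 is
   subtracted. The first two cycles are skipped because instruments often
   report unsettled optics there; by cycle 8 a normally loaded reaction is
   still orders of magnitude below threshold, so the window measures pure
   background. This is a design choice; the window is exposed as
   `baseline_cycles` (set `NULL` to disable).
2. **Efficiency.** A log-linear regression of baseline-corrected
   fluorescence on cycle is fitted in a sliding window (default 4 cycles,
   minimum 3 — with fewer points $R^2$ is vacuous), keeping the rising
   window that maximizes $R^2$. The efficiency is the base of the fitted
   exponential minus one. Four cycles is long enough to average out
   per-cycle noise and short enough to stay inside the exponential phase
   of a typical 40-cycle run where the signal spans only ~2 orders of
   magnitude between detectability and plateau.
3. **Threshold cycle.** The fractional cycle where the corrected trace
   first reaches the threshold, by linear interpolation between bracketing
   cycles. The default threshold is 10% of the median per-well plateau
   across the plate: high enough to clear baseline noise, low enough to
   sit inside the exponential phase; it is overridable (`threshold`)
   because instruments let operators set it manually.

When only a Ct table is available, `quantify_ct_table()` computes $R_0$
with unit threshold fluorescence ($R_{C_t} = 1$) and per-primer
efficiencies. The unknown instrument threshold then cancels in every
within-gene ratio — relative quantities, normalization factors and
normalized profiles are unchanged — so nothing downstream depends on it.

### Replicate screening and aggregation

`detect_outliers()` screens amplification efficiencies for wells that
disagree with their replicates. Per gene it fits the one-way ANOVA model
of efficiency against replicate group and applies the textbook outlier
test: the largest absolute studentized *deleted* residual is compared to a
Bonferroni-corrected $t$ threshold at `alpha` (default 0.05, the
conventional level; the hypotheses being screened are "efficiency
comparable within groups" and "comparable between groups"). The flagged
well is removed and the test repeated. We deliberately do **not** gate on
the ANOVA $F$ statistic: a single grossly aberrant well inflates the
within-group mean square and can mask itself completely (on a 15-well
example with one well at $E = 0.70$ among values near 1.00, $F \approx
1.1$), whereas its studentized residual is enormous. Under the null the
flag rate per replicate set is $\approx$ `alpha` (slightly conservative,
as Bonferroni corrections are); the test suite verifies this calibration
on 500 simulated sets.

Technical replicates are aggregated by the **geometric mean** of their
$R_0$ — quantification noise is multiplicative on the linear scale (Ct
noise is additive, and $R_0$ is exponential in Ct), so the geometric mean
is the natural location estimate. Biological replicates are never pooled:
each of the 30 samples enters the stability analysis separately, which is
what gives the stability measures their power. We aggregate technical
replicates before ranking rather than feeding all wells in; the
alternative (all wells) slightly inflates every gene's apparent variance
by the technical component and does not change the rankings in our
simulations.

Relative quantities are calibrated per gene to the highest-expressing
sample (values in $(0, 1]$, at least one exact 1 per gene), matching the
spreadsheet convention most stability tools expect.

## 2. Stepwise pairwise-variation ranking

For genes $j, k$ with relative quantities $a_{ij}$, the pairwise variation
is the sample standard deviation over samples of $\log_2(a_j / a_k)$ —
zero for two ideal controls whose ratio is constant. A gene's **M value**
is its mean pairwise variation with all other candidates. `genorm()`
iteratively removes the gene with the highest M and recomputes until two
genes remain; those two cannot be ordered (pairwise variation is
symmetric) and are reported as a tied most-stable pair.

The number of reference genes worth using is decided from the pairwise
variation $V_{n/n+1}$: the SD over samples of
$\log_2(\mathrm{NF}_n / \mathrm{NF}_{n+1})$, where $\mathrm{NF}_n$ is the
geometric mean of the $n$ most stable genes. `recommend_count()` returns
the smallest $n$ with $V_{n/n+1} \le 0.15$; the comparison is inclusive
because the conventional reading treats a series value exactly at the
cutoff as acceptable. If nothing qualifies, the full panel size is
returned with an `exceeds_cutoff` flag rather than an arbitrary subset.

Numerical conventions: log base 2 throughout (the fold-change
convention); pairwise SDs use the $n-1$ denominator and are computed over
shared samples when values are missing; NFs are undefined (reported `NA`)
for samples missing any member gene; ties in M during elimination are
broken by removing the gene later in input order, and tied rounds are
recorded on the fit object. M and V are invariant to per-gene rescaling
(everything is built from log ratios), so the calibrator choice is
irrelevant to the ranking.

## 3. Intra/inter-group variance decomposition

`normfinder()` separates *how noisy* a gene is within sample groups from
*how biased* it is between them. With $y_{igj}$ the $\log_2$ quantity of
gene $i$ in sample $j$ of group $g$:

1. **Sample-effect removal:** $z_{igj} = y_{igj} - \bar y_{\cdot gj}$
   (per-sample mean over genes). Global per-sample effects — loading,
   cDNA input — are absorbed here, which also makes the result invariant
   to per-gene rescaling.
2. **Group statistics:** $d_{ig}$ = group mean of $z$ minus the
   group-size-weighted overall mean (so larger, better-estimated groups
   anchor the centering; balanced designs are unaffected);
   $\sigma^2_{ig}$ = within-group sample variance of $z$, scaled by
   $L/(L-1)$ to undo the variance absorbed by centering across $L$ genes;
   both floored at 0.
3. **Shrinkage:** the dispersion of *true* group differences is estimated
   by method of moments,
   $\gamma^2 = \max\!\big(0,\ \mathrm{Var}(d_{ig}) -
   \overline{\sigma^2_{ig}/n_g}\big)$, and each observed difference is
   shrunk by its reliability,
   $d^*_{ig} = d_{ig}\,\gamma^2 / (\gamma^2 + \sigma^2_{ig}/n_g)$ (zero
   when $\gamma^2 = 0$: no evidence of real group effects anywhere).
4. **Stability value:**
   $\rho_i = \frac1G \sum_g \big( |d^*_{ig}| +
   \sqrt{\sigma^2_{ig}/n_g} \big)$ — a gene is penalized for systematic
   group bias *and* for the sampling error its noise would inject into a
   normalization factor. Lower is more stable.

The best two-gene combination treats each pair as a pseudo-gene with
$d_{\mathrm{pair}} = (d_i + d_k)/2$ and $\sigma^2_{\mathrm{pair}} =
(\sigma^2_i + \sigma^2_k)/4$ and minimizes $\rho$ by exhaustive search
(ties broken lexicographically and recorded). Opposite-sign group biases
cancel in the average, which is why the best pair is often better than
the best single gene. Without a grouping (or a single group), $\rho$
reduces to the gene's SD after sample-effect removal.

This estimator is a documented, self-consistent implementation of the
intra/inter-group decomposition idea; exact numeric agreement with any
particular spreadsheet add-in is not claimed. Its defining formulas are
pinned down by oracle tests (independent step-by-step recomputation on
random matrices to 1e−9) and by parameter-recovery simulations.

Interpretation note: the two algorithms measure different things — the
stepwise M value rewards genes that co-vary with the panel, the
decomposition rewards genes with small group bias and small sampling
error — so their rankings legitimately disagree on middling genes. The
package treats them as complementary and reports both.

## 4. Normalization and strategy comparison

`normalization_factor()` is the geometric mean of the chosen references'
quantities per sample; `normalize_targets()` divides target $R_0$ by it.
`compare_normalizations()` reports, per shared sample,
$100 \cdot (\mathrm{NF}_{\max} - \mathrm{NF}_{\min}) / \mathrm{NF}_{\max}$
— expressed relative to the larger NF so the number equals the relative
change in normalized expression induced by switching reference sets; it
is symmetric and bounded in $[0, 100)$. `run_validation()` assembles, per
sample subset, the stepwise method's recommended set, the
decomposition's best pair, and the least-stable genes flagged by both
methods, normalizes the targets with each, and tabulates the NF
differences. For reporting, biological replicates are summarized as mean
± SD (the plotting helper), a choice the underlying tables do not force
on the user.

## 5. The synthetic-data generator

`sim_config()` encodes the emulated study: 10 conditions (leaf, stem,
rachis, root; drought, salt, cold, heat, wounding, flooding applied to
leaves) × 3 biological replicates = 30 samples, 12 tissue and 18
abiotic-stress samples, 3 technical replicates each; 11 candidate
reference genes and 7 cellulose-synthase-family target genes with strong
tissue/stress-specific expression.

The generative model works in Ct space, the scale on which the
instrument's noise actually lives:

* per (gene, sample): a $\log_2$ expression deviation = condition shift +
  Normal biological noise (`bio_sd`, in $\log_2$ units);
* the true threshold cycle is `base_ct` − deviation / $\log_2(1+E)$, and
  the true $R_0$ follows from the quantification identity exactly (the
  generator is the inverse of `compute_r0()` to 1e−9, a tested
  invariant);
* per well: Normal technical Ct noise (`tech_sd`, default 0.15 cycles — a
  typical SYBR triplicate scatter);
* optional traces: baseline + plateau-saturated exponential,
  $F = \mathrm{plateau} \cdot x/\sqrt{1+x^2}$ with
  $x = R_0(1+E)^c/\mathrm{plateau}$. The saturation knee is deliberately
  sharp so the curve is still purely exponential at the default threshold
  height; the fitting contract only concerns the exponential phase.

Defaults were mapped from the emulated study's printed summaries:
baseline Cts span 21–26.7 (two abundant genes near Ct 21, the scarcest
near 27); per-gene biological SDs span 0.15–0.90 $\log_2$ units, with
stress-specific shifts on two genes (SAMDC down-regulated under several
stresses, TUB6 responsive to wounding/flooding/cold) raising their
effective across-sample dispersion to ≈1.1. A printed per-gene Ct *range*
over 30 samples was converted to a generative SD via the expected range
of a Normal sample, range ≈ 4.1σ at n = 30 — so the printed extremes 0.88
and 5.10 cycles correspond to σ ≈ 0.21 and ≈ 1.24. The defaults keep one
gene (U2AF) clearly tightest: with only 30 samples the sampling error of
any stability estimate is large enough that near-tied candidates cannot
be reliably ordered, and a design whose "most stable gene" is a
coin-flip would make ground-truth recovery tests meaningless. Primer
efficiencies are the printed per-primer values (0.967–1.079); the
validator accepts (0.9, 1.15).

What the generator does **not** emulate: inhibitors and primer-dimer
artifacts, multi-plate batch effects, probe chemistries, non-Normal
heavy-tailed technical error, and correlated biological noise between
genes beyond the shared per-sample effect. Tests passing on this
generator therefore demonstrate correctness of the *computations* and
sensible behavior under a realistic noise envelope — not robustness to
every pathology of real plates.

Problem sizes used in the shipped tests were chosen to exercise the
design at its native scale (30 samples × 11 candidates, 20 replicate
simulations for stochastic checks, 50 random matrices for oracle
equivalence, 500 sets for the outlier-test calibration).

## 6. Numerical choices and degenerate inputs

* Ct interpolation is linear between bracketing cycles; a trace that
  never reaches threshold, or whose first cycle already exceeds it, is a
  hard per-well error (surfaced as `qc_note` by the plate-level driver).
* Flat traces and traces without a rising positive-fluorescence window
  are errors, not silent zeros.
* Efficiency windows with non-positive corrected fluorescence or
  non-positive slope are skipped; $R^2$ comparisons among remaining
  windows are exact (no tolerance).
* With exactly two genes, both M values equal the single pairwise SD
  (documented edge behavior); the stepwise ranking itself requires three.
* Missing values: pairwise SDs use shared samples (≥2 required per
  pair); NFs are `NA` where a member gene is missing; the decomposition
  requires a complete matrix and drops incomplete samples with a warning.
* Singleton replicate groups are untestable for outliers and are left
  unflagged with a note.
* All stochastic functions take explicit seeds; artifacts record the seed
  and an input hash in a run manifest.

## 7. Known limitations

* The stepwise ranking inherits the known weakness of pairwise-ratio
  measures: co-regulated gene sets look artificially stable. Running both
  algorithms and inspecting disagreements is the intended mitigation.
* The decomposition's $\gamma^2$ is a single pooled moment estimate; with
  very few genes or groups it is noisy, and $\rho$ differences smaller
  than ~1 sampling SE should not be over-interpreted.
* No confidence intervals are attached to M or $\rho$; ranks near the
  middle of the table are not meaningfully ordered at n = 30.
* Multi-plate inter-run calibration and melting-curve QC are out of
  scope; inputs are assumed to come from one calibrated run.
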