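# emmod — empirical mode modeling of coupled environmental time series

`emmod` is an R package for asking *does variable A force variable B, and
on which time scale?* of long monthly environmental records — the kind of
question posed of agricultural production totals and lake nutrient
concentrations, where a slow nonlinear trend, a strong annual cycle, weak
interannual oscillations, and autocorrelated noise are superimposed on one
another.

It implements the empirical mode modeling (EMM) chain end to end:

1. **Ingestion** — CSV station records, multi-station averaging, natural
   cubic-spline regularization onto a monthly decimal-year grid.
2. **Empirical mode decomposition (EMD)** — sifting a series into
   intrinsic mode functions (IMFs) $x(t)=\sum_k c_k(t)+r(t)$, with the
   residual $r(t)$ carrying the decadal nonlinear trend.
3. **Hilbert band classification** — each IMF's mean instantaneous
   frequency $\bar f$ assigns it a period $T=1/\bar f$ and a band:
   intra-annual ($0.5 \le T \le 2$ yr), interannual ($T > 3$ yr), an
   explicit unclassified gap in between.
4. **Convergent cross mapping (CCM)** — simplex projection in a
   time-delay embedding; direction `X:Y` (states of X predict Y) with
   convergent skill $\rho(L)$ over library sizes $L$ is evidence that
   *Y forces X*. All neighbor searches enforce a 12-sample (one-year)
   exclusion radius against autocorrelation and seasonal leakage.
5. **Surrogate significance** — Ebisuzaki random-phase surrogates preserve
   the power spectrum; the empirical p-value is
   $p = 1-\mathrm{CDF}(\rho_{XY}^N)\,\big|_{\rho_{XY}}$.

A synthetic-data module (`emm_emulator_pair()`, `coupled_logistic_pair()`,
`null_pair()`, `irregular_station_sampler()`) generates fixtures with the
statistical anatomy the analysis assumes, so the whole chain is testable
without any external download.

## Worked example

Generate a coupled driver/response pair (driver forces response with lag 1
month), decompose, cross map, and test significance:

```r
library(emmod)

pair <- emm_emulator_pair(emulator_config(seed = 42))
pair$driver
#> <emm_series> driver: 570 points, 1973.0000..2020.4167

dec <- emm_decompose(pair$driver)
classify_imfs(dec)
#>   component imf_index mean_period_years         band
#> 1      imf1         1          1.076272 intra-annual
#> 2      imf2         2          3.405351  interannual
#> 3      imf3         3         11.025889  interannual
#> 4      imf4         4         16.354514  interannual
#> 5  residual        NA                NA        trend

# driver forces response, so the response's states should predict the
# driver (direction response:driver) with convergent skill
cfg <- embedding_config(E = 3, exclusion_radius = 12)
yx <- ccm_sweep(standardize(pair$response), standardize(pair$driver), cfg,
                subsamples = 10, seed = 42)
yx
#> <emm_ccm> response:driver: skill 0.693 -> 0.934 over L = 5..568
assess_convergence(yx)$convergent
#> [1] TRUE

surrogate_test(standardize(pair$response), standardize(pair$driver),
               "surrogate-Y", N = 200, cfg, seed = 43)
#> <emm_surrtest> response:driver: rho = 0.934, N = 200, p = 0.0000
```

Reading the output: the annual mode (1.08 yr) lands in the intra-annual
band and the slow modes in the interannual band; cross-map skill rises
from 0.69 at a 5-point library to 0.93 at the full library (convergence
Δ = 0.24), and the observed skill exceeds all 200 phase-randomized
surrogates (p = 0) — the designed causal direction is detected.

The same chain runs from CSV inputs and a flat config file through
`run_all()` (stages: `run_decomposition()`, `run_scaled_comparison()`,
`run_ccm_suite()`, `run_surrogate_tests()`), writing fixed-format CSV
tables and a JSON manifest; `inst/scripts/emm-pipeline.R` wraps it for the
shell, and `inst/extdata/run-config-template.txt` documents the config
schema.

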