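# phosflux

Substrate-preference kinetics for engineered phosphatases, and dynamic
simulation of *N*-acetylglucosamine (GlcNAc) biosynthesis under biosensor
feedback.

## The problem

GlcNAc production in engineered *E. coli* hinges on a promiscuous
phosphatase (BT4131 and its variants M1–M4) that dephosphorylates four
competing phosphosugars: Glc6P, Fru6P, GlcN6P and the desired substrate
GlcNAc6P. Engineering campaigns quantify each variant by its catalytic
efficiency $k_{cat}/K_m$ per substrate, and the question that matters for
the cell factory is dynamic: given a variant's measured preference
profile, how does the pathway behave when the phosphatase is expressed
under a GlcNAc6P-responsive biosensor, with glucose uptake throttled by
phosphosugar pressure?

`phosflux` is for enzymologists and metabolic engineers who need both
halves in one tested, seeded, tabular workflow:

* **Kinetics** — Michaelis–Menten fitting of initial-velocity assays
  ($v_0 = v_{max} s / (K_m + s)$, $k_{cat} = v_{max}/[E]$), fluorescence
  plate normalisation $(FP - FP_{bg})/(OD - OD_{bg})$, and fold-change /
  percent-change preference reports over a kcat/Km panel. The measured
  BT4131 variant panel ships as a fixture (`bt4131_panel()`).
* **Simulation** — an 8-state, 12-reaction dimensionless ODE model of the
  pathway (glucose → Glc6P → Fru6P → GlcN6P → GlcNAc6P → GlcNAc, with
  phosphatase side-drains to glucose, fructose and glucosamine). The four
  phosphatase rates carry a Hill induction prefactor
  $p + v_{max}\, x_7^n/(K_a^n + x_7^n)$ driven by GlcNAc6P, and uptake is
  inhibited as $v_1 = v_{1max} K_i^{n_t}/(K_i^{n_t} + (\sum \text{phosphosugars})^{n_t})$.
  Unknown kinetic constants are sampled (seeded, paired across variants)
  and variants are compared by ensemble medians and per-draw win
  fractions.

Everything takes data frames and returns tibbles; fitted and simulated
objects have `tidy()`, `glance()` and `autoplot()` methods. Synthetic-data
generators (`generate_velocity_data()`, `generate_plate_data()`) carry
their ground truth so every stage is testable without external data.

## Worked example

Fit a noisy synthetic assay at the standard design (1–80 mM grid,
triplicates, 1% CV), then inspect the packaged variant panel:

```r
library(phosflux)

d <- generate_velocity_data(1, 5, assay_design(noise_cv = 0.01, seed = 42))
fit_michaelis_menten(d, enzyme_conc = 0.5)
#> Michaelis-Menten fit (21 obs, 7 concentrations)
#>   vmax = 0.991676 (se 0.00458)
#>   Km   = 4.83744 mM (se 0.0866)
#>   kcat = 1.98335 min^-1, kcat/Km = 0.41 mM^-1 min^-1
```

The generating truth was `vmax = 1`, `Km = 5`: both recovered within ~3%.
The preference report compares every variant to wild type per substrate —
on GlcNAc6P, M1 is the published "1.4-fold increase" (excess) and M4 the
"9.5-fold" (ratio):

```r
preference_report(bt4131_panel()) |>
  dplyr::filter(substrate == "GlcNAc6P") |>
  dplyr::select(variant, kcat_km, ratio, excess, percent_change)
#> # A tibble: 5 × 5
#>   variant kcat_km ratio excess percent_change
#>   <chr>     <dbl> <dbl>  <dbl>          <dbl>
#> 1 WT         13.3  1      0                0
#> 2 M1         31.9  2.40   1.40           140.
#> 3 M2         67.5  5.08   4.08           408.
#> 4 M3         74.7  5.63   4.63           463.
#> 5 M4        126.   9.51   8.51           851.
```

`check_reported_changes()` re-derives all ten published comparison claims
from the panel and flags each against its printed value and convention.

A small paired ensemble (25 draws here; 200 is the analysis default)
compares variants on shared parameter draws:

```r
ens <- run_ensemble(sampling_spec(n_draws = 25, seed = 1))
compare_variants(ens) |>
  dplyr::select(variant, median_final_product, median_max_glcnac6p, win_fraction)
#> # A tibble: 4 × 4
#>   variant median_final_product median_max_glcnac6p win_fraction
#>   <chr>                  <dbl>               <dbl>        <dbl>
#> 1 WT                      9.52              0.328          0.5
#> 2 M1                      9.36              0.116          0.52
#> 3 M2                     11.8               0.0701         0.56
#> 4 M3                     16.4               0.0950         1
```

M3 — the variant with the strongest GlcNAc6P preference — makes the most
GlcNAc in every draw (`win_fraction = 1` against WT) while keeping the
GlcNAc6P signal far below the wild-type peak. `autoplot(ens)` draws the
per-variant product distributions; `tidy(ens)` returns the per-draw
summaries. See the methods vignette
(`vignettes/glcnac-pathway-methods.Rmd`) for the model, the sampling
scheme, numerical choices, and a frank account of which published
qualitative observations this parameterisation does and does not
reproduce.

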