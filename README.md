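# rootcea

Tooth-level Markov cost-effectiveness analysis of topical strategies for
high-risk root caries: semiannual 38% silver diamine fluoride (SDF)
application versus 5% sodium fluoride (NaF) varnish.

## The problem

Root caries — decay of exposed root surfaces — is common in adults with
limited dental access, and untreated lesions end in extraction. SDF is cheap,
brush-on, and both *prevents* new lesions and *arrests* active ones; NaF
varnish is preventive only. For a 45-year-old safety-net patient with 21
teeth, which strategy buys more extraction-free tooth-years per dollar over
19 years?

`rootcea` answers this with a five-state Markov cohort model run per tooth.
States: caries-free, active root caries, caries arrest, persistent caries,
and extraction (absorbing). Each model year has two 6-month transitions — a
natural-history step (incidence only) and a treatment visit (prevention,
arrest, extraction) — with arrested teeth relabelled caries-free and
persistent lesions relabelled active at each cycle start. Under NaF the
arrest branch is structurally closed.

Per strategy *s*, discounted outcomes are accrued over the 38 half-cycle
boundaries (3% per year, boundary time *t = k/2*):

- effect: `E_s = Σ_k 0.5 · u' x_k · 1.03^(-k/2)` (utility-weighted
  non-extracted occupancy `x_k`, in extraction-free tooth-years per tooth);
- cost: application cost per surviving tooth plus the tooth's share of the
  semiannual visit costs (examination, radiography, care
  assistance/transport), summed over the 21-tooth cohort.

Strategies are compared by the incremental cost-effectiveness ratio
`ICER = ΔC / ΔE` and net monetary benefit `NMB = WTP·E − C` at a reference
willingness-to-pay of US$50 000 per tooth-year. One-way sensitivity analysis
re-runs the comparison across each unit-cost range, and probabilistic
sensitivity analysis (1000 Monte Carlo draws; beta distributions on
probabilities, gamma on costs) yields cost-effectiveness acceptability
curves.

The packaged default parameters are **synthetic, calibrated stand-ins**: the
original transition probabilities live in unpublished supplementary
material, so `calibrate_base_case()` fitted probabilities (and a caries-state
utility weight) that reproduce the published base-case costs and effects
within 0.3%. They are suitable for method validation, not for quoting as
clinical estimates.

## Worked example

```r
library(rootcea)

params <- default_parameters()   # calibrated synthetic fixture
res <- base_case(params)
tidy(res)
#> # A tibble: 2 × 7
#>   strategy   cost incremental_cost effect incremental_effect  icer     nmb
#>   <chr>     <dbl>            <dbl>  <dbl>              <dbl> <dbl>   <dbl>
#> 1 NAF       8863.              NA    1.39              NA      NA   60641.
#> 2 SDF      16699.            7836.   7.71               6.32 1239. 368926.
```

NaF costs US$8863 and yields 1.39 extraction-free tooth-years per tooth; SDF
costs US$16 699 for 7.71 tooth-years. SDF therefore buys 6.32 extra
tooth-years for US$7836 — an ICER of US$1239 per extraction-free tooth-year,
far below the US$50 000 reference willingness-to-pay, for an incremental NMB
of about US$308 000.

```r
one_way(params, "c_sdf", c(31, 39, 47))
#> # A tibble: 3 × 4
#>   parameter value  icer incremental_nmb
#>   <chr>     <dbl> <dbl>           <dbl>
#> 1 c_sdf        31  808.         311011.
#> 2 c_sdf        39 1239.         308285.
#> 3 c_sdf        47 1671.         305559.

psa <- run_psa(draw_psa(params, n = 1000, seed = 42))
curve <- ceac(psa, seq(0, 5000, by = 50))
ceac_crossover(curve, "SDF")
#> [1] 1239
autoplot(curve)
```

A higher SDF price raises the ICER but never threatens cost-effectiveness;
the acceptability curve crosses 50% at a willingness-to-pay of about
US$1239 per tooth-year, matching the deterministic ICER.

Batch runs: `report_base_case()`, `report_one_way()`, `report_psa()` write
publication-style CSV tables with JSON manifests, and `inst/cli/rootcea` is
a thin command-line wrapper over them.

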