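# taxalag

Quantifying how long it takes to formally describe a species, from the
metadata of its type series.

## The problem

A new species does not enter science when it is first caught: it enters when
its description is published. Between those two moments sit years — sometimes
decades — of fieldwork, shelf time and writing. For groups in crisis, such as
tropical frogs, that lag is a conservation problem in itself: undescribed
species have no legal protection, and many will vanish before they are named.

`taxalag` turns the raw material of that question — the collection dates of
the holotype and paratypes and the publication date of each description —
into a reproducible analysis. Given one table of type-series metadata it
computes, for every species, three additive periods:

* **overall description process** — first type specimen collected → description published;
* **collection** — first → last type specimen collected;
* **description sensu stricto** — last type specimen collected → publication
  (delimitation, diagnosis, writing, review).

Day spans are converted to years with a fixed 365.25-day year, so
`overall = collection + description` holds exactly for every species.

Around that core the package provides:

* a parser for imprecise collection-date strings ("5–7 December 2008",
  "February 2007", "1925"), resolved to the **midpoint** of the implied day
  interval (floor of the mean day, so "February 2007" → 2007-02-14);
* **field-trip segmentation**: consecutive collection events more than
  30 days apart belong to different trips;
* the **summary battery** per region and period: min, mean, SD, 10% trimmed
  mean, median, MAD (×1.4826), max, range, skewness, excess kurtosis, SE and
  a normal 95% CI half-width;
* **Gaussian linear mixed models** for log description time with genus and
  region random intercepts (ML, identity link), Type-II Wald chi-square
  tests, null-model comparison by likelihood ratio and AIC, and
  simulation-based scaled-quantile residual diagnostics (uniformity,
  dispersion, outliers);
* **temporal trends** per year with linear-versus-additive (penalized cubic
  spline) model selection by R², plus LOESS smoothing for presentation;
* a **synthetic-data generator** that draws whole type-series datasets from
  the exact generative structure the mixed model assumes —
  `description_y = exp(b0 + Xb + u_genus + v_region + e)` — with known
  ground truth, so every stage of the pipeline is testable without any
  external download.

## Worked example

Simulate the default synthetic study (four regions, 896 species, seed 11),
decompose the lags, and fit the global mixed model:

```r
library(taxalag)

gen  <- generate_dataset(generator_config(seed = 11))
gen$records
#> <taxalag_records> 896 species, 3070 collection events, 0 excluded
#>   regions: Ecuador (208), India (204), Madagascar (215), Melanesia (269)

lags <- compute_lags(gen$records)
summary_table(lags, "global")   # abridged, rounded
#>        period   n mean_y median_y trimmed_mean_y mad_y skew se_y
#> 1     overall 896  11.67     6.98           8.65  5.61 4.65 0.51
#> 2 description 896   7.21     4.95           5.94  3.79 2.77 0.23
#> 3  collection 896   4.46     0.04           1.40  0.06 6.06 0.46

cumulative_within(lags, c(5, 10, 25))
#>   threshold_y fraction
#> 1           5    0.327
#> 2          10    0.626
#> 3          25    0.914

fit <- fit_lmm(build_model_frame(gen$records, lags))
fit
#> <taxalag_fit> scope global | n = 896 | fixed: genetics, n_authors, n_types,
#>   n_species_in_paper, n_trips, genus_richness | random: genus, region
#>   logLik -1067.92, AIC 2155.84, converged: TRUE

wald_anova(fit)
#>                 term chisq df            p
#> 1           genetics 15.13  1 0.0001006206
#> 2          n_authors  9.14  1 0.0025055461
#> 3            n_types  0.17  1 0.6781977382
#> 4 n_species_in_paper  2.54  1 0.1111598113
#> 5            n_trips  9.79  1 0.0017565284
#> 6     genus_richness  0.47  1 0.4926955669

simulate_residuals(fit, seed = 1)
#> <taxalag_residuals> n = 896, n_sim = 250
#>   uniformity KS D = 0.023 (p = 0.733)
#>   dispersion ratio = 1.008 (p = 0.853)
#>   outliers = 7 (p = 1.000)
```

Reading the output: the pooled lag distribution is heavily right-skewed
(mean 11.7 y vs median 7.0 y), most species have a near-zero collection
period (median 0.04 y — half the type series are gathered in a single trip:
51.9% here), and on the log scale descriptions that used genetics took
longer (positive coefficient, p ≈ 1e-4) while more authors and more field
trips are associated with faster descriptions. The residual diagnostics show
the model reproduces its own data (uniform residuals, dispersion ratio ≈ 1),
as they should on generator output.

The same pipeline runs on real data: `read_records()` ingests a CSV or XLSX
table (long or wide layout, with a column mapping for foreign headers),
routes malformed rows to an exclusion log instead of dropping them silently,
and `run_all(pipeline_config(...))` writes every table and model JSON in one
deterministic pass. A thin command-line wrapper is installed at
`inst/cli/taxalag.R`.

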