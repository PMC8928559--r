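# predchar

Predictive characterization of crop wild relative germplasm: selecting
small subsets of georeferenced wild populations that are more likely than
chance to carry a target trait, so breeders can collect and screen dozens
of populations instead of hundreds.

Wild relatives of crops (the motivating case is wild lentils — *Lens
nigricans*, *L. ervoides*, *L. lamottei*, *L. culinaris* ssp.
*orientalis* — across Europe and Turkey) evolved under natural selection
and hold adaptive variation that cultivated gene pools lack. `predchar`
implements the two standard selection strategies over a georeferenced
occurrence table and gridded environmental layers:

* **Environmental filtering** — threshold rules on each population's site
  environment. Drought candidates live where the De Martonne aridity
  index `IarDM = P / (T + 10)` and its flowering-season variant
  `IarDMf = mean(12 Pm / (Tm + 10), March–June)` are both below 15;
  salinity candidates sit on conductive topsoil (> 4 dS/m, falling back
  to the 2–4 dS/m tier); waterlogging candidates combine poorly drained
  texture classes (Clay, Silty Clay, Sandy Clay, Silty Clay Loam) with
  `IarDM > 25`. Each subset is capped at 30 populations with
  largest-remainder quotas proportional to the ecogeographic categories
  represented.
* **Calibration** — nine presence/absence algorithms (GLM, GAM, GBM, CTA,
  ANN, FDA, MARS, RF, SRE) trained on accessions scored with a Disease
  Severity Rating (DSr 0–100; the first decile is labelled resistant),
  evaluated by the True Skill Statistic
  `TSS = sensitivity + specificity − 1` over repeated stratified 75/25
  splits, with permutation variable importance, suitability projection on
  a 0–1000 scale against a TSS-maximizing cutoff, and an explicit
  *unmodelable* verdict when every algorithm fails (mean TSS < 0.2).

Both strategies lean on an **ecogeographic land characterization (ELC)
map**: random-forest variable importance with correlation pruning selects
the layers, k-means with an elbow stopping rule (at most six clusters per
bioclimatic/edaphic/geophysic component) clusters them, and the realized
cluster triples become categories that proxy distinct adaptive scenarios.

A seeded synthetic-data generator (`synthetic_truth()`, `make_stack()`,
`sample_occurrences()`, `simulate_dsr()`) produces spatially structured
layers, environment-dependent occurrences and link-driven severity scores
with all ground truth recorded, so every stage is testable without any
download. See the methods vignette
(`vignettes/predictive-characterization.Rmd`) for the models, parameter
defaults and design decisions.

## Worked example

A complete run on a simulated study (624 populations, four taxa, a 60 x 60
grid at 2.5 arc-min):

```r
library(predchar)

truth <- synthetic_truth(seed = 42)
stack <- make_stack(truth, n_rows = 60, n_cols = 60)
populations <- sample_occurrences(truth, stack, n = 624)

ranking <- rank_variables(populations, stack, seed = 1) |>
  prune_correlated(data = populations[default_registry()$name])
retained_variables(ranking)
#> [1] "tmean_annual" "prec_annual"  "bulk_density" "sand_pct"     "elevation"
#> [6] "solar_dec"

elc <- elc_map(stack, retained_variables(ranking), seed = 2)
elc
#> <pc_elc> 12 categories from 3 x 3 x 2 clusters on a 60 x 60 grid (36 no-data cells)

populations <- assign_category(elc, populations) |> add_env_indices()
drought <- select_drought(populations)
drought
#> <pc_subset> drought: 30 members of 106 candidates (capped), 4 ELC categories
tidy(drought)[1:3, c("trait", "pop_id", "rank", "rank_key", "elc_category")]
#> # A tibble: 3 × 5
#>   trait   pop_id      rank rank_key elc_category
#>   <chr>   <chr>      <int>    <dbl>        <int>
#> 1 drought ID_0145473     1     8.23            5
#> 2 drought GE_6457020     2     8.25            5
#> 3 drought GE_0647029     3     8.27            6
```

Twenty-one ecogeographic variables collapse to six: every bioclimatic
layer is correlated with annual mean temperature, so temperature alone
survives pruning. The 624 populations fall into 12 ELC categories; 106
populations pass both aridity filters and the subset is capped to the 30
most flowering-arid sites (`rank_key` is `IarDMf`, so rank 1 is the driest
flowering season), spread over 4 categories proportionally to their
candidate counts.

Calibration on 351 simulated rust evaluations:

```r
evaluations <- simulate_dsr(truth, populations[rep_len(1:624, 351), ])
labelled <- binarize_dsr(evaluations)
labelled <- dplyr::bind_cols(labelled,
  populations[rep_len(1:624, 351), retained_variables(ranking)])
suite <- train_suite(labelled, retained_variables(ranking), n_runs = 25, seed = 3)
glance(suite)
#> # A tibble: 9 × 5
#>   algorithm mean_tss sd_tss n_failed performance
#>   <chr>        <dbl>  <dbl>    <int> <ord>
#> 1 GLM          0.623 0.0931        0 Good
#> 2 MARS         0.610 0.141         0 Good
#> 3 GAM          0.576 0.149         0 Fair
#> 4 FDA          0.555 0.136         0 Fair
#> 5 SRE          0.490 0.169         0 Fair
#> 6 ANN          0.442 0.190         0 Fair
#> 7 CTA          0.402 0.183         0 Fair
#> 8 GBM          0.196 0.0931        0 Fail
#> 9 RF           0.118 0.120         0 Fail

result <- select_and_project(suite, populations, top_n = 30)
result
#> <pc_calibration> GLM best run 9 (TSS 0.772, cutoff 525): 228 resistant of 621 projected; top subset 30
```

35 of the 351 accessions fall strictly below the first-decile DSr
threshold and are labelled resistant. GLM leads with mean TSS 0.623
("Good"); its best run (held-out TSS 0.772) is refitted and projected,
labelling 228 of the 621 characterizable populations resistant (three sit
on no-data cells), and the 30 with the highest suitability form the
screening subset. `result$top3` holds permutation-importance tables for
the three best algorithms so a model dominated by a mechanistically
meaningless variable can be excluded (`exclude_variables=`) or overridden
(`choose=`). `ggplot2::autoplot()` works on the ELC map, the TSS suite
and the projection; `run_pipeline()` chains all stages from one config
and writes a manifest.

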