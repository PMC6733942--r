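# synoptic

Analysis of repeated synoptic water-chemistry surveys of nested stream
networks.

A synoptic campaign samples many sites across a watershed almost
simultaneously at stable flow, giving a spatial snapshot of dissolved
solutes (DOC, NO₃⁻, SRP, …). Repeating the snapshot across the flow season
lets three watershed-scale questions be answered quantitatively, and this
package computes the corresponding metrics for any number of watersheds,
seasons and solutes:

* **Variance collapse** — at what drainage area does among-site variance in
  (z-scored) concentration drop towards zero? The threshold is read as the
  characteristic patch size of the landscape sources and sinks of that
  solute. Detection is a single change point in variance: the Gaussian
  log-likelihood ratio
  `LR(k) = n·log σ̂²(all) − k·log σ̂²(1..k) − (n−k)·log σ̂²(k+1..n)`
  maximised over splits of the area-ordered series, with a seeded
  permutation test (`p = (1 + #{LRᵖᵉʳᵐ ≥ LRᵒᵇˢ}) / (n_perm + 1)`) and the
  threshold reported as the geometric mean of the bracketing areas.
* **Subcatchment leverage** — each site's percent influence on outlet
  chemistry under area-proportional runoff,
  `Lᵢ = 100 · ((Cᵢ − C_out)/C_out) · (Aᵢ/A_out)`.
  Conservative transport gives zero mean leverage over a disjoint site
  partition; a positive mean indicates net in-network removal, a negative
  mean net production.
* **Spatial stability** — Spearman rank correlation `r_s` of site
  concentrations between two campaigns (t approximation for n > 10, exact
  permutation null for n ≤ 10): does the spatial configuration of sources
  and sinks persist through the season?

Field datasets of this kind are rarely deposited, so the package includes a
synthetic stream-network generator (random binary trees, patch-structured
source fields with a controllable characteristic patch area, conservative
area-weighted routing, optional net first-order reaction `exp(−k_r)` per
reach, Gaussian-copula seasonal coupling) whose known parameters make every
metric testable by parameter recovery. See the methods vignette
(`vignettes/synoptic-methods.Rmd`) for the full model description and
design rationale.

## Worked example

Simulate a three-watershed study design (42-, 41- and 31-site watersheds,
two seasons, three solutes) and run the full pipeline:

```r
library(synoptic)

sim    <- simulate_dataset(default_study_configs(), seed = 20)
report <- run_metrics_pipeline(sim$dataset, n_perm = 999, seed = 20)

subset(report$collapse, solute == "DOC")
#>  watershed_id season solute  n lr_statistic p_value threshold_area_km2
#>        Tundra  early    DOC 42         19.0   0.006              15.29
#>        Tundra   late    DOC 42         30.0   0.001              24.08
#>          Lake  early    DOC 41         31.6   0.002               2.66
#>          Lake   late    DOC 41         29.5   0.001              11.11
#>        Alpine  early    DOC 31         27.6   0.004               2.89
#>        Alpine   late    DOC 31         38.7   0.001              19.79

report$stability[report$stability$solute == "DOC", ]
#>  watershed_id solute n_pairs    r_s  p_value significant
#>        Tundra    DOC      42 0.7451 1.52e-08        TRUE
#>          Lake    DOC      41 0.3237 3.90e-02        TRUE
#>        Alpine    DOC      31 0.7452 1.52e-06        TRUE
```

The detected DOC collapse thresholds track each watershed's generating
patch area (Tundra was simulated with 20 km² patches, Lake with 5 km²),
and DOC spatial stability is high where the seasonal copula correlation
was set high (Tundra, `rho_season = 0.85`) and low where the landscape was
set to reorganise (Lake, `rho_season = 0.15`). Leverage summaries behave
the same way: Tundra NO₃⁻ was simulated with net removal (`k_r = +0.05`)
and shows positive mean leverage (+1.5% early season), while Tundra DOC
(`k_r = −0.02`, net production) shows negative mean leverage.

Real data enter through two delimited tables — a long-format chemistry
table (`site_id, watershed_id, drainage_area_km2, season, solute,
concentration`, with `"<x"` below-detection sentinels supported) and a
two-column edge list (`site_id, downstream_id`, blank for the outlet):

```r
ds <- read_network("network.csv", read_chemistry_table("chemistry.csv"))
validate_dataset(ds)
report <- run_metrics_pipeline(ds, seed = 1)
write_report(report, "results/")
```

A thin command-line wrapper over the same functions lives at
`inst/cli/synoptic.R` (`simulate`, `metrics`, `recover`, `all`
subcommands).

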