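# decrates

Historical biogeography on time-calibrated phylogenies: maximum-likelihood
dispersal–extinction–cladogenesis (DEC) models with time-stratified
dispersal multipliers, DIVALIKE and BAYAREALIKE variants, marginal
ancestral range estimation, biogeographic stochastic mapping, and
dispersal/speciation **rates through time** (colonization, emigration,
immigration and in situ speciation per time bin, with quartile bands
across pseudoreplicated histories).

The package is aimed at systematists asking *where* a clade's lineages
were, and *which regions acted as sources, sinks and cradles when*: fit a
range-evolution model on an ultrametric tree plus a taxon-by-area presence
table, estimate ancestral ranges, sample event histories consistent with
the tips, and summarize the per-bin rate statistics

- in situ speciation rate λ_X(t₁) = s_X(t₁) / L_X(t₀),
- colonization rate c_{X→Y}(t₁) = d_{X→Y}(t₁) / Br(t₁),
- emigration rate E_X(t₁) = df_X(t₁) / Br(t₁),
- immigration rate I_X(t₁) = dt_X(t₁) / Br(t₁),

where s, d, df, dt are per-bin event counts, L_X(t₀) is the number of
lineages occupying X at the bin's old edge and Br(t₁) is the total branch
length in the bin (lineage-Myr). A relay summary reports which area leads
each statistic in each bin and where the leadership changes hands.

## Worked example

Simulate a dataset under the packaged Neotropical scenario (134 tips,
six areas A–F, crown age 8.6 Ma, two multiplier slices at 11 and 7 Ma),
fit constrained and unconstrained DEC, compare, and map histories:

```r
library(decrates)

scen <- neotropical_preset(seed = 1)
phy  <- simulate_chronogram(scen)
sim  <- simulate_ranges(phy, scen)

fit_con <- fit_range_model(phy, sim$geography, "DEC", epoch = scen$epoch)
fit_con
#> Range-evolution model fit (DEC, time-stratified multipliers)
#>   tips: 134   areas: 6   states: 63
#>   d = 0.1806  e = 5.464e-06   lnL = -166.6911
#>   AIC = 337.38   AICc = 337.47 (n = 134 tips)

fit_unc <- fit_range_model(phy, sim$geography, "DEC")
model_selection(list(fit_con, fit_unc))
#> Model comparison (AICc sample size n = 134 tips)
#>  model constrained     lnL n_params    d e j    AIC  dAIC  AIC_wt   AICc dAICc AICc_wt
#>    DEC        TRUE -166.69        2 0.18 0 0 337.38  0.00 1.0e+00 337.47  0.00 1.0e+00
#>    DEC       FALSE -177.33        2 0.05 0 0 358.65 21.27 2.4e-05 358.74 21.27 2.4e-05
```

The fitted dispersal rate recovers the generator's scale (d = 0.16), the
extirpation rate collapses to the boundary (a structural property of
DEC-style cladogenesis discussed in the methods vignette), and the model
fitted **with** the generating multiplier matrix beats the unconstrained
fit decisively by AICc — on data that were actually simulated with those
multipliers.

Downstream, on the fitted model:

```r
anc <- ancestral_ranges(fit_con)   # per-node range posteriors, MAP range/area
hs  <- stochastic_map(fit_unc, n = 100, seed = 42)
rs  <- rates_through_time(hs, bin_width = 0.5)
relay_summary(rs)                  # which area leads λ, E, I in each bin
summarize_flows(hs)                # mean pairwise dispersal counts, source/sink
```

`run_pipeline()` chains the whole thing (six model×constraint fits,
comparison table, mapping on the unconstrained DEC fit, rates, relay) and
writes seed- and hash-stamped TSV/JSON outputs; reruns with the same
config are byte-identical.

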