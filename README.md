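# sebalwp

Crop evapotranspiration (ET) retrieval from thermal satellite imagery and
crop water productivity (WP) mapping, for agro-hydrologists working in
data-sparse rain-fed regions. The package implements the SEBAL family of
surface energy balance models on Landsat-like scenes, validates the
retrieved daily ET against the FAO-56 Penman–Monteith reference equation
at meteorological stations, upscales the evaporative fraction between
overpasses to seasonal ET, and maps water productivity — the kilograms of
grain harvested per cubic metre of water consumed — with zonal statistics
and correlation analysis against elevation, temperature and precipitation.

## The model

At every pixel the latent heat flux is the residual of the surface energy
balance,

```
λET = Rn − G − H                        [W m⁻²]
```

with net radiation `Rn = (1 − α)Rs↓ + RL↓ − RL↑ − (1 − ε)RL↓`, soil heat
flux `G` parameterized from surface temperature, albedo and NDVI, and
sensible heat `H = ρ_air Cp dT / r_ah` calibrated on a cold (well-watered,
`H = 0`) and a hot (desiccated, `λET = 0`) anchor pixel, with a
Monin–Obukhov stability iteration of the aerodynamic resistance. The
evaporative fraction `Λ = λET/(Rn − G)`, assumed constant over the day,
scales to daily ET via `ET24 = 86400 Λ Rn24 / λ_vap` (mm/d), and linear
interpolation of `Λ` between overpasses yields daily, monthly and seasonal
ET. Water productivity follows as

```
WP [kg m⁻³] = 1.5 · yield [kg/mu] / ET [mm]        (1 mu = 666.667 m²)
```

Reference ET uses the FAO-56 Penman–Monteith equation
`ET0 = [0.408 Δ(Rn − G) + γ 900/(T+273) U2 (es − ea)] / [Δ + γ(1 + 0.34 U2)]`.

Because provincial satellite/met/yield archives cannot ship with a
package, a seeded synthetic-scene generator with known
evaporative-fraction ground truth exercises the full chain end to end: the
surface temperature field is constructed by inverting the package's own
flux chain, so the retrieval has an exact known answer on noise-free
scenes. See the methods vignette (`vignettes/sebalwp-methods.Rmd`) for the
full model description and design choices.

## Worked example

Station validation against the bundled published daily-ET pairs:

```r
library(sebalwp)
validateDailyET(exampleStationET())
#>       station       date et_pm et_sebal abs_error rel_error flagged
#> 1 Mount Wutai 2020-08-10 3.581    3.761    0.1797     4.778   FALSE
#> 2       Taigu 2020-08-10 5.084    5.163    0.0786     1.522   FALSE
#> 3       Lishi 2020-08-10 7.348    7.504    0.1560     2.079   FALSE
```

Absolute errors are `|SEBAL − PM|` in mm/d; relative errors (in %) stay
below 5, i.e. the energy-balance retrieval agrees with the reference
equation to within a few percent at all three stations.

Retrieval on a synthetic scene with known truth:

```r
cfg <- synthConfig(rows = 60, cols = 60, seed = 42,
                   noiseSd = list(reflectance = 0, thermal = 0))
gen <- generateScene(cfg)                       # scene + truth + DEM + met
res <- sebalScene(gen$scene, gen$dem, gen$met)  # full energy balance
res$anchors
#> AnchorPair: cold (56,1) Ts=296.00K | hot (1,56) Ts=321.00K
#>   dT = -57.2851 + 0.19353 * Ts;  11 iterations, converged: TRUE
err <- lambdaInst(res$flux) - gen$truth$lambda_true
sqrt(mean(err^2))   # 3.8e-04
```

The evaporative fraction is recovered to a few parts in 10⁴ on a
noise-free scene (the residual is the stability-iteration stopping
tolerance, not model error). `runPipeline(pipelineConfig())` chains
scenes, temporal upscaling, WP mapping and station validation, writing
rasters (ESRI ASCII grid), CSV tables and a checksummed JSON manifest.

A thin command-line wrapper with subcommands (`synth-scene`, `sebal-run`,
`pm-et0`, `validate`, `wp-map`, `wp-corr`, `run-all`) is installed at
`inst/scripts/sebalwp-cli.R`.

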