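# ptegarden

Screening of potentially toxic elements (PTEs) in urban-garden soils and
the vegetables grown on them, for the question every community garden
eventually asks: **is the produce safe to eat?**

The package is aimed at environmental scientists and risk assessors
working with soil/produce concentration tables (mg/kg dry weight) for the
eleven elements As, B, Ba, Cd, Co, Cr, Cu, Mo, Ni, Pb, Zn. It implements,
as tested and reusable functions, the full screening chain used in
urban-agriculture surveys; its defaults and bundled reference tables are
tuned to a survey of Andalusian urban gardens (peri-urban, city and
pyrite-belt mining areas).

## The indices at its core

| Quantity | Definition | Threshold |
|---|---|---|
| Contamination factor | CF = C_soil / C_background | Hakanson classes: <1 low, 1–3 moderate, 3–6 considerable, ≥6 very high |
| Pollution load index | PLI = (∏ CFᵢ)^(1/n) | >1 overall contamination |
| Transfer factor | TF = C_plant,dw / C_soil,dw | ≥1 accumulator |
| Estimated daily intake | EDI = Cm·IR·Ef·Ed·f_fw / (BW·AT_nc) | — |
| Hazard quotient / index | HQ = EDI/RfD, HI = Σ HQ | >1 possible effects |
| Carcinogenic risk (As) | CR = Cm·IR·f_fw·Ef·Ed·SF / (BW·AT_c) | >10⁻⁵ unacceptable |

Supporting machinery: left-censored (`<LOD`) concentration handling with
minimum-value imputation, regulatory trigger-value and EU food-limit
screening, back-calculation of unpublished ingestion rates from published
hazard tables (with a residual check that flags transcription errors),
Shapiro-gated ANOVA/Tukey vs Kruskal–Wallis/Mann–Whitney group comparisons
with compact letter displays, and a log-normal synthetic data generator
for end-to-end and parameter-recovery testing.

## Worked example

Recompute the dietary risk for chard from the bundled survey mean
concentrations under the calibrated adult profile (70 kg adult, 4.94 g
fresh chard/day, 30-year exposure):

```r
library(ptegarden)
prof <- risk_profile("calibrated")
vm <- vegetable_means()
vm <- vm[vm$source != "market", ]
names(vm)[names(vm) == "source"] <- "area"
rt <- risk_from_means(vm, prof$exposure, prof$element_params)
subset(rt, species == "chard", select = c(species, area, hq_As, hi, cr_as))
#>    species       area   hq_As     hi    cr_as
#> 15   chard peri-urban 0.00054 0.0109 9.34e-08
#> 16   chard     mining 0.00544 0.0185 9.41e-07
#> 17   chard       city 0.00138 0.0132 2.39e-07
```

Reading: even in the mining area, the arsenic hazard quotient (0.0054)
and the 11-element hazard index (0.0185) are two orders of magnitude
below the HQ/HI threshold of 1, and the lifetime arsenic cancer risk
(9.4 × 10⁻⁷) is an order of magnitude below the 10⁻⁵ acceptability limit
— eating this chard is not a health concern by these criteria, despite
strongly contaminated soils.

The same chain runs end-to-end on synthetic data:

```r
ds <- survey_like_fixture(seed = 42)          # 15 gardens, 7 species
tab <- contamination_table(ds)
head(unique(tab[, c("garden_code", "area", "pli")]), 4)
#>    garden_code       area  pli
#> 1         SG01 peri-urban 1.06
#> 7         SG02       city 1.59
#> 13        SG03       city 1.65
#> 19        SG04       city 1.53
```

A command-line front end covers the full pipeline and per-stage
subcommands (`run`, `soil-indices`, `tf`, `risk`, `stats`, `simulate`,
`calibrate-ir`):

```sh
Rscript inst/cli/ptegarden simulate --seed 42 --out data/
Rscript inst/cli/ptegarden run --soil data/soil.csv --plants data/plants.csv \
    --config data/config.json --out results/
```

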