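---
title: "Soil and produce screening for potentially toxic elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil and produce screening for potentially toxic elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptegarden)
```

## What the package computes

`ptegarden` implements the screening chain used to judge whether vegetables
grown on urban garden soils are safe to eat, for eleven potentially toxic
elements (PTEs): As, B, Ba, Cd, Co, Cr, Cu, Mo, Ni, Pb, Zn. The chain runs
soils → contamination indices → soil-to-plant transfer → dietary exposure →
non-carcinogenic and carcinogenic risk, with a two-stage statistical layer
for group contrasts and a synthetic-data generator so every stage can be
exercised and parameter-recovery-tested without any external data.

Its defaults and bundled reference tables are tuned to a survey of
Andalusian urban gardens spanning three area types: a peri-urban reference
garden, twelve city gardens, and two gardens in the Iberian Pyrite Belt
mining district.

## Models and formulas

**Censored concentrations.** Field XRF returns left-censored values below
its detection limit. Following the survey's rule, every censored entry of
an element is replaced by the *lowest uncensored value of that element over
the whole dataset* (`impute_censored()`). The replacement is idempotent,
never alters an observed value, and never lowers the dataset minimum. The
pooling scope (all samples, not per garden) is the plain reading of
"lowest value of all those obtained"; with per-garden pooling some gardens
would have no replacement value at all.

**Contamination factor and PLI.** For element $i$,
$\mathrm{CF}^i = C^i_\text{soil} / C^i_\text{bk}$ with $C^i_\text{bk}$ the
regional geochemical background. Classes follow Hakanson: CF < 1 low,
1–3 moderate, 3–6 considerable, ≥ 6 very high. The source material displays
the reciprocal formula while describing this one in words; only this
orientation is consistent with the classes and with the reported mining
CFs of 6–12, so it is the one implemented. Class boundaries (1, 3, 6) are
not assigned by the strict inequalities of the original scale; we assign
them upward, the conservative choice for screening. The pollution load
index is the geometric mean of the CFs, computed in log space for
numerical stability; PLI > 1 flags overall contamination. The default CF
element set is the six elements with regional backgrounds (As, Cr, Cu, Ni,
Pb, Zn), and CF/PLI are computed on per-garden mean concentrations
(matching how such surveys report garden-level stars/PLIs), with a
per-sample option. Backgrounds are deliberately **not** shipped: they are
site-specific; CF/PLI require a user-supplied background block.

**Transfer factor.** $\mathrm{TF} = C_\text{plant,dw} / C_\text{soil,dw}$.
The default pairing divides each plant sample by the mean soil
concentration of the garden it grew in ("the soil where the plant had
grown"); an area-mean pairing is available for area-level summaries, since
published area figures do not state which pairing they used. TF ≥ 1 rows
are flagged.

**Dietary exposure and risk.** For a vegetable with dry-weight
concentration $C_m$:

$$\mathrm{EDI} = \frac{C_m \cdot IR \cdot E_f \cdot E_d \cdot f_{fw}}{BW \cdot AT_{nc}},
\qquad \mathrm{HQ} = \frac{\mathrm{EDI}}{\mathrm{RfD}}, \qquad
\mathrm{HI} = \sum_{i} \mathrm{HQ}_i,$$

$$\mathrm{CR} = \frac{C_m \cdot IR \cdot f_{fw} \cdot E_f \cdot E_d \cdot SF}{BW \cdot AT_{c}}.$$

$IR$ is the fresh-weight ingestion rate (kg/day), $f_{fw} = 0.085$
converts the dry-weight concentration to the fresh-weight basis of the
ingestion rate, $BW = 70$ kg, $E_f = 365$ d/y, $E_d = 30$ y,
$AT_{nc} = 30 \times 365 = 10950$ d, and $AT_c = 78 \times 365 = 28470$ d
(lifetime averaging for the carcinogenic endpoint). With these defaults
the time terms of the EDI cancel, so EDI is independent of $E_d$ — a
property asserted numerically in the tests. HQ or HI > 1 flags possible
non-carcinogenic effects; CR > 10⁻⁵ is deemed unacceptable. The slope
factor is 1.5 (mg/kg-bw/day)⁻¹ for As, the only element with a
carcinogenic endpoint here. The closed-form consistency
$\mathrm{CR} = \mathrm{HQ}_{As} \cdot \mathrm{RfD}_{As} \cdot SF \cdot
E_d \cdot 365 / AT_c$ (when $E_f = 365$) is used as a cross-check to
1e-12 relative.

**Exposure frequency.** The survey does not state $E_f$; 365 d/y is
required for its hazard table to be internally consistent and is the
default.

## The two shipped profiles, and why there are two

The survey's text lists literature RfDs (with Pb 0.0035 and no value for
Mo) but its hazard-quotient table cannot be reproduced with them: back-
solving every Pb cell gives RfD 0.002, and the Mo cells imply 0.005.
Similarly the per-species ingestion rates were taken from regional
consumption statistics but never printed. `calibrate_ingestion_rate()`
recovers them: each (species, area, element) cell implies
$IR = \mathrm{RfD} \cdot \mathrm{HQ} \cdot BW / (f_{fw} C_m)$, and the
species IR is the median over cells. Cells deviating more than 25% from
the species median are flagged — this residual check is what catches the
table's transcription errors (exponent slips in the onion As and Ni
cells, among others), and the median makes the recovery robust to them.

The package therefore ships:

* `risk_profile("calibrated")` — RfDs with Pb 2e-3 and Mo 5e-3 plus the
  back-calculated IRs (chard 4.94, onion 18.25, tomato 24.9, zucchini
  5.60, eggplant 5.09, lettuce 10.54, pepper 6.63 g fresh/day). This is
  the profile that reproduces the published hazard table.
* `risk_profile("reference")` — the literature RfD set as printed
  (Pb 3.5e-3, Mo absent), for users who prefer the canonical values; Mo
  is then excluded from HI with a warning.

Using the calibrated profile, the recomputed hazard indices match the
published ones to well under 2% — with one documented exception: the
published chard-mining HI (0.018) disagrees with the sum of its *own*
printed HQ column (0.0185), which our recomputation reproduces cell by
cell. The acceptance test for that single value is deliberately left
failing rather than adjusting anything toward it.

## Statistics layer

`compare_groups()` mirrors the standard survey procedure: Shapiro–Wilk
per group at $\alpha$ (default 0.05; the survey does not state its
$\alpha$, and per-group testing is the plain reading of "data were
normally distributed"); if all groups pass, one-way ANOVA with Tukey HSD,
otherwise Kruskal–Wallis with pairwise Mann–Whitney. Pairwise p-values
are unadjusted by default (mirroring common practice in these surveys);
Holm adjustment is a flag. Constant groups cannot be Shapiro-tested and
are routed to the rank-based branch. The compact letter display is
computed by insert-and-absorb: start with one letter covering all groups,
split it on each significant pair, absorb redundant subsets; letters are
ordered so "a" contains the highest-mean group.

`pooled_descriptives()` combines per-garden (n, mean, min, max) summaries
into area statistics with sample-size weights; when raw values are given
the same statistics are computed directly and must agree (property-tested
against the concatenated-raw oracle). Area *medians* cannot be recovered
from garden summaries and are only reported when raw data are supplied —
a documented limitation, which is also why published area medians are not
reproduction targets.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` draws soil concentrations log-normally per
area × element (median, geometric SD) — matching the right skew of trace
elements in field soils — censors them at per-element detection limits,
draws pH from a truncated normal on (4, 9.5), and builds plant samples as
*paired garden* soil mean × species TF × multiplicative log-normal noise.
Pairing plants to their garden (not the area mean) keeps both TF pairing
modes testable. A truth record (medians, TFs, realised censoring
fractions) rides along, separate from the analysis inputs.

`survey_like_fixture()` is the fixed stated world used by the end-to-end
tests: 1 peri-urban + 12 city + 2 mining gardens, 8 soil samples each
(120 soils; the survey analysed 102), 7 species × 2 replicates per garden
(210 plants; the survey had 282). Its area medians for As, Cr, Cu, Pb and
Zn are the survey's published area medians, Ni is flat across areas, and
its TF matrix is loosely derived from published plant/soil ratios with
all values < 1. A soil geometric SD of 1.3 was chosen so that the
fixture's qualitative contrasts (mining ≫ peri-urban for ore elements;
Ni within 35% everywhere) are stable at the fixture's sample sizes; this
understates the real spread of mining-area As (which ranged over an order
of magnitude) — a deliberate simplification.

What a green synthetic test does *not* establish: the generator has no
spatial correlation, no pH-dependent bioavailability, no species × garden
interaction beyond the TF matrix, and its plant noise is homoscedastic on
the log scale. It validates the *arithmetic and plumbing* of the
pipeline, not agronomic realism.

**Recovery tests and their stated worlds.** TF recovery: plant noise
σ = 0.3 on the log scale, 200 samples per species over 10 gardens, soil
gsd 1.2; the median computed TF must sit within 10% of truth (the
median's sampling error there is ≈ 2.7%, so the band is comfortable
without being vacuous). IR recovery: multiplicative σ = 0.2 noise on the
hazard quotients with 220 cells per species (the operation requires ≥ 3;
more cells keep the median's sampling error ≈ 2.4% against the 5% band).
Seeds are fixed constants chosen once.

## Numerical and edge-case choices

* PLI in log space (overflow-safe for long CF vectors); empty or
  non-positive inputs are errors, not NA.
* Trigger-value and food-limit screening use strict `>`; a value equal to
  the limit does not flag. Elements without a limit are skipped and
  reported as `NA`, never errors.
* Unknown species and garden codes fail loudly; silent defaults would
  corrupt group statistics. Extensions go through the config
  (`species:`, `areas:` blocks).
* Censoring tokens `<LOD`, `<LD`, `<dl`, `nd` (case/space-insensitive)
  are recognised; an explicit `<element>_censored` column overrides.
* `risk_table()` drops elements without an RfD from HQ/HI with a warning
  (relevant under the reference profile, which has no Mo RfD).
* All-censored elements are an error for imputation: no replacement value
  exists.
* Writers emit a `# generated_by` header; readers skip `#` comments; a
  write/read round trip reproduces values and censoring flags exactly.

## Known limitations

* Single adult deterministic receptor: no child scenario, no dermal or
  inhalation pathways, no Monte-Carlo uncertainty propagation.
* Total soil concentrations only; no bioavailable-pool (CaCl₂/DTPA)
  modelling.
* CF/PLI need user-supplied backgrounds; none are bundled.
* Published area medians and the survey's specific pairwise letter
  outcomes are not reproducible from the bundled summaries (raw
  per-sample data were never published) — the procedures are implemented
  and property-tested instead.

## A worked check

```{r}
prof <- risk_profile("calibrated")
vm <- vegetable_means()
vm <- vm[vm$source != "market", ]
names(vm)[names(vm) == "source"] <- "area"
rt <- risk_from_means(vm, prof$exposure, prof$element_params)
subset(rt, species == "chard",
       select = c(species, area, hq_As, hi, cr_as))
```

Every HI is far below 1 and every As CR below 10⁻⁵: by these screening
criteria, consumption of the surveyed produce poses no appreciable risk —
the survey's central conclusion, recomputed.
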