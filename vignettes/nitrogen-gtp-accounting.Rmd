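---
title: "Warming and cooling accounting of agricultural nitrogen use"
author: "ngtp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Warming and cooling accounting of agricultural nitrogen use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngtp)
```

## The model

Reactive nitrogen added to agricultural soils cascades into several
climate-active species. The package follows a deliberately simple Tier-1
style accounting of that cascade, built from three linear stages.

**Stage 1 — the annual N budget.** The total N input is the sum of five
sources, all in Tg N yr⁻¹:

$$N_T = N_{SN} + N_{AM} + N_{CR} + N_{AD} + N_{BNF}$$

(synthetic fertilizer, animal manure, crop residue, atmospheric deposition,
biological N fixation). Deposition and fixation may instead be estimated
from areas as `area × rate` (`deposition_n()`, `bnf_n()`), but directly
supplied totals are the primary path: everything downstream depends only on
the five Tg values.

**Stage 2 — gas fluxes.** Each flux is `N_T × EF × m`, with `EF` an
emission/uptake factor and `m` an element→molecule mass conversion fixed at
integer atomic weights (44/28 for N₂O/N₂O-N, 17/14 for NH₃, 16/12 for CH₄,
44/12 for CO₂). The N₂O flux has a direct term (`EF = 0.01` kg N₂O-N per kg
N) and a leaching-indirect term in which 30% of applied N leaches as
nitrate and 0.0075 kg N₂O-N is emitted per kg leached. NH₃ uses `EF = 0.1`
(reported as molecular NH₃); NOx uses `EF = 0.005` and stays on the
nitrogen-mass basis because its GTP coefficients are defined per kg NOx-N.
The CH₄ term blends a lowland (flooded-soil) emission factor 0.008 kg
CH₄-C kg⁻¹ N with an upland uptake-suppression magnitude 0.012, weighted by
the fraction `f_lowland` of N applied to flooded soils; both move the
atmospheric CH₄ burden upward, so both carry warming direction. CO₂
sequestration uses 0.053 kg CO₂-C kg⁻¹ N and is stored as a positive uptake
magnitude.

**Stage 3 — GTP decomposition.** The Global Temperature change Potential of
a gas at horizon *t* (20 or 100 years) is the temperature change its pulse
emission causes at *t* relative to the same mass of CO₂; multiplying each
flux by its coefficient yields Tg CO₂e. Coefficients are supplied as
literature intervals (e.g. N₂O 260–290 at 20 years) and collapsed to a
scalar by a range policy; warming components (N₂O, CH₄) and cooling
components (NH₃ aerosol, NOx–O₃/CH₄, NOx aerosol, CO₂ sequestration) are
kept as non-negative magnitudes, and the only signed quantity is

$$GTP_{net} = \text{warming total} - \text{cooling total}.$$

All three stages are homogeneous of degree one in $N_T$, which gives the
package's strongest structural guarantees: period aggregation commutes with
the decomposition, and period-level *shares* of warming and cooling are
completely independent of the annual trajectory — only cumulative N input
matters.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `ef_n2o_direct` | kg N₂O-N kg⁻¹ N | 0.01 | Tier-1 direct emission factor |
| `ef_n2o_leach` | kg N₂O-N kg⁻¹ N leached | 0.0075 | indirect, via groundwater |
| `frac_leach` | kg NO₃-N kg⁻¹ N | 0.3 | leached fraction |
| `ef_nh3` | kg NH₃-N kg⁻¹ N | 0.1 | volatilization |
| `ef_nox` | kg NOx-N kg⁻¹ N | 0.005 | soil NOx |
| `ef_ch4_lowland` | kg CH₄-C kg⁻¹ N | 0.008 | flooded-soil emission |
| `ef_ch4_upland` | kg CH₄-C kg⁻¹ N | 0.012 | suppressed aerobic uptake |
| `ef_co2_seq` | kg CO₂-C kg⁻¹ N | 0.053 | N-stimulated C storage |
| `f_lowland` | – | 0.15 | share of N on flooded soils |
| policy | – | `"mid"` | interval → scalar collapse |

Factors are stored unsigned; the flux engine owns all directions. That is a
design choice: published factor tables mix sign conventions (uptake factors
quoted negative in tables, positive in prose), and storing magnitudes makes
double negation impossible.

`f_lowland = 0.15` is a calibration, not a measured quantity: the effective
CH₄ factor implied by the reference flux series (≈ 0.0114 kg CH₄-C kg⁻¹ N)
equals `0.15·0.008 + 0.85·0.012`, and no independent estimate of the split
is available at this level of aggregation.

## Design choices where the design was open

**Range policy.** Only interval midpoints reproduce the reference
1961/2010 GTP values (e.g. 1.4424 Tg N₂O × 275 = 396.7 Tg CO₂e), so `"mid"`
is the default and the bounds are exposed as an explicit envelope
(`range_envelope()`) rather than silently. For the CH₄ pathway the
reference component values imply the lower bound while the reference *net*
values imply the midpoint; we use the midpoint everywhere for internal
consistency — a user wanting the component-level convention can pass
`policy = "low"`.

**Mass bases.** The coefficient table is nominally "per kg N", but the
reference results are only consistent with mixed bases: molecular mass for
N₂O, NH₃, CH₄ and CO₂, nitrogen mass for both NOx pathways. The package
makes the basis an explicit, documented attribute of each pathway
(`ngtp_coefficients()$mass_basis`) instead of a unit printed in a caption.

**No mid-pipeline rounding.** Tg↔kg↔Mha conversions are exact powers of
ten, and numbers are rounded (2 decimals) only at report rendering. The
benchmark source table itself carries a rounding inconsistency — its 1961
column sums to 74.94 Tg but is printed as 74.93 — which propagates ~0.05 Tg
CO₂e differences into year-level GTP values; the reproduction tolerance
(`max(0.5%, 0.5 Tg)`) absorbs exactly this.

**Degenerate inputs.** Zero N input produces an all-zero record at every
stage; shares (source shares, cooling shares) are undefined at zero totals
and raise an error rather than returning `NaN`. Negative N amounts, leached
fractions outside [0, 1], inverted intervals, or a positive interval on a
cooling pathway are rejected at construction.

## The synthetic series generator

The historical annual source series (FAOSTAT vintage) is not shipped.
`generate_series()` emulates it: each source interpolates between the
built-in 1961 and 2010 anchor records along a linear, exponential or
logistic trajectory that hits the anchors exactly, with optional
multiplicative lognormal noise (unit mean, user CV < 0.5, independent
across years and sources, seeded). Defaults — exponential for fertilizer
(~10× growth), linear elsewhere — mimic the qualitative shape of the
historical record, not its interannual structure.

What passing tests on synthetic data do and do not show: linearity makes
period *shares* and all structural invariants trajectory-independent, so
those results transfer to the real series unchanged; cumulative *totals*
(e.g. 50-year warming) do depend on the trajectory and are therefore
checked as properties (additivity, linearity, monotonicity, determinism),
not against the reference cumulative numbers.

## Verification

```{r}
rep <- reproduction_report()
all(rep$within)
head(rep[c("quantity", "reference", "computed", "abs_diff")])
```

The test suite additionally cross-checks every engine against an
independent single-expression recomputation on random inputs (10⁻¹²
relative), and the problem sizes are intentionally desk-scale: two anchor
years for all reference comparisons and 50-year synthetic series for the
aggregation properties.

## Known limitations

- Emission factors are global scalars: no spatial, crop, climate or
  management disaggregation, and no process-based (e.g. DNDC-type) flux
  dynamics.
- GTP coefficients are taken as inputs; no radiative-forcing or
  pulse-response computation, and no horizons besides 20 and 100 years.
- The linear N₂O response ignores the evidence for nonlinearity at high N
  rates; results at strongly different N regimes should be read as Tier-1
  bookkeeping, not prediction.
- NOx speciation (NO vs NO₂), manure-management chains and residue burning
  are out of scope.
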