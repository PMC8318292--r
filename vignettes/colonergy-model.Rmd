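---
title: "The colonergy model: COD-based energy flux through the resected gut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The colonergy model: COD-based energy flux through the resected gut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonergy)
```

## The problem

After extensive small-intestine resection, nutrient absorption in the upper
gastrointestinal (GI) tract becomes inefficient, and the colon's microbial
community partially compensates: polymers that escape digestion are
hydrolyzed and fermented to short-chain fatty acids (SCFAs — acetate,
propionate, butyrate), which the colonic mucosa absorbs. `colonergy`
implements a two-compartment, steady-state model of this energy flux. It is
aimed at researchers in host–microbiome energetics who need a quantitative
ileocecal-output boundary condition for colon microbiome models, or who
want to ask how surgical shortening of the small intestine shifts the
*amount* and the *form* of absorbed energy.

## Currency: chemical oxygen demand

Masses of different macronutrients are not additive in any meaningful way,
but their electron content is. The model therefore carries every flux in
grams of chemical oxygen demand (gCOD/d): the mass of O~2~ required for
complete oxidation, with 8 g COD per electron equivalent (e^-^ eq), since
one mole of O~2~ (32 g) accepts 4 moles of electrons. For a pseudo-formula
C~c~H~h~O~o~N~n~ the electron equivalents on complete oxidation to CO~2~
(with nitrogen at the −III state, leaving as ammonia) are

$$e^-\,\mathrm{eq} = 4c + h - 2o - 3n,$$

so COD per gram is $8\,e^-\mathrm{eq} / \mathrm{FW}$. Formula weights use
the integer atomic masses C=12, H=1, O=16, N=14 — the convention under
which the standard constant table is exact (carbohydrate
CH~1.826~O~0.913~: FW 28.434 g, 1.125 gCOD/g; protein
CH~2.063~O~0.626~N~0.282~: 1.132; fat CH~1.838~O~0.118~: 2.850). These
masses are a documented constant, not a configuration knob: IUPAC masses
would give 2.845 for fat and silently break agreement with the published
constants.

Energy conversions (kcal per gCOD) are likewise a fixed table — 3.643
(carbohydrate), 4.771 (protein), 3.263 (fat), 3.266/3.258/3.260 for
acetate/propionate/butyrate — rather than being derived as gross energy
divided by COD. For carbohydrate and fat the two routes coincide (and a
unit test pins that coincidence); for protein they do not (5.65/1.132 ≈
4.99 ≠ 4.771), and we keep the published 4.771, which is also the value
consistent with the published secretion table (5.7 gCOD/d ↔ 27 kcal/d).
Two published SCFA COD values (acetic 1.066, propionic 1.513) are
truncations rather than roundings of the exact ratios (64/60, 112/74); the
package stores the exact ratios and the tests compare at the printed
precision accordingly.

Two constants have no published value and are package choices: fecal
microbial biomass is valued at the 55/45 protein/carbohydrate mix of its
COD (4.26 kcal/gCOD), consistent with biomass being about 55% protein; and
aromatics are valued at 3.3 kcal/gCOD, in the narrow 3.2–3.6 band that
organic compounds occupy per unit COD. Both affect only the kcal *display*
of fecal components, never the COD ledger.

## Upper GI: piecewise absorption

Absorption in the small intestine is complete while enough intestine
remains; it degrades linearly once the removed fraction exceeds the
anatomical reserve length (ARL). For each macronutrient record
(α true digestibility, β post-resection inefficiency slope, ARL as a
fraction of small-intestine length), the absorbed fraction at removed
fraction $r$ is

$$a(r) = \alpha - \beta\,\max(0,\; r - \mathrm{ARL}),$$

with $\mathrm{UGA} = \mathrm{GEI}\cdot a(r)$ and
$\mathrm{ICO} = \mathrm{GEI} - \mathrm{UGA} + \mathrm{GIS}$, where GIS are
the gastrointestinal secretions (mucin carbohydrate 3.4, protein 5.7, fat
3.1 gCOD/d). $a(r)$ may be negative: at high resection the protein channel
becomes a net *source*, because secretions are no longer reabsorbed.
Resection is always expressed as a fraction removed, never in centimetres.

Defaults: α = 0.90 (carbohydrate), 0.90 (protein), 0.96 (fat);
β = 1.041/1.147/0.930; ARL = 0.43/0.11/0 — literature digestibilities plus
rates estimated from ileostomy-cohort regressions.

**Which carbohydrate pool does α act on?** A design question with real
consequences. The model splits dietary carbohydrate into available
starch+sugars (AvSS), resistant starch (RS) and non-starch polysaccharides
(NSP). `colonergy` applies the carbohydrate α/β/ARL record to the AvSS
pool only and routes RS and NSP to the colon in full — that is what
"resistant" means physiologically, and the literature α = 0.90 is stated
for sugars. The alternative (α acting on total carbohydrate, fiber
escaping only via the 10% residual) over-credits the upper GI by the
fibers' ~26 gCOD/d: it pushes intact-gut absorbed COD to ~621 gCOD/d and
metabolizable energy to ~2190 kcal/d, and leaves the colon too little
substrate for SCFAs to reach their well-established 5–10% share of intact
energy uptake. Under the AvSS reading the intact-physiology outputs land
where the clinical energy-balance literature puts them (see the worked
numbers in the README), and net absorption of the digestible carbohydrate
pool at 100% resection is 29.5% — matching the reported ~29%.

## Colon: chemostat hydrolysis plus fixed fermentation stoichiometry

The colon is idealized as one well-mixed continuous reactor (chemostat)
with transit time θ. Particulate polymers hydrolyze with first-order
kinetics, so a fraction

$$f = \frac{k\,\theta}{1 + k\,\theta}$$

of an entering polymer is hydrolyzed (the survivors, $1/(1+k\theta)$,
leave in stool). The same form describes colonic fat absorption, with the
exact inverse $k = (1-r)/(\theta r)$ recovering the rate from an observed
residual fraction $r$. Fitted rates: $k_{hyd,RS} = 2.8$/d,
$k_{hyd,protein} = 2.2$/d, $k_{abs,fat} = 0.48$/d. AvSS reaching the colon
is treated as immediately fermentable (hydrolysis limits only particulate
pools), and NSP is inert by default ($k_{hyd,NSP} = 0$) — it persists in
stool and no rate has been estimated for it; both choices are exposed in
`colon_params()`.

Fermentable carbohydrate COD is partitioned by a reaction *solved from
conservation laws*, not hard-coded: fixing the biomass yield (0.042 mol
C~5~H~7~O~2~N per C-mol) and the molar SCFA ratios (1 Ac : 0.31 Prop :
0.15 n-But, the typical human fecal ratio), the acetate coefficient is the
unique root of the electron balance, CO~2~ follows from carbon, NH~3~ from
nitrogen, and H~2~O from oxygen; hydrogen is then a redundant check that
closes identically. The published carbohydrate stoichiometry drops out of
this solver to ±0.001 and serves as a regression test; users may vary the
ratios. The protein reaction, by contrast, is carried as published
constants (biomass 0.020, acetate 0.199, propionate 0.043, iso-butyrate
0.043, aromatics 0.016, CO~2~ 0.091, NH~3~ +0.261, H~2~O −0.180 per
C-mol), because its branched-chain and aromatics yields are empirical and
no generating recipe is stated anywhere. Those printed coefficients close
the nitrogen balance only to ~0.8% and COD to ~0.5%, which is why the
default balance tolerance is 1% — and why COD yield fractions are
renormalized to sum to exactly one before being applied to fluxes, so that
the global ledger GEI + GIS = UGA + LGA + FE closes to machine precision
(a property test exercises this over 1000 random configurations). No
methanogenesis or hydrogen off-gas is modelled: all electrons end in
biomass, SCFAs, aromatics or stool.

Of the SCFAs produced, 95% are absorbed (per acid) and 5% leave with
stool; microbial biomass and aromatics are never absorbed. Metabolizable
energy intake (MEI) values upper-GI-absorbed macronutrients at their
post-absorption energies (4.1/4.39/9.3 kcal/g — protein pays the urinary
nitrogen penalty) and colon-absorbed SCFAs and fat at their kcal/gCOD
constants. "Dietary COD recovery" is defined net of secretions,
$(\mathrm{MCOD} - \mathrm{GIS})/\mathrm{COD}_{diet}$, the definition under
which the intact gut recovers ~92%.

## The transit time θ

θ appears only in the products $k\theta$, so it is *not identifiable* from
steady-state residual fractions: doubling θ and halving every rate leaves
every flux unchanged (a test demonstrates exactly this confound). No
numeric θ accompanies the fitted rates in the source literature. We
therefore calibrated θ once, within the physiologically defensible 0.5–3 d
window, against the intact-physiology energy outputs, froze it at
**θ = 0.7 d**, and report all rates conditional on it. Fitting never moves
θ.

## What does not fit

With one θ for all conditions the model reproduces the intact-gut
headline outputs and the fecal-energy phenomenology of resection (3-fold
fecal energy increase by 95% removal; fat reaching about half of fecal
energy at 100%; a monotone rise of the SCFA share of MEI), but its dietary
COD recovery at 100% removal is ~54%, short of the ~62% reported in the
clinical modeling literature. Recovery at full resection rises with θ
(60% needs θ ≥ 1.4 d), but such θ pushes intact-gut MEI above its
tolerance — no single θ satisfies both, under any of the pool-routing
variants we examined (AvSS instantly fermentable vs hydrolysis-limited,
NSP fermentable vs inert, proportional vs fiber-first ICO attribution).
We document the shortfall rather than split θ by condition; the
corresponding check in the test suite is honestly red.

## Parameter fitting

Both fitting stages minimize the plain (unweighted) sum of squared
residuals between observed and predicted kcal/d channels; `1/SE^2`
weighting is available behind a flag but is not the default.

*Upper GI* (ileostomy-cohort data, ICO channels): the objective is
non-smooth in the breakpoint ARL, so the optimizer is a deterministic
profile search — for each ARL on a fixed 0, 0.05, …, 0.95 grid the
remaining parameters solve a *linear* least-squares problem exactly (the
model is affine in α and β at fixed ARL), and the best cell is refined by
bounded one-dimensional minimization. Bounds: α ∈ [0,1], β ∈ [0,3],
ARL ∈ [0,1]. α is fixed at its literature value by default (it is a
digestibility, not a free dial) but can be freed. Designs with fewer than
three distinct resection levels per channel are rejected as
unidentifiable, with the offending parameter named.

*Colon* (intact-colon cohort, fecal channels): rates are fitted with the
upper-GI parameters frozen, in the order dictated by the flow of COD —
carbohydrate ($k_{hyd,RS}$) and fat ($k_{abs}$) channels first, protein
($k_{hyd,protein}$) second, because carbohydrate-grown biomass lands 55%
in the fecal *protein* channel. Because a small reverse coupling also
exists (protein-grown biomass contributes 45% to the carbohydrate
channel), the two stages are cycled (default 6 times) to a fixed point;
each one-dimensional problem is a bounded deterministic search on
[0, 50]/d. Noise-free synthetic data regenerate all generating parameters
to 10^-3^.

## The synthetic cohort generator

No per-subject clinical table is published, so the fitting machinery is
exercised against synthetic cohorts that emulate the *reported* design:
group A (total colectomy — the ileocecal output observed directly) and
group B (colon intact, fecal output observed), each on a resection grid
spanning 0–0.95 with 2–15 subjects per point. Noise is applied to the
channel means — mean-zero Gaussian with SE = CV·mean/√n, truncated at
zero — which is exactly the information content of a published
mean-and-error-bar figure. The generator does **not** emulate per-subject
diet heterogeneity, within-subject repeated measures, or non-Gaussian
measurement error; parameter-recovery results therefore show the
estimator is correct and well-conditioned under the stated design, not
that real cohort data are this clean. Every generated set is reproducible
from its integer seed, and the generator restores the caller's RNG
stream.

## Numerical choices and problem sizes

* Balance tolerance 1% (set by the published protein stoichiometry's own
  closure); solver-built reactions close to ~10^-15^.
* Breakpoint refinement and rate searches use bounded golden-section
  minimization with tight tolerances (10^-7^–10^-8^); all fits are
  deterministic given their configuration — there is no stochastic
  restart anywhere.
* Degenerate inputs fail loudly: negative ICO components, resection
  fractions outside [0,1], zero-electron substrates, single-level
  designs. A parameter set that would drive an ICO component negative is
  floored at zero with a warning, with the floored mass credited to
  absorption so the ledger still closes (unreachable with the default
  parameters).
* Test-suite problem sizes: 1000 random configurations for the
  conservation property, 40–50 draws for the stoichiometry properties,
  300 replicates for the SE-scaling check, and full fits on 7-point
  grids; the suite runs in well under a minute on one core.

## Known limitations

* Steady state only: no transit dynamics, no adaptation of the remnant
  intestine (clinically, absorption improves over months post-surgery).
* One well-mixed colon compartment: no proximal/distal gradient, although
  aromatics production is distal in reality.
* Fixed SCFA ratios and biomass yield: no pH, thermodynamic or
  community-composition feedback.
* No gas energy: H~2~/CH~4~ are assumed zero, so digestible energy equals
  gross minus fecal energy exactly.
* Urine and surface energy are not modelled beyond the protein
  post-absorption coefficient.
* The θ/rate confound and the full-resection recovery shortfall discussed
  above.
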