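---
title: "Models and methods behind chemoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoflux)
```

chemoflux analyses steady-state multiomics data from glucose-limited
chemostat cultures, where the dilution rate D pins the specific growth rate
μ. This vignette explains the models the package implements, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was open.

## The chemostat series and the Crabtree switch

A study is a set of steady states ordered by μ. Below a critical rate the
culture is purely respiratory: no ethanol is secreted and the respiratory
quotient RQ = q~CO2~ / |q~O2~| equals 1. At and above the critical rate the
cell supplements oxidative phosphorylation with substrate-level
phosphorylation: ethanol appears and RQ rises above 1.

`generate_chemostat_series()` encodes these regimes directly. Two
conventions deserve a note:

* **Onset at the critical rate.** The fermentative regime is defined as
  μ ≥ `critical_rate`, with a small positive ethanol flux already at the
  switch point, and the default μ grid snaps its closest interior point
  onto the critical rate. Consequently `detect_critical_rate()` — "the
  smallest rate with ethanol above threshold" — returns the critical rate
  itself, matching how the switch is reported for a sampled design. The
  open alternative (ethanol strictly above the critical rate) would make
  the detector return the next grid point, which is a property of the grid
  rather than of the physiology.
* **Decoupling.** O2/CO2 decoupling may precede ethanol accumulation in
  real cultures; `decoupling_rate` defaults to the critical rate but can be
  set lower to emulate the earlier onset.

Measurement noise (1% CV by default) is applied multiplicatively to the
glucose and O2 rates only; CO2 is derived as RQ·|q~O2~| so the RQ structure
is exact at any noise level.

## Proteome allocation laws

Functional groups occupy mass fractions of the proteome that vary linearly
with μ, with a possible slope change at the critical rate. Defaults (all
configurable, fractions on 0–1 scale):

| group | below critical rate | above |
|---|---|---|
| translation | 0.35 μ + 0.13 | same line |
| amino acid biosynthesis | rises from 0.04 to 0.13 | constant 0.13 |
| mitochondria | slope +0.20 from 0.10 | slope −0.14 |
| glycolysis | slope −0.15 from 0.15 | constant |
| chaperones | slope −0.10 from 0.08 | constant |
| lipid metabolism | constant 0.03 | slope −0.02 |
| four housekeeping groups | constants 0.03/0.025/0.02/0.015 | same |
| other | remainder | remainder |

The translation slope/intercept, the 13% plateau and the −0.14
mitochondrial slope are the pattern's anchor values; the remaining slopes
are plausible magnitudes chosen once. "Other" absorbs the remainder, so
fractions always sum to one.

`generate_proteome()` splits each group's mass over its proteins with a
fixed lognormal composition (SD 1.5 natural-log units, giving the
several-decade dynamic range of absolute proteomes) that does not change
across conditions, draws molecular weights once (lognormal around 50 kDa),
and converts mass fractions to copies per cell with the per-condition
protein content. At `cv_noise = 0`, `compute_group_fractions()` with the
molecular weights as mass weights recovers the laws to machine precision —
the round trip that the allocation fits are tested against.

`fit_piecewise_allocation()` estimates a change point by exhaustive search
over interior grid rates (exact and cheap at n ≤ 9), with the knot shared
by both segments and ties resolved to the smallest candidate. Pearson r on
zero-variance input is reported as `NA` rather than 0, to surface
degenerate fits.

## The mRNA–protein coupling model

The transcriptome generator draws, per gene, a protein-per-mRNA offset
(lognormal; default mean 5, SD 1.75 natural-log units — a ratio range
spanning roughly one to tens of thousands of protein molecules per mRNA)
and couples within-gene log deviations across conditions to the protein's
deviations at correlation 0.72. The pooled log–log regression of protein on
mRNA then has R² ≈ 0.52 by the variance decomposition

R² = (V~b~ + ρV~w~)² / ((V~b~+V~w~)(V~b~+σ~b~²+V~w~)),

where V~b~ is the between-gene variance of log abundance (≈ 3.3 under the
default proteome), V~w~ the small within-gene variance and σ~b~ the offset
SD. The default σ~b~ = 1.75 was fixed from this formula; across seeds the
realized R² varies by about ±0.02. The generator models correlation
structure only — no translation-efficiency mechanism, no measurement
censoring, no count noise — so passing tests show the downstream statistics
are correct, not that real transcriptomes behave this way.

## Quantification calibrations

The iBAQ chain divides a protein's intensity by its count of theoretically
observable peptides (`count_observable_peptides()`: LysC cleaves after K,
trypsin after K/R except before proline; peptides of 7–30 residues count,
with 0 missed cleavages by default — both choices configurable), fits
log amount on log signal over the spike-in calibrants by OLS in the
prediction direction, and converts relative amounts to copies per cell as
mass fractions × protein content / MW × Avogadro. Extrapolation beyond the
calibrant domain is allowed but flagged. The mRNA calibration uses the same
log–log regression form (the functional form is not uniquely determined by
the protocol; log–log is the standard choice and is stated as such), then
propagates reference-condition absolute values by fold-changes.

## Flux analysis

`fba()`/`fva()` solve the steady-state LPs with a dense bounded-variable
two-phase simplex written for this package (Bland's rule, deterministic
pivoting, tolerance 1e-9). Problem sizes here are tens of variables, where
a dense tableau-free implementation with a fresh basis solve per iteration
is transparent and fast; degenerate alternate optima are accepted — only
FVA intervals are contract-stable, the point solution is not unique.
Exchange fluxes are negative for uptake. FVA is run with growth fixed at
its measured/target value.

The toy network has 24 reactions: the ten-step EMP glycolysis, pyruvate
decarboxylase/alcohol dehydrogenase fermentation, a lumped TCA cycle
(pyruvate + 5 NAD → 3 CO2 + 5 NADH), lumped oxidative phosphorylation with
P/O = 1.5, exchanges, a fixed non-growth-associated maintenance of
0.7 mmol ATP gDW⁻¹ h⁻¹, and a biomass reaction (5 G6P + 2 PYR + 2 NADH +
40 ATP per unit growth). All species including the conjugate pairs ATP/ADP
and NAD/NADH are balanced, so exchange bounds genuinely cap uptake. Its
respiratory optimum at glucose uptake 1 is the rational value 19.3/163 h⁻¹,
derived by hand from the ATP and redox balances and used as the LP oracle.

Enzyme constraints follow the GECKO construction: per-enzyme usage
variables with v ≤ kcat·u; measured enzymes bounded at mean + 1 SD
(converted from copies per cell via the 13 pg cell dry mass); complexes
bounded by the average of their measured subunits; unmeasured enzymes
drawing from a shared pool (protein content − measured mass) × f × σ with
f = 0.4461 g/g and σ = 0.49; zero measurements treated as unmeasured.
Flexibilization relaxes, one at a time, the measured enzyme whose bound
most limits growth — the limiting enzyme is found by finite-difference
sensitivity of the growth optimum to each bound (the LP duals are not
exposed by the solver layer), and its bound is doubled; rule and factor are
deliberate interpretations of "relax until the model grows", logged in the
change log.

## The loglinear thermokinetic model

Near-equilibrium thermodynamics gives a flux proportional to enzyme amount
times reaction affinity; expanding the affinity in log metabolite
concentrations and subtracting the reference condition eliminates the
equilibrium constants and yields

j^c = J^c / e^c = J⁰/e⁰ + Σ~i~ a~i~ ln(X~i~^c / X~i~⁰),

where the coefficients a~i~ — the intrinsic turnover numbers, with the
dimension of a kcat — carry each metabolite's activating (positive) or
inhibiting (negative) effect. Allosteric effectors outside the reaction
stoichiometry can be appended as extra metabolites and are treated
identically.

Inference is Bayesian. The likelihood of condition c is the normal
probability mass over the condition's flux-variability interval divided by
the interval width, with mean j_pred^c and variance δ² = Σ(j_pred −
j_obs)²/(n − I) (n conditions, I metabolites); terms are computed in log
space so far-tail intervals underflow gracefully, a zero-width interval
degenerates continuously to the normal log-density, and δ² is floored at
1e-12 to keep exact fits finite. The prior is a common
Normal(mean(j_obs), sd(j_obs)²) for every a~i~ — the formula variant of the
protocol; a standard-error variant is available via
`default_prior(variance = "se")`.

The sampler is random-walk Metropolis with per-chain proposal scales
adapted toward the 0.234 acceptance target during burn-in (Robbins–Monro,
frozen afterwards so the kept samples satisfy detailed balance). Because
the model is linear in a, chains start overdispersed around the
least-squares solution; with an uninformative design (all ratios 1) the
start falls back to the prior. Defaults are 4 chains × 5,000 kept samples,
thinning 5, burn-in 1,000 — a desk-scale protocol; longer runs are a matter
of flags. Convergence is diagnosed by the Gelman–Rubin statistic with a
1.1 threshold (the diagnostic is standard; the cutoff is ours), and
`classify_effect()` refuses unconverged posteriors.

The synthetic kinetic truths are drawn with |a| between 0.5 and 2 with
random sign, reference specific fluxes between 0 and 2, and metabolite
ratios lognormal with SD 1 — i.e. effects of appreciable magnitude on the
same scale as the specific flux. This matters: the empirical prior centres
on the observed specific fluxes, so it is a sensible prior exactly when
turnover numbers and specific fluxes share a scale, which is also the
premise under which the method is meaningful on real data. With near-zero
effects and a large reference flux the prior would dominate and coverage
of the truth would degrade — a property of the prescribed prior, not of
the sampler.

## Regulation and phosphosites

ρ~e~ = ln(e_test/e_ref) / ln(J_test/J_ref) compares two steady states;
values in (0.5, 1.5) classify the flux change as driven by enzyme
abundance. Zero or sign-flipping fluxes make the coefficient undefined,
with the reason reported. Only the enzyme coefficient is computed; the
metabolite/transcription/phosphorylation companions are reserved fields
without a defining formula here. Fold-changes are taken on log2 scale
against the slowest-rate condition, which the analysis requires to be
stated explicitly rather than guessed (the slowest measured rate is the
natural choice).

Functional phosphorylation events correlate flux and phosphopeptide
fold-changes (Pearson, log scale): significantly positive ⇒ activating,
negative ⇒ inhibiting. A Benjamini–Hochberg screen across peptides
(`fpe_screen()`) guards the calls against noise; the single-pair
`infer_fpe()` uses its raw p value. Trend tests versus μ use Spearman
correlation with exact small-sample p values for n ≤ 9 and the
t approximation above that.

## Numerical and scope notes

* All generators are pure functions of (parameters, seed); the RNG state of
  the caller is saved and restored. Pipeline stages draw their seeds from a
  master seed and record them in the manifest.
* TSV output is written at full double precision (`%.17g`, locale
  independent), so table round trips are exact for finite values.
* The approximate `translation_rate()` — proteome residue demand over
  ribosome count, with 12,000 residues per ribosome-equivalent — is
  explicitly flagged approximate: it ignores the active-ribosome fraction
  and is not asserted to reproduce any particular elongation rate.
* Problem sizes used throughout the tests (nine conditions, ~2,500
  genes, 24-reaction network, 4 × 5,000 MCMC samples) are the package's
  desk-scale defaults; they exercise every code path with known ground
  truth while keeping a full run in minutes.
* Known limitations: the generator produces no missing values, no
  peptide-level censoring and no count noise; the toy network is not a
  genome-scale reconstruction (user models load through the JSON schema);
  enrichment operates on user-supplied sets, not a live ontology; the LP
  layer is dense and intended for models up to a few hundred reactions.
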