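---
title: "Models and methods behind thermoshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoshift)
```

Thermal shift proteomics infers drug binding from protein thermal stability:
a protein bound to a compound usually denatures at a higher temperature than
its unbound form. thermoshift implements two readouts of that effect from TMT
reporter intensities — the classic per-temperature ladder (TPP, scored with
abundance and stability scores) and the single-tube ramp (STPP-UP, scored as
a corrected differential-abundance contrast) — together with the kinetic
model and simulator that tie the two designs to a common ground truth. This
vignette records the models, the defaults, and the reasoning behind the
choices that were genuinely open.

## The kinetic model

Denaturation is modelled as two-state and irreversible with a first-order
Arrhenius rate,

$$k(T) = A \, e^{-E_a / (R\,T_K)},$$

with $T_K$ in kelvin and $R = 8.314$ J mol$^{-1}$ K$^{-1}$. The soluble
fraction after a heating program $T(t)$ is

$$S = \exp\!\Big(-\int k(T(t))\, dt\Big).$$

This is the simplest model in which denaturation accrued early in an
incremental ramp persists and accumulates until the final temperature — the
property that makes a single ramped sample informative about the whole
stability profile. It deliberately ignores refolding, multi-state
intermediates, aggregation kinetics, and ligand-binding thermodynamics
(no $K_d \to \Delta T_m$ mapping); a melting-point shift is imposed directly
as a ground-truth perturbation, not derived from binding.

A protein's melting point is anchored operationally: `calibrate_kinetics(tm)`
solves for $A$ so that a 3-minute hold at `tm` leaves exactly half the
protein soluble, matching the T$_{m\text{-}50}$ definition used with
10-point ladder data (50% loss relative to the lowest temperature).

**Activation energy default.** $E_a$ sets how steeply the rate grows with
temperature (local log-slope $E_a / (R T_K^2)$), and therefore where a ramp
"concentrates" its denaturation. The package default is
$E_a = 5.5\times 10^5$ J/mol. With kinetics calibrated to the 51 degC
mammalian-average melting point, this value places the isothermal equivalent
of the standard 37→57 degC, 0.2 degC/s ramp at $\approx 52$ degC
(`isothermal_equivalent_temperature(calibrate_kinetics(51), stpp_ramp())`),
matching the empirically reported ramp↔ladder correspondence. A markedly
lower $E_a$ (for instance 250 kJ/mol, a value sometimes quoted for
unfolding alone) puts the equivalent near 48.8 degC, which is inconsistent
with that correspondence; values of 400–600 kJ/mol are typical for
irreversible thermal denaturation of globular proteins in cells. $E_a$ is a
parameter everywhere it appears.

**Numerics.** Hold segments integrate in closed form. Ramp segments use
adaptive quadrature (`stats::integrate`, absolute tolerance below 1e-9 on
the exponent) with a fixed-step midpoint product (dt = 0.01 s) as fallback;
the same fixed-step integrator, written independently in the test suite, is
the oracle the quadrature is checked against. Equivalent-temperature lookup
is bracketed root finding on [0, 100] degC resolved to 0.01 degC.
Melting-curve fitting is nonlinear least squares over a fixed multi-start
grid (deterministic given the data), parameterized as midpoint/steepness/
plateau with box constraints; near-constant fraction profiles and fits that
collapse to a bound return a flagged failure instead of raising.

## The simulator

`simulate_experiment()` draws, per protein: T$_{m\text{-}50}$
$\sim N(51, 4^2)$ degC, base reporter intensity $\sim$ log-normal
(log2 mean 20, log2 sd 2 — corrected reporter intensities around $10^6$
spanning a few orders of magnitude), activation energy
$\sim N(5.5\times10^5, (5\times10^4)^2)$ J/mol truncated positive, a
non-melting plateau $\sim N(0.03, 0.01^2)$ truncated to [0, 0.2], and a
unique-peptide count $1 + \text{Poisson}(6)$. The noise-free signal in a
channel is

$$\text{base} \times 2^{\text{abundance effect (treated only)}} \times
  \big(p + (1-p)\,S\big),$$

then an additive background floor (default 1000) is applied and
multiplicative log-normal noise with unit mean and a given CV (default 0.1)
multiplies the total; missing values are written as zeros, the MaxQuant
convention.

Two modelling points deserve emphasis:

* **The plateau is load-bearing.** A pure two-state model drives survival at
  the top ladder temperatures to numerical zero for essentially every
  protein, which a completeness filter then deletes wholesale — unlike real
  data, where melting curves flatten at a few percent soluble fraction and
  high-temperature channels keep a small genuine signal. The plateau term
  reproduces that, and also keeps the variance of ramp-denatured proteins
  comparable to everyone else's, which matters for variance moderation.
* **Planted benchmark targets are canonical.** In the recovery benchmarks
  (one +4 degC stabilized target among abundance-only decoys) the target's
  baseline melting point and activation energy are pinned to the proteome's
  typical values (51 degC, default $E_a$) via `treatment_effect()`. A target
  whose random melting point lands above T$_{max}$ is physically invisible
  to a 57 degC ramp — the method's documented blind spot — so recovery rates
  are defined for a target the design can in principle see.

The simulator does **not** model peptide-level quantification, spectral
interference, TMT ratio compression, channel-correlated noise, or
lysate-versus-intact-cell differences. Passing the planted-effect benchmarks
therefore demonstrates correctness of the analysis chain under clean
multiplicative noise, not performance on real spectra.

The default noise CV of 0.1 and the background floor are documentation of
the simulation conditions, not claims about any real dataset.

## Normalization

`variance_stabilize()` fits, per channel $c$ within a normalization group,
the generalized-log transform

$$h_c(x) = \mathrm{glog}_2\!\big((x - a_c)/b_c\big), \qquad
  \mathrm{glog}_2(y) = \log_2\big(y + \sqrt{y^2 + 1}\big),$$

by trimmed profile maximum likelihood: Gaussian likelihood of transformed
values about per-protein means, including the log-Jacobian of the transform
(without which plain least squares is degenerate — inflating every $b_c$
collapses all residuals), over the best-fitting 90% of proteins (trim
fraction 0.1, re-selected twice). The offset $a_c$ absorbs additive
background — this is the role "background correction" plays in the model —
and the scale $b_c$ sets both the channel loading and the intensity below
which the transform linearizes. After the fit, scales are adjusted by exact
root finding so channel medians within a group agree to machine precision.
Channels are fitted in a canonical internal order so the result is invariant
to how the caller ordered the columns.

Normalization groups must contain channels that measure the same quantity
per protein up to noise: one group per ladder temperature for TPP (this also
absorbs the globally decreasing signal at higher temperatures), and one
group per heating program (ramped test vs 37 degC control) for STPP-UP.
Normalizing a whole STPP-UP plex as one group is tempting but wrong under
this model: each protein carries a systematic, protein-specific survival
offset between the two programs, and the group-mean model will distort the
channel transforms trying to absorb it.

## Moderated testing

`moderated_ttest()` implements the standard empirical-Bayes variance
moderation: per-protein pooled variance $s^2$ on $d$ df, hyperparameters
$(d_0, s_0^2)$ from the closed-form moment estimator on $\log s^2$
(trigamma matching), posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and a t statistic on
$d_0 + d$ df with two-sided p-values and Benjamini–Hochberg adjustment.
The estimator is checked against limma as an independent oracle in the test
suite; limma is not used in the computation itself.

**Correction-aware standard errors.** The STPP-UP contrast compares treated
test channels with untreated test channels shifted by the control-batch
fold change $\Delta$ (the base-abundance correction). With the default
replicate-averaged correction, the same realized $\hat\Delta$ is added to
every untreated test replicate, so its sampling noise never appears in
within-group variance and a naive two-group test is anticonservative — in
null simulations it produced several spurious hits per 2000 proteins. The
default test therefore pools within-group variance across all four
condition-by-role groups ($d = n - 4$) and uses the contrast variance factor
$1/n_{Tt} + 1/n_{Ut} + 1/n_{Tc} + 1/n_{Uc}$. With per-replicate (matched)
correction the offset noise is already inside the corrected channels and the
plain two-group test applies; `run_stpp(replicate_matched = TRUE)` selects
that pairing.

**Score FDR.** Stability scores get tail-area FDRs without parametric
p-values: robust z-transform (median/MAD), null scale re-estimated from the
central 75% quantile band (truncation heuristic — the bulk of the proteome
is assumed unaffected), normal tail areas, and a null-proportion-scaled
step-up that is monotone non-increasing in |z|. This mirrors the central-
matching strategy of local-FDR tools while staying closed-form.

## Scores and hit classification

For TPP, per-replicate fold-change profiles (treated − control per ladder
temperature, on the transformed scale) yield an **abundance score** (mean
log2 FC at the two lowest temperatures, 37 and 40.4 degC, where essentially
nothing has denatured) and a **stability score**
$\sum_T (\text{FC}_T - \text{abundance score})$, which is exactly invariant
to any constant abundance shift. Replicate scores are averaged only after
per-replicate computation, preserving variance information for the moderated
one-sample test against zero; FDR comes from the score-based estimator
above. Classification is two-tier: *hit* for score > 3 with FDR < 0.01,
else *candidate* for score > 2 with FDR < 0.05, with hit taking precedence;
thresholds are signed, so destabilization shows as negative scores on the
volcano rather than as hits, and all thresholds are arguments.

For STPP-UP, hits require |log2 FC| > 0.5 and adjusted p < 0.001. Published
analyses of this design use two p-value conventions (0.001 for the volcano
classification, 0.05 for the underlying enrichment test); the stricter
threshold is the default and both are configurable. A hit is flagged
*correction-driven* when the control-batch fold change points opposite to
the enrichment it creates and is at least half its magnitude
($\theta = 0.5$; "mostly correction" has no published formula, so the
dominance fraction is explicit and adjustable).

## Filtering and I/O

The QC cascade follows the standard protein-level rules: drop decoy
(reverse) hits, potential contaminants, site-only identifications, proteins
with fewer than two unique peptides, and (by default) proteins lacking a
strictly positive signal in every mapped channel. Rules apply in that order
for reporting purposes only — the surviving set is order-independent — and
filtering is idempotent. Filtering precedes normalization; whether the
original analyses filtered for completeness before or after normalization is
unstated, and filtering first keeps the normalization input complete.
The reader/writer use the MaxQuant proteinGroups dialect ("+" flags, one
"Reporter intensity corrected k" column per channel); the default ladder
replaces the published "68.6" entry (a transposition of 58.6 between 55.5
and 62) and sorts ascending, with the verbatim ladder behind
`tpp_default_ladder(verbatim = TRUE)`.

## Problem sizes and determinism

The planted-effect benchmarks used by the tests and the acceptance script
run 2000-protein proteomes with 20 (tests) or 10 (script) independent seeds
per readout, 3 replicates for STPP-UP and 2 for TPP, matching the replicate
counts of the corresponding published experiments; melting-curve robustness
uses 100 noise seeds at sigma = 0.02. Every stochastic step takes an
explicit integer seed, and all pipeline stages are deterministic given their
inputs, so identical configs produce identical outputs byte for byte.

## Known limitations

* One kinetic family (two-state irreversible + plateau) stands behind both
  designs; real proteomes mix reversible and multi-state behavior.
* The glog fit's offsets are weakly identified when channels carry little
  additive background; the Jacobian term and trimming keep the fit stable,
  but offsets should be read as nuisance parameters, not background
  estimates.
* Score-FDR assumes the unaffected bulk dominates the central 75% band; a
  treatment shifting a third of the proteome would violate it.
* STPP-UP cannot see targets melting above T$_{max}$, and weakly expressed
  targets lose fold-change contrast to the background floor — both are
  properties of the design the simulator reproduces, not artifacts.
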