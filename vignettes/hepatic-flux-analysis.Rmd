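---
title: "Hepatic G6P flux analysis from triple-tracer mass isotopomer distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hepatic G6P flux analysis from triple-tracer mass isotopomer distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g6pflux)
```

## The measurement problem

In vivo hepatic carbohydrate fluxes cannot be observed directly: the liver
simultaneously takes up glucose (glucokinase, GCK), produces glucose
(glucose-6-phosphatase, G6Pase), synthesizes glycogen (glycogen synthase,
GS), degrades glycogen (glycogen phosphorylase, GP), and makes new glucose
6-phosphate from trioses (gluconeogenesis, GNG). Net measurements such as
blood glucose concentration confound all five. The triple stable-isotope
tracer design resolves them:

* **[U-^13^C]glucose** infused at a known rate $I_6$ dilutes into the blood
  glucose pool; its m+6 enrichment gives total glucose turnover
  ($R_a = I_6/d_{glc}$). m+6 carbon that reappears in UDP-glucose measures
  the direct (blood glucose derived) contribution to the hepatic
  UDP-glucose pool, $c_{glc}$ — the signature of glucose cycling.
* **[1-^2^H]galactose** infused at $I_{gal}$ enters UDP-glucose directly;
  its ^2^H dilution gives UDP-glucose turnover ($R_u = I_{gal}/d_{UDPglc}$).
  ^2^H that reappears in blood glucose measures the UDP-glucose
  contribution to blood glucose, $c_{UDPglc}$ (glycogen cycling).
* **[2-^13^C]glycerol** labels the triose-phosphate pool to enrichment $p$.
  A hexose newly assembled from two trioses is binomially labeled
  ($m{+}1 : m{+}2 = 2p(1-p) : p^2$), so mass isotopomer distribution
  analysis (MIDA) yields both $p$ and the fraction $f$ of each hexose pool
  that is newly synthesized — the gluconeogenic fraction.
* **Paracetamol** is a sampling trick: urinary paracetamol-glucuronide
  reports the isotopic composition of the hepatic UDP-glucose pool without
  biopsy.

Blood spots and urine are collected hourly over a 6 h infusion; the
parameters are evaluated during isotopic steady state (240–360 min by
default).

## Two derivatization channels

Glucose is measured twice by GC-MS: as the **aldonitrile pentaacetate**
(default fragment C~16~H~21~NO~10~), which loses the carbon-1 hydrogen
during derivatization and is therefore a pure ^13^C channel, and as the
**pentaacetate** (default fragment C~16~H~22~O~11~), which retains that
hydrogen so its m+1 carries both ^13^C and the galactose-derived ^2^H. The
difference between the two channels' m+1 excesses isolates the ^2^H
enrichment (`deuterium_enrichment()`); MIDA m+1/m+2 excesses are read from
the carbon-only channel so the ^2^H label cannot contaminate them. The
fragment formulas are configurable because instrument methods may monitor
other ions.

## Natural-abundance correction

Correction matrices are built from the full elemental composition of the
derivative fragment (C, H, N, O at IUPAC abundances), not carbon only: the
acetyl carbons alone contribute >1.6% m+1, which would bias MIDA at the
precursor enrichments this analysis works at ($p \approx 0.03$–$0.1$).
Column $j$ of the matrix is the isotopologue envelope of a fragment already
carrying $j$ tracer labels (those carbons are excluded from the
natural-abundance binomial). The reported corrected spectrum is the
nonnegative least squares (NNLS) solution of $M x \approx y$ — direct
inversion can go negative under noise.

One subtlety matters for the downstream statistics: NNLS is *biased* for
isotopologues whose true abundance is near zero, because clipping noise at
zero redistributes intensity into neighboring channels (at realistic noise
this inflates a small m+2 by a few percent, which squares into the MIDA
$f = \text{m+2}/p^2$). The correction therefore also returns the
unconstrained triangular solution (`s0..s6`, "signed"), which is unbiased
under symmetric noise; all pooled parameter estimation uses the signed
values, while the NNLS spectra remain the reported MIDs.

## From excesses to the six primary parameters

Per animal, linear quantities are averaged over the steady-state window:
m+6 excess of blood glucose gives $d_{glc}$ (purity-normalized), the
^2^H m+1 enrichment of UDP-glucose gives $d_{UDPglc}$, enrichment ratios
give $c_{glc}$, $c_{UDPglc}$ and the m+3/m+6 recycling ratios.

The MIDA pair $(p, f)$ is *not* computed per sample and averaged, for a
statistical reason: the m+2 excess (~0.005 at $p = 0.1$) sits on a ~0.036
natural-abundance background, so its per-sample relative error is large
and the per-sample estimator $f = (m_1 + 2m_2)^2/(4 m_2)$ is heavy-tailed.
Instead:

1. $p$ comes from the pooled ratio $r = \sum m_2 / \sum m_1$ over **all**
   informative time points (the ratio is invariant to the mono-exponential
   approach to plateau, because both isotopologues trace the same newly
   synthesized material) and both derivative channels (the ^2^H label
   cannot reach m+2), using signed excesses so noise is not rectified into
   bias; then $p = 2r/(1+2r)$.
2. $f$ is the window-mean m+1 excess divided by $2p(1-p)$ — m+1 is an
   order of magnitude better measured than m+2.
3. By default `animal_fluxes()` pools the ratio across all animals of a
   treatment group (`p_pooling = "group"`): the precursor enrichment is
   set by the shared glycerol infusion against gluconeogenic dilution, so
   it is a group-level physiological quantity, while $f$ stays
   per animal. `p_pooling = "animal"` disables this. $p$ is always
   estimated per analyte (blood vs UDP-glucose), because hepatic zonation
   can make the effective precursor pools differ; `p_source = "blood"`
   applies the blood-glucose $p$ to UDP-glucose if desired.

## The flux balance

At isotopic steady state the fluxes into hepatic G6P (GCK, GP, GNG) equal
the fluxes out of it (G6Pase, GS); glycolysis is deliberately not a model
flux (it cannot be sampled repeatedly in vivo), so GCK and GNG are lower
bounds exactly as discussed in the source literature for this design. The
shipped `"g6p_balance"` closure is:

$$R_a = I_6/d_{glc}, \quad R_u = I_{gal}/d_{UDPglc}, \quad EGP = R_a - I_6$$
$$G6Pase = \frac{EGP}{1 - c_{glc}}, \quad GS = R_u - I_{gal}, \quad
T = G6Pase + GS$$
$$GCK = c_{glc}\,T, \quad GNG_{G6P} = f_{UDPglc}\,T, \quad
GP = T - GCK - GNG_{G6P}$$

The G6Pase equation corrects tracer dilution for glucose cycling: labeled
glucose taken up by GCK and re-exported hides part of the true G6Pase flux
from naive dilution. `GNG_blood` ($f_{glc} R_a$), the glucose balance
($G6Pase - GCK$), the glycogen balance ($GS - GP$) and clearance
($R_a$ / blood glucose) are reported alongside. Every returned flux set
satisfies the balance identity to machine precision; parameter sets
implying $GP < 0$ (i.e. $c_{glc} + f_{UDPglc} > 1$) are an explicit
per-animal error, never clipped. The solver is pluggable
(`register_closure()`) so alternative published equation systems can be
registered and cross-validated.

```{r worked}
fx <- solve_fluxes(list(d_glc = 0.0625, d_udpglc = 1/31, c_glc = 0.25,
                        c_udpglc = 0.3, f_glc = 0.5, f_udpglc = 0.5),
                   rates = list(I6 = 2.5, Igal = 1))
unlist(fx[c("Ra", "Ru", "G6Pase", "GS", "GCK", "GNG_G6P", "GP")])
```

## Units and protocol constants

All fluxes are µmol·kg^-1^·min^-1^; clearance is mL·kg^-1^·min^-1^ (mM ≡
µmol/mL). The default protocol is the standard mouse infusate —
[U-^13^C]glucose 2.5 mg/mL, [2-^13^C]glycerol 16 mg/mL, [1-^2^H]galactose
6 mg/mL, paracetamol 2 mg/mL at 0.5 mL/h into a 22 g animal — converted
with the molecular masses of the *labeled* species, giving
$I_6 \approx 5.09$ and $I_{gal} \approx 12.5$ µmol·kg^-1^·min^-1^. Tracer
isotopic purity defaults to 0.99 and normalizes the dilutions.

## The synthetic experiment

Because the pipeline's accuracy cannot be audited on animals, the package
ships a forward simulator that is a first-class, tested component:

* `synthetic_truth()` fixes the five fluxes (validated against the balance
  identity), the precursor enrichment $p$ (default 0.10, a typical triose
  enrichment under a strong glycerol infusion), the m+3/m+6 recycling
  fraction (default 0.15), pool time constants ($\tau_{glc} = 45$,
  $\tau_{UDPglc} = 60$ min — consistent with plateaus by 240 min), a 60 min
  urinary collection lag, and log-normal multiplicative measurement noise
  (default CV 5% per isotopologue intensity, typical GC-MS error).
* `steady_state_enrichments()` inverts the closure algebraically to the
  six parameters and pool MIDs. Two reported-only parameters are not
  determined by the closure and come from steady-state label balances:
  $f_{glc} = G6Pase \cdot GNG_{G6P} / (T (I_6 + G6Pase))$, and
  $c_{UDPglc}$ from a ^2^H balance across the glucose/G6P cycle with
  last-in-first-out glycogen (freshly synthesized glycogen is the first
  re-released). The model treats the G6P-to-UDP-glucose route as carrying
  no ^2^H back into UDP-glucose, matching the closure's reading of
  $d_{UDPglc}$ as pure galactose dilution.
* `simulate_experiment()` applies the mono-exponential plateau approach,
  convolves with the channel-specific natural-abundance matrices, adds
  noise, and emits the exact long-format schema the real-data entry point
  reads — so synthetic data exercise every line of the analysis path.

What the simulator does **not** emulate: non-steady-state flux dynamics,
slow drift of pool sizes during infusion (G6P accumulation under S4048
violates the stable-pool assumption in reality), renal or intestinal
glucose production, G6PC-independent glucose release via lysosomal
glycogen breakdown, chromatographic interferences, or between-time-point
autocorrelation of instrument response. Passing recovery tests therefore
demonstrate correctness of the algebra and estimators under the stated
error model, not robustness to all real-world pathologies.

## Numerical and statistical choices

* Steady-state window fixed at [240, 360] min with a drift diagnostic
  (linear fit across the window; |relative drift| < 10% passes); the
  window is never shrunk adaptively — a failing animal is flagged.
* Noise floors (default 10^-4^ excess) mark parameters indeterminate
  rather than returning wild ratios; indeterminate time points are `NA`
  and excluded from pooling.
* MIDA $f$ marginally above 1 is clipped to 1 with a warning; infeasible
  flux solutions are errors carrying the offending value.
* Group summaries are mean ± SEM. `compare_groups()` runs a two-way ANOVA
  with type-II sums of squares (robust default for the near-balanced 2×2
  design; the choice matters little when cells are balanced) followed by
  Tukey HSD on the four cell means, reporting only the four contrasts the
  design interprets: treatment effect within each infusion arm and
  infusion effect within each treatment arm, flagged at α = 0.05.
* Determinism: every stochastic step is seeded; identical config + seed
  reproduce identical output bundles byte for byte.

## Precision limits

Simulation at the default noise model (5% CV per intensity) shows the
turnover-type quantities ($R_a$, $R_u$, G6Pase, GS, GCK) are recovered
with 2–3% median error for a 7-animal group, but the MIDA-derived
gluconeogenic flux — and hence GP, which is computed by difference — carry
~10% median error: the m+2 excess that anchors $p$ is intrinsically small
at $p \approx 0.1$ and its corrected value inherits leaked intensity noise
from the much larger m+0/m+1 peaks. This is an information limit of the
measurement design at that precursor enrichment, not an estimator defect
(the estimators are unbiased); higher glycerol enrichment, lower intensity
CV, or more in-window samples relax it. Configurations in which GP is a
small share of G6P turnover inflate its *relative* error further, since GP
is a difference of large numbers. The acceptance suite states these
recovery properties as tests and reports honest numbers.

## A worked cohort

```{r cohort}
truths <- example_group_truths(noise_cv = 0.03, tau_glc = 20,
                               tau_udpglc = 20)
cohort <- simulate_cohort(4, truths["shSCR_vehicle"], seed = 7)
animals <- suppressWarnings(
  animal_fluxes(sample_parameters(correct_mid_table(cohort))))
round(colMeans(animals[, c("Ra", "Ru", "GCK", "G6Pase", "GS", "GP",
                           "GNG_G6P")]), 1)
```

The group means can be compared with the fluxes implied directly by that
group's parameter set, `solve_fluxes(example_group_params()[1, ])`.
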