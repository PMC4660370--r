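---
title: "Methods: models, numerics and design choices in allokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, numerics and design choices in allokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

allokin packages the quantitative workup of an allosteric-inhibition study
of an oligomeric enzyme. The motivating system is IMP dehydrogenase
(IMPDH): GMP inhibits it competitively at the active site, while GDP and
GTP act through the regulatory Bateman domain, associating tetramers into
low-activity octamers. Three assay chains — enzyme kinetics, isothermal
titration calorimetry (ITC), and small-angle X-ray scattering (SAXS) — each
come with a seeded synthetic-data generator emulating the corresponding
experimental design, so every stage is exercised end to end in the test
suite. This vignette records the models, the tunable parameters, the
numerical choices, and the places where the design was genuinely open.

## Enzyme kinetics

### Rate laws

At fixed co-substrate (the assays emulate saturating, constant NAD⁺ at
0.5 mM), velocity as a function of substrate `S` and inhibitor `I` takes
one of three forms:

* no inhibition: \(v = V_{max} S / (K_m + S)\);
* competitive: \(v = V_{max} S / (K_m (1 + I/K_i) + S)\);
* partial (hyperbolic) mixed-type:
  \[v = \frac{V_{max}\,(1 + \beta I/(\alpha K_i))\, S}
           {K_m (1 + I/K_i) + S (1 + I/(\alpha K_i))}.\]

The mixed form nests the others: \(\alpha = 1, \beta = 1\) removes the
inhibitor's effect entirely; \(\beta = 0\) with \(\alpha \to \infty\)
converges to the competitive law; at \(I \to \infty\) velocity tends to
\(\beta V_{max} S/(\alpha K_m + S)\). These identities are enforced as
tests. At any fixed `I` the law is exactly Michaelis–Menten with apparent
parameters
\(V_{max}^{app} = V_{max}(1+\beta I/(\alpha K_i))/(1+I/(\alpha K_i))\) and
\(K_m^{app} = K_m(1+I/K_i)/(1+I/(\alpha K_i))\), which is what the
Hanes–Woolf diagnostic (`S/v` against `S`; slope \(1/V_{max}^{app}\))
visualizes: competitive inhibition gives lines parallel to the control,
mixed-type inhibition changes the slope by
\((1+I/(\alpha K_i))/(1+\beta I/(\alpha K_i))\).

Scope limits: no substrate inhibition, no Hill cooperativity, no
bi-substrate (NAD⁺-varying) kinetics, and no normalization to kcat —
velocities stay in their assay units, so absolute rates are unit-free in
all recovery checks while `Km`, `Ki`, `α`, `β` are physical.

### Fitting and mechanism selection

`fit_inhibition_global()` fits all three candidates over the full (S, I)
grid in one weighted nonlinear least-squares problem each
(Levenberg–Marquardt via minpack.lm, box bounds: all parameters positive,
\(\alpha \in (10^{-2}, 10^6]\), \(\beta \in [0, 10]\)). A sequential route
— per-level Michaelis–Menten fits whose apparent parameters are then read
against `I` — is retained as a diagnostic (`apparent`), because with noisy
per-level fits it is markedly less stable than the global fit; the global
route is the default and the one whose standard errors are reported.

Starting values matter more than usual here because the no-inhibition
model, fitted to strongly inhibited data, can run a parameter into its
bound and leave a singular Hessian. All candidates therefore multistart:
`(Vmax, Km)` anchored on a control-series fit, `Ki` from the median nonzero
inhibitor level (and ±10×), and four `(α, β)` combinations spanning weak to
strong coupling; the best converged solution wins. Weighting is unweighted
by default (`1/v²` available via `weighting = "inv_v2"`); the default
reflects that absorbance-derived initial velocities have roughly constant
absolute noise over the usable range.

Mechanism choice uses AICc on the weighted residual sum of squares, with a
simplicity tie-break: if a simpler candidate (none < competitive < mixed)
comes within ΔAICc = 2 of the winner, the simpler one is selected and the
fit is flagged ambiguous. Parameters pinned at the `α` upper or `β` lower
bound are flagged, not silently accepted.

### Initial velocities from time courses

`estimate_initial_velocity()` converts an A340 progress curve to µM/min via
Beer–Lambert with the standard NADH extinction coefficient
ε₃₄₀ = 6220 M⁻¹cm⁻¹ (a textbook constant, configurable). The linear window
is the longest initial prefix with ≥ 5 points, R² ≥ 0.995, **and** no
systematic residual sign trend (Wald–Wolfowitz runs test, p > 0.01). The
runs test is essential: an R²-only rule accepts smoothly curved prefixes —
for an exponential-approach curve the fitted slope over a window of length
T is biased by about T/2τ regardless of noise level, so R² alone can pass a
window carrying a 15–25% velocity bias. A perfectly flat or exactly linear
trace (zero residual variance) short-circuits as linear.

## ITC

### Model

The cell is treated with the continuous-displacement dilution model: after
cumulative injected volume ΔV, macromolecule and ligand totals are
\(M_t = M_0 e^{-\Delta V/V_0}\) and \(X_t = X_0 (1 - e^{-\Delta V/V_0})\).
For `n` identical independent sites with association constant `Ka`, the
bound fraction per state solves the mass-action quadratic (evaluated in the
cancellation-stable form \(2b/(a + \sqrt{a^2-4b})\), which matters in the
tight-binding limit). The per-injection heat is the difference in total
heat content between consecutive equilibrium states with the standard
perfusion correction
\(\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2\). An
independent test oracle recomputes the same heats by generic root finding
on the free-ligand equation; the two routes agree to below 10⁻⁸ relative
on randomized protocols.

The default protocol mirrors the emulated experiment: 200 µL cell, 20 µM
macromolecule, 300 µM ligand, 19 × 2 µL injections at 25 °C. Scope limits:
integrated heats only (no thermogram peak integration), no multi-site or
competitive-displacement models, dilution heat only as a constant offset
(no blank titration is simulated).

### Fitting and identifiability

`fit_single_site()` fits `n`, `Ka` (log scale, multistarted over
10⁴–10⁷ M⁻¹), `ΔH`, and optionally a constant baseline offset. The Wiseman
parameter `c = n·M_t·Ka` governs how much the isotherm shape constrains the
parameters: the three emulated conditions sit at c ≈ 12 (apo), 0.8 (GTP)
and 0.3 (GDP). At low c the (n, ΔH, offset) directions are nearly
collinear, so the recovery analyses fix `n = 1` (the stoichiometry is known
for this single-site system — standard ITC practice at low c) and omit the
baseline, since the generator injects no dilution heat; both switches are
exposed (`fix_n`, `fit_baseline`) and default to the conservative
real-data behavior (n free, baseline fitted). First-injection discarding is
available (`discard_first`) but off by default. An all-zero-heat titration
is returned flagged `unidentifiable` with ΔH = 0 rather than fitted.

`derive_thermodynamics()` uses ΔG = RT·ln(Kd in molar) with
R = 1.9872×10⁻³ kcal·mol⁻¹K⁻¹ and defines −TΔS ≡ ΔG − ΔH, so the
decomposition identity holds exactly by construction; table output rounds
to 1 decimal the way such results are conventionally reported.

## SAXS

### The chain

`saxs_characterize()` runs: per-q normalization of a concentration series
and linear extrapolation of I(q)/c against c to infinite dilution (with
uncertainty from the per-q regression, or propagated σ when only two
concentrations exist); Guinier fitting; Dmax estimation via a regularized
indirect Fourier transform (IFT); Porod volume and mass; and the
tetramer/octamer call.

**Guinier.** The window is the widest low-q stretch with ≥ 8 points and
qRg ≤ 1.3, required to show no systematic residual trend (runs test,
p > 0.01). When the trend check fails, the upper qRg edge retreats
(1.3 → 0.55 in steps of 0.15) before any low-q points are sacrificed,
because curvature sits at the high edge while beam-proximity artifacts sit
at the low edge. On exact model curves, whose only "noise" is the model
curvature itself, no window ever passes a trend test; the fallback is then
the least-curved (smallest-qRg) window, which is the least biased. This
keeps sphere-curve Rg errors below 1%, where a fixed qRg ≤ 1.3 window
carries 1–2% curvature bias.

**IFT.** p(r) lives on 101 uniform points of [0, Dmax] with p(0) =
p(Dmax) = 0, obtained by minimizing
\(\|(Ap - I)/\sigma\|^2 + \lambda\|p''\|^2\) under p ≥ 0, with A the
\(4\pi \sin(qr)/(qr)\,dr\) kernel. The box-constrained quadratic program is
solved by L-BFGS-B with the analytic gradient after normalizing intensities
to order 1 (the optimizer's gradient tolerances are absolute; raw Debye
intensities of ~10¹³ would stall it instantly). λ = 0 is refused. The
automatic λ takes the L-curve corner over a 10-decade grid, guarded by a
discrepancy rule — the corner may not degrade χ² by more than 30% over the
best achievable, else the strongest smoothing within that budget is used;
the guard exists because discrete corner detection is unstable when the
χ²(λ) path is nearly flat (noiseless curves). `Rg_pr` and `I0_pr` come
from the moments of p.

**Dmax.** Candidates spanning 1.6–4.5 Guinier radii are scanned; a
candidate is admissible when p decays to ≤ 1% of its peak over the terminal
5% of [0, Dmax], shows no negativity beyond solver tolerance, and — the
truncation guard — its χ² sits within 2× of the large-Dmax plateau
(truncating real pair distances inflates χ² sharply). The smallest
admissible candidate is refined by one more step: bodies with thin
protrusions (the finger-domain arms of the bead models here) leave a faint
but resolvable p(r) shelf below the 1% threshold, so the most generous fit
is inspected for a contiguous shelf above its own tail floor
(max(3× floor, 10⁻⁴ of peak)) extending at most 1.3× beyond the dominant
support, and Dmax extends to its end when one is found. Without the shelf
step the 1%-decay rule lands 13–17% short on disc-plus-arm bodies; with
it, the self-consistency tests hold to 10%. This remains the least
determined quantity in the chain: for particles whose extremities carry a
fraction of a percent of the scattering mass, Dmax beyond ~±10% is simply
not in the data.

**Porod.** \(Q = \int q^2 I\,dq\) is assembled from the analytic Guinier
extension on [0, q_min], the data trapezoid up to q_cut = 0.25 Å⁻¹, and an
analytic \(K/q_{cut}\) tail with K from the mean of \(I q^4\) over the
pre-cutoff stretch (skipped with a warning if it comes out negative). Then
\(V_p = 2\pi^2 I(0)/Q\), and mass = 0.6 Da/Å³ × Vp, rounded to integer
kDa — the conversion constant that reproduces the reference volume-to-mass
pairs this workflow is benchmarked against. The mass ratio to 4× monomer
classifies: [0.8, 1.3) tetramer, [1.6, 2.4] octamer, anything else
(including the deliberate gap) "other" rather than a forced call.

**Debye profiles.** \(I(q) = \sum_{ij} f_i f_j \sin(qd_{ij})/(qd_{ij})\)
with volume-weighted sphere amplitudes (series-expanded below x = 0.02 to
dodge cancellation). Pair distances are histogrammed at 0.5 Å per
radius-class pair; each bin contributes through its weighted mean distance
with a second-order within-bin-variance correction, which keeps the
histogram route within 0.1% of the exact double sum.

### Bead models

`gen_bead_assembly()` provides the two synthetic scatterers. The tetramer
is a 4-fold symmetric disc of R = 17 Å beads (center, plus rings of 8, 12
and 16 beads at 23, 41 and 52 Å) with four thin diagonal arms of R = 8 Å
beads at 57 and 71 Å emulating the finger-domain protrusions; the octamer
stacks two such discs co-axially at z = ±19 Å, tail-to-tail. The geometry
was calibrated once, before any analysis, against the target hydrodynamics
of the emulated system — Guinier Rg ≈ 45 Å (tetramer) and ≈ 50 Å
(octamer), model Dmax 158/163 Å — and frozen; the octamer doubles the bead
volume exactly by construction. One deliberate difference from a real
protein: overlapping beads make the internal density lumpy, which raises
∫ρ² and leaves the bead body's Porod volume (~0.35/0.70 ×10⁶ Å³) below a
homogeneous particle of the same envelope. Classification is unaffected —
the mass ratios against a 57 kDa monomer land near 0.9 and 1.8, inside the
tetramer and octamer bands — but absolute Porod masses of the bead models
are smaller than those of the protein they emulate, and the analysis
scripts report them as what they are.

## Synthetic designs: what they emulate, what they do not

* **Kinetics**: 9-level 2-fold substrate dilution series 19.5–5000 µM, six
  inhibitor levels (0 plus 20–5000 µM log-spaced), 3 replicates;
  multiplicative Gaussian noise (2% default) plus a small additive floor
  (0.2% of Vmax). Real assays add coupled-enzyme lags, pipetting
  covariance and day effects that are not modeled, so passing recovery
  tests demonstrates estimator correctness under the stated error model,
  not robustness to systematic error.
* **ITC**: Gaussian heat noise at 2% of the titration's own largest
  expected injection heat — tied to the titration's heat scale so that the
  noise level is comparable across binding strengths (scaling it to the
  stoichiometric-limit heat instead would drown low-c conditions in noise
  an instrument would not produce). No baseline drift, no injection-volume
  error.
* **SAXS**: q from 0.005 to 0.35 Å⁻¹ in 400 points; concentrations 1.25,
  2.5, 5, 10, 20 mg/mL; Poisson-like σ ∝ √I with a floor, scaled so the
  lowest-q relative error is 1%; optional low-q interparticle
  structure-factor attenuation `(1 − k_sf·c·e^{−(q/q_{sf})²})`, default off.
  No instrumental smearing, no buffer-subtraction artifacts, no radiation
  damage.

Every generator is a pure function of (truth, design, seed), saves and
restores the global RNG state, and round-trips bit-exactly through the
package's readers and writers.

## Problem sizes and runtime

The recovery studies use 20 seeded replicates per kinetics truth set
(162 observations each), 11 per ITC condition, and 20 full SAXS chains per
oligomeric state — sizes chosen so the whole test suite and the acceptance
script each complete in about a minute on a single core while leaving the
recovery-rate estimates stable to a seed or two.

## Known limitations

* Mechanism selection near the competitive/mixed boundary (β within noise
  of 0 and large α) is resolved to the simpler model by design; genuinely
  partial inhibitors with β below the noise floor will be reported
  competitive with the ambiguity flag set.
* Low-c ITC isotherms do not determine (n, ΔH, offset) jointly; the
  package exposes the standard remedies rather than pretending otherwise.
* Dmax inherits the ±10% indeterminacy discussed above.
* The Hanes–Woolf slope-equality F-test operates on transformed,
  heteroscedastic data; it is a visual-diagnostic companion, not a
  substitute for the AICc comparison (with proportional noise it rejects
  exact parallelism more often than its nominal level).
* The infinite-dilution extrapolation assumes the structure factor is
  linear in concentration over the measured range.
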