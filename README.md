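# allokin

Quantitative analysis chain for allosteric enzyme-inhibition studies, built
around the biology of IMP dehydrogenase (IMPDH), the rate-limiting enzyme of
guanine-nucleotide biosynthesis. Guanine nucleotides regulate eukaryotic
IMPDHs in two distinct ways: GMP competes with the substrate IMP at the
active site, while GDP and GTP bind the regulatory Bateman domain and drive
the tetramer to associate into a catalytically compromised octamer —
a partial, mixed-type allosteric inhibition that is visible in solution
scattering as a doubling of the particle volume.

The package implements the three assay workups this kind of study needs, plus
seeded synthetic-data generators that emulate each experimental design, so
the whole chain is testable end to end without instrument data.

## Models

**Enzyme kinetics.** Initial velocities on a (substrate, inhibitor) grid are
fitted globally to three candidate rate laws:

- none: `v = Vmax·S/(Km + S)`
- competitive: `v = Vmax·S/(Km(1 + I/Ki) + S)`
- partial (hyperbolic) mixed-type:
  `v = Vmax·(1 + βI/(αKi))·S / [Km(1 + I/Ki) + S(1 + I/(αKi))]`

where `α` is the substrate–inhibitor heterotropic interaction factor
(`α → ∞` recovers competitive) and `β` the fractional activity of the
ternary complex (`β = 0` is dead-end). Candidates are compared by AICc with
a Δ < 2 tie going to the simpler mechanism; Hanes–Woolf plots (`S/v` vs `S`)
and per-level apparent `(Vmax, Km)` serve as diagnostics.

**ITC.** Integrated injection heats are fitted to the single-site isotherm
(mass-action quadratic per injection state, continuous-dilution cell
correction, perfusion heat correction), and the fitted `Kd` and `ΔH` are
decomposed via `ΔG = RT·ln Kd` and `−TΔS = ΔG − ΔH`.

**SAXS.** Concentration series are normalized and extrapolated to infinite
dilution; `Rg` comes from an automatically windowed Guinier fit
(`qRg ≤ 1.3`, residual runs test); `p(r)` and `Dmax` from a nonnegative,
smoothness-regularized indirect Fourier transform; the Porod invariant
gives the particle volume `Vp = 2π²I(0)/Q` and a mass estimate
(0.6 Da/Å³), which a threshold rule turns into a tetramer/octamer/other
call. Theoretical curves for coarse bead models come from the Debye
equation with a pair-distance-histogram acceleration.

## Worked example

```r
library(allokin)

truth <- list(mechanism = "mixed", Vmax = 1, Km = 51, Ki = 210,
              alpha = 6.5, beta = 0.033)            # a GDP-like inhibitor
d <- gen_kinetics_dataset(truth, seed = 11)          # 9 S-levels x 6 I-levels x 3
fit_inhibition_global(d)
```

```
Global inhibition fit (162 observations)
  mechanism: mixed
  Vmax         1.0007  (se 0.00236)
  Km           50.915  (se 0.662)
  Ki           205.42  (se 6.27)
  alpha        6.4375  (se 0.278)
  beta       0.040359  (se 0.00746)
  AICc: none=-451.51  competitive=-778.74  mixed=-1428.16
```

The mixed mechanism wins by a wide AICc margin and every generating
parameter is recovered within its standard error band: the inhibitor binds
with `Ki ≈ 0.21 mM`, weakens apparent substrate affinity about 6.4-fold
(`α`), and leaves the ternary complex ~4% active (`β`).

The numbered scripts under `analysis/` run the three full chains
(`01_kinetics.R`, `02_itc.R`, `03_saxs.R`) and write their tables under
`results/`. For instance `analysis/02_itc.R` prints:

```
apo  Kd =  1.64 uM | dG =  -7.9 | dH = -26.2 | -TdS =  18.3 kcal/mol
GTP  Kd =    25 uM | dG =  -6.3 | dH = -53.9 | -TdS =  47.6 kcal/mol
GDP  Kd =  60.7 uM | dG =  -5.8 | dH = -30.1 | -TdS =  24.4 kcal/mol
```

showing the entropic penalty that accompanies substrate binding once the
enzyme is locked in the nucleotide-bound octameric state.

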