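Package: allokin
Title: Allosteric Enzyme Inhibition Kinetics, ITC Binding Thermodynamics and
    SAXS Oligomer Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for studies of allosteric enzyme
    inhibition, exemplified by IMP dehydrogenase (IMPDH) and its regulation by
    guanine nucleotides. Provides global nonlinear regression of partial
    (hyperbolic) mixed-type inhibition with mechanism classification (Ki,
    alpha, beta), Hanes-Woolf diagnostics and initial-velocity extraction from
    absorbance time courses; single-site isothermal titration calorimetry
    isotherm fitting with thermodynamic decomposition (Kd, dG, dH, -TdS); and a
    small-angle X-ray scattering toolchain (infinite-dilution extrapolation,
    Guinier fitting, regularized indirect Fourier transform p(r), Porod volume
    and mass estimation, Debye-equation bead-model profiles) with
    tetramer/octamer oligomeric-state classification. Seeded synthetic-data
    generators emulate the corresponding experimental designs so every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
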