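Package: vwfdyn
Title: Shear-Driven von Willebrand Factor Unfolding Dynamics on the
    Platelet Surface
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulator for the conservative, dimensionless dynamics of a
    surface-grafted von Willebrand factor (VWF) multimer under
    time-varying shear stress.  Provides the potential-landscape and
    bifurcation analysis of the globule-stretch transition (fold
    catastrophe at the critical shear), time integration of the equation
    of motion under analytic or CSV-sampled shear waveforms with physical
    boundary handling and separatrix-crossing detection, and the
    activation criteria for shear-induced platelet activation: the
    cumulative shear stress integral, its closed-form threshold as a
    function of multimer size, the momentum sufficient condition, the
    critical rectangular-impulse duration curve and its amplitude
    asymptote.  Results are returned as tibbles with broom-style tidy()
    and glance() methods and ggplot2 autoplot() methods; a command-line
    interface is included for batch use on shear histories exported from
    computational fluid dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
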