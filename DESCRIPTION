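Package: ocuvegf
Title: Compartmental Pharmacokinetics of Topical and Intravitreal Anti-VEGF Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and fits a three-compartment (tear film, aqueous humor,
    vitreous humor) ordinary-differential-equation model of ranibizumab
    transport and VEGF binding in the eye. Supports event-driven dosing with
    eye drops, drug-eluting contact lenses, and intravitreal injections;
    closed-form untreated VEGF steady states; Nelder-Mead least-squares
    fitting of interface permeabilities to ex vivo porcine ELISA data;
    Metropolis-Hastings identifiability analysis; local one-at-a-time
    sensitivity analysis; and dosing-regimen sweeps for the in vivo human
    eye. Trajectories and results are returned as tibbles with ggplot2
    autoplot methods and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
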