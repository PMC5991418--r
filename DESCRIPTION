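Package: mutucomp
Title: Bistability Analysis for Two Cross-Feeding Competitors in a Chemostat
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing a two-species microbial community that
    competes for a shared carbon source while exchanging cross-feeding
    metabolites. Implements the five-variable chemostat model with
    double-Monod growth kinetics, its two-variable extended Lotka-Volterra
    reduction (linear mutualism plus quadratic competition in the growth
    term), and the analysis toolkit built on top of both: steady-state
    enumeration and linear stability, necessary conditions for bistability,
    nullcline and basin-of-attraction maps, regime classification and
    two-parameter regime scans, one-parameter branch tracing with
    saddle-node and transcritical bifurcation detection, and a Monte-Carlo
    survey of bistability frequency under random chemostat parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
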