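Package: moodcycle
Title: Mood-Expectation Dynamics of Bipolar Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a nonlinear dynamical model of mood
    regulation in which mood and learned expectation interact through a
    prediction-error (surprise) signal. Mood sensitivity acts as a
    bifurcation parameter: above a critical value the model undergoes a
    supercritical Hopf bifurcation and mood settles into a limit cycle,
    the model's signature of a bipolar state. Asymmetric sensitivities to
    positive and negative surprise split the phase plane into two linear
    half-plane regimes (node or spiral), for which closed-form stability
    criteria are provided alongside event-accurate piecewise-smooth ODE
    integration. Includes piecewise-constant stochastic reality forcing,
    QIDS-SR16 depression scoring, medication-intervention protocols
    (antidepressant mood elevation, sensitivity increase, lithium-like
    sensitivity reduction), and two-parameter stability scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
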