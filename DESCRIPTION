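Package: saccsim
Title: Closed-Loop Simulation of Saccade and Microsaccade Triggering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the neural triggering of saccades and microsaccades with a
    one-dimensional superior-colliculus map (101 leaky-integrator neurons with
    Mexican-hat lateral connectivity and a thresholded burst layer) coupled to a
    brainstem trigger formed by mutually inhibitory omnipause and burst neurons,
    a cerebellar stop circuit that chokes ongoing movements, and a pulse-step
    oculomotor plant inside a closed visual loop with 50-ms feedback delay.
    Spatiotemporally correlated noise injected into the collicular map produces
    spontaneous fixational microsaccades; single-parameter lesions reproduce the
    saccadic intrusions of parkinsonian and cerebellar disorders. Includes a
    velocity-threshold saccade detector, main-sequence and square-wave-jerk
    statistics, and named experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    deSolve
Config/testthat/edition: 3
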