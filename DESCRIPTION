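Package: cartqol
Title: System Dynamics Simulation of Health-Related Quality of Life in CAR
    T-Cell Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An exploratory system dynamics (stock-flow) simulator of
    health-related quality of life (HRQoL) for cancer patients before and
    after CAR T-cell therapy. Five coupled stocks (tumor burden, CAR T-cell
    level, side-effect severity, physical and psychological well-being) are
    integrated with a fixed-step fourth-order Runge-Kutta scheme with
    discrete infusion and death events resolved at step boundaries. The
    package ships three calibrated patient scenarios (complete response,
    relapse, no infusion) and two improvement strategies (reduced
    approval-to-infusion delay, enhanced daily social support), four HRQoL
    trajectory metrics (post-infusion drop, recovery time, peak, durability
    of the peak), a univariate plus/minus 10 percent sensitivity harness, an
    extreme-condition test battery, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
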