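Package: crkinetics
Title: Kinetic-GFR Creatinine Trajectories and Their Sensitivity to the
    Volume Change Rate
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: One-compartment creatinine kinetics under a constant volume
    change rate: closed-form evaluation of the serum creatinine trajectory
    used in kinetic GFR estimation, analytic first and second partial
    derivatives of the creatinine concentration with respect to the volume
    change rate, location of the derivative curve's extrema, the tangency
    condition and benchmark generation rate / initial creatinine that
    separate an always-negative derivative from a potentially positive
    one, and a regime classifier for the "positive paradox" in which
    removing fluid lowers (and giving fluid raises) the later creatinine.
    Includes named clinical fixtures, curve sampling with CSV export, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
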