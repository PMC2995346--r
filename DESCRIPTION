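Package: twostroke
Title: Opponent Motion-Energy Modelling of Two-Stroke Apparent Motion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an elaborated opponent motion-energy model for
    two-stroke apparent motion: space-time stimulus synthesis (single-cycle
    and repeating seven-frame two-stroke sequences), even/odd Gabor spatial
    filters and fast/slow biphasic temporal filters, four oriented energy
    sensors with flicker-energy normalisation, and normalised net motion
    energy (NE) as a function of inter-stimulus interval. Fits the temporal
    scale factor k to psychophysical direction-discrimination and
    motion-after-effect data by RMS error over a k grid, estimates filter
    centre frequencies from the amplitude spectrum of the temporal impulse
    response, and provides a synthetic two-alternative forced-choice and
    after-effect observer generator for parameter-recovery testing, plus
    the group summary statistics and paired t-tests used to compare
    photopic and scotopic viewing conditions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
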