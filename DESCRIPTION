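Package: iatkit
Title: Construction, Administration, Scoring and Simulation of Implicit
    Association Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless engine for the Implicit Association Test (IAT):
    builds the seven-block randomized task structure with balanced pairing
    blocks, administers it trial-by-trial with millisecond latency capture
    and forced error correction, cleans response latencies and computes
    differential (D) scores, simulates synthetic respondents and full
    crossed-design studies (app type by input method, randomized order),
    and reproduces the comparative statistical analyses such studies use
    (group descriptives, ANOVA/Kruskal-Wallis tests, a chi-squared
    randomization check, and noncentral-F post-hoc power).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
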