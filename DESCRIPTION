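Package: prxopt
Title: Timely Optimal Cerebral Perfusion Pressure and Autoregulation
    Limits from Short Neuromonitoring Episodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of continuous arterial blood pressure (ABP) and
    intracranial pressure (ICP) monitoring for neurocritical care. Computes
    the pressure reactivity index (PRx) as a moving Pearson correlation of
    slow ABP and ICP variations, fits the U-shaped PRx-versus-driver curve
    to identify the optimal cerebral perfusion pressure (CPPopt), optimal
    ABP, and the lower/upper limits of cerebrovascular autoregulation
    (LLCA/ULCA), and classifies 24-minute monitoring segments as
    artifact-distorted or informative with radial-basis support vector
    machines so that optima can be identified from short (2-hour) episodes.
    Includes a synthetic multimodal monitoring simulator with a known
    ground-truth autoregulation curve, a five-way individualized-management
    decision per 2-hour window, percentage-time yield reporting, and
    classifier evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
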