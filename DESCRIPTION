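Package: opsmatch
Title: Declarative Registry and Matching Engine for Image-Processing Operations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative, extensible registry of algorithm plugins ("ops")
    described by YAML metadata descriptors, matched to user requests by name
    and parameter types through a deterministic engine.  The engine can adapt
    ops between functional shapes (function, computer, inplace), convert
    parameters between data types, supply defaults for optional parameters,
    and inject op dependencies recursively.  Ships a foundational
    image-processing op collection (Gaussian and Difference-of-Gaussians
    filtering, histograms, Otsu thresholding, FFT, normal CDF and
    significance masks), a fluent request builder with provenance logging,
    and a command-line front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    stats,
    utils,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
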