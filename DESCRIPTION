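Package: vqmvpa
Title: Multi-Voxel Pattern Analysis of Visual Quality Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how perceived image quality shapes neural
    representations in the human visual pathway. Implements a counterbalanced
    event-related design generator with exact inter-stimulus-interval
    scheduling, a synthetic trial-level beta-pattern simulator with planted
    semantic and quality structure, split-half voxel-reliability selection and
    pattern extraction, representational similarity analysis against ideal
    semantic and quality models, kernel-regression mapping between region
    response patterns with repetition-based noise ceilings, and support-vector
    decoding of perceived quality from single regions and region combinations,
    scored with rank and linear correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
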