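Package: tracephys
Title: Fiber Photometry, Sharp-Wave Ripple and Freezing Analysis for Trace Fear Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for trace-fear-conditioning neurophysiology:
    isosbestic-corrected fiber-photometry dF/F with peri-event trial extraction,
    baseline z-scoring and pre/post-shock epoch means; threshold-based
    sharp-wave-ripple (SWR) detection from hippocampal LFP with epoch-wise
    incidence; epoch-wise freezing statistics and their coupling to ripple
    counts; and the associated statistical tests (paired t, Welch t, mixed-design
    ANOVA with Sidak post hoc, Pearson correlation). Ships synthetic-data
    generators for all three input streams with known ground truth, so every
    stage of the pipeline can be validated against recoverable targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
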