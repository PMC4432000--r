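Package: driftwood
Title: Source Assignment and Founder-Effect Analysis for Dominant-Marker
    Island Colonization Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing postglacial island colonization with dominant
    (band presence/absence) molecular markers such as AFLPs. Individuals
    sampled on recipient islands are allocated to candidate source regions by
    a multilocus log10-likelihood assignment test with a minimum
    log-likelihood-difference threshold; the genetic founder effect is
    quantified with six measures (minimum colonizing propagules by set cover,
    population and regional diversity ratios from mean pairwise differences,
    marker proportion, and minimum and assignment-based source-region
    counts) together with private-marker counts and a glacial-survival
    screen. Floristic similarity between islands and candidate sources,
    endemic counts and colonization-interval estimates complement the
    genetic analyses, and a forward simulator of regionally structured
    band-frequency data with known colonization ground truth supports
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
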