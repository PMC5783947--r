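Package: acekit
Title: Design and Kinetic Analysis of Aptamer-Complementary Element
    Microarray Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for engineering duplexed-aptamer (DA) biosensor libraries
    and analysing the non-equilibrium microarray assays used to profile them.
    Enumerates, counts and names aptamer-complementary elements (ACEs) tiling
    an aptamer, including single-mismatch variants; generates probe sequences
    and randomized sub-array layouts; reads and writes spot-level intensity
    and condition tables; applies the three spot-rejection rules and replicate
    aggregation; converts calibrated fluorescence losses into spontaneous
    (k_off) and ligand-induced (k*_off) duplex dissociation rates; fits
    Michaelis-Menten dose-response curves for K_Fit and k*_off,max; assembles
    5'/3'/enantio/mismatch heat-map landscapes and forward/reverse linear
    maps; estimates nearest-neighbor duplex and self-structure free energies;
    and simulates complete slide datasets with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
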