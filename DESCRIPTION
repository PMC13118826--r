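Package: asdtools
Title: Pre-Formulation Screening and Performance Analysis for Amorphous
    Solid Dispersions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational chain for amorphous solid dispersion (glassy
    solution) formulation development of poorly soluble drugs: Hansen
    solubility parameter and Flory-Huggins miscibility screening of
    drug-polymer pairs, Gordon-Taylor glass-transition prediction with the
    Simha-Boyer rule, powder flow (Carr's index, USP <1174> classes) and
    tablet quality checks, dissolution-profile similarity (f2) with
    regulatory decision logic and release-kinetics model selection
    (zero-order, first-order, Higuchi, Hixson-Crowell), and
    non-compartmental pharmacokinetics with relative bioavailability and
    one-way ANOVA. Includes a seeded synthetic-data generator (kinetic
    release curves, one-compartment oral-absorption plasma profiles) so the
    full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
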