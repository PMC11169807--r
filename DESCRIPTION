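Package: mabctools
Title: Marker-Assisted Backcrossing Simulation, HRM Marker Design and
    Genetic Background Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing marker-assisted backcross
    (MABC) programmes that introgress a recessive target allele -- such as
    the Brassica rapa self-compatibility allele mm of the M-locus protein
    kinase (MLPK) -- into a recurrent parent. Provides a genome map with
    physical/genetic coordinate interpolation, a meiosis simulator for
    backcross and selfed populations, genome-wide HRM (high-resolution
    melting) INDEL marker design with nearest-neighbor melting-temperature
    prediction and delta-Tm screening, KASP-style target-locus genotyping,
    recurrent-parent genome recovery (PR) and background homozygosity (HGB)
    scoring with two-step marker-assisted selection, introgression-segment
    delineation from dense genotype calls, shared-segment intersection
    across individuals, and compatibility-index (CI) phenotype
    classification, orchestrated by a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
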