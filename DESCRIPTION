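Package: surfsim
Title: Individual-Based Simulation of Gene Surfing at Range-Expansion Fronts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of a haploid population
    with one neutral diallelic locus expanding over a rectangular lattice of
    demes, under phenotype-limited (PhLRE), boundary-limited (BLRE) and
    stationary-habitat scenarios. Each generation applies Poisson reproduction,
    stepping-stone migration to orthogonally adjacent demes, and random culling
    to the carrying capacity. Columns are snapshotted as "frozen records" when
    they first fill to carrying capacity, and a spatial-genetics layer computes
    per-column summaries of the front: homogeneous-domain and cline
    segmentation, the amplitude-weighted mean frequency of the allele-frequency
    power spectrum, and within-, between- and corrected between-population
    average pairwise differences. A sweep runner replicates parameter grids,
    averages statistics across replicates, and ships presets for the standard
    experiment designs; a thin command-line interface wraps the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
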