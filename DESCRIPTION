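Package: loxtraj
Title: Geometric, Stereochemical and Energetic Analysis of
    Lipoxygenase-Fatty Acid Simulation Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of lipoxygenase-polyunsaturated fatty
    acid complexes, aimed at the docosahexaenoic acid (DHA) hydroperoxidation
    pathway.  Reads multi-model PDB trajectories and semantic atom-selection
    configs; computes per-frame geometric descriptors (distances, plane
    angles, dihedrals, Kabsch RMSD, domain centre separation and
    gyration-tensor principal-axis angles), hydrogen-bond and pi-stacking
    contact series, stereochemical labels from coordinates (Z/E per double
    bond, two-letter pentadienyl labels, pro-R/pro-S methylene hydrogens,
    R/S at a tetrahedral centre, antarafacial/suprafacial oxygen-addition
    faces), precatalytic-structure statistics and reaction-coordinate
    descriptors for each mechanistic step, and Boltzmann-exponential
    averages and stationary-point energy ladders from per-snapshot barrier
    tables.  A synthetic-structure generator with recorded ground truth
    makes every stage testable without molecular-dynamics or QM/MM software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
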