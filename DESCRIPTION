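Package: h33dyn
Title: Temporal Analysis of Histone Variant H3.3 Deposition During
    Cell-Fate Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the deposition dynamics of the histone
    variant H3.3 along a bifurcating reprogramming time course.  Provides
    strand-aware assignment of ChIP peaks to promoter, genebody and
    intergenic categories; library normalisation, FPKM and fold-over-input
    enrichment calling; binned average-enrichment profiles and gene-set
    trajectories; route-dependent expression clustering (Cluster I-IV);
    "D-onwards" onset classification of presence trajectories, route
    exclusivity and deposition-versus-expression precedence; discovery of
    top-loss genes, functional targets, route-exclusive activators and
    hypergeometric marker-set enrichment; and a deterministic synthetic
    branching time-course generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
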