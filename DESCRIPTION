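Package: biphasix
Title: Ecology of a Two-Member Microbiota Across a Biphasic Host-Environment Life Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying a two-species bacterial community that
    alternates between a host-associated phase (the Caenorhabditis elegans
    gut) and a free-living environmental phase (growth on agar plates).
    Provides tidy readers and writers for replicate-level colony-forming-unit
    (CFU) assay tables and genome-trait tables, estimation of habitat-specific
    relative fitness and carrying capacities from co-culture CFU data, a
    discrete biphasic life-cycle simulator (deterministic replicator dynamics
    and a stochastic serial-transfer bottleneck mode), genome-trait-based
    Grime C-S-R life-history classification, exact small-sample nonparametric
    tests with false-discovery-rate correction, and a synthetic-data
    generator that emulates the assay designs so every stage can be tested
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
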