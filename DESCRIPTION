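Package: kintags
Title: Genetic Kin Recognition Tag Dynamics Under Host-Parasite Coevolution
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic multilocus population-genetic simulator of genetic
    kin recognition (tag-based kin discrimination) in a haploid, viscous
    population whose parasite-resistance alleles are under lagged negative
    frequency-dependent selection imposed by coevolving parasites (Red Queen
    dynamics). Four freely recombining loci are tracked: a parasite-resistance
    tag locus, an otherwise-neutral tag locus, a recognition-locus selector
    (Choice), and a help/defect behaviour locus (Trait). The package iterates
    exact genotype-frequency recursions to a fixed point or limit cycle,
    computes observables (scaled tag diversity, tag-trait linkage
    disequilibrium, relatedness of tag-matched partners, parasite
    susceptibility), offers figure-style parameter-sweep presets, and
    validates the mean-field recursion against a finite-population
    agent-based Monte-Carlo oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
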