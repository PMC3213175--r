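Package: denovoscreen
Title: Screening for De Novo Originated Protein-Coding Genes in Primate Trio Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A conservative screen for protein-coding genes that originated de
    novo on the human lineage, working from gapped human/chimpanzee/orangutan
    alignments of candidate coding regions. Assesses open-reading-frame
    disruption in the outgroups (premature stops, frameshift indels, missing
    starts, alternative-start rescue, an 80 percent intact-protein rule),
    polarizes human-specific ORF-enabling mutations by counterfactual
    reversion against the shared outgroup state, computes RNA-seq style
    unique-read expression statistics over coding regions with library-size
    normalization, and estimates lineage-specific substitution rates under the
    HKY85 model on the three-taxon tree. Ships a synthetic-data module that
    generates labeled trio scenarios, HKY85-evolved alignments with known
    branch lengths, and Poisson read counts, so every stage is testable
    against planted ground truth.
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
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ape,
    withr
Config/testthat/edition: 3
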