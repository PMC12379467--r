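Package: pepSIP
Title: Protein Stable Isotope Probing with De Novo Peptide Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for protein stable isotope probing (protein-SIP) built
    around sample-matching peptide databases assembled from de novo
    sequencing output. Provides isotopologue envelope computation at
    arbitrary label abundance, per-peptide relative isotope abundance (RIA)
    and labeling-ratio estimation, target-decoy false discovery rate
    control with entrapment-based false discovery proportion estimation,
    peptide-centric lowest common ancestor taxonomy with GO-slim
    functional rollup, taxonomy drop-off auditing for hidden labeled
    populations, and a seeded simulator of mock labeled communities for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
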