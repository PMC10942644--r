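Package: ftmicro
Title: Control-Informed Analysis of Low-Biomass Fallopian Tube Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing low-biomass 16S rRNA gene amplicon surveys of
    the fallopian tube and other surgical sites. Implements a staged,
    control-informed contamination filter over species-by-sample read count
    tables with a full per-taxon provenance ledger, bacterial-load comparisons
    from qPCR 16S copy concentrations, Shannon diversity and principal
    component ordination of the filtered community, and per-individual
    prevalence comparisons between ovarian cancer and non-cancer patients,
    including niche composition of the top-ranked species and surgery-type
    sensitivity analyses. A synthetic cohort generator with planted ground
    truth (true fallopian-tube taxa, reagent and air contaminants, a
    cancer-associated prevalence shift) makes every stage testable without
    access to raw sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
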