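Package: replicoex
Title: Resource Competition and Coexistence of Template Replicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the dynamical coexistence of competing template
    replicators (RNA-like polynucleotide sequences) feeding on shared
    monomer pools. Explicit sequences, pairing schemes (complementary or
    homologous pairing with antiparallel or parallel strand polarity) and
    kinetic rate constants are compiled into mass-action ordinary
    differential equation systems over all replication intermediates;
    systems are integrated to steady state with a stiff solver, outcomes
    are classified as coexistence or competitive exclusion, and local
    stability is assessed from the leading eigenvalue of the analytic
    Jacobian. For homologous pairing with two monomer types and uniform
    degradation a closed-form coexistence criterion based on
    weighted-composition statistics is provided, together with the
    head-block rule for irregular coexistence and survey protocols that
    estimate coexistence fractions over combined sequence spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    seqinr,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
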