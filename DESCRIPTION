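Package: mirlink
Title: Integration of miRNA and mRNA Differential Expression into
    Anti-Correlated Regulatory Pairs
Version: 0.1.0
Authors@R:
    person("Mir", "Link", email = "mirlink@example.org", role = c("aut", "cre"))
Description: Statistical integration of miRNA and mRNA differential
    expression evidence into anti-correlated miRNA-target calls. For
    paired designs (miRNA and mRNA profiled on the same samples) it
    tests one-sided anti-correlation per candidate pair with simple or
    partial Pearson/Spearman correlation; for unpaired designs it tests
    per-miRNA directional association of targets with anti-directional
    differentially expressed genes using one-sided Fisher, Lancaster
    mid-P, or Boschloo unconditional exact tests, plus rotation and
    CAMERA-style competitive gene-set comparators. Includes
    Benjamini-Hochberg and Storey q-value multiplicity control,
    hypergeometric over-representation analysis, a paired two-group
    miRNA-mRNA simulator with known anti-correlated regulatory pairs
    and group-level confounding, and a simulation benchmark reporting
    F1, precision-recall curves, AUPRC and empirical FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
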