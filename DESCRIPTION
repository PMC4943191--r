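Package: islemol
Title: Paired Island-Mainland Molecular Evolution Statistics
Version: 0.1.0
Authors@R:
    person("Island-Mainland", "Maintainers", email = "maintainers@islemol.org",
           role = c("aut", "cre"))
Description: Codon-aware polymorphism and divergence statistics for paired
    island-mainland species comparisons. Computes synonymous and
    non-synonymous nucleotide diversity (Nei-Gojobori site counting and
    pathway averaging), lineage-specific dN, dS and omega by outgroup
    parsimony with Jukes-Cantor correction, selection-efficiency and
    adaptive-evolution statistics (pi_N/(pi_N+pi_S), direction of selection,
    pi_S/d_S effective-population-size proxies, gamma-DFE omega-to-Ne
    conversion), and paired inference on relative island values (exact
    Wilcoxon signed-rank tests, percentile bootstrap confidence intervals,
    correlations). Includes a coalescent island-colonization sequence
    generator with founder bottlenecks for end-to-end validation with known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
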