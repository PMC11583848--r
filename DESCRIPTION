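Package: ptmd
Title: Selective Ribosome Profiling Analysis of P-Site tRNA-Mediated mRNA Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing co-translational recruitment of the CCR4-NOT
    deadenylase complex from selective ribosome profiling data and for linking
    ribosome P-site codon identity to mRNA turnover. Implements footprint
    length filtering and P-site offset assignment with triplet-periodicity QC,
    Fisher's exact enrichment testing of immunoprecipitated footprint species
    with percentage-ratio codon/amino-acid/tripeptide enrichment at the E-, P-
    and A-sites, weighted arginine-codon mRNA scores, first-order half-life
    fitting for metabolic-labeling and reporter time courses with
    score-stratified one-sided Wilcoxon comparisons, A-site dwell-time
    estimation with P-site-conditioned correlation analysis, and a tRNA D-arm
    feature classifier (13:22:46 base triplet, D-loop alpha-element length)
    for P-site tRNA-mediated decay propensity. A synthetic-data module
    generates transcriptomes, two-library footprint sets, decay time courses
    and tRNA sets with known ground truth so the whole pipeline is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
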