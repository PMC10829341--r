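Package: viroecol
Title: Virome Ecology of Depth-Stratified Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the ecological analysis of viral communities
    recovered from stratified aquatic metagenomes. Builds a viral OTU
    (vOTU) catalogue by greedy nucleotide-identity clustering with
    lifestyle (temperate/lytic) and novelty classification; normalises
    per-contig read counts to transcripts-per-million (TPM) and computes
    viral fractions, Shannon diversity, Bray-Curtis community distances,
    permutational multivariate ANOVA with Benjamini-Hochberg adjustment,
    depth-diversity regression and depth-cluster Venn membership; links
    phages to prokaryotic hosts by CRISPR-spacer matching, identical tRNA
    sharing and prophage genomic context with a consensus phylum call;
    clusters viral auxiliary metabolic gene (AMG) proteins into
    orthologous groups by Markov clustering, screens their abundances
    against water chemistry, and tests pairwise AMG co-occurrence with an
    exact hypergeometric null. A seeded synthetic community generator
    with planted host links, orthologous families and chemistry
    correlations makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    vegan,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
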