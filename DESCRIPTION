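Package: dupepi
Title: Genomic Epidemiology of EPSPS Duplication Genotypes and SSR Population
    Structure in Kochia
Version: 0.1.0
Authors@R:
    person("dupepi", "developers", email = "dupepi@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic-based epidemiology of glyphosate resistance in
    kochia (Bassia scoparia). Quantifies relative gene copy number from qPCR
    Ct values by the delta-Ct method for an EPSPS-duplication marker panel
    (EPSPS, type I and type II repeat junctions, and a Fhy3/FAR1-like mobile
    genetic element), classifies individuals into duplication genotypes
    (A/B/C/S) by rule-based thresholds, and analyses pentanucleotide SSR
    genotypes: fragment-size allele binning, missing-data filtering,
    Hardy-Weinberg and linkage exact tests with Fisher's combined probability,
    rarefied allelic richness and bootstrap F_IS, neighbour-joining trees on
    Prevosti distance with locus bootstrap, PCA of allele counts, and a
    simplified admixture-model Gibbs sampler with run alignment and Evanno
    delta-K model choice. Includes a synthetic-data generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
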