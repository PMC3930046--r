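Package: octopop
Title: Octoploid-Aware SNP Discovery and Population Assignment for Sturgeons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering single-nucleotide polymorphisms in
    octoploid fishes from transcriptome allele read counts, discriminating
    true SNPs from paralogous sequence variants under a two-tetrasomic-loci
    dosage model (the 3:1 allelic-ratio filter), quality-controlling
    biallelic genotype panels, computing Latter's FST genetic distances and
    Weir-Cockerham theta, building UPGMA population trees with locus
    bootstrap, and selecting minimal informative SNP panels by
    resampling-based locus ranking with leave-one-out population
    assignment.  Includes readers and writers for allele-count tables,
    genotype matrices, the GenePop dialect, bracketed-marker tables and
    Newick, plus a synthetic-data generator emulating Ponto-Caspian
    sturgeon populations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
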