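Package: mapkstress
Title: Stress Transcriptomics of MAPK Deletion Mutants in Beauveria bassiana
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-course stress transcriptomics of
    mitogen-activated protein kinase (MAPK) deletion mutants in the
    entomopathogenic fungus Beauveria bassiana. Implements zero-count
    filtering, FPKM, log2 + quantile normalization, TMM scale factors and the
    log-centered log-ratio (logCLR) transform; a fold-change-threshold
    classifier of mutant stress responsiveness (wild-type responsive, mutant
    silent) with DEG set algebra; weighted co-expression module detection
    (soft threshold, topological overlap, static tree cut, eigengenes,
    module-trait correlation) and k-means co-expression compendia;
    hypergeometric over-representation testing against GMT annotation maps;
    and phenotype statistics (relative growth inhibition from colony
    diameters, extracellular acidification rate from plate-reader series).
    A negative-binomial simulator emulates the 18-library pooled
    strain x stress x time design with planted responsive genes and
    co-expression blocks for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, withr, fgsea
Suggests: testthat (>= 3.0.0), edgeR, limma, mclust, jsonlite
Config/testthat/edition: 3
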