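Package: rallyscan
Title: Selection Mapping by Regression of Alleles on Years (RALLY)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps quantitative selection loci (QSLs) in historical crop
    variety panels by regressing marker allele counts on year of variety
    release with a per-marker binomial logistic model (RALLY), and corrects
    the resulting test statistics for drift and population structure with a
    parametric control that estimates the null mean and scale of the Z
    statistics by folded-normal composite likelihood. Includes a forward
    simulator of a recurrent-selection breeding program producing selected
    and unselected variety panels with known QTL truth, a mixed-model GWAS
    baseline, a deterministic marker-QTL hitch-hiking recursion with power
    estimation, LD-based grouping of significant markers into QSLs, local
    heritability partitioning with multiple genomic relationship matrices,
    ridge and LASSO marker-effect direction analysis, and multivariate
    breeder's-equation selection parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
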