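Package: hirrm
Title: Hierarchical Non-Linear Mixed-Model GWAS of Growth Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis of longitudinal growth traits
    with a two-hierarchy random regression model. The first hierarchy fits
    each individual's trajectory with a biologically meaningful growth curve
    (Richards, Bertalanffy, Gompertz, Logistic) or Legendre polynomials by
    (non-linear) least squares; the second hierarchy treats the fitted curve
    parameters as correlated quantitative traits and maps QTLs with a
    multivariate genomic mixed model. Restricted maximum likelihood
    estimation of genetic and permanent-environmental covariance matrices, a
    canonical transformation decomposing the multivariate model into
    independent univariate models, EMMAX-style whitened marker tests with a
    summed pleiotropy chi-square statistic, genomic control, and a
    simulation framework for power and ROC evaluation are included, together
    with PLINK bed/bim/fam input and output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
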