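Package: kcsnet
Title: Keystone Candidate Scoring on Microbiome-Metabolome Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A longitudinal microbiome-metabolome association analysis pipeline
    for paired 16S genus tables and targeted metabolomics panels. Implements the
    preprocessing contracts (missingness filtering, median imputation and
    scaling, panel normalization, variance-stabilizing transforms), ordination
    and omnibus statistics (Bray-Curtis, PCoA, marginal PERMANOVA with
    restricted permutations, mixed-effects differential metabolite models),
    subject-effect residualization with all-against-all Spearman association
    testing under per-family false discovery rate control, eigenvector-based
    A/B feature labeling, typed association networks with centrality analysis
    and MCODE cluster detection, discrete power-law degree-distribution
    diagnostics (maximum-likelihood fit, Kolmogorov-Smirnov bootstrap, Vuong
    model comparisons), and a composite Keystone Candidate Score that ranks
    candidate keystone genera. A synthetic-data generator with planted ground
    truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    permute,
    igraph,
    ape,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
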