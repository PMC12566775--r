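Package: callusmap
Title: Genetic Mapping of Maize Callus Type from GBS Segment Markers and
    Bulked Segregant RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting a binary tissue-culture phenotype (Type I
    versus Type II callus) in a maize B73xA188 F2 population. Converts noisy
    genotyping-by-sequencing SNP calls into chromosomal segment (bin) markers,
    maps the phenotype with a per-marker logistic-regression scan (FDR and
    permutation thresholds) and with EM-based binary-model interval mapping
    (LOD thresholds, support intervals, variance explained), tests pooled-bulk
    allele read counts with a binomial generalized linear model under a
    Bonferroni genome-wide cutoff, genotypes inbred derivatives at QTL peaks,
    and intersects QTL support intervals with differentially expressed gene
    lists to nominate candidate genes. A synthetic-data generator simulates F2
    meiosis without crossover interference, an additive liability model for
    the binary phenotype, GBS-like genotype degradation, and binomial bulk
    read counts, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
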