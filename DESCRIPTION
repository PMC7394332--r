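Package: methylink
Title: Integrated Methylation-Expression Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Large-scale integrated analysis linking CpG methylation to gene
    expression. For every gene, samples are ranked by expression and split
    into Up/Medium/Down tertiles; signed fold changes and Welch t-tests
    contrast the expression groups, and Illumina 450k-style probe annotation
    is expanded into one-to-one probe-gene-region records. Per-probe and
    grouped (gene region, CpG-island relation, whole gene) methylation
    statistics are computed: tertile medians and means, beta-differences,
    two-sample Kolmogorov-Smirnov tests, and Pearson correlation with
    expression. Includes a six-filter post-processing cascade with
    correlation-direction summaries and top-k hotspot selection, a
    deterministic synthetic data generator with planted regulatory
    structure, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
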