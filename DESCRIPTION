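Package: msiagree
Title: Agreement Analysis for Imaging Mass Spectrometry Molecular Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for imaging mass spectrometry (MSI) based molecular
    histology. Reduces MALDI imaging MS datasets to pixel-by-feature
    matrices via multi-representation peak picking with ppm-tolerance
    peak-list collation, decomposes the reduced data with five
    unsupervised multivariate methods (PCA, non-negative matrix
    factorization, maximum autocorrelation factorization, fuzzy c-means
    and probabilistic latent semantic analysis, with k-means as an
    exploratory sixth), and computes agreement plots: integer consensus
    images that count how many methods independently mark each tissue
    pixel as belonging to a spectrally distinct region. Includes a
    synthetic phantom generator with ground truth, target-image
    validation machinery, minimal imzML input/output, and dataload/FLOP
    resource accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    data.table,
    jsonlite,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
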