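Package: alkylotroph
Title: Detection of Methanogenic Hydrocarbon Degradation in Oil-Reservoir Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based scoring of crude-oil biodegradation (degrees 0-4) from
    GC-MS total ion chromatograms, formula-driven MRM screening of the
    alkyl-coenzyme M homolog series (C4-C28), qPCR standard-curve absolute
    quantification and amplicon/metatranscriptomic normalization for
    Candidatus Methanoliparum, co-occurrence evidence classification, and a
    transformed ridge regression linking gene expression to degradation
    degree. Includes a synthetic-data generator that emulates the statistical
    structure of oil-reservoir survey data so the whole pipeline is testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
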