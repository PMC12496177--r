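Package: hlaimpute
Title: HLA Genotype Imputation with an Encrypted-Domain-Faithful Inference Path
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes classical HLA alleles from flanking SNP genotypes using
    one logistic regression per allele trained on a phased reference panel in
    the SNP2HLA/Beagle dialect. Inference runs in two interchangeable modes: a
    plaintext pipeline (linear scores, top-2 selection, sigmoid, homozygosity
    thresholding) and a bit-faithful plaintext emulation of the integer
    arithmetic a torus-FHE server would perform (fixed-point scale encoding,
    chunked linear accumulation, normalization, cmpbit/mux comparison circuits,
    look-up-table sigmoid, division-by-t thresholding), so the encrypted
    evaluation path can be validated against the plaintext oracle. Includes
    pair-accuracy evaluation with P-group mapping and MAF-binned reporting,
    and a synthetic panel simulator with tag-SNP linkage for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    glmnet
Config/testthat/edition: 3
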