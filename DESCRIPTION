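Package: curiocat
Title: Curiosity-Driven Category Learning in an Infant Autoencoder Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Neurocomputational simulation of infant category learning with a
    4-3-4 sigmoid autoencoder trained by the generalized delta rule.
    Implements familiarization/novelty-preference experiments with externally
    imposed presentation orders (maximum, minimum, medium and random mean
    successive Euclidean distance) and with four intrinsically motivated
    stimulus-selection policies (curiosity, objective complexity, subjective
    novelty, plasticity), together with the sequence-complexity analytics used
    to characterize what a curious learner chooses: exhaustive permutation
    ranking by mean successive Euclidean distance, per-step distance ranks,
    block habituation contrasts and rank-based tests of the peripheral-SSE
    categorization index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
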