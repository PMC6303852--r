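Package: sectionseer
Title: Shallow Neural Bag-of-N-Grams Classification of Rhetorical Sentence
    Roles in Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns rhetorical section labels (objective, background,
    methods, results, conclusions) to the sentences of structured biomedical
    abstracts with a fast, shallow linear-embedding classifier over bags of
    word n-grams. Sentence order is exploited through a token-augmentation
    preprocessor that injects a numeric sentence-position token and
    prefix-tagged tokens from neighbouring sentences into each sentence's
    bag. N-gram vectors can be pre-trained without labels by negative
    sampling, in fixed-window (CBOW-style) or whole-sentence (sent2vec-style)
    context modes, and transferred into the supervised classifier for
    low-label regimes. Includes readers and writers for the PubMed-RCT
    plain-text corpus dialect, a structured-abstract corpus simulator,
    support-weighted F1 evaluation, hyperparameter grid search, and a
    semi-supervised learning-curve harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
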