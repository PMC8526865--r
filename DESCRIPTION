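Package: lwltools
Title: Looking-While-Listening Infant Gaze Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for looking-while-listening (LWL) studies of
    infant noun comprehension: classification of 60 Hz eye-tracking samples
    into areas of interest, trial- and infant-level exclusion rules,
    proportion-index statistics over yoked stimulus pairs, exact Wilcoxon
    signed-rank and Kruskal-Wallis inference, default-prior Bayes factors
    (Jeffreys-Zellner-Siow t test and stretched-beta correlation),
    cluster-based permutation tests on the gaze time course, and
    word-frequency-imbalance measures from parental questionnaires and
    CHAT-format transcripts. A synthetic gaze generator with known ground
    truth makes every stage verifiable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
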