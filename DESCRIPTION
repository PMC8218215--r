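Package: nicotopics
Title: Rule-Based Topic Surveillance of Nicotine-Related Social Media Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An infoveillance pipeline for keyword-matched Twitter corpora
    about nicotine. Implements an auditable filtering cascade (keyword check,
    retweet removal, language filter, song-lyric phrase exclusion, deleted
    account drop), partitioning of posts into social-bot and nonbot cohorts by
    an account-level bot score threshold, a six-step text normalization
    (URL removal, mention collapsing to a common token, hashtag removal,
    lower-casing and punctuation stripping, nonprintable character removal,
    stop-word removal with dictionary lemmatization), unigram and bigram
    frequency analysis, rule-based multi-label classification into 15
    nicotine-related topics, and per-cohort prevalence, coverage, and topic
    co-occurrence reporting. A synthetic corpus generator with known ground
    truth (topic labels, bot status, retweet, language, and lyric
    contamination) makes every stage testable without any platform access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
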