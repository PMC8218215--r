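# shared fixtures and independent oracles

# normalization resources loaded once per test run
STOPWORDS <- default_stopwords()
LEMMAS <- default_lemmatizer()
LEXICON <- default_lexicon(STOPWORDS, LEMMAS)

make_tweet <- function(tweet_id, text, author_id = paste0("a_", tweet_id),
                       lang = "en", is_retweet = FALSE,
                       created_at = "2019-01-15T12:00:00Z") {
  tibble::tibble(
    tweet_id = tweet_id, text = text, author_id = author_id,
    lang = lang, is_retweet = is_retweet, created_at = created_at
  )
}

make_corpus <- function(texts, ...) {
  dplyr::bind_rows(lapply(seq_along(texts), function(i) {
    make_tweet(sprintf("t%03d", i), texts[i], ...)
  }))
}

# brute-force pattern matcher, independent of the package implementation:
# enumerates all index combinations for subsequence matching instead of
# scanning, and checks adjacency / membership by explicit loops
brute_match <- function(tokens, pattern) {
  k <- length(tokens)
  pt <- pattern$tokens
  if (k == 0) {
    return(FALSE)
  }
  if (pattern$kind == "unigram") {
    for (tok in tokens) if (tok == pt[1]) return(TRUE)
    return(FALSE)
  }
  if (pattern$kind == "bigram") {
    if (k < 2) return(FALSE)
    for (i in seq_len(k - 1)) {
      if (tokens[i] == pt[1] && tokens[i + 1] == pt[2]) return(TRUE)
    }
    return(FALSE)
  }
  # ordered_group: any strictly increasing index tuple equal to the pattern
  m <- length(pt)
  if (k < m) return(FALSE)
  idx <- utils::combn(k, m)
  for (j in seq_len(ncol(idx))) {
    if (all(tokens[idx[, j]] == pt)) return(TRUE)
  }
  FALSE
}

brute_classify <- function(tokens, lexicon) {
  hits <- vapply(lexicon, function(patterns) {
    any(vapply(patterns, function(p) brute_match(tokens, p), logical(1)))
  }, logical(1))
  names(lexicon)[hits]
}

# random pattern / lexicon / token generators over a small alphabet
rand_pattern <- function(alphabet) {
  kind <- sample(c("unigram", "bigram", "ordered_group"), 1)
  n <- switch(kind, unigram = 1, bigram = 2,
              ordered_group = sample(2:3, 1))
  topic_pattern(kind, sample(alphabet, n, replace = TRUE))
}

rand_lexicon <- function(alphabet, n_topics = 4) {
  topics <- lapply(seq_len(n_topics), function(i) {
    lapply(seq_len(sample(1:3, 1)), function(j) rand_pattern(alphabet))
  })
  names(topics) <- paste0("topic", seq_len(n_topics))
  nicotopics:::new_topic_lexicon(topics)
}
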