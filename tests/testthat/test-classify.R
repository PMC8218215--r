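test_that("pattern kinds implement membership, adjacency, and ordered subsequence", {
  toks <- c("@person", "look", "nicotine", "free", "today")
  expect_true(match_pattern(toks, topic_pattern("bigram", c("nicotine", "free"))))
  expect_false(match_pattern(toks, topic_pattern("bigram", c("free", "nicotine"))))
  expect_true(match_pattern(toks, topic_pattern("unigram", "@person")))

  toks2 <- c("quit", "want", "smoking")
  expect_true(match_pattern(toks2, topic_pattern("ordered_group", c("quit", "smoking"))))
  expect_false(match_pattern(toks2, topic_pattern("ordered_group", c("smoking", "quit"))))

  expect_false(match_pattern(character(),
                             topic_pattern("unigram", "nicotine")))
})

test_that("bigrams require adjacency even when tokens occur apart", {
  toks <- c("nicotine", "almost", "free")
  expect_false(match_pattern(toks, topic_pattern("bigram", c("nicotine", "free"))))
  expect_true(match_pattern(toks, topic_pattern("ordered_group", c("nicotine", "free"))))
})

test_that("pattern construction enforces token arity", {
  expect_error(topic_pattern("unigram", c("a", "b")), "unigram")
  expect_error(topic_pattern("bigram", "a"), "bigram")
  expect_error(topic_pattern("ordered_group", "a"), "ordered_group")
  expect_error(topic_pattern("trigram", c("a", "b", "c")))
})

test_that("the shipped lexicon has the 15 expected topics", {
  expect_length(LEXICON, 15)
  expect_setequal(names(LEXICON), c(
    "person tagging", "addiction", "appeal", "NRT", "vaping", "smoking",
    "nicotine health risks", "withdrawal", "quit nicotine", "cessation",
    "polysubstance use", "caffeine", "underage use", "new products",
    "nicotine is safe"
  ))
})

test_that("classification is multi-label over matching topics", {
  nt <- normalize_tweet("Hey @person look who is nicotine free today",
                        STOPWORDS, LEMMAS)
  expect_setequal(classify_tweet(nt$tokens, LEXICON),
                  c("person tagging", "quit nicotine"))

  nt2 <- normalize_tweet("@friend my JUUL has me addicted", STOPWORDS, LEMMAS)
  expect_setequal(
    classify_tweet(nt2$tokens, LEXICON),
    c("person tagging", "vaping", "addiction")
  )
  expect_equal(classify_tweet(c("morning", "walk"), LEXICON), character())
})

test_that("classifier agrees with the brute-force subsequence oracle", {
  set.seed(99)
  alphabet <- c(letters[1:6], "@person")
  for (rep in 1:40) {
    lex <- rand_lexicon(alphabet)
    toks <- sample(alphabet, sample(0:8, 1), replace = TRUE)
    expect_equal(classify_tweet(toks, lex), brute_classify(toks, lex),
                 info = paste("tokens:", paste(toks, collapse = " ")))
  }
})

test_that("classification is monotone in patterns and in tokens", {
  set.seed(7)
  alphabet <- letters[1:6]
  for (rep in 1:15) {
    lex <- rand_lexicon(alphabet, n_topics = 3)
    toks <- sample(alphabet, sample(1:6, 1), replace = TRUE)
    base <- classify_tweet(toks, lex)

    # adding a pattern to a topic never removes that topic
    lex2 <- unclass(lex)
    lex2[["topic1"]] <- c(lex2[["topic1"]], list(rand_pattern(alphabet)))
    lex2 <- nicotopics:::new_topic_lexicon(lex2)
    expect_true(all(base %in% classify_tweet(toks, lex2)))

    # appending tokens never removes a topic
    more <- c(toks, sample(alphabet, 2, replace = TRUE))
    expect_true(all(base %in% classify_tweet(more, lex)))
  }
})

test_that("corpus classification composes per-tweet results and round-trips", {
  corpus <- make_corpus(c(
    "craving nicotine so bad",
    "quit #nicotine cold turkey",
    "morning walk"
  ))
  norm <- normalize_corpus(corpus, STOPWORDS, LEMMAS)
  asg <- classify_corpus(norm, LEXICON)
  expect_equal(asg$tweet_id, corpus$tweet_id)
  for (i in seq_len(nrow(asg))) {
    expect_equal(asg$topics[[i]], classify_tweet(norm$tokens[[i]], LEXICON))
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_assignment(asg, path)
  expect_equal(read_assignment(path), asg)

  empty <- classify_corpus(norm[0, ], LEXICON)
  expect_equal(nrow(empty), 0)
})
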