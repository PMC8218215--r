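test_that("configs are validated", {
  expect_error(synth_config(bot_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(topic_mixture = c(smoking = 0.5)), "background")
  expect_error(
    synth_config(topic_mixture = c(smoking = 0.5, background = 0.6)),
    "sum to 1"
  )
  expect_error(synth_config(n_tweets = -1), "non-negative")
  mix <- default_topic_mixture()
  expect_equal(sum(mix), 1)
  expect_length(mix, 16) # 15 topics + background
})

test_that("n_tweets = 0 yields empty corpus and truth", {
  out <- generate_corpus(synth_config(n_tweets = 0), lexicon = LEXICON)
  expect_equal(nrow(out$tweets), 0)
  expect_equal(nrow(out$scores), 0)
  expect_equal(nrow(out$truth$tweets), 0)
})

test_that("the same seed reproduces the corpus exactly", {
  cfg <- synth_config(n_tweets = 200, seed = 17)
  a <- generate_corpus(cfg, lexicon = LEXICON)
  b <- generate_corpus(cfg, lexicon = LEXICON)
  expect_identical(a, b)
  c2 <- generate_corpus(synth_config(n_tweets = 200, seed = 18),
                        lexicon = LEXICON)
  expect_false(identical(a$tweets$text, c2$tweets$text))
})

test_that("every generated text contains the keyword and ids are unique", {
  out <- generate_corpus(synth_config(n_tweets = 300, seed = 2),
                         lexicon = LEXICON)
  expect_true(all(grepl("nicotine", tolower(out$tweets$text), fixed = TRUE)))
  expect_equal(anyDuplicated(out$tweets$tweet_id), 0)
  expect_equal(anyDuplicated(out$truth$tweets$tweet_id), 0)
})

test_that("bot scores respect the threshold gate by construction", {
  out <- generate_corpus(synth_config(n_tweets = 600, seed = 21),
                         lexicon = LEXICON)
  joined <- dplyr::left_join(out$truth$accounts, out$scores, by = "author_id")
  expect_true(all(is.na(joined$score[joined$status == "deleted"])))
  expect_true(all(joined$score[joined$status == "bot"] >= 4))
  expect_true(all(joined$score[joined$status == "nonbot"] < 4))
})

test_that("boundary score mass places bots exactly at the threshold", {
  out <- generate_corpus(
    synth_config(n_tweets = 500, seed = 8, boundary_score_mass = 1,
                 bot_fraction = 0.5, deleted_account_fraction = 0),
    lexicon = LEXICON
  )
  bots <- out$truth$accounts$author_id[out$truth$accounts$status == "bot"]
  sc <- out$scores$score[out$scores$author_id %in% bots]
  expect_true(all(sc == 4.0))
  part <- partition_by_bot_score(out$tweets, out$scores, threshold = 4)
  expect_setequal(part$bot$author_id, bots)
})

test_that("embedded patterns survive normalization and match", {
  base <- "just thinking"
  uni <- topic_pattern("unigram", "craving")
  txt <- embed_pattern(base, uni)
  expect_true("crave" %in% normalize_tweet(txt, STOPWORDS, LEMMAS)$tokens ||
              "craving" %in% normalize_tweet(txt, STOPWORDS, LEMMAS)$tokens)

  bi <- topic_pattern("bigram", c("cold", "turkey"))
  toks <- normalize_tweet(embed_pattern(base, bi), STOPWORDS, LEMMAS)$tokens
  expect_true(match_pattern(toks, bi))

  og <- topic_pattern("ordered_group", c("quit", "smoke"))
  toks2 <- normalize_tweet(embed_pattern(base, og), STOPWORDS, LEMMAS)$tokens
  expect_true(match_pattern(toks2, og))
})

test_that("classifier recall on embedded ground truth is total", {
  out <- generate_corpus(synth_config(n_tweets = 400, seed = 31),
                         lexicon = LEXICON)
  norm <- normalize_corpus(out$tweets, STOPWORDS, LEMMAS)
  asg <- classify_corpus(norm, LEXICON)
  ok <- purrr::map2_lgl(out$truth$tweets$topics, asg$topics,
                        ~ all(.x %in% .y))
  expect_true(all(ok))
})

test_that("realized composition fractions sit inside exact 99% binomial bands", {
  cfg <- synth_config(n_tweets = 2000, seed = 12)
  out <- generate_corpus(cfg, lexicon = LEXICON)
  tr <- out$truth$tweets
  n <- nrow(tr)
  in_band <- function(k, p) {
    k >= qbinom(0.005, n, p) && k <= qbinom(0.995, n, p)
  }
  expect_true(in_band(sum(tr$retweet), cfg$retweet_fraction))
  expect_true(in_band(sum(tr$non_english), cfg$non_english_fraction))
  expect_true(in_band(sum(tr$lyric), cfg$lyric_fraction))
  expect_true(in_band(sum(tr$status == "deleted"),
                      cfg$deleted_account_fraction))
})

test_that("ground truth round-trips through its CSV export", {
  out <- generate_corpus(synth_config(n_tweets = 50, seed = 5),
                         lexicon = LEXICON)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(out$truth, path)
  tab <- readr::read_csv(path, col_types = readr::cols())
  expect_equal(nrow(tab), 50)
  expect_equal(tab$tweet_id, out$truth$tweets$tweet_id)
  expect_equal(tab$status, out$truth$tweets$status)
})
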