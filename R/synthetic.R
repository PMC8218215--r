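#' Synthetic corpus configuration
#'
#' Describes the composition of a generated keyword-matched corpus:
#' how many posts, which topics their texts embed and in what proportions,
#' and the contamination rates the filtering cascade must handle (retweets,
#' non-English posts, song-lyric false positives, deleted accounts, social
#' bots). Defaults mirror the composition of a year-long "nicotine"
#' keyword stream: about 65% retweets, 11% non-English posts among the
#' rest, ~2% lyric false positives, ~12% of remaining posts from accounts
#' deleted before screening, and ~6.6% of screened posts authored by
#' social bots; the default topic mixture is proportional to the topic
#' prevalences observed in such a stream with total coverage 83%.
#'
#' @param n_tweets number of posts to generate.
#' @param topic_mixture named probabilities over topic names plus a
#'   `background` mass for unclassifiable posts; must sum to 1.
#' @param bot_fraction probability a scored account is a social bot.
#' @param retweet_fraction probability a post is a retweet.
#' @param non_english_fraction probability a post carries a non-English
#'   language code.
#' @param lyric_fraction probability a post embeds one of the lyric
#'   exclusion phrases.
#' @param deleted_account_fraction probability a post's account was
#'   deleted (missing bot score).
#' @param multi_topic_rate probability a topical post carries a second,
#'   distinct topic.
#' @param hashtag_keyword_fraction probability the inclusion keyword
#'   appears only in its hashtag form (`#nicotine`).
#' @param boundary_score_mass probability a bot's score is exactly the
#'   conventional threshold 4.0 (to exercise boundary handling).
#' @param seed integer seed; identical configs generate identical corpora.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_tweets = 5000,
                         topic_mixture = default_topic_mixture(),
                         bot_fraction = 0.066,
                         retweet_fraction = 0.653,
                         non_english_fraction = 0.109,
                         lyric_fraction = 0.019,
                         deleted_account_fraction = 0.118,
                         multi_topic_rate = 0.15,
                         hashtag_keyword_fraction = 0.10,
                         boundary_score_mass = 0,
                         seed = 1L) {
  probs <- c(bot_fraction, retweet_fraction, non_english_fraction,
             lyric_fraction, deleted_account_fraction, multi_topic_rate,
             hashtag_keyword_fraction, boundary_score_mass)
  if (any(probs < 0 | probs > 1)) {
    abort("all fractions must lie in [0, 1]")
  }
  if (n_tweets < 0 || n_tweets != as.integer(n_tweets)) {
    abort("n_tweets must be a non-negative integer")
  }
  if (is.null(names(topic_mixture)) || any(!nzchar(names(topic_mixture)))) {
    abort("topic_mixture must be a named probability vector")
  }
  if (!"background" %in% names(topic_mixture)) {
    abort("topic_mixture must include a 'background' mass")
  }
  if (any(topic_mixture < 0) || abs(sum(topic_mixture) - 1) > 1e-9) {
    abort("topic_mixture (including background) must sum to 1")
  }
  structure(
    list(
      n_tweets = as.integer(n_tweets),
      topic_mixture = topic_mixture,
      bot_fraction = bot_fraction,
      retweet_fraction = retweet_fraction,
      non_english_fraction = non_english_fraction,
      lyric_fraction = lyric_fraction,
      deleted_account_fraction = deleted_account_fraction,
      multi_topic_rate = multi_topic_rate,
      hashtag_keyword_fraction = hashtag_keyword_fraction,
      boundary_score_mass = boundary_score_mass,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Default topic mixture of the generator
#'
#' Topic masses proportional to the per-topic prevalences of a year-long
#' nicotine keyword stream, scaled so topical posts make up 83% of the
#' corpus and unclassifiable background posts 17%.
#'
#' @return named probability vector over the 15 topics plus `background`.
#' @export
default_topic_mixture <- function() {
  prev <- c(
    "person tagging" = 40.27, "smoking" = 20.96, "vaping" = 20.89,
    "addiction" = 19.85, "NRT" = 12.14, "quit nicotine" = 10.23,
    "nicotine health risks" = 7.95, "underage use" = 6.89,
    "caffeine" = 5.40, "appeal" = 4.68, "new products" = 4.24,
    "cessation" = 3.43, "withdrawal" = 3.00, "polysubstance use" = 2.50,
    "nicotine is safe" = 0.50
  )
  mix <- 0.83 * prev / sum(prev)
  c(mix, background = 1 - sum(mix))
}

# filler vocabulary: not stop words, not lemma-table keys, and absent from
# every default lexicon pattern, so background posts stay unclassifiable
.filler_words <- c(
  "morning", "window", "honestly", "maybe", "random", "later", "walk",
  "weather", "update", "story", "corner", "city", "street", "music",
  "sunny", "tuesday", "lunch", "office", "playlist", "afternoon"
)

.lyric_phrases <- c("bad nicotine", "nicotine heroin",
                    "nicotine stain", "silver spoon")

.non_english_langs <- c("es", "fr", "de", "pt", "ja", "und")

#' Embed a topic pattern into a base text
#'
#' Appends the pattern's tokens, space-joined, to the base text. Because
#' pattern tokens are stored normalized (lower-case, lemmatized, stop-word
#' free) they are fixed points of the normalizer, so the returned text is
#' guaranteed to match the pattern after normalization: bigram tokens stay
#' adjacent and ordered-group tokens keep their order.
#'
#' @param base_text base text (may be empty).
#' @param pattern a [topic_pattern()].
#' @return the augmented text.
#' @export
embed_pattern <- function(base_text, pattern) {
  if (!inherits(pattern, "topic_pattern") || length(pattern$tokens) == 0) {
    abort("pattern must be a nonempty topic_pattern")
  }
  str_trim(paste(base_text, paste(pattern$tokens, collapse = " ")))
}

#' Generate a synthetic keyword-matched corpus with ground truth
#'
#' Every post's raw text contains the keyword "nicotine" (or `#nicotine`).
#' Posts assigned topics embed, for each intended topic, one randomly
#' chosen pattern from that topic's lexicon entry, so the rule-based
#' classifier recovers the intended label by construction. Contamination
#' is drawn independently per post: retweets (marked by the metadata flag,
#' an `"RT @"` text prefix, or both), non-English language codes, lyric
#' phrases, and account status. Scored bots draw scores uniformly on
#' `[4, 5]` and nonbots on `[0, 4)`, so the threshold gate at 4 is
#' unambiguous; `boundary_score_mass` can place bot scores exactly at 4.0.
#' Each post is authored by its own account.
#'
#' @param config a [synth_config()].
#' @param lexicon the topic lexicon to embed patterns from (defaults to
#'   the shipped 15-topic lexicon).
#' @return list with `tweets` (raw corpus tibble), `scores` (bot-score
#'   tibble), and `truth` (list with `tweets`: tweet-level intended
#'   topics and contamination flags; `accounts`: author_id and intended
#'   status among `bot`, `nonbot`, `deleted`).
#' @export
generate_corpus <- function(config = synth_config(),
                            lexicon = default_lexicon()) {
  if (!inherits(config, "synth_config")) {
    abort("config must come from synth_config()")
  }
  topics <- setdiff(names(config$topic_mixture), "background")
  unknown <- setdiff(topics, names(lexicon))
  if (length(unknown) > 0) {
    abort(sprintf("topic_mixture names absent from lexicon: %s",
                  paste(unknown, collapse = ", ")))
  }
  n <- config$n_tweets
  if (n == 0) {
    return(list(
      tweets = empty_corpus(),
      scores = tibble(author_id = character(), score = double()),
      truth = list(
        tweets = tibble(tweet_id = character(), author_id = character(),
                        topics = list(), status = character(),
                        retweet = logical(), non_english = logical(),
                        lyric = logical()),
        accounts = tibble(author_id = character(), status = character())
      )
    ))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  tweet_id <- sprintf("t%07d", seq_len(n))
  author_id <- sprintf("acct%07d", seq_len(n))

  # intended topics: primary draw over mixture, optional distinct second
  primary <- sample(names(config$topic_mixture), n, replace = TRUE,
                    prob = config$topic_mixture)
  wants_second <- runif(n) < config$multi_topic_rate
  topic_sets <- map(seq_len(n), function(i) {
    if (primary[i] == "background") {
      return(character())
    }
    out <- primary[i]
    others <- setdiff(topics, out)
    if (wants_second[i] && length(others) > 0) {
      w <- config$topic_mixture[others]
      if (sum(w) > 0) {
        out <- c(out, sample(others, 1, prob = w))
      }
    }
    out
  })

  is_retweet_truth <- runif(n) < config$retweet_fraction
  non_english <- runif(n) < config$non_english_fraction
  lyric <- runif(n) < config$lyric_fraction
  status <- ifelse(
    runif(n) < config$deleted_account_fraction, "deleted",
    ifelse(runif(n) < config$bot_fraction, "bot", "nonbot")
  )
  hashtag_kw <- runif(n) < config$hashtag_keyword_fraction

  texts <- vapply(seq_len(n), function(i) {
    kw <- if (hashtag_kw[i]) "#nicotine" else "nicotine"
    filler <- sample(.filler_words, sample(2:5, 1), replace = TRUE)
    txt <- paste(c(kw, filler), collapse = " ")
    for (topic in topic_sets[[i]]) {
      pats <- lexicon[[topic]]
      txt <- embed_pattern(txt, pats[[sample.int(length(pats), 1)]])
    }
    if (lyric[i]) {
      txt <- paste(txt, sample(.lyric_phrases, 1))
    }
    if (is_retweet_truth[i]) {
      # exercise both retweet markers: flag only, prefix only, or both
      mode <- sample(c("flag", "prefix", "both"), 1)
      if (mode %in% c("prefix", "both")) {
        txt <- paste0("RT @someone ", txt)
      }
      attr(txt, "rt_mode") <- mode
    }
    txt
  }, character(1))
  # retweet metadata flag: set unless this retweet is prefix-marked only
  rt_mode <- vapply(seq_len(n), function(i) {
    if (!is_retweet_truth[i]) "" else {
      if (str_starts(texts[i], fixed("RT @"))) {
        sample(c("prefix", "both"), 1)
      } else {
        "flag"
      }
    }
  }, character(1))
  is_retweet_flag <- rt_mode %in% c("flag", "both")

  lang <- ifelse(non_english,
                 sample(.non_english_langs, n, replace = TRUE), "en")

  t0 <- as.POSIXct("2018-09-30 00:00:00", tz = "UTC")
  created_at <- format(
    t0 + runif(n, 0, 366 * 86400),
    "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"
  )

  score <- rep(NA_real_, n)
  is_bot <- status == "bot"
  is_nonbot <- status == "nonbot"
  score[is_bot] <- ifelse(
    runif(sum(is_bot)) < config$boundary_score_mass,
    4.0, runif(sum(is_bot), 4, 5)
  )
  score[is_nonbot] <- runif(sum(is_nonbot), 0, 4)

  tweets <- tibble(
    tweet_id = tweet_id,
    text = texts,
    author_id = author_id,
    lang = lang,
    is_retweet = is_retweet_flag,
    created_at = created_at
  )
  scores <- tibble(author_id = author_id, score = score)
  truth <- list(
    tweets = tibble(
      tweet_id = tweet_id,
      author_id = author_id,
      topics = topic_sets,
      status = status,
      retweet = is_retweet_truth,
      non_english = non_english,
      lyric = lyric
    ),
    accounts = tibble(author_id = author_id, status = status)
  )
  list(tweets = tweets, scores = scores, truth = truth)
}

#' Write generator ground truth as CSV
#'
#' One row per generated tweet: intended topics (pipe-separated), account
#' status, and contamination flags.
#'
#' @param truth the `truth` element returned by [generate_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  tab <- truth$tweets
  readr::write_csv(
    tibble(
      tweet_id = tab$tweet_id,
      author_id = tab$author_id,
      topics = map_chr(tab$topics, paste, collapse = "|"),
      status = tab$status,
      retweet = tab$retweet,
      non_english = tab$non_english,
      lyric = tab$lyric
    ),
    path
  )
  invisible(path)
}
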