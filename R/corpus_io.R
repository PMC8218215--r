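#' Read a tweet corpus from a JSON-lines file
#'
#' One JSON object per line with fields `tweet_id`, `text`, `author_id`,
#' `lang` (two-letter code or `"und"`), `is_retweet`, and `created_at`
#' (an ISO 8601 UTC timestamp, kept as a string so round-trips are exact).
#'
#' @param path path to a JSONL file.
#' @return a tibble with one row per tweet, in file order.
#' @seealso [write_tweets()]
#' @export
read_tweets <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("tweet file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(str_trim(lines))]
  if (length(lines) == 0) {
    return(empty_corpus())
  }
  records <- map2(lines, seq_along(lines), function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) {
        abort(sprintf("malformed tweet record at line %d: %s", i, conditionMessage(e)))
      }
    )
    missing_cols <- setdiff(tweet_cols, names(rec))
    if (length(missing_cols) > 0) {
      abort(sprintf(
        "tweet record at line %d is missing field(s): %s",
        i, paste(missing_cols, collapse = ", ")
      ))
    }
    tibble(
      tweet_id = as.character(rec$tweet_id),
      text = as.character(rec$text),
      author_id = as.character(rec$author_id),
      lang = as.character(rec$lang),
      is_retweet = as.logical(rec$is_retweet),
      created_at = as.character(rec$created_at)
    )
  })
  validate_corpus(bind_rows(records))
}

#' Write a tweet corpus as JSON lines
#'
#' @param tweets a tweet corpus tibble (see [read_tweets()] for the fields).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  tweets <- validate_corpus(tweets)
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    jsonlite::toJSON(as.list(tweets[i, tweet_cols]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

empty_corpus <- function() {
  tibble(
    tweet_id = character(), text = character(), author_id = character(),
    lang = character(), is_retweet = logical(), created_at = character()
  )
}

#' Read per-account bot scores
#'
#' A two-column CSV with header `author_id,score`. Scores are on the 0-5
#' scale produced by account-level bot classifiers such as Botometer; a
#' blank score means the account could not be scored because it had been
#' deleted by the time screening ran.
#'
#' @param path path to the CSV file.
#' @return a tibble with columns `author_id` (character) and `score`
#'   (numeric, `NA` for deleted accounts).
#' @export
read_bot_scores <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("bot score file not found: '%s'", path))
  }
  scores <- readr::read_csv(
    path,
    col_types = readr::cols(author_id = readr::col_character(),
                            score = readr::col_double())
  )
  missing_cols <- setdiff(c("author_id", "score"), names(scores))
  if (length(missing_cols) > 0) {
    abort(sprintf("bot score file must have columns author_id,score (missing: %s)",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_bot_scores(scores)
}

#' Write per-account bot scores as CSV
#'
#' @param scores tibble with columns `author_id`, `score`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bot_scores <- function(scores, path) {
  scores <- validate_bot_scores(scores)
  readr::write_csv(scores, path, na = "")
  invisible(path)
}

validate_bot_scores <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("author_id", "score") %in% names(scores))) {
    abort("bot scores must be a data frame with columns author_id, score")
  }
  bad <- !is.na(scores$score) & (scores$score < 0 | scores$score > 5)
  if (any(bad)) {
    abort(sprintf(
      "bot score out of [0, 5] for account(s): %s",
      paste(head(scores$author_id[bad], 5), collapse = ", ")
    ))
  }
  if (anyDuplicated(scores$author_id)) {
    abort("duplicate author_id in bot score table")
  }
  as_tibble(scores)[, c("author_id", "score")]
}

#' Pipeline configuration
#'
#' Bundles the tunable settings of the full pipeline. Defaults reproduce the
#' study design: the keyword `"nicotine"` (its hashtag form matches by
#' substring containment), the four song-lyric exclusion phrases, an
#' inclusive bot-score threshold of 4 on the 0-5 scale, and percentages
#' reported half-up at 2 decimal places.
#'
#' @param keyword inclusion keyword matched case-insensitively in raw text.
#' @param exclusion_phrases character vector of phrases removed as lyric
#'   false positives (case-insensitive contiguous substrings of raw text).
#' @param bot_threshold accounts with score >= this value are social bots.
#' @param stopwords character vector of stop words; default ships with the
#'   package, see [default_stopwords()].
#' @param lemmatizer named character vector mapping token -> lemma; default
#'   ships with the package, see [default_lemmatizer()].
#' @param lexicon a topic lexicon, see [default_lexicon()].
#' @param drop_hashtag_tokens if `TRUE` (default) a hashtag is removed as a
#'   whole token during normalization; if `FALSE` only the `#` marker is
#'   stripped and the tag text is kept.
#' @param rounding decimal places for reported percentages.
#' @param seed integer seed recorded alongside outputs for provenance.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(keyword = "nicotine",
                            exclusion_phrases = c(
                              "bad nicotine", "nicotine heroin",
                              "nicotine stain", "silver spoon"
                            ),
                            bot_threshold = 4,
                            stopwords = default_stopwords(),
                            lemmatizer = default_lemmatizer(),
                            lexicon = default_lexicon(),
                            drop_hashtag_tokens = TRUE,
                            rounding = 2,
                            seed = 1L) {
  if (bot_threshold < 0 || bot_threshold > 5) {
    abort("bot_threshold must lie in [0, 5]")
  }
  if (rounding < 0) {
    abort("rounding must be >= 0")
  }
  if (!nzchar(keyword)) {
    abort("keyword must be nonempty")
  }
  structure(
    list(
      keyword = keyword,
      exclusion_phrases = exclusion_phrases,
      bot_threshold = bot_threshold,
      stopwords = stopwords,
      lemmatizer = lemmatizer,
      lexicon = lexicon,
      drop_hashtag_tokens = drop_hashtag_tokens,
      rounding = rounding,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  keyword:           ", x$keyword, "\n")
  cat("  exclusion phrases: ", paste(x$exclusion_phrases, collapse = "; "), "\n")
  cat("  bot threshold:     >=", x$bot_threshold, "of 5\n")
  cat("  stop words:        ", length(x$stopwords), "\n")
  cat("  lemma entries:     ", length(x$lemmatizer), "\n")
  cat("  topics:            ", length(x$lexicon), "\n")
  invisible(x)
}
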