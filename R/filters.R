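#' Filtering cascade with an auditable ledger
#'
#' The corpus is reduced in the study's order: keyword check, retweet
#' removal, language filter, lyric-phrase exclusion, deleted-account drop,
#' and finally a bot/nonbot partition by score threshold. Each stage records
#' how many posts it removed; the ledger identity
#' `input = final kept + sum(removed)` is enforced throughout.
#'
#' @name filter_stage
NULL

#' Create an empty filter ledger
#'
#' @param input_count number of posts entering the cascade.
#' @return a `filter_ledger`: a tibble with columns `stage`, `removed`,
#'   `remaining` and attribute `input_count`.
#' @export
new_filter_ledger <- function(input_count) {
  stopifnot(is.numeric(input_count), input_count >= 0)
  structure(
    tibble(stage = character(), removed = integer(), remaining = integer()),
    input_count = as.integer(input_count),
    class = c("filter_ledger", "tbl_df", "tbl", "data.frame")
  )
}

#' Append a stage to a filter ledger
#'
#' @param ledger a `filter_ledger`.
#' @param stage stage name.
#' @param removed number of posts removed at this stage (>= 0).
#' @return the updated ledger.
#' @export
ledger_add_stage <- function(ledger, stage, removed) {
  stopifnot(inherits(ledger, "filter_ledger"), removed >= 0)
  before <- if (nrow(ledger) == 0) {
    attr(ledger, "input_count")
  } else {
    ledger$remaining[nrow(ledger)]
  }
  if (removed > before) {
    abort(sprintf("stage '%s' removed %d posts but only %d remained",
                  stage, as.integer(removed), before))
  }
  out <- bind_rows(ledger, tibble(
    stage = stage,
    removed = as.integer(removed),
    remaining = as.integer(before - removed)
  ))
  attr(out, "input_count") <- attr(ledger, "input_count")
  class(out) <- class(ledger)
  out
}

#' Check the conservation identity of a ledger
#'
#' @param ledger a `filter_ledger`.
#' @return `TRUE` if `input_count == final remaining + sum(removed)`.
#' @export
ledger_conserved <- function(ledger) {
  stopifnot(inherits(ledger, "filter_ledger"))
  input <- attr(ledger, "input_count")
  if (nrow(ledger) == 0) {
    return(TRUE)
  }
  identical(
    as.integer(input),
    as.integer(ledger$remaining[nrow(ledger)] + sum(ledger$removed))
  ) && all(ledger$removed >= 0)
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("<filter_ledger> input:", attr(x, "input_count"), "posts\n")
  print(as_tibble(x))
  invisible(x)
}

# one filtered stage: returns list(kept, entry = tibble row)
stage_result <- function(tweets, keep, stage) {
  list(
    kept = tweets[keep, , drop = FALSE],
    removed = sum(!keep),
    stage = stage
  )
}

#' Keep posts containing the inclusion keyword
#'
#' Case-insensitive substring containment on the raw text, so the hashtag
#' form (`#` + keyword) is kept as well. Applied to raw text because the
#' normalizer later removes hashtags.
#'
#' @param tweets a tweet corpus tibble.
#' @param keyword nonempty inclusion keyword.
#' @return list with elements `kept` (the filtered corpus), `removed`
#'   (count), and `stage` (name).
#' @export
keyword_filter <- function(tweets, keyword = "nicotine") {
  tweets <- validate_corpus(tweets)
  if (!nzchar(keyword)) {
    abort("keyword must be nonempty")
  }
  keep <- str_detect(str_to_lower(tweets$text), fixed(str_to_lower(keyword)))
  stage_result(tweets, keep, "keyword")
}

#' Remove retweets
#'
#' A post is a retweet if its metadata flag is set or its raw text begins
#' with `"RT @"`; streamed records vary in which marker they carry, so both
#' are honored. Removing retweets lets each post be treated as an
#' independent observation.
#'
#' @inheritParams keyword_filter
#' @return list with `kept`, `removed`, `stage`.
#' @export
remove_retweets <- function(tweets) {
  tweets <- validate_corpus(tweets)
  keep <- !(tweets$is_retweet | str_starts(tweets$text, fixed("RT @")))
  stage_result(tweets, keep, "retweets")
}

#' Keep English-language posts
#'
#' Keeps posts whose language code is exactly `"en"`. Undetermined
#' (`"und"`) or missing codes are removed: only verifiably English posts
#' are retained.
#'
#' @inheritParams keyword_filter
#' @return list with `kept`, `removed`, `stage`.
#' @export
filter_english <- function(tweets) {
  tweets <- validate_corpus(tweets)
  keep <- !is.na(tweets$lang) & tweets$lang == "en"
  stage_result(tweets, keep, "non_english")
}

#' Remove posts containing excluded phrases
#'
#' Drops posts whose lower-cased raw text contains any of the phrases as a
#' contiguous substring. The default phrases are song-lyric fragments that
#' match the keyword search without being about nicotine use.
#'
#' @inheritParams keyword_filter
#' @param phrases nonempty character vector of phrases.
#' @return list with `kept`, `removed`, `stage`.
#' @export
remove_excluded_phrases <- function(tweets,
                                    phrases = c(
                                      "bad nicotine", "nicotine heroin",
                                      "nicotine stain", "silver spoon"
                                    )) {
  tweets <- validate_corpus(tweets)
  if (length(phrases) == 0) {
    abort("phrases must be nonempty")
  }
  low <- str_to_lower(tweets$text)
  hit <- rep(FALSE, nrow(tweets))
  for (ph in phrases) {
    hit <- hit | str_detect(low, fixed(str_to_lower(ph)))
  }
  stage_result(tweets, !hit, "excluded_phrases")
}

#' Partition posts into bot / nonbot cohorts by account score
#'
#' Posts from accounts with a missing score (deleted accounts, which cannot
#' be screened) are dropped. Among scored accounts, the threshold is
#' inclusive: score >= `threshold` is a social bot, score < `threshold` a
#' nonbot. Accounts present in the corpus but absent from the score table
#' are treated as missing, with a warning.
#'
#' @inheritParams keyword_filter
#' @param scores bot-score tibble from [read_bot_scores()].
#' @param threshold bot threshold in `[0, 5]`; default 4.
#' @return list with `nonbot`, `bot`, `dropped_deleted` (disjoint corpora
#'   whose union is the input), `removed` (the deleted-account drop count),
#'   and `stage`.
#' @export
partition_by_bot_score <- function(tweets, scores, threshold = 4) {
  tweets <- validate_corpus(tweets)
  scores <- validate_bot_scores(scores)
  if (threshold < 0 || threshold > 5) {
    abort("threshold must lie in [0, 5]")
  }
  joined <- left_join(tweets, scores, by = "author_id")
  unknown <- setdiff(tweets$author_id, scores$author_id)
  if (length(unknown) > 0) {
    warn(sprintf(
      "%d account(s) in corpus absent from score table; treated as deleted",
      length(unknown)
    ))
  }
  deleted <- is.na(joined$score)
  is_bot <- !deleted & joined$score >= threshold
  list(
    nonbot = tweets[!deleted & !is_bot, , drop = FALSE],
    bot = tweets[is_bot, , drop = FALSE],
    dropped_deleted = tweets[deleted, , drop = FALSE],
    removed = sum(deleted),
    stage = "deleted_accounts"
  )
}

#' Run the full filtering cascade
#'
#' Applies, in order: keyword filter, retweet removal, language filter,
#' excluded-phrase removal, then the bot-score partition (which drops posts
#' from deleted accounts). Returns both cohorts together with the ledger.
#'
#' @inheritParams keyword_filter
#' @param scores bot-score tibble.
#' @param config a [pipeline_config()].
#' @return list with `nonbot`, `bot`, `dropped_deleted`, `ledger` (a
#'   `filter_ledger` whose final `remaining` is `nrow(nonbot) + nrow(bot)`).
#' @export
filter_cascade <- function(tweets, scores, config = pipeline_config()) {
  tweets <- validate_corpus(tweets)
  ledger <- new_filter_ledger(nrow(tweets))

  s <- keyword_filter(tweets, config$keyword)
  ledger <- ledger_add_stage(ledger, s$stage, s$removed)
  s <- remove_retweets(s$kept)
  ledger <- ledger_add_stage(ledger, s$stage, s$removed)
  s <- filter_english(s$kept)
  ledger <- ledger_add_stage(ledger, s$stage, s$removed)
  s <- remove_excluded_phrases(s$kept, config$exclusion_phrases)
  ledger <- ledger_add_stage(ledger, s$stage, s$removed)

  part <- partition_by_bot_score(s$kept, scores, config$bot_threshold)
  ledger <- ledger_add_stage(ledger, part$stage, part$removed)

  list(
    nonbot = part$nonbot,
    bot = part$bot,
    dropped_deleted = part$dropped_deleted,
    ledger = ledger
  )
}
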