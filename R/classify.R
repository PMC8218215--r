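#' Match a single topic pattern against a token sequence
#'
#' Matching semantics by pattern kind:
#' * `unigram` — the token occurs anywhere in the sequence;
#' * `bigram` — the two tokens occur adjacently, in order;
#' * `ordered_group` — the tokens occur in order as a (not necessarily
#'   contiguous) subsequence.
#'
#' @param tokens ordered character vector of normalized tokens.
#' @param pattern a [topic_pattern()].
#' @return `TRUE` if the pattern occurs; always `FALSE` on empty tokens.
#' @examples
#' match_pattern(c("@person", "look", "nicotine", "free", "today"),
#'               topic_pattern("bigram", c("nicotine", "free")))
#' @export
match_pattern <- function(tokens, pattern) {
  if (!inherits(pattern, "topic_pattern")) {
    abort("pattern must be a topic_pattern")
  }
  k <- length(tokens)
  if (k == 0) {
    return(FALSE)
  }
  pt <- pattern$tokens
  switch(pattern$kind,
    unigram = pt %in% tokens,
    bigram = {
      if (k < 2) return(FALSE)
      any(tokens[-k] == pt[1] & tokens[-1] == pt[2])
    },
    ordered_group = {
      # greedy left-to-right scan: earliest matches never preclude a
      # subsequence completion, so greedy is exact here
      j <- 1L
      for (tok in tokens) {
        if (tok == pt[j]) {
          j <- j + 1L
          if (j > length(pt)) return(TRUE)
        }
      }
      FALSE
    }
  )
}

#' Classify one normalized tweet into topics
#'
#' Rule-based multi-label classification: a tweet receives every topic for
#' which at least one of the topic's patterns matches its token sequence.
#' A tweet can carry several topics or none; tweets matching no topic form
#' the unclassified remainder.
#'
#' @param tokens ordered character vector of normalized tokens (or the
#'   list returned by [normalize_tweet()]).
#' @param lexicon a `topic_lexicon`.
#' @return character vector of matched topic names, in lexicon order
#'   (possibly empty).
#' @export
classify_tweet <- function(tokens, lexicon) {
  if (!inherits(lexicon, "topic_lexicon")) {
    abort("lexicon must be a topic_lexicon")
  }
  if (is.list(tokens) && !is.null(tokens$tokens)) {
    tokens <- tokens$tokens
  }
  hit <- map_lgl(lexicon, function(patterns) {
    any(map_lgl(patterns, function(p) match_pattern(tokens, p)))
  })
  names(lexicon)[hit]
}

#' Classify a normalized corpus
#'
#' @param normalized tibble from [normalize_corpus()].
#' @param lexicon a `topic_lexicon`.
#' @return a topic assignment: tibble with columns `tweet_id` and `topics`
#'   (list column of character vectors), one row per tweet.
#' @export
classify_corpus <- function(normalized, lexicon) {
  tibble(
    tweet_id = normalized$tweet_id,
    topics = map(normalized$tokens, classify_tweet, lexicon = lexicon)
  )
}

#' Write a topic assignment as CSV
#'
#' Columns `tweet_id` and `topics`, the latter pipe-separated (empty
#' string for unclassified tweets).
#'
#' @param assignment tibble from [classify_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  readr::write_csv(
    tibble(
      tweet_id = assignment$tweet_id,
      topics = map_chr(assignment$topics, paste, collapse = "|")
    ),
    path
  )
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(tweet_id = readr::col_character(),
                            topics = readr::col_character())
  )
  tab$topics[is.na(tab$topics)] <- ""
  tibble(
    tweet_id = tab$tweet_id,
    topics = map(str_split(tab$topics, fixed("|")),
                 function(x) x[nzchar(x)])
  )
}
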