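#' Topic lexicons and patterns
#'
#' A topic lexicon maps topic names to lists of matchable patterns. A
#' pattern is one of three kinds: a `unigram` (one token, matched by
#' membership), a `bigram` (two tokens that must occur adjacently in
#' order), or an `ordered_group` (two or more tokens that must occur in
#' order but not necessarily adjacently). Pattern tokens are stored
#' normalized: the lexicon reader pushes every phrase through the same
#' normalizer as the tweets, so matching is consistent by construction.
#'
#' @name topic_lexicon
NULL

#' Construct a topic pattern
#'
#' @param kind one of `"unigram"`, `"bigram"`, `"ordered_group"`.
#' @param tokens character vector of normalized tokens (1 for a unigram,
#'   exactly 2 for a bigram, >= 2 for an ordered group).
#' @return an object of class `topic_pattern`.
#' @export
topic_pattern <- function(kind, tokens) {
  kind <- match.arg(kind, c("unigram", "bigram", "ordered_group"))
  tokens <- as.character(tokens)
  n <- length(tokens)
  ok <- switch(kind,
    unigram = n == 1,
    bigram = n == 2,
    ordered_group = n >= 2
  )
  if (!ok) {
    abort(sprintf("a %s pattern cannot have %d token(s): [%s]",
                  kind, n, paste(tokens, collapse = ", ")))
  }
  if (any(!nzchar(tokens))) {
    abort("pattern tokens must be nonempty")
  }
  structure(list(kind = kind, tokens = tokens), class = "topic_pattern")
}

#' @export
format.topic_pattern <- function(x, ...) {
  sprintf("%s[%s]", x$kind, paste(x$tokens, collapse = " "))
}

#' @export
print.topic_pattern <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

new_topic_lexicon <- function(topics) {
  if (length(topics) == 0 || is.null(names(topics)) ||
      any(!nzchar(names(topics)))) {
    abort("a lexicon must be a named list of pattern lists")
  }
  if (anyDuplicated(names(topics))) {
    abort("topic names must be unique")
  }
  empty <- names(topics)[map_int(topics, length) == 0]
  if (length(empty) > 0) {
    abort(sprintf("topic(s) with no patterns: %s",
                  paste(empty, collapse = ", ")))
  }
  structure(topics, class = "topic_lexicon")
}

#' @export
print.topic_lexicon <- function(x, ...) {
  cat(sprintf("<topic_lexicon> %d topics\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm,
                paste(map_chr(x[[nm]], format), collapse = " | ")))
  }
  invisible(x)
}

#' Read a topic lexicon from a YAML file
#'
#' The file holds a top-level `topics` mapping; each topic is a list of
#' single-key entries `kind: phrase` (e.g. `- bigram: cold turkey`). Each
#' phrase is normalized with the supplied stop-word list and lemmatizer so
#' that stored pattern tokens match normalized tweet tokens exactly.
#'
#' @param path path to the YAML lexicon.
#' @param stopwords,lemmatizer the normalization resources; must be the
#'   same ones used for the tweets.
#' @return a `topic_lexicon`.
#' @export
read_lexicon <- function(path,
                         stopwords = default_stopwords(),
                         lemmatizer = default_lemmatizer()) {
  if (!file.exists(path)) {
    abort(sprintf("lexicon file not found: '%s'", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$topics)) {
    abort("lexicon file must have a top-level 'topics' mapping")
  }
  topics <- imap(raw$topics, function(entries, topic) {
    map(entries, function(entry) {
      if (!is.list(entry) || length(entry) != 1 || is.null(names(entry))) {
        abort(sprintf("topic '%s': each pattern must be a single 'kind: phrase' entry",
                      topic))
      }
      kind <- names(entry)
      phrase <- as.character(entry[[1]])
      toks <- normalize_tweet(phrase, stopwords, lemmatizer)$tokens
      if (length(toks) == 0) {
        abort(sprintf("topic '%s': phrase '%s' normalizes to nothing",
                      topic, phrase))
      }
      topic_pattern(kind, toks)
    })
  })
  new_topic_lexicon(topics)
}

#' The default 15-topic nicotine lexicon
#'
#' The shipped lexicon covers person tagging, addiction, appeal, NRT
#' (nicotine replacement therapy), vaping, smoking, nicotine health risks,
#' withdrawal, quit nicotine, cessation, polysubstance use, caffeine,
#' underage use, new products, and nicotine is safe. The pattern lists are
#' a documented reconstruction from published topic descriptions, not a
#' verbatim copy of any study's unpublished pattern sets; they are shipped
#' as an editable YAML file (see
#' `system.file("extdata", "lexicon_default.yml", package = "nicotopics")`).
#'
#' @inheritParams read_lexicon
#' @return a `topic_lexicon` with exactly 15 topics.
#' @export
default_lexicon <- function(stopwords = default_stopwords(),
                            lemmatizer = default_lemmatizer()) {
  read_lexicon(
    system.file("extdata", "lexicon_default.yml",
                package = "nicotopics", mustWork = TRUE),
    stopwords, lemmatizer
  )
}
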