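#' Six-step tweet normalization
#'
#' Raw text is reduced to an ordered sequence of lower-case lemmatized
#' tokens by: (1) URL removal, (2) collapsing of account mentions to the
#' common token `@person`, (3) hashtag removal, (4) lower-casing and
#' stripping of punctuation and special characters, (5) removal of
#' nonprintable characters and emoticons, (6) whitespace tokenization with
#' stop-word removal and dictionary lemmatization.
#'
#' URLs, mentions, and hashtags must be handled before punctuation is
#' stripped: once `@` and `#` are gone those markers cannot be recognized.
#' The token `@person` is protected from punctuation stripping so that it
#' survives as a matchable token.
#'
#' @name normalize_stage
NULL

# sentinel that survives the punctuation strip; restored to "@person"
.person_sentinel <- "zqzpersonzqz"
.mention_re <- "(^|\\s)@[A-Za-z0-9_]+"
.hashtag_re <- "(^|\\s)#[A-Za-z0-9_]+"
.url_re <- "(?i)(https?://|www\\.)\\S+"

#' Default English stop-word list
#'
#' A standard English function-word list shipped with the package, one word
#' per line, with contractions stored apostrophe-free (the normalizer
#' deletes apostrophes before tokenizing). Negations (`no`, `not`, `never`,
#' `nor`) are deliberately kept out of the list because they carry meaning
#' for health-claim patterns such as "nicotine not harmful".
#'
#' @param path optional path to an alternative list (one word per line).
#' @return character vector of stop words.
#' @export
default_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stopwords_en.txt",
                                package = "nicotopics", mustWork = TRUE)
  words <- readLines(path, warn = FALSE, encoding = "UTF-8")
  words <- str_trim(words)
  unique(words[nzchar(words) & !str_starts(words, fixed("#"))])
}

#' Default dictionary lemmatizer
#'
#' A token-to-lemma lookup table shipped as a two-column CSV
#' (`form,lemma`). It covers common English irregular forms plus the
#' inflections of the nicotine-domain vocabulary used by the topic lexicon
#' (e.g. `quitting -> quit`, `vaping -> vape`, `cigarettes -> cigarette`).
#' Every lemma in the table is a fixed point, so applying the map twice
#' changes nothing; unknown tokens pass through unchanged.
#'
#' @param path optional path to an alternative `form,lemma` CSV.
#' @return named character vector mapping form to lemma.
#' @export
default_lemmatizer <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lemmas_en.csv",
                                package = "nicotopics", mustWork = TRUE)
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(form = readr::col_character(),
                            lemma = readr::col_character())
  )
  lem <- setNames(tab$lemma, tab$form)
  # a lemma that is itself re-mapped would make lemmatization order-dependent
  chained <- intersect(unname(lem), names(lem)[unname(lem) != names(lem)])
  chained <- chained[lem[chained] != chained]
  if (length(chained) > 0) {
    abort(sprintf("lemma table is not idempotent; chained forms: %s",
                  paste(head(chained, 5), collapse = ", ")))
  }
  lem
}

# vectorized core: character vector of texts -> list(tokens = list, n_mentions = int)
normalize_texts <- function(texts, stopwords, lemmatizer,
                            drop_hashtag_tokens = TRUE) {
  s <- str_replace_all(texts, .url_re, " ")              # (1) URLs
  n_mentions <- str_count(s, .mention_re)                # (2) mentions
  s <- str_replace_all(s, .mention_re, paste0("\\1", .person_sentinel))
  if (drop_hashtag_tokens) {                             # (3) hashtags
    s <- str_replace_all(s, .hashtag_re, "\\1")
  } else {
    s <- str_replace_all(s, "(^|\\s)#", "\\1")
  }
  s <- str_to_lower(s)                                   # (4) casing ...
  s <- str_remove_all(s, "'")                            # don't -> dont
  # (4)+(5): punctuation, special and nonprintable characters (incl.
  # emoticons and non-ASCII symbols) all fall outside the kept class
  s <- str_replace_all(s, "[^a-z0-9 ]", " ")
  s <- str_squish(s)
  toks <- str_split(s, fixed(" "))
  lem_names <- names(lemmatizer)
  toks <- map(toks, function(tk) {                       # (6) tokens
    tk <- tk[nzchar(tk)]
    tk[tk == .person_sentinel] <- "@person"
    tk <- tk[!(tk %in% stopwords)]
    hit <- match(tk, lem_names)
    tk[!is.na(hit)] <- unname(lemmatizer[hit[!is.na(hit)]])
    tk
  })
  list(tokens = toks, n_mentions = as.integer(n_mentions))
}

#' Normalize a single text
#'
#' @param text a raw tweet text.
#' @param stopwords character vector of stop words.
#' @param lemmatizer named character vector mapping token to lemma.
#' @param drop_hashtag_tokens drop whole hashtag tokens (default) or keep
#'   the tag text with the `#` marker stripped.
#' @return list with `tokens` (character vector, possibly empty) and
#'   `n_mentions` (number of account mentions collapsed to `@person`).
#' @examples
#' normalize_tweet("@CDC I LOVE quitting!! http://t.co/x")
#' @export
normalize_tweet <- function(text,
                            stopwords = default_stopwords(),
                            lemmatizer = default_lemmatizer(),
                            drop_hashtag_tokens = TRUE) {
  stopifnot(is.character(text), length(text) == 1)
  out <- normalize_texts(text, stopwords, lemmatizer, drop_hashtag_tokens)
  list(tokens = out$tokens[[1]], n_mentions = out$n_mentions[1])
}

#' Normalize a corpus
#'
#' @param tweets a tweet corpus tibble ([read_tweets()]).
#' @inheritParams normalize_tweet
#' @return tibble with columns `tweet_id`, `tokens` (list column of
#'   character vectors), `n_mentions`; one row per input tweet, order and
#'   ids preserved.
#' @export
normalize_corpus <- function(tweets,
                             stopwords = default_stopwords(),
                             lemmatizer = default_lemmatizer(),
                             drop_hashtag_tokens = TRUE) {
  tweets <- validate_corpus(tweets)
  if (nrow(tweets) == 0) {
    return(tibble(tweet_id = character(), tokens = list(),
                  n_mentions = integer()))
  }
  out <- normalize_texts(tweets$text, stopwords, lemmatizer,
                         drop_hashtag_tokens)
  tibble(tweet_id = tweets$tweet_id, tokens = out$tokens,
         n_mentions = out$n_mentions)
}

#' Write / read a normalized corpus as JSON lines
#'
#' @param normalized tibble from [normalize_corpus()].
#' @param path file path.
#' @return `path` invisibly for the writer; the tibble for the reader.
#' @export
write_normalized <- function(normalized, path) {
  lines <- vapply(seq_len(nrow(normalized)), function(i) {
    jsonlite::toJSON(
      list(
        tweet_id = normalized$tweet_id[i],
        tokens = normalized$tokens[[i]],
        n_mentions = normalized$n_mentions[i]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_normalized
#' @export
read_normalized <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(str_trim(lines))]
  if (length(lines) == 0) {
    return(tibble(tweet_id = character(), tokens = list(),
                  n_mentions = integer()))
  }
  recs <- map(lines, jsonlite::fromJSON)
  tibble(
    tweet_id = map_chr(recs, "tweet_id"),
    tokens = map(recs, function(r) as.character(r$tokens)),
    n_mentions = map_int(recs, function(r) as.integer(r$n_mentions))
  )
}
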