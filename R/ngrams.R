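#' Extract contiguous n-grams from a token sequence
#'
#' An n-gram is a contiguous sequence of n words: the tokens
#' `["player", "breaks", "record"]` contain the unigrams "player",
#' "breaks", "record" and the bigrams "player breaks" and "breaks record".
#'
#' @param tokens ordered character vector of tokens.
#' @param n n-gram length, a positive integer.
#' @return character vector of all length-`n` windows in order, joined by
#'   single spaces; empty when fewer than `n` tokens.
#' @examples
#' extract_ngrams(c("player", "breaks", "record"), 2)
#' @export
extract_ngrams <- function(tokens, n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != as.integer(n)) {
    abort("n must be a positive integer")
  }
  k <- length(tokens)
  if (k < n) {
    return(character())
  }
  if (n == 1) {
    return(as.character(tokens))
  }
  vapply(seq_len(k - n + 1), function(i) {
    paste(tokens[i:(i + n - 1)], collapse = " ")
  }, character(1))
}

#' Rank the most frequent n-grams in a normalized corpus
#'
#' Counts are aggregated over all tweets; ties are broken
#' lexicographically so the ranking is deterministic.
#'
#' @param normalized tibble from [normalize_corpus()] (or any tibble with a
#'   `tokens` list column).
#' @param n n-gram length.
#' @param top_k maximum number of rows returned (>= 1).
#' @return tibble with columns `ngram`, `count`, sorted by decreasing
#'   count then ngram.
#' @export
ngram_frequency <- function(normalized, n, top_k = 25) {
  if (top_k < 1) {
    abort("top_k must be >= 1")
  }
  grams <- unlist(map(normalized$tokens, extract_ngrams, n = n),
                  use.names = FALSE)
  if (length(grams) == 0) {
    return(tibble(ngram = character(), count = integer()))
  }
  tab <- table(grams)
  out <- tibble(ngram = names(tab), count = as.integer(tab))
  out <- arrange(out, desc(.data$count), .data$ngram)
  slice_head(out, n = top_k)
}
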