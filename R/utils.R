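#' Round half up
#'
#' Rounds to `digits` decimal places with exact halves rounded away from zero,
#' the convention used for all reported percentages. Base [round()] rounds
#' half to even, which would print e.g. 0.125 as 0.12 rather than 0.13.
#'
#' @param x numeric vector.
#' @param digits non-negative integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.345, 2) # 2.35
#' round_half_up(-2.345, 2) # -2.35
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # the epsilon guards against binary representation error, e.g. 2.345
  # stored as 2.34499...97 must still round up to 2.35
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count, reported at fixed precision
#'
#' @param count non-negative integer numerator.
#' @param total positive integer denominator.
#' @param digits decimal places (default 2, the reporting precision).
#' @return `100 * count / total`, rounded half-up.
#' @export
as_pct <- function(count, total, digits = 2) {
  if (total <= 0) {
    abort("percentage undefined for a non-positive total")
  }
  round_half_up(100 * count / total, digits)
}

# shared validation for tweet corpora (tibble with the six raw fields)
tweet_cols <- c("tweet_id", "text", "author_id", "lang", "is_retweet", "created_at")

validate_corpus <- function(tweets, arg = "tweets") {
  if (!is.data.frame(tweets)) {
    abort(sprintf("`%s` must be a data frame of tweet records", arg))
  }
  missing_cols <- setdiff(tweet_cols, names(tweets))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing tweet field(s): %s", arg,
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(tweets$tweet_id)) {
    dup <- tweets$tweet_id[duplicated(tweets$tweet_id)][1]
    abort(sprintf("duplicate tweet_id in corpus: '%s'", dup))
  }
  if (nrow(tweets) > 0 && any(!nzchar(tweets$tweet_id) | is.na(tweets$tweet_id))) {
    abort("tweet_id must be nonempty")
  }
  if (nrow(tweets) > 0 && any(!nzchar(tweets$text) | is.na(tweets$text))) {
    abort("tweet text must be nonempty")
  }
  invisible(as_tibble(tweets))
}
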