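#' Per-cohort reporting: prevalence, coverage, topic overlap
#'
#' All reporting arithmetic runs on exact counts; percentages are rounded
#' half-up only at the reporting boundary, at 2 decimal places by default.
#'
#' @name report_stage
NULL

assigned_topic_count <- function(assignment, topic) {
  sum(map_lgl(assignment$topics, function(t) topic %in% t))
}

#' Topic prevalence in a corpus
#'
#' `100 * (number of tweets assigned the topic) / n_tweets`, e.g. a topic
#' carried by 120,962 of 300,360 tweets has prevalence 40.27%.
#'
#' @param assignment topic assignment tibble from [classify_corpus()].
#' @param n_tweets corpus size (> 0).
#' @param topic topic name.
#' @param digits reporting precision.
#' @return prevalence percentage, rounded half-up.
#' @export
compute_prevalence <- function(assignment, n_tweets, topic, digits = 2) {
  if (n_tweets <= 0) {
    abort("prevalence undefined for an empty corpus")
  }
  as_pct(assigned_topic_count(assignment, topic), n_tweets, digits)
}

#' Coverage and unclassified share of a corpus
#'
#' Coverage is the percentage of tweets carrying at least one topic; the
#' unclassified share is its complement, computed before rounding so the
#' two always sum to 100 up to rounding.
#'
#' @inheritParams compute_prevalence
#' @return named numeric vector `c(coverage_pct, unclassified_pct)`.
#' @export
compute_coverage <- function(assignment, n_tweets, digits = 2) {
  if (n_tweets <= 0) {
    abort("coverage undefined for an empty corpus")
  }
  n_classified <- sum(map_int(assignment$topics, length) > 0)
  raw <- 100 * n_classified / n_tweets
  c(
    coverage_pct = round_half_up(raw, digits),
    unclassified_pct = round_half_up(100 - raw, digits)
  )
}

#' Topic co-occurrence (confusion) matrix
#'
#' Cell (i, j) is the percentage of the corpus belonging to both topic i
#' and topic j; the diagonal therefore equals each topic's prevalence and
#' the matrix is symmetric.
#'
#' @inheritParams compute_prevalence
#' @param topics character vector of topic names (row/column order).
#' @return a symmetric numeric matrix with topic names as dimnames.
#' @export
compute_overlap_matrix <- function(assignment, n_tweets, topics, digits = 2) {
  if (n_tweets <= 0) {
    abort("overlap undefined for an empty corpus")
  }
  k <- length(topics)
  # tweet x topic incidence, then co-occurrence by crossproduct
  inc <- matrix(0L, nrow = nrow(assignment), ncol = k,
                dimnames = list(NULL, topics))
  for (i in seq_len(nrow(assignment))) {
    hit <- intersect(assignment$topics[[i]], topics)
    if (length(hit) > 0) inc[i, hit] <- 1L
  }
  co <- crossprod(inc)
  out <- round_half_up(100 * co / n_tweets, digits)
  dimnames(out) <- list(topics, topics)
  out
}

#' Summary statistics for one cohort
#'
#' @inheritParams compute_overlap_matrix
#' @param cohort cohort label, e.g. `"nonbot"` or `"bot"`.
#' @return an object of class `cohort_stats`: list with `cohort`,
#'   `n_tweets`, `topic_counts` (named integer), `prevalence_pct` (named
#'   numeric), `coverage_pct`, `unclassified_pct`.
#' @export
cohort_stats <- function(assignment, n_tweets, topics, cohort = "nonbot",
                         digits = 2) {
  if (n_tweets < nrow(assignment)) {
    abort("n_tweets cannot be smaller than the number of assigned tweets")
  }
  counts <- setNames(
    vapply(topics, function(t) assigned_topic_count(assignment, t),
           integer(1)),
    topics
  )
  if (n_tweets > 0) {
    cov <- compute_coverage(assignment, n_tweets, digits)
    prev <- setNames(as_pct(counts, n_tweets, digits), topics)
  } else {
    cov <- c(coverage_pct = NA_real_, unclassified_pct = NA_real_)
    prev <- setNames(rep(NA_real_, length(topics)), topics)
  }
  structure(
    list(
      cohort = cohort,
      n_tweets = as.integer(n_tweets),
      topic_counts = counts,
      prevalence_pct = prev,
      coverage_pct = unname(cov["coverage_pct"]),
      unclassified_pct = unname(cov["unclassified_pct"])
    ),
    class = "cohort_stats"
  )
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats> %s cohort: %d tweets, coverage %.2f%%\n",
              x$cohort, x$n_tweets, x$coverage_pct))
  print(as_tibble_cohort_stats(x))
  invisible(x)
}

as_tibble_cohort_stats <- function(x) {
  tibble(
    topic = names(x$topic_counts),
    count = unname(x$topic_counts),
    prevalence_pct = unname(x$prevalence_pct)
  )
}

#' Compare topic prevalence between two cohorts
#'
#' Signed differences (first minus second cohort), ranked by absolute
#' difference so the topics separating the cohorts most come first.
#'
#' @param stats_a,stats_b `cohort_stats` over the same topic set
#'   (conventionally nonbot first, bot second).
#' @return tibble with columns `topic`, `pct_a`, `pct_b`, `diff_pct`,
#'   sorted by `abs(diff_pct)` descending.
#' @export
compare_cohorts <- function(stats_a, stats_b) {
  if (!identical(names(stats_a$topic_counts), names(stats_b$topic_counts))) {
    abort("cohorts must be summarized over the same topic set")
  }
  out <- tibble(
    topic = names(stats_a$prevalence_pct),
    pct_a = unname(stats_a$prevalence_pct),
    pct_b = unname(stats_b$prevalence_pct),
    diff_pct = unname(stats_a$prevalence_pct - stats_b$prevalence_pct)
  )
  arrange(out, desc(abs(.data$diff_pct)))
}

#' Write reporting tables as CSV
#'
#' @param stats a `cohort_stats`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_cohort_stats <- function(stats, path) {
  tab <- as_tibble_cohort_stats(stats)
  tab <- bind_rows(
    tab,
    tibble(
      topic = c(".coverage", ".unclassified"),
      count = c(NA_integer_, NA_integer_),
      prevalence_pct = c(stats$coverage_pct, stats$unclassified_pct)
    )
  )
  readr::write_csv(tab, path, na = "")
  invisible(path)
}

#' @rdname write_cohort_stats
#' @param overlap matrix from [compute_overlap_matrix()].
#' @export
write_overlap_matrix <- function(overlap, path) {
  tab <- as_tibble(overlap, rownames = "topic")
  readr::write_csv(tab, path)
  invisible(path)
}

#' Heatmap of a topic-overlap matrix
#'
#' @param overlap matrix from [compute_overlap_matrix()].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_overlap_heatmap <- function(overlap) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_overlap_heatmap requires the ggplot2 package")
  }
  df <- as_tibble(overlap, rownames = "row")
  df <- tidyr::pivot_longer(df, -"row", names_to = "col",
                            values_to = "pct")
  df$row <- factor(df$row, levels = rownames(overlap))
  df$col <- factor(df$col, levels = colnames(overlap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "% of corpus") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
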