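#' Run the full infoveillance pipeline and write the report bundle
#'
#' Chains filtering, cohort partition, normalization, n-gram frequency
#' analysis, topic classification, and reporting, writing every stage
#' output as plain delimited text under `out_dir`:
#'
#' * `ledger.csv` — the filter ledger (`stage,removed,remaining`);
#' * `cohort_<cohort>.jsonl` — the kept posts per cohort;
#' * `stats_<cohort>.csv` — per-topic counts and prevalence plus coverage;
#' * `overlap_<cohort>.csv` — the topic co-occurrence matrix;
#' * `unigrams_<cohort>.csv`, `bigrams_<cohort>.csv` — top n-grams;
#' * `assignment_<cohort>.csv` — per-tweet topic assignment;
#' * `cohort_comparison.csv` — signed nonbot-minus-bot prevalence
#'   differences ranked by absolute value.
#'
#' The pipeline is deterministic: identical inputs and config produce
#' identical outputs.
#'
#' @param tweets_path path to a JSONL tweet corpus ([read_tweets()]).
#' @param scores_path path to a bot-score CSV ([read_bot_scores()]).
#' @param out_dir output directory (created if absent).
#' @param config a [pipeline_config()].
#' @param top_k rows kept in the n-gram frequency tables.
#' @return invisibly, a list with `ledger`, `cohorts` (named list of kept
#'   corpora), `stats`, `overlap`, `comparison`, and `files` (paths
#'   written).
#' @export
run_pipeline <- function(tweets_path, scores_path, out_dir,
                         config = pipeline_config(), top_k = 25) {
  stage <- "read"
  result <- tryCatch({
    tweets <- read_tweets(tweets_path)
    scores <- read_bot_scores(scores_path)

    stage <- "filter"
    cascade <- filter_cascade(tweets, scores, config)
    if (!ledger_conserved(cascade$ledger)) {
      abort("filter ledger failed conservation check")
    }

    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    ledger_path <- file.path(out_dir, "ledger.csv")
    readr::write_csv(as_tibble(cascade$ledger), ledger_path)
    files <- c(files, ledger_path)

    topics <- names(config$lexicon)
    cohorts <- list(nonbot = cascade$nonbot, bot = cascade$bot)
    stats <- list()
    overlap <- list()
    for (cohort in names(cohorts)) {
      posts <- cohorts[[cohort]]
      p <- file.path(out_dir, sprintf("cohort_%s.jsonl", cohort))
      write_tweets(posts, p)
      files <- c(files, p)

      stage <- paste0("normalize:", cohort)
      normalized <- normalize_corpus(
        posts, config$stopwords, config$lemmatizer,
        config$drop_hashtag_tokens
      )

      stage <- paste0("ngrams:", cohort)
      for (n in 1:2) {
        tab <- ngram_frequency(normalized, n, top_k)
        p <- file.path(out_dir, sprintf(
          "%s_%s.csv", c("unigrams", "bigrams")[n], cohort
        ))
        readr::write_csv(tab, p)
        files <- c(files, p)
      }

      stage <- paste0("classify:", cohort)
      assignment <- classify_corpus(normalized, config$lexicon)
      p <- file.path(out_dir, sprintf("assignment_%s.csv", cohort))
      write_assignment(assignment, p)
      files <- c(files, p)

      stage <- paste0("report:", cohort)
      st <- cohort_stats(assignment, nrow(posts), topics, cohort,
                         config$rounding)
      stats[[cohort]] <- st
      p <- file.path(out_dir, sprintf("stats_%s.csv", cohort))
      write_cohort_stats(st, p)
      files <- c(files, p)

      if (nrow(posts) > 0) {
        ov <- compute_overlap_matrix(assignment, nrow(posts), topics,
                                     config$rounding)
      } else {
        ov <- matrix(0, length(topics), length(topics),
                     dimnames = list(topics, topics))
      }
      overlap[[cohort]] <- ov
      p <- file.path(out_dir, sprintf("overlap_%s.csv", cohort))
      write_overlap_matrix(ov, p)
      files <- c(files, p)
    }

    stage <- "compare"
    comparison <- compare_cohorts(stats$nonbot, stats$bot)
    comparison <- rename(comparison, nonbot_pct = "pct_a", bot_pct = "pct_b")
    p <- file.path(out_dir, "cohort_comparison.csv")
    readr::write_csv(comparison, p)
    files <- c(files, p)

    list(
      ledger = cascade$ledger,
      cohorts = cohorts,
      dropped_deleted = cascade$dropped_deleted,
      stats = stats,
      overlap = overlap,
      comparison = comparison,
      files = files
    )
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s",
                  stage, conditionMessage(e)))
  })
  invisible(result)
}
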