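mk_assignment <- function(topic_sets) {
  tibble::tibble(
    tweet_id = sprintf("t%03d", seq_along(topic_sets)),
    topics = topic_sets
  )
}

test_that("prevalence is the rounded percentage of assigned tweets", {
  asg <- mk_assignment(list("A", c("A", "B"), "B", character()))
  expect_equal(compute_prevalence(asg, 4, "A"), 50)
  expect_equal(compute_prevalence(asg, 4, "B"), 50)
  expect_equal(compute_prevalence(asg, 4, "C"), 0)
  expect_error(compute_prevalence(asg, 0, "A"), "empty corpus")
})

test_that("coverage and unclassified shares are complementary", {
  asg <- mk_assignment(list("A", c("A", "B"), "B", character()))
  cov <- compute_coverage(asg, 4)
  expect_equal(unname(cov), c(75, 25))

  all_classified <- mk_assignment(list("A", "B"))
  expect_equal(unname(compute_coverage(all_classified, 2)), c(100, 0))

  # rounding halves go up, and the two shares are computed pre-rounding
  asg3 <- mk_assignment(c(rep(list("A"), 2), rep(list(character()), 6)))
  cov3 <- compute_coverage(asg3, 8)
  expect_equal(unname(cov3), c(25, 75))
})

test_that("overlap matrix cells enumerate pairwise intersections", {
  asg <- mk_assignment(list("A", c("A", "B"), "B", character()))
  ov <- compute_overlap_matrix(asg, 4, c("A", "B"))
  expect_equal(ov["A", "B"], 25)
  expect_equal(ov["A", "A"], 50)
  expect_equal(ov["B", "B"], 50)
  expect_equal(ov, t(ov))

  disjoint <- mk_assignment(list("A", "B"))
  ov2 <- compute_overlap_matrix(disjoint, 2, c("A", "B"))
  expect_equal(ov2["A", "B"], 0)

  # a single tweet carrying both topics puts 100 at their intersection
  one <- mk_assignment(list(c("person tagging", "quit nicotine")))
  ov3 <- compute_overlap_matrix(one, 1, c("person tagging", "quit nicotine"))
  expect_equal(ov3["person tagging", "quit nicotine"], 100)
})

test_that("cohort stats satisfy their internal identities", {
  asg <- mk_assignment(list("A", c("A", "B"), "B", character(), "A"))
  st <- cohort_stats(asg, 5, c("A", "B"), cohort = "nonbot")
  expect_equal(unname(st$topic_counts), c(3L, 2L))
  expect_equal(unname(st$prevalence_pct), c(60, 40))
  expect_equal(st$coverage_pct + st$unclassified_pct, 100)
  expect_gte(st$coverage_pct, max(st$prevalence_pct))
  expect_lte(st$coverage_pct, min(100, sum(st$prevalence_pct)))
  # double counting: sum over tweets of |topics| equals sum of counts
  expect_equal(sum(lengths(asg$topics)), sum(st$topic_counts))
})

test_that("cohort comparison ranks signed differences by magnitude", {
  mk_stats <- function(prev, cohort) {
    asg <- mk_assignment(list(character()))
    st <- cohort_stats(asg, 1, names(prev), cohort)
    st$prevalence_pct[] <- prev
    st
  }
  nonbot <- mk_stats(c("person tagging" = 40.27, "new products" = 4.24,
                       "addiction" = 19.85), "nonbot")
  bot <- mk_stats(c("person tagging" = 20.47, "new products" = 14.62,
                    "addiction" = 9.22), "bot")
  cmp <- compare_cohorts(nonbot, bot)
  expect_equal(cmp$topic, c("person tagging", "addiction", "new products"))
  expect_equal(cmp$diff_pct, c(19.80, 10.63, -10.38))

  same <- compare_cohorts(nonbot, nonbot)
  expect_true(all(same$diff_pct == 0))

  bot_other <- mk_stats(c(x = 1), "bot")
  expect_error(compare_cohorts(nonbot, bot_other), "same topic set")
})

test_that("reporting invariants hold on pipeline output across seeds", {
  for (seed in c(4, 15)) {
    corpus <- generate_corpus(synth_config(n_tweets = 500, seed = seed),
                              lexicon = LEXICON)
    cas <- filter_cascade(corpus$tweets, corpus$scores)
    norm <- normalize_corpus(cas$nonbot, STOPWORDS, LEMMAS)
    asg <- classify_corpus(norm, LEXICON)
    n <- nrow(cas$nonbot)
    topics <- names(LEXICON)
    st <- cohort_stats(asg, n, topics)
    ov <- compute_overlap_matrix(asg, n, topics)

    expect_equal(ov, t(ov))
    for (topic in topics) {
      expect_equal(ov[topic, topic], st$prevalence_pct[[topic]])
      expect_lte(st$topic_counts[[topic]], n)
    }
    for (i in topics) for (j in topics) {
      expect_lte(ov[i, j], min(ov[i, i], ov[j, j]) + 1e-9)
    }
    expect_equal(st$coverage_pct + st$unclassified_pct, 100,
                 tolerance = 0.011)
    expect_gte(st$coverage_pct, max(st$prevalence_pct))
    expect_equal(sum(lengths(asg$topics)), sum(st$topic_counts))
  }
})

test_that("percentages are rounded half-up at the reporting boundary", {
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(2.344, 2), 2.34)
  expect_equal(round_half_up(-2.345, 2), -2.35)
  expect_equal(as_pct(1, 8), 12.5)
  expect_error(as_pct(1, 0), "non-positive")
})
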