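---
title: "Surveillance of nicotine-related Twitter topics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveillance of nicotine-related Twitter topics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicotopics)
```

## The problem

Public posts on Twitter are an organic record of how people experience
nicotine: cravings, quit attempts, replacement therapies, vaping, and the
misconceptions (for instance that nicotine by itself is harmless) that
health-education campaigns would want to correct. Automated accounts
("social bots") post into the same stream and can distort any description
of public opinion, so an infoveillance analysis needs to (i) clean a
keyword-matched stream down to independent, English, on-topic posts,
(ii) stratify posts into bot and nonbot cohorts using account-level bot
scores, and (iii) describe what each cohort talks about.

`nicotopics` implements that analysis as a deterministic, auditable
pipeline: a filtering cascade with a conservation-checked ledger, a
six-step text normalizer, unigram/bigram frequency analysis, a rule-based
multi-label classifier over 15 nicotine topics, and per-cohort prevalence,
coverage, and topic co-occurrence reporting. A synthetic corpus generator
with known ground truth makes every stage testable without platform
access.

## The filtering cascade

Posts flow through five stages, in a fixed order:

1. **keyword** — keep posts whose raw text contains "nicotine"
   case-insensitively; the hashtag form `#nicotine` matches by substring
   containment. This runs on *raw* text because the normalizer later
   removes hashtags.
2. **retweets** — remove posts flagged as retweets *or* whose text begins
   `"RT @"`. Streamed records vary in which marker they carry; honoring
   both makes the stage robust. Removing retweets lets each post be
   treated as an independent observation.
3. **non-English** — keep only `lang == "en"`. Undetermined (`"und"`) or
   missing codes are removed: unknown-language posts cannot be verified as
   English, and the analysis keeps only verifiably English posts.
4. **excluded phrases** — remove posts containing any of four song-lyric
   fragments ("bad nicotine", "nicotine heroin", "nicotine stain",
   "silver spoon") as case-insensitive contiguous substrings of the raw
   text. Substring semantics are deliberate: "nicotine stained my teeth"
   contains "nicotine stain" and is removed. One phrase ("silver spoon")
   does not itself contain the keyword, which is consistent with the
   filter operating *inside* the keyword-matched corpus.
5. **deleted accounts / bot partition** — posts whose account has no bot
   score (the account was deleted before screening) are dropped; among
   scored accounts the threshold is *inclusive*: score ≥ 4 on the 0–5
   scale is a social bot, score < 4 a nonbot. Bot scores are consumed as
   an external per-account input (e.g. Botometer batch output); the
   package does not compute them.

Every stage appends `(stage, removed, remaining)` to a ledger whose
identity `input = final kept + Σ removed` is enforced at construction and
re-checked by `ledger_conserved()`. Swapping the retweet and language
stages changes the ledger lines but provably not the final kept set (the
two predicates are pointwise); the suite tests this.

## Normalization

`normalize_tweet()` applies six transformations whose *order* is the only
self-consistent one: URLs, mentions, and hashtags must be handled before
punctuation stripping, otherwise the `@`/`#` markers are destroyed and
those steps become impossible.

1. URL removal (`http(s)://…`, `www.…`);
2. every account mention collapses to the common token `@person`
   (`n_mentions` records how many); `@person` is protected from
   punctuation stripping so it survives as a matchable token — "person
   tagging" is itself a topic;
3. hashtag removal — by default the whole hashtag token is dropped (the
   literal reading of "removal of hashtags"); `drop_hashtag_tokens =
   FALSE` instead strips only the `#` marker. Consequence, documented and
   accepted: a post matched only via `#nicotine` may normalize to tokens
   lacking "nicotine", which is why the keyword filter runs upstream on
   raw text;
4. lower-casing, apostrophe deletion (so "don't" becomes "dont"), and
   replacement of all remaining punctuation/special characters by spaces;
5. nonprintable character removal — emoticons and non-ASCII symbols fall
   outside the kept `[a-z0-9 ]` class (implemented jointly with step 4);
6. whitespace tokenization, stop-word removal, dictionary lemmatization.

Two shipped resources parameterize step 6 and are deliberate design
choices, since no standard list is prescribed for this analysis:

* **Stop words** (`default_stopwords()`): a Snowball-derived English
  function-word list with contractions stored apostrophe-free. Negations
  (`no`, `not`, `never`, `nor`) are *kept out* of the list because the
  "nicotine is safe" topic must distinguish "nicotine is not harmful"
  from "nicotine is harmful". Trade-off: collapsed contractions such as
  "we'll" → "well" also remove the standalone word "well"; harmless here
  because no lexicon pattern uses such tokens.
* **Lemmatizer** (`default_lemmatizer()`): a `form → lemma` dictionary
  covering the domain vocabulary (quitting→quit, vaping→vape,
  cigarettes→cigarette, craving→crave, …) plus common irregulars. Every
  lemma is a fixed point (checked at load), which together with the
  stop-word filter makes normalization idempotent: normalizing a rejoined
  token stream returns the same tokens. Idempotence is property-tested.

Exact token output is reconstruction-dependent — a different stop list or
lemmatizer yields different tokens — so no result in this package depends
on matching any external study token-for-token.

## Topics and the rule-based classifier

A topic lexicon maps 15 topic names to pattern lists. A pattern is a
**unigram** (token membership), a **bigram** (adjacent ordered pair), or
an **ordered group** (tokens in order as a not-necessarily-contiguous
subsequence — the distinction from a bigram implies gaps are allowed).
A tweet receives *every* topic with at least one matching pattern;
classification is multi-label by design and needs no tie-breaking. Tweets
matching nothing form the unclassified remainder.

The shipped lexicon (`default_lexicon()`,
`inst/extdata/lexicon_default.yml`) is an editable, clearly labeled
reconstruction from published topic *descriptions*; the original pattern
lists are unpublished. Pattern phrases are written in surface form and
pushed through the same normalizer as the tweets at load time, so
matching is consistent by construction. Two reconstruction choices
matter:

* the smoking and vaping vocabularies are kept token-disjoint (vaping
  uses `vape`/`juul`/`ecig`/`ecigarette` rather than an "e cigarette"
  bigram that would also fire smoking's `cigarette` unigram), so mixtures
  over these topics can be recovered cleanly from generator output;
* overlap between topics is otherwise a *feature*, not a bug: "quit
  smoking" legitimately fires both cessation and smoking, and the overlap
  matrix exists precisely to report such co-occurrence.

The greedy left-to-right subsequence scan used for ordered groups is
exact: taking the earliest possible match for each pattern token never
precludes completing the subsequence. The suite nevertheless checks the
classifier against a brute-force oracle that enumerates index
combinations, on randomized token lists and lexicons.

## Reporting

All arithmetic runs on exact counts; percentages are rounded only at the
reporting boundary, **half-up at 2 decimal places** (base R's round()
rounds half to even, which would misprint half-way values). Per cohort:

* **prevalence** of topic *t* = 100 · (posts carrying *t*) / n;
* **coverage** = 100 · (posts with ≥ 1 topic) / n, with the unclassified
  share computed as the pre-rounding complement so the two always sum to
  100 up to rounding;
* **overlap matrix**: cell (i, j) = percentage of the cohort belonging to
  both topics; symmetric, with each topic's prevalence on the diagonal;
* **cohort comparison**: signed nonbot − bot prevalence differences,
  ranked by absolute value.

## The synthetic corpus generator

`generate_corpus()` emulates the *composition* of a year-long keyword
stream, with every nuisance process switchable and seeded:

* every text contains the keyword (10% only in hashtag form);
* intended topics are drawn from a mixture (default proportional to the
  per-topic prevalences such a stream exhibits, scaled to 83% coverage
  with a 17% unclassifiable background; withdrawal and polysubstance use
  are assigned plausible masses of 3.0 and 2.5 points since no published
  figure exists for them); a `multi_topic_rate` (default 0.15) adds a
  second distinct topic;
* topical texts embed one randomly chosen pattern of each intended topic
  via `embed_pattern()`; because stored pattern tokens are fixed points
  of the normalizer, the classifier recovers every intended label
  (100% recall by construction — tested; precision is reported, never
  asserted, because rule overlap is legitimate);
* contamination is drawn independently per post: retweets 0.653 (marked
  by flag, `"RT @"` prefix, or both, to exercise both detection paths),
  non-English 0.109 (marked via the `lang` field only — language
  *detection* is out of scope), lyric phrases 0.019 (one of the four
  phrases appended verbatim), deleted accounts 0.118, bots 0.066 among
  scored accounts. These defaults are the published stage arithmetic of
  such a stream expressed as per-post rates;
* bots draw scores uniformly on [4, 5], nonbots on [0, 4), so the
  threshold gate is unambiguous; `boundary_score_mass` can pin bot scores
  exactly at 4.0 to exercise the inclusive boundary;
* each post is authored by its own account (the generator models no
  account-level post clustering).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linguistic realism (texts are filler words plus
embedded patterns), actual non-English text, account/post network
structure, topic drift over time, and above all the *true* pattern lists
of any particular study. Tests on generator output validate the
machinery (filtering, normalization, matching, arithmetic), not the
lexicon's real-world sensitivity.

## Statistical checks and problem sizes

Composition and mixture recovery are judged against **exact 99% central
binomial bands** (`qbinom(0.005, n, p)` to `qbinom(0.995, n, p)`): for
independent per-post draws the realized count is Binomial(n, p) exactly,
so no normal approximation is needed. Recovery runs use n = 2,000 posts
at fixed seeds with `multi_topic_rate = 0`, which accounts exactly for
the secondary-topic process (with it switched on, each topic's classified
prevalence exceeds its mixture mass by roughly rate × mass of the other
topics). The test suite uses corpora of 150–2,000 posts; the acceptance
script reports a full run at n = 20,000 — sizes chosen so estimates are
stable at the 2-dp reporting precision while the whole suite stays fast.

## Known limitations

* The lexicon is a reconstruction; prevalences computed with it are not
  comparable to any study that used unpublished pattern lists.
* Language filtering trusts the `lang` metadata; no detector is applied.
* The dictionary lemmatizer only maps listed forms; unseen inflections
  pass through unchanged.
* Retweet detection by `"RT @"` prefix can in principle remove a quoted
  manual retweet that a flag-based pipeline would keep.
* Bot scoring is external: the package stratifies by a supplied score and
  cannot detect bots among unscored accounts.

## A worked run

```{r example, eval = FALSE}
corpus <- generate_corpus(synth_config(n_tweets = 2000, seed = 42))
dir <- tempfile()
dir.create(dir)
write_tweets(corpus$tweets, file.path(dir, "tweets.jsonl"))
write_bot_scores(corpus$scores, file.path(dir, "scores.csv"))
res <- run_pipeline(file.path(dir, "tweets.jsonl"),
                    file.path(dir, "scores.csv"),
                    file.path(dir, "report"))
res$ledger
res$stats$nonbot
head(res$comparison)
```
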