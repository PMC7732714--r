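test_that("generation is deterministic given the seed", {
  g1 <- small_corpus(seed = 11L, n = 30L)
  g2 <- small_corpus(seed = 11L, n = 30L)
  expect_identical(g1, g2)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(g1$posts, p1)
  write_corpus(g2$posts, p2)
  expect_identical(readLines(p1), readLines(p2))
  g3 <- small_corpus(seed = 12L, n = 30L)
  expect_false(identical(g1$posts$body, g3$posts$body))
})

test_that("latent flags follow the configured group structure", {
  gen <- small_corpus(seed = 2L, n = 200L,
                      intersection_rate_opiates = 0,
                      intersection_rate_sw = 0.5)
  tr <- merge(gen$truth, gen$posts[, c("id", "group")],
              by.x = "post_id", by.y = "id")
  expect_false(any(tr$is_suicidal[tr$group == "opiates"]))
  expect_true(all(tr$is_suicidal[tr$group == "suicidewatch"]))
  expect_true(all(tr$is_opioid[tr$group == "opiates"]))
  expect_false(any(tr$is_opioid[tr$group %in% c("control", "depression")]))
  sw_op <- mean(tr$is_opioid[tr$group == "suicidewatch"])
  expect_gt(sw_op, 0.5 - 3 * sqrt(0.25 / 200))
  expect_lt(sw_op, 0.5 + 3 * sqrt(0.25 / 200))
})

test_that("full separability makes groups lexically disjoint", {
  lex <- toy_lexicons()
  gen <- generate_corpus(generator_config(
    seed = 6L,
    n_posts_per_group = c(control = 150L, suicidewatch = 150L,
                          depression = 5L, opiates = 5L),
    lexicons = lex, separability = 1, keyword_rate = 0))
  posts <- gen$posts[gen$posts$group %in% c("suicidewatch", "control"), ]
  toks <- corpus_tokens(posts)
  # oracle classifier: flag any post containing a suicidal-lexicon word
  flagged <- vapply(toks, function(tt)
    any(tt %in% c(names(lex$suicidal), names(lex$negative))),
    logical(1))
  expect_identical(unname(flagged), posts$group == "suicidewatch")
})

test_that("inserted key phrases appear at the configured rate", {
  lex <- toy_lexicons()  # disjoint from both keyword lists
  gen <- generate_corpus(generator_config(
    seed = 8L,
    n_posts_per_group = c(control = 5L, suicidewatch = 400L,
                          depression = 5L, opiates = 400L),
    lexicons = lex, keyword_rate = 0.6))
  posts <- gen$posts
  sw <- posts[posts$group == "suicidewatch", ]
  op <- posts[posts$group == "opiates", ]
  p_sw <- mean(contains_keyword(sw, keywords_c1()))
  p_op <- mean(contains_keyword(op, keywords_c2()))
  se <- 3 * sqrt(0.6 * 0.4 / 400)
  expect_gt(p_sw, 0.6 - se); expect_lt(p_sw, 0.6 + se)
  expect_gt(p_op, 0.6 - se); expect_lt(p_op, 0.6 + se)
  # rate 1 with these lexicons: keyword presence identifies the flag exactly
  gen1 <- generate_corpus(generator_config(
    seed = 9L,
    n_posts_per_group = c(control = 50L, suicidewatch = 50L,
                          depression = 50L, opiates = 50L),
    lexicons = lex, keyword_rate = 1))
  expect_identical(unname(contains_keyword(gen1$posts, keywords_c2())),
                   gen1$truth$is_opioid[match(gen1$posts$id,
                                              gen1$truth$post_id)])
})

test_that("first-person singular usage is elevated in at-risk groups", {
  gen <- generate_corpus(generator_config(
    seed = 13L,
    n_posts_per_group = c(control = 1000L, suicidewatch = 1000L,
                          depression = 1000L, opiates = 5L),
    pronoun_shift = 0.08))
  fps <- c("i", "i'm", "me", "my", "myself", "i've", "i'll")
  rate <- function(group) {
    toks <- unlist(corpus_tokens(gen$posts[gen$posts$group == group, ]))
    mean(toks %in% fps)
  }
  expect_gt(rate("suicidewatch"), rate("control"))
  expect_gt(rate("depression"), rate("control"))
})

test_that("generated word counts span the configured range", {
  gen <- small_corpus(seed = 14L, n = 300L)
  wc <- mapply(word_count, gen$posts$title, gen$posts$body)
  expect_gte(min(wc), generator_config()$length_distribution$min_words)
  expect_true(any(wc < 30))   # sampler's lower window is exercised
  expect_true(any(wc > 500))  # and the upper one
})

test_that("simulated annotators follow the error model", {
  gen <- small_corpus(seed = 21L, n = 50L)
  perfect <- annotator_config(sensitivity = 1, specificity = 1, seed = 3L)
  votes <- simulate_annotations(gen$posts, gen$truth, perfect,
                                question = "suicide_risk")
  flag <- gen$truth$is_suicidal[match(gen$posts$id, gen$truth$post_id)]
  for (j in 1:3) expect_identical(votes[[paste0("vote", j)]],
                                  as.integer(flag))
  one <- annotator_config(n_annotators = 1L, sensitivity = 0.7,
                          specificity = 0.7, seed = 4L)
  v1 <- simulate_annotations(gen$posts, gen$truth, one, "suicide_risk")
  expect_identical(majority_labels(v1)$label, v1$vote1)
})

test_that("majority-vote accuracy matches the closed form 3p^2(1-p)+p^3", {
  n <- 10000L
  posts <- posts_from_texts(rep("x", n), community = "suicidewatch")
  truth <- data.frame(post_id = posts$id, is_suicidal = TRUE,
                      is_opioid = FALSE)
  cfg <- annotator_config(sensitivity = 0.8, specificity = 0.8, seed = 5L)
  votes <- simulate_annotations(posts, truth, cfg, "suicide_risk")
  maj <- majority_labels(votes)$label
  p_closed <- 3 * 0.8^2 * 0.2 + 0.8^3  # 0.896
  se <- sqrt(p_closed * (1 - p_closed) / n)
  expect_lt(abs(mean(maj == 1L) - p_closed), 3 * se)
})

test_that("pairwise annotator agreement matches p^2 + (1-p)^2", {
  n <- 4000L
  posts <- posts_from_texts(rep("x", n))
  truth <- data.frame(post_id = posts$id,
                      is_suicidal = rep(c(TRUE, FALSE), n / 2),
                      is_opioid = FALSE)
  cfg <- annotator_config(sensitivity = 0.8, specificity = 0.8, seed = 6L)
  votes <- simulate_annotations(posts, truth, cfg, "suicide_risk")
  rep <- corpus_report(posts, truth, votes)
  expected <- 0.8^2 + 0.2^2  # 0.68
  se <- sqrt(expected * (1 - expected) / n)
  expect_length(rep$pairwise_agreement, 3L)
  for (a in rep$pairwise_agreement)
    expect_lt(abs(a - expected), 3 * se)
})

test_that("corpus report summarizes counts and omits absent annotations", {
  gen <- small_corpus(seed = 22L, n = 40L)
  rep <- corpus_report(gen$posts, gen$truth)
  expect_identical(rep$n_posts, 160L)
  expect_identical(as.integer(rep$posts_per_group["opiates"]), 40L)
  expect_true(is.null(rep$pairwise_agreement))
  expect_true(all(rep$keyword_prevalence >= 0))
})

test_that("truth sidecar files round-trip", {
  gen <- small_corpus(seed = 23L, n = 20L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_truth(gen$truth, path)
  expect_identical(read_truth(path), gen$truth)
})

test_that("generator configs are validated", {
  expect_error(generator_config(separability = 0), "separability")
  expect_error(generator_config(intersection_rate_sw = 1.5))
  lex <- default_lexicons(); lex$suicidal <- numeric(0)
  expect_error(generator_config(lexicons = lex), "empty")
})
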