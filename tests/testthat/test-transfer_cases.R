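test_that("case configurations carry the documented defaults", {
  c1 <- case_config("C1")
  expect_identical(c1$train_positive_group, "suicidewatch")
  expect_identical(c1$train_negative_group, "control")
  expect_identical(c1$target_group, "opiates")
  expect_true("want to die" %in% c1$keywords)
  c2 <- case_config("C2")
  expect_identical(c2$train_positive_group, "opiates")
  expect_identical(c2$train_negative_group, "depression")
  expect_identical(c2$target_group, "suicidewatch")
  expect_true(all(c("hydros", "fentanyl", "suboxone") %in% c2$keywords))
  c1b <- case_config("C1", target_group = "depression")
  expect_identical(c1b$target_group, "depression")
})

test_that("keyword matching is token-boundary contiguous and case-blind", {
  posts <- posts_from_texts(c(
    "i want to die tonight",
    "my suicidal thoughts are back",
    "Took some HYDROS yesterday",
    "the suicidality is overwhelming",
    "nothing drug related here",
    "hydrostatic pressure is a physics topic"))
  expect_identical(unname(contains_keyword(posts, keywords_c1())),
                   c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(unname(contains_keyword(posts, keywords_c2())),
                   c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # "suicidal thoughts" contains token "suicidal" but not token "suicide"
  expect_false(contains_keyword(posts[2, ], "suicide"))
  expect_true(contains_keyword(posts[2, ], "suicidal"))
  # multi-word phrases match across punctuation-free token runs only
  posts2 <- posts_from_texts(c("i want. to die", "i want to die"))
  expect_identical(unname(contains_keyword(posts2, "want to die")),
                   c(FALSE, TRUE))
  expect_false(any(contains_keyword(posts, character(0))))
})

test_that("heuristic labels equal keyword presence", {
  posts <- posts_from_texts(c("scored fentanyl again", "just sad today"))
  expect_identical(heuristic_labels(posts), c(1L, 0L))
})

# pool with controllable keyword content and word counts
keyword_pool <- function(n_kw, n_other, words = 60L) {
  filler <- function() paste(rep("filler word here we go", words %/% 5),
                             collapse = " ")
  texts <- c(replicate(n_kw, paste("i want to die .", filler())),
             replicate(n_other, filler()))
  posts_from_texts(texts, community = "opiates")
}

test_that("the evaluation sampler caps keyword posts and honors the window", {
  pool <- keyword_pool(1200L, 1200L)
  sp <- sample_spec(seed = 5L)
  smp <- keyword_sample(pool, sp, keywords_c1())
  expect_identical(nrow(smp), 500L)
  expect_identical(sum(smp$keyword_flag), 250L)
  expect_true(all(smp$word_count >= 30 & smp$word_count <= 500))
  expect_false(anyDuplicated(smp$id) > 0)
  smp2 <- keyword_sample(pool, sp, keywords_c1())
  expect_identical(smp2, smp)

  few <- keyword_pool(100L, 1200L)
  smp3 <- keyword_sample(few, sp, keywords_c1())
  expect_identical(sum(smp3$keyword_flag), 100L)
  expect_identical(nrow(smp3), 500L)
})

test_that("the sampler filters by word count and reports shortfalls", {
  short <- posts_from_texts(rep("too short", 600))  # 2 words each
  expect_error(keyword_sample(short, sample_spec(), keywords_c1()),
               "shortfall")
  mixed <- rbind(keyword_pool(10L, 500L),
                 posts_from_texts(rep("tiny", 400)))
  mixed$id <- sprintf("m%04d", seq_len(nrow(mixed)))
  expect_error(keyword_sample(mixed, sample_spec(n = 400L), keywords_c1()),
               NA)
})

test_that("majority rule is a strict-majority over odd vote sets", {
  expect_identical(majority_label(c(1L, 1L, 0L)), 1L)
  expect_identical(majority_label(c(0L, 0L, 0L)), 0L)
  expect_error(majority_label(c(1L, 0L)), "odd")
  # exhaustive: all 8 vote triples, invariance under permutation
  for (a in 0:1) for (b in 0:1) for (c_ in 0:1) {
    v <- c(a, b, c_)
    expected <- as.integer(sum(v) >= 2)
    expect_identical(majority_label(v), expected)
    expect_identical(majority_label(v[c(2, 3, 1)]), expected)
    expect_identical(majority_label(rev(v)), expected)
  }
})

test_that("stratified accuracy decomposes by label and recombines", {
  # perfect predictor
  sa <- stratified_accuracy(c(0.1, 0.1, 0.9), c(1, 1, 0))
  expect_identical(sa$all_data, 1)
  expect_identical(sa$positive_only, 1)
  expect_identical(sa$negative_only, 1)
  # always-negative predictor on a 120/380 sample
  labels <- c(rep(1, 120), rep(0, 380))
  sa2 <- stratified_accuracy(rep(0.9, 500), labels)
  expect_equal(sa2$all_data, 0.76)
  expect_identical(sa2$positive_only, 0)
  expect_identical(sa2$negative_only, 1)
  expect_identical(sa2$predicted_positive_count, 0L)
  # prevalence-weighted identity
  withr::with_seed(3, {
    s <- runif(200); y <- rbinom(200, 1, 0.4)
    sa3 <- stratified_accuracy(s, y)
    w <- mean(y)
    expect_equal(sa3$all_data,
                 w * sa3$positive_only + (1 - w) * sa3$negative_only,
                 tolerance = 1e-12)
  })
  expect_true(is.na(stratified_accuracy(c(0.2, 0.3), c(1, 1))$negative_only))
})

test_that("ratio-curve accuracy follows r*a+ + (1-r)*a-", {
  # predictor perfect on positives, always wrong on negatives
  labels <- rep(c(1, 0), each = 200)
  scores <- rep(c(0.1, 0.1), each = 200)  # predicts positive always
  rc <- ratio_curve(scores, labels, n_rows = 500L, n_reps = 200L, seed = 2L)
  for (k in seq_len(nrow(rc))) {
    r <- rc$ratio[k]
    se <- sqrt(r * (1 - r) / 500) / sqrt(200)
    expect_lt(abs(rc$accuracy[k] - r), 3 * se + 1e-9)
  }
  expect_true(all(diff(rc$accuracy) > 0))  # monotone when a+ > a-
  expect_error(ratio_curve(scores, rep(1, 400)), "positive and negative")
})

test_that("a symmetric predictor yields its accuracy at the balanced ratio", {
  withr::with_seed(7, {
    labels <- rep(c(1, 0), each = 300)
    a <- 0.8  # same class-conditional accuracy on both sides
    correct <- rbinom(600, 1, a)
    scores <- ifelse(labels == 1, ifelse(correct == 1, 0.1, 0.9),
                     ifelse(correct == 1, 0.9, 0.1))
    rc <- ratio_curve(scores, labels, ratios = 0.5, n_rows = 500L,
                      n_reps = 200L, seed = 3L)
    expect_lt(abs(rc$accuracy - mean(correct)), 0.02)
  })
})

test_that("a transfer case trains on source groups and scores the target", {
  gen <- small_corpus(seed = 31L, n = 120L, sep = 0.9)
  specs <- list(model_spec("LR", "TFIDF", seed = 1L))
  res <- run_case(case_config("C1"), gen$posts, specs,
                  spec_sample = sample_spec(min_words = 10L,
                                            max_words = 1500L),
                  L = 100L, seed = 2L)
  preds <- res$predictions[["LR/TFIDF"]]
  opi_ids <- gen$posts$id[gen$posts$group == "opiates"]
  expect_true(all(preds$id %in% opi_ids))
  expect_true(all(res$target_posts$group == "opiates"))
  # intersection posts (latent suicidal flag) score lower than the rest
  flag <- gen$truth$is_suicidal[match(preds$id, gen$truth$post_id)]
  expect_lt(mean(preds$score[flag]), mean(preds$score[!flag]))

  # swapping the groups reproduces the C2 protocol unchanged
  res2 <- run_case(case_config("C2"), gen$posts, specs,
                   spec_sample = sample_spec(min_words = 10L,
                                             max_words = 1500L),
                   L = 100L, seed = 2L)
  sw_ids <- gen$posts$id[gen$posts$group == "suicidewatch"]
  expect_true(all(res2$predictions[["LR/TFIDF"]]$id %in% sw_ids))
  expect_error(run_case(case_config("C1", target_group = "nowhere"),
                        gen$posts, specs), "empty")
})
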