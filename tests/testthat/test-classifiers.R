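# small separable corpus used across classifier tests: class-1 documents
# contain the marker token "riskword" somewhere, class-0 never do
sep_task <- function(n = 240L, len = 15L, seed = 1L) {
  withr::with_seed(seed, {
    vocabulary <- paste0("w", 1:30)
    y <- rep(0:1, length.out = n)
    toks <- lapply(y, function(cl) {
      tt <- sample(vocabulary, len, replace = TRUE)
      if (cl == 1L) tt[sample(len, 1L)] <- "riskword"
      tt
    })
    list(tokens = toks, y = as.integer(y))
  })
}

test_that("splits are stratified 64/16/20 and reproducible", {
  y <- rep(c("a", "b"), each = 50)
  sp <- split_corpus(y, seed = 3L)
  expect_length(sp$train, 64L)
  expect_length(sp$validation, 16L)
  expect_length(sp$test, 20L)
  expect_identical(sort(c(sp$train, sp$validation, sp$test)), 1:100)
  expect_identical(split_corpus(y, seed = 3L), sp)
  expect_false(identical(split_corpus(y, seed = 4L), sp))

  y2 <- rep(c(0, 1), times = c(300, 700))
  sp2 <- split_corpus(y2, seed = 5L)
  for (part in sp2) {
    prop <- mean(y2[part] == 1)
    expect_lt(abs(prop - 0.7), 0.01)
  }
  expect_error(split_corpus(c(rep(0, 4), rep(1, 100))), "fewer than 5")
})

test_that("evaluation metrics match their defining formulas", {
  ev <- eval_report(scores = c(0.9, 0.9, 0.1, 0.1),
                    labels = c(0, 0, 1, 1))
  expect_identical(ev$accuracy, 1)
  expect_identical(ev$f1, 1)
  expect_identical(ev$auc, 1)

  # confusion counts TP=8 FP=2 FN=2 TN=8 -> precision=recall=F1=0.8
  scores <- c(rep(0.2, 8), rep(0.8, 2),   # 10 positives: 8 caught
              rep(0.2, 2), rep(0.8, 8))   # 10 negatives: 2 false alarms
  labels <- c(rep(1, 10), rep(0, 10))
  ev2 <- eval_report(scores, labels)
  expect_equal(ev2$precision, 0.8)
  expect_equal(ev2$recall, 0.8)
  expect_equal(ev2$f1, 0.8)
  expect_equal(ev2$accuracy, 0.8)
  # F1 is the harmonic mean of the reported precision and recall
  expect_equal(ev2$f1,
               2 * ev2$precision * ev2$recall / (ev2$precision + ev2$recall),
               tolerance = 1e-9)
  expect_true(is.na(eval_report(c(0.2, 0.8), c(1, 1))$auc))
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  withr::with_seed(11, {
    for (rep_i in 1:3) {
      n <- 50L
      r <- round(runif(n), 2)  # ties included
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      pos <- r[y == 1]; neg <- r[y == 0]
      cmp <- outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b))
      expect_equal(auc_rank(r, y), mean(cmp), tolerance = 1e-12)
    }
  })
})

test_that("label flipping reflects AUC around one half", {
  withr::with_seed(12, {
    r <- runif(100); y <- rbinom(100, 1, 0.5)
    expect_equal(auc_rank(r, y), 1 - auc_rank(r, 1 - y), tolerance = 1e-12)
  })
})

test_that("logistic regression separates a linearly separable cluster task", {
  task <- sep_task()
  spec <- model_spec("LR", "TFIDF", seed = 1L)
  fit <- train_classifier(spec, task$tokens, task$y, L = 30L)
  rec <- predict(fit, task$tokens)
  expect_identical(mean(rec$predicted_class == task$y), 1)
  expect_true(all(rec$score >= 0 & rec$score <= 1))
})

test_that("scores follow the 0-equals-risk orientation convention", {
  task <- sep_task()
  fit <- train_classifier(model_spec("LR", "TFIDF"), task$tokens, task$y,
                          L = 30L)
  rec <- predict(fit, task$tokens)
  # risky documents (label 1) score low; safe ones high
  expect_lt(mean(rec$score[task$y == 1]), 0.5)
  expect_gt(mean(rec$score[task$y == 0]), 0.5)
  expect_lt(max(rec$score[task$y == 1]), min(rec$score[task$y == 0]))
  expect_identical(rec$predicted_class, as.integer(rec$score < 0.5))
})

test_that("the bag-of-unigram FAST model is order invariant", {
  task <- sep_task()
  spec <- model_spec("FAST", "W2V",
                     params = list(ngram = 1L, epochs = 40L), seed = 2L)
  fit <- train_classifier(spec, task$tokens, task$y, L = 30L)
  shuffled <- withr::with_seed(9, lapply(task$tokens, sample))
  p1 <- predict(fit, task$tokens)$score
  p2 <- predict(fit, shuffled)$score
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_gt(eval_report(p1, task$y)$f1, 0.9)
})

test_that("each sequence family learns the marker-token task", {
  task <- sep_task(n = 300L)
  sp <- split_corpus(task$y, seed = 2L)
  for (fam in c("CNN", "RNN", "ATTENTION")) {
    params <- if (fam == "CNN")
      list(d = 16L, n_filters = 8L, hidden = 16L, batch = 32L,
           epochs = 10L, lr = 0.05, filter_sizes = c(3L, 8L))
    else list(d = 16L, hidden = 16L, batch = 32L, epochs = 8L, lr = 1e-2)
    spec <- model_spec(fam, "W2V", params = params, seed = 3L)
    fit <- train_classifier(spec, task$tokens[sp$train], task$y[sp$train],
                            L = 20L)
    rec <- predict(fit, task$tokens[sp$test])
    ev <- eval_report(rec$score, task$y[sp$test])
    expect_gt(ev$f1, 0.9)
    expect_true(all(rec$score >= 0 & rec$score <= 1))
    # probabilities stay valid on arbitrary unseen tokens
    junk <- list(paste0("junk", 1:20), "zzz", rep("riskword", 20))
    pj <- predict(fit, junk)$score
    expect_true(all(pj >= 0 & pj <= 1))
  }
})

test_that("training is deterministic given the model seed", {
  task <- sep_task(n = 160L)
  for (fam in c("LR", "RF", "FAST")) {
    cmb <- if (fam == "FAST") "W2V" else "TFIDF"
    f1 <- train_classifier(model_spec(fam, cmb, seed = 7L), task$tokens,
                           task$y, L = 20L)
    f2 <- train_classifier(model_spec(fam, cmb, seed = 7L), task$tokens,
                           task$y, L = 20L)
    expect_equal(predict(f1, task$tokens)$score,
                 predict(f2, task$tokens)$score, tolerance = 1e-12)
  }
  c1 <- train_classifier(model_spec("CNN", "W2V",
                                    params = list(d = 8L, n_filters = 4L,
                                                  hidden = 8L, epochs = 2L,
                                                  batch = 64L),
                                    seed = 7L),
                         task$tokens, task$y, L = 20L)
  c2 <- train_classifier(model_spec("CNN", "W2V",
                                    params = list(d = 8L, n_filters = 4L,
                                                  hidden = 8L, epochs = 2L,
                                                  batch = 64L),
                                    seed = 7L),
                         task$tokens, task$y, L = 20L)
  expect_identical(predict(c1, task$tokens)$score,
                   predict(c2, task$tokens)$score)
})

test_that("family/combination compatibility is enforced", {
  expect_error(model_spec("RNN", "TFIDF"), "sequence input")
  expect_error(model_spec("FAST", "TFIDF+W2V"), "bag-of-n-gram")
  expect_error(model_spec("LR", "W2V+GLOVE"), "alternative")
  expect_true(isTRUE(combination_supported("CNN", "TFIDF+W2V+CHAR2VEC")))
})

test_that("the metric grid covers pairs, skips misfits, keeps row order", {
  task <- sep_task(n = 200L)
  g <- grid_run(task$tokens, task$y, families = c("LR", "RNN"),
                combinations = c("TFIDF", "TFIDF+GLOVE"), L = 20L,
                seed = 4L)
  expect_identical(nrow(g), 4L)
  expect_identical(g$family, c("LR", "LR", "RNN", "RNN"))
  # LR+GLOVE unrunnable without a pretrained table; RNN takes sequences only
  expect_match(g$skipped[g$family == "LR" & g$combination == "TFIDF+GLOVE"],
               "pretrained")
  expect_true(all(!is.na(g$skipped[g$family == "RNN"])))
  expect_false(is.na(g$f1[g$family == "LR" & g$combination == "TFIDF"]))
  g2 <- grid_run(task$tokens, task$y, families = c("LR", "RNN"),
                 combinations = c("TFIDF", "TFIDF+GLOVE"), L = 20L,
                 seed = 4L)
  expect_identical(g, g2)
})

test_that("degenerate training inputs are rejected", {
  task <- sep_task(n = 40L)
  expect_error(train_classifier(model_spec("LR", "TFIDF"), task$tokens,
                                rep(1L, 40L)), "single-class")
  expect_error(train_classifier(model_spec("LR", "TFIDF+GLOVE"),
                                task$tokens, task$y), "pretrained")
})
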