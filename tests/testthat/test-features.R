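test_that("tf-idf downweights shared terms and fixes the dimension", {
  m <- fit_tfidf(list(c("a", "b"), c("a", "c")), D = 4L)
  idf <- stats::setNames(m$idf, m$ngrams)
  expect_lt(idf[["a"]], idf[["b"]])
  gen <- small_corpus(seed = 2L, n = 40L)
  toks <- corpus_tokens(gen$posts)
  m100 <- fit_tfidf(toks)
  expect_identical(m100$D, 100L)
  X <- tfidf_transform(m100, toks[1:10])
  expect_identical(dim(X), c(10L, 100L))
  nrm <- sqrt(rowSums(X^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-12))
})

test_that("tf-idf values match a hand-computed oracle", {
  # three documents; unigrams+bigrams counted explicitly below
  docs <- list(c("a", "b", "a"), c("a", "c"), c("b", "b", "c"))
  m <- fit_tfidf(docs, D = 8L)  # the corpus has exactly 8 distinct n-grams
  X <- tfidf_transform(m, docs)
  # oracle: smoothed idf log((1+N)/(1+df)) + 1 with N = 3
  idf <- function(df) log((1 + 3) / (1 + df)) + 1
  # doc 1 raw ngram counts: a=2, b=1, "a b"=1, "b a"=1
  raw <- c(a = 2 * idf(2), b = 1 * idf(2),
           `a b` = 1 * idf(1), `b a` = 1 * idf(1))
  expected <- raw / sqrt(sum(raw^2))
  for (g in names(expected))
    expect_equal(unname(X[1, g]), unname(expected[g]), tolerance = 1e-9)
  # document with none of the selected n-grams -> zero vector
  X0 <- tfidf_transform(m, list(c("zzz", "qqq")))
  expect_identical(unname(X0[1, ]), rep(0, m$D))
})

test_that("tf-idf warns and shrinks when fewer n-grams exist than D", {
  expect_warning(m <- fit_tfidf(list(c("a", "b")), D = 50L), "available")
  expect_lt(m$D, 50L)
})

test_that("trained embeddings reflect co-occurrence structure", {
  # tokens paired in identical contexts vs a token seen elsewhere
  set.seed(1)
  docs <- c(replicate(150, rep(c("alpha", "beta"), 6), simplify = FALSE),
            replicate(150, rep(c("gamma", "delta"), 6), simplify = FALSE))
  emb <- train_word_embeddings(docs, d = 24L, window = 2L, epochs = 6L,
                               seed = 3L)
  expect_identical(ncol(emb$vectors), 24L)
  cs <- function(a, b) {
    va <- emb$vectors[a, ]; vb <- emb$vectors[b, ]
    sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  expect_gt(cs("alpha", "beta"), cs("alpha", "delta"))
  expect_gt(cs("gamma", "delta"), cs("gamma", "beta"))
  emb2 <- train_word_embeddings(docs, d = 24L, window = 2L, epochs = 6L,
                                seed = 3L)
  expect_identical(emb$vectors, emb2$vectors)
  expect_error(train_word_embeddings(list("a")), "too small")
})

test_that("pretrained embedding files load, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("alpha 1 0 0 0 0.5",
               "beta 0 1 0 0 -0.25",
               "gamma 0 0 1 0 0"), path)
  tab <- load_pretrained(path)
  expect_identical(dim(tab$vectors), c(3L, 5L))
  expect_identical(unname(tab$vectors["beta", 5]), -0.25)
  # unknown tokens share one fixed oov vector
  m <- embed_tokens(c("nope", "alsono"), tab)
  expect_identical(m[1, ], m[2, ])
  writeLines(c("alpha 1 0", "beta 1"), path)
  expect_error(load_pretrained(path), "line 2")
  writeLines(c("alpha 1 0", "alpha 0 1"), path)
  expect_error(load_pretrained(path), "duplicate")

  gen_docs <- list(c("x", "y", "x", "z"), c("y", "z", "y", "x"))
  emb <- train_word_embeddings(gen_docs, d = 8L, window = 2L,
                               epochs = 2L, seed = 1L)
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(emb, p2)
  back <- load_pretrained(p2)
  expect_equal(back$vectors[rownames(emb$vectors), ], emb$vectors,
               tolerance = 1e-6)
})

test_that("character embeddings aggregate by mean over characters", {
  tab <- char_embedding_table(d = 12L, seed = 2L)
  v1 <- char_embed("a", tab)
  expect_identical(drop(v1), unname(tab$vectors["a", ]))
  expect_identical(char_embed("silent", tab), char_embed("listen", tab))
  expect_identical(ncol(char_embed("word", tab)), 12L)
  # characters outside the table contribute zero vectors
  expect_identical(drop(char_embed("é", tab)), rep(0, 12L))
})

test_that("assembled document vectors have combination-determined widths", {
  gen <- small_corpus(seed = 7L, n = 30L)
  toks <- corpus_tokens(gen$posts)[1:40]
  tf <- fit_tfidf(toks)
  emb <- train_word_embeddings(toks, d = 100L, epochs = 1L, seed = 1L)
  ch <- char_embedding_table(d = 100L, seed = 1L)
  expect_identical(ncol(assemble_documents(toks[1:5], "TFIDF",
                                           tfidf = tf)), 100L)
  expect_identical(ncol(assemble_documents(toks[1:5], "TFIDF+W2V",
                                           tfidf = tf,
                                           embeddings = emb)), 200L)
  expect_identical(
    ncol(assemble_documents(toks[1:5], "TFIDF+W2V+CHAR2VEC", tfidf = tf,
                            embeddings = emb, char_table = ch)), 300L)
  expect_error(assemble_documents(toks[1:5], "TFIDF+W2V", tfidf = tf),
               "embedding table")
  expect_error(assemble_documents(toks[1:5], "NOPE"), "combination")
})

test_that("sequence inputs concatenate word and character channels", {
  docs <- list(c("x", "y", "x", "z"), c("y", "z", "y", "x"))
  emb <- train_word_embeddings(docs, d = 8L, window = 2L, epochs = 1L,
                               seed = 1L)
  ch <- char_embedding_table(d = 8L, seed = 1L)
  m <- assemble_sequence(c("x", "y"), emb)
  expect_identical(dim(m), c(2L, 8L))
  m2 <- assemble_sequence(c("x", "y"), emb, ch)
  expect_identical(dim(m2), c(2L, 16L))
  expect_identical(m2[, 1:8], m)
  expect_error(assemble_sequence("x", emb, char_embedding_table(d = 4L)),
               "dim")
})

test_that("document vectors are invariant to token order", {
  gen <- small_corpus(seed = 8L, n = 20L)
  toks <- corpus_tokens(gen$posts)[1:10]
  tf <- fit_tfidf(toks, D = 50L)
  emb <- train_word_embeddings(toks, d = 16L, epochs = 1L, seed = 1L)
  shuffled <- lapply(toks, function(tt) tt[sample(length(tt))])
  # mean-pooled embeddings ignore order entirely
  expect_equal(doc_embedding_mean(shuffled, emb),
               doc_embedding_mean(toks, emb), tolerance = 1e-12)
  # unigram tf-idf components ignore order (bigram components need not)
  uni <- !grepl(" ", tf$ngrams)
  X1 <- tfidf_transform(tf, toks)
  X2 <- tfidf_transform(tf, shuffled)
  sel <- rowSums(X1[, !uni, drop = FALSE]) == 0 &
    rowSums(X2[, !uni, drop = FALSE]) == 0
  expect_equal(X1[sel, uni], X2[sel, uni], tolerance = 1e-12)
})
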