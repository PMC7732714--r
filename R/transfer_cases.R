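#' Configuration of a transfer experiment
#'
#' C1 trains suicide-watch versus control and predicts suicidality on
#' opioid-community posts, screening the evaluation sample with the suicide
#' keyword list.  C2 trains opioid communities versus depression and
#' predicts opioid misuse on suicide-watch posts, screening with the drug
#' keyword list.  All four components can be overridden.
#'
#' @param name `"C1"` or `"C2"` (sets the defaults), or any label when all
#'   groups are given explicitly.
#' @param train_positive_group,train_negative_group,target_group group
#'   names.
#' @param keywords keyword/phrase list for evaluation sampling.
#' @return object of class `redsup_case_config`.
#' @export
case_config <- function(name = c("C1", "C2"),
                        train_positive_group = NULL,
                        train_negative_group = NULL,
                        target_group = NULL,
                        keywords = NULL) {
  name <- match.arg(name)
  def <- if (name == "C1")
    list(pos = "suicidewatch", neg = "control", tgt = "opiates",
         kw = keywords_c1())
  else
    list(pos = "opiates", neg = "depression", tgt = "suicidewatch",
         kw = keywords_c2())
  structure(list(name = name,
                 train_positive_group = train_positive_group %||% def$pos,
                 train_negative_group = train_negative_group %||% def$neg,
                 target_group = target_group %||% def$tgt,
                 keywords = keywords %||% def$kw),
            class = "redsup_case_config")
}

#' Specification of the keyword-stratified evaluation sample
#'
#' @param n sample size (default 500).
#' @param keyword_cap maximum number of keyword-containing posts in the
#'   sample (default 250).
#' @param min_words,max_words word-count window for eligible posts
#'   (defaults 30 and 500).
#' @param seed integer seed.
#' @return object of class `redsup_sample_spec`.
#' @export
sample_spec <- function(n = 500L, keyword_cap = 250L, min_words = 30L,
                        max_words = 500L, seed = 1L) {
  stopifnot(keyword_cap <= n, min_words < max_words, n >= 1L)
  structure(list(n = as.integer(n), keyword_cap = as.integer(keyword_cap),
                 min_words = as.integer(min_words),
                 max_words = as.integer(max_words), seed = as.integer(seed)),
            class = "redsup_sample_spec")
}

#' Test posts for keyword presence
#'
#' A post contains a keyword when the keyword's cleaned token sequence
#' occurs contiguously in the cleaned tokens of the post's title+body;
#' matching is case-insensitive and respects token boundaries, so
#' `"suicidal thoughts"` does not match the keyword `"suicide"` while the
#' single token `"suicidality"` matches the keyword `"suicidality"`.
#'
#' @param posts posts data frame.
#' @param keywords character vector of keywords/phrases (empty list matches
#'   nothing).
#' @return logical vector, one element per post.
#' @export
contains_keyword <- function(posts, keywords) {
  if (!length(keywords)) return(rep(FALSE, nrow(posts)))
  toks <- corpus_tokens(posts)
  docs <- vapply(toks, function(tt)
    paste0(" ", paste(tt, collapse = " "), " "), character(1))
  kw <- vapply(keywords, function(k)
    paste0(" ", paste(tokenize(clean_text(k)), collapse = " "), " "),
    character(1))
  out <- rep(FALSE, length(docs))
  for (k in kw) out <- out | grepl(k, docs, fixed = TRUE)
  out
}

#' Draw the keyword-stratified evaluation sample
#'
#' From the pool of posts inside the word-count window, draws up to
#' `keyword_cap` posts uniformly from those containing a keyword and fills
#' the remainder uniformly from the rest, for a sample of exactly `n` when
#' the pool allows.  Deterministic given the spec's seed.
#'
#' @param posts posts data frame (the evaluation pool).
#' @param spec a [sample_spec()].
#' @param keywords keyword list.
#' @return data frame: the sampled posts with columns `keyword_flag` and
#'   `word_count` appended.
#' @export
keyword_sample <- function(posts, spec, keywords) {
  stopifnot(inherits(spec, "redsup_sample_spec"))
  wc <- mapply(word_count, posts$title, posts$body, USE.NAMES = FALSE)
  pool <- posts[wc >= spec$min_words & wc <= spec$max_words, , drop = FALSE]
  wc <- wc[wc >= spec$min_words & wc <= spec$max_words]
  if (nrow(pool) < spec$n)
    stop("pool of eligible posts (", nrow(pool), ") is smaller than the ",
         "requested sample (", spec$n, "); shortfall ",
         spec$n - nrow(pool))
  flag <- contains_keyword(pool, keywords)
  with_seed_(spec$seed, {
    kw_idx <- which(flag)
    other_idx <- which(!flag)
    n_kw <- min(length(kw_idx), spec$keyword_cap)
    take_kw <- if (n_kw > 0) sample(kw_idx, n_kw) else integer(0)
    n_rest <- spec$n - n_kw
    if (length(other_idx) >= n_rest) {
      take_rest <- sample(other_idx, n_rest)
    } else {
      # not enough keyword-free posts: top up from the remaining keyword pool
      extra <- setdiff(kw_idx, take_kw)
      take_rest <- c(other_idx,
                     sample(extra, n_rest - length(other_idx)))
    }
    take <- c(take_kw, take_rest)
    out <- pool[take, , drop = FALSE]
    out$keyword_flag <- flag[take]
    out$word_count <- wc[take]
    rownames(out) <- NULL
    out
  })
}

#' Majority-rule label from an odd number of binary votes
#'
#' @param votes integer 0/1 vector of odd length.
#' @return 1 if a strict majority of votes are 1, else 0.
#' @export
majority_label <- function(votes) {
  stopifnot(all(votes %in% c(0L, 1L)))
  if (length(votes) %% 2L == 0L)
    stop("majority rule requires an odd number of votes, got ",
         length(votes))
  as.integer(sum(votes) > length(votes) / 2)
}

#' Majority-rule labels for an annotation table
#'
#' @param annotations data frame with `post_id` and `vote1` ... `voteN`
#'   columns (N odd), as produced by [simulate_annotations()].
#' @return data frame `post_id`, `label`.
#' @export
majority_labels <- function(annotations) {
  vote_cols <- grep("^vote", names(annotations), value = TRUE)
  votes <- as.matrix(annotations[, vote_cols, drop = FALSE])
  data.frame(post_id = annotations$post_id,
             label = apply(votes, 1, majority_label),
             stringsAsFactors = FALSE)
}

#' Heuristic labels from keyword presence
#'
#' Labels a post as implicative of the condition exactly when it contains
#' any keyword from the list.
#'
#' @param posts posts data frame.
#' @param keywords keyword list (defaults to the drug list used for opioid
#'   misuse).
#' @return integer 0/1 vector.
#' @export
heuristic_labels <- function(posts, keywords = keywords_c2()) {
  as.integer(contains_keyword(posts, keywords))
}

#' Run a transfer case end to end
#'
#' Trains each model specification on the case's two source groups (the
#' positive group labeled 1), entirely excluding the target group, then
#' scores every target-group post inside the word-count window.
#'
#' @param case a [case_config()].
#' @param posts posts data frame with a `group` column.
#' @param specs list of [model_spec()] objects (one per model).
#' @param spec_sample a [sample_spec()]; its word-count window defines the
#'   prediction pool.
#' @param L sequence length for NN models (default 1500).
#' @param seed integer seed for the train/validation split.
#' @param pretrained optional pretrained embeddings for GLOVE combinations.
#' @return list with `predictions` (named list of per-model data frames
#'   `id`, `score`, `predicted_class`), `models` (the fitted classifiers),
#'   and `target_posts` (the scored pool).
#' @export
run_case <- function(case, posts, specs, spec_sample = sample_spec(),
                     L = 1500L, seed = 1L, pretrained = NULL) {
  stopifnot(inherits(case, "redsup_case_config"))
  if (inherits(specs, "redsup_model_spec")) specs <- list(specs)
  src <- posts[posts$group %in% c(case$train_positive_group,
                                  case$train_negative_group), , drop = FALSE]
  tgt <- posts[posts$group == case$target_group, , drop = FALSE]
  if (!nrow(tgt)) stop("target group '", case$target_group, "' is empty")
  if (!nrow(src)) stop("no posts in the source groups")
  wc <- mapply(word_count, tgt$title, tgt$body, USE.NAMES = FALSE)
  tgt <- tgt[wc >= spec_sample$min_words & wc <= spec_sample$max_words, ,
             drop = FALSE]
  if (!nrow(tgt))
    stop("no target-group posts inside the word-count window")
  y <- as.integer(src$group == case$train_positive_group)
  toks <- corpus_tokens(src)
  sp <- split_corpus(y, seed = seed)
  tgt_toks <- corpus_tokens(tgt)
  models <- list(); preds <- list()
  for (spec in specs) {
    key <- paste(spec$family, spec$combination, sep = "/")
    fit <- train_classifier(spec, toks[sp$train], y[sp$train],
                            toks[sp$validation], y[sp$validation],
                            L = L, pretrained = pretrained)
    models[[key]] <- fit
    preds[[key]] <- predict(fit, tgt_toks, ids = tgt$id)
  }
  list(predictions = preds, models = models, target_posts = tgt)
}

#' Accuracy stratified by reference label
#'
#' @param scores oriented scores (0 = positive class).
#' @param labels reference 0/1 labels (1 = positive class).
#' @return list with `all_data`, `positive_only`, `negative_only` (each the
#'   accuracy on that stratum, `NA` when the stratum is empty) and
#'   `predicted_positive_count` (number of scores below 0.5).
#' @export
stratified_accuracy <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- as.integer(scores < 0.5)
  acc <- function(sel) if (any(sel)) mean(pred[sel] == labels[sel])
                       else NA_real_
  list(all_data = acc(rep(TRUE, length(labels))),
       positive_only = acc(labels == 1L),
       negative_only = acc(labels == 0L),
       predicted_positive_count = sum(pred == 1L))
}

#' Accuracy as a function of the positive-label ratio
#'
#' For each ratio `r`, draws `n_rows` posts with replacement —
#' `round(r * n_rows)` from the label-positive posts and the rest from the
#' label-negative posts — scores the fixed predictor on the resample, and
#' averages the accuracy over `n_reps` draws.  The expectation equals
#' `r * a+ + (1 - r) * a-` for a predictor with class-conditional
#' accuracies `a+` and `a-`.
#'
#' @param scores oriented scores for the evaluation posts.
#' @param labels reference 0/1 labels.
#' @param ratios positive-class ratios to sweep (default 0.1 to 0.9).
#' @param n_rows resample size (default 500).
#' @param n_reps draws per ratio (default 1; use 200 or more for smooth
#'   curves).
#' @param seed integer seed.
#' @return data frame `ratio`, `accuracy` (and `sd` across reps).
#' @export
ratio_curve <- function(scores, labels, ratios = seq(0.1, 0.9, by = 0.1),
                        n_rows = 500L, n_reps = 1L, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg))
    stop("ratio curve requires both positive and negative reference labels")
  correct <- as.integer((scores < 0.5) == (labels == 1L))
  with_seed_(seed, {
    out <- lapply(ratios, function(r) {
      accs <- vapply(seq_len(n_reps), function(rep_i) {
        n_pos <- round(r * n_rows)
        take <- c(sample(pos, n_pos, replace = TRUE),
                  sample(neg, n_rows - n_pos, replace = TRUE))
        mean(correct[take])
      }, numeric(1))
      data.frame(ratio = r, accuracy = mean(accs),
                 sd = if (n_reps > 1) stats::sd(accs) else NA_real_)
    })
    do.call(rbind, out)
  })
}
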