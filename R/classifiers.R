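#' Classifier families
#'
#' The seven classifier families of the pipeline: logistic regression (LR),
#' random forest (RF), support vector machine (SVM), a fastText-style
#' averaged bag-of-n-grams network (FAST), an LSTM sequence classifier
#' (RNN), an attention-based bidirectional LSTM (ATTENTION), and a
#' convolutional text classifier (CNN).
#'
#' @return character vector of family names.
#' @export
classifier_families <- function() {
  c("LR", "RF", "SVM", "FAST", "RNN", "ATTENTION", "CNN")
}

#' Specification of one classifier run
#'
#' @param family one of [classifier_families()].
#' @param combination one of [feature_combinations()].
#' @param params named list overriding the family's default hyperparameters
#'   (see [default_hyperparams()]).
#' @param seed integer seed for this model's randomness.
#' @return object of class `redsup_model_spec`.
#' @export
model_spec <- function(family, combination = "W2V", params = list(),
                       seed = 1L) {
  family <- match.arg(family, classifier_families())
  ok <- combination_supported(family, combination)
  if (!isTRUE(ok)) stop(family, " with ", combination, ": ", ok)
  structure(list(family = family, combination = combination,
                 params = params, seed = as.integer(seed)),
            class = "redsup_model_spec")
}

#' Default hyperparameters per classifier family
#'
#' The CNN defaults are the pipeline's reference configuration: parallel
#' convolutions with filter sizes 3 and 8, ReLU activations, max-over-time
#' pooling, a randomly initialized learned embedding layer of dimension 100
#' with dropout 0.5, batch size 512, 6 epochs, cross-entropy loss.  The
#' recurrent families use an LSTM with hidden size 100; ATTENTION is
#' bidirectional with additive attention pooling.  Learning rates and the
#' number of filters are not pinned down by the reference configuration and
#' were chosen so that the fixed epoch budget converges on corpora of a few
#' thousand posts (monitored on the validation split).
#'
#' @param family one of [classifier_families()].
#' @return named list of hyperparameters.
#' @export
default_hyperparams <- function(family) {
  switch(family,
    LR = list(lambda = NULL, alpha = 0),
    RF = list(num_trees = 100L),
    SVM = list(kernel = "radial", cost = 1),
    FAST = list(d = 100L, ngram = 2L, min_count = 2L, epochs = 8L,
                lr = 2, batch = 64L, max_features = 50000L),
    RNN = list(d = 100L, hidden = 100L, batch = 64L, epochs = 6L,
               lr = 2e-3),
    ATTENTION = list(d = 100L, hidden = 100L, batch = 64L, epochs = 6L,
                     lr = 2e-3),
    CNN = list(d = 100L, filter_sizes = c(3L, 8L), n_filters = 100L,
               hidden = 64L, dropout = 0.5, batch = 512L, epochs = 6L,
               lr = 2e-3),
    stop("unknown family: ", family))
}

# TRUE, or a character reason why the pair cannot run
combination_supported <- function(family, combination) {
  cmb <- tryCatch(parse_combination(combination), error = function(e) NULL)
  if (is.null(cmb)) return(paste("unknown combination", combination))
  if (cmb$w2v && cmb$glove)
    return("W2V and GLOVE are alternative embedding sources")
  if (family %in% c("LR", "RF", "SVM", "CNN")) return(TRUE)
  if (family == "FAST") {
    if (identical(combination, "W2V")) return(TRUE)
    return("FAST learns its own bag-of-n-gram embeddings (use W2V)")
  }
  # RNN / ATTENTION: sequence input only
  if (identical(combination, "W2V")) return(TRUE)
  "recurrent families take sequence input only (use W2V)"
}

#' Stratified train/validation/test split
#'
#' Splits 8:2 into train+validation versus test, then the remainder 8:2
#' again into train versus validation (64/16/20 overall), stratified by
#' label and deterministic given the seed.
#'
#' @param labels vector of class labels.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_corpus <- function(labels, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 5L))
    stop("label '", names(counts)[counts < 5L][1],
         "' has fewer than 5 items; cannot satisfy both 8:2 splits")
  with_seed_(seed, {
    tr <- va <- te <- integer(0)
    for (lv in names(counts)) {
      idx <- sample(which(labels == lv))
      n <- length(idx)
      n_te <- round(0.2 * n)
      n_va <- round(0.2 * (n - n_te))
      te <- c(te, idx[seq_len(n_te)])
      va <- c(va, idx[n_te + seq_len(n_va)])
      tr <- c(tr, idx[(n_te + n_va + 1):n])
    }
    list(train = sort(tr), validation = sort(va), test = sort(te))
  })
}

# ---- FAST: averaged bag-of-n-gram embeddings + linear classifier ---------

fit_fast <- function(token_lists, y, d, ngram, min_count, epochs, lr, batch,
                     max_features, seed) {
  grams <- lapply(token_lists, function(tt)
    if (ngram >= 2L) doc_ngrams(tt) else tt)
  freq <- table(unlist(grams, use.names = FALSE))
  freq <- freq[freq >= min_count]
  if (!length(freq)) stop("no n-grams above min_count for FAST")
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  keep <- names(freq)[ord][seq_len(min(length(freq), max_features))]
  gid <- stats::setNames(seq_along(keep), keep)
  n <- length(grams)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    id <- unname(gid[grams[[i]]])
    id <- id[!is.na(id)]
    if (!length(id)) next
    tf <- table(id)
    ii <- c(ii, rep(i, length(tf)))
    jj <- c(jj, as.integer(names(tf)))
    xx <- c(xx, as.numeric(tf) / length(id))
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(n, length(keep)))
  with_seed_(seed, {
    E <- matrix(stats::runif(length(keep) * d, -0.5, 0.5) / d,
                length(keep), d)
    w <- numeric(d); b <- 0
    for (ep in seq_len(epochs)) {
      perm <- sample(n)
      lr_ep <- lr * (1 - (ep - 1) / epochs)
      for (s in seq(1, n, by = batch)) {
        rows <- perm[s:min(n, s + batch - 1)]
        Xb <- X[rows, , drop = FALSE]
        H <- as.matrix(Xb %*% E)
        p <- stats::plogis(drop(H %*% w) + b)
        g <- (p - y[rows]) / length(rows)
        gw <- drop(crossprod(H, g))
        dH <- tcrossprod(g, w)
        touched <- which(Matrix::colSums(Xb != 0) > 0)
        if (length(touched)) {
          gE <- as.matrix(Matrix::crossprod(Xb[, touched, drop = FALSE], dH))
          E[touched, ] <- E[touched, ] - lr_ep * gE
        }
        w <- w - lr_ep * gw
        b <- b - lr_ep * sum(g)
      }
    }
    list(gid = gid, E = E, w = w, b = b, ngram = ngram)
  })
}

predict_fast <- function(fit, token_lists) {
  grams <- lapply(token_lists, function(tt)
    if (fit$ngram >= 2L) doc_ngrams(tt) else tt)
  vapply(grams, function(g) {
    id <- unname(fit$gid[g])
    id <- id[!is.na(id)]
    if (!length(id)) return(stats::plogis(fit$b))
    tf <- table(id)
    h <- drop(crossprod(as.numeric(tf) / length(id),
                        fit$E[as.integer(names(tf)), , drop = FALSE]))
    stats::plogis(sum(h * fit$w) + fit$b)
  }, numeric(1))
}

# ---- shared assembly helpers for the sequence models ---------------------

seq_embedding_init <- function(vocab, table) {
  if (is.null(table)) return(matrix(0, 0, 0))
  m <- matrix(rep(table$oov_vector, each = length(vocab$index) + 2L),
              nrow = length(vocab$index) + 2L)
  m[1, ] <- 0  # padding row
  tok <- names(vocab$index)
  hit <- tok %in% rownames(table$vectors)
  if (any(hit))
    m[vocab$index[hit] + 1L, ] <- table$vectors[tok[hit], , drop = FALSE]
  m
}

#' Train one classifier
#'
#' Fits the requested family on tokenized training documents with binary
#' risk labels (1 = positive/risk class).  The validation split is used for
#' monitoring only; there is no early stopping.  All fitted transformations
#' (vocabulary, TF-IDF model, embedding tables) are learned on the training
#' split and stored in the returned object, so prediction on new documents
#' reuses them unchanged.
#'
#' @param spec a [model_spec()].
#' @param tokens list of token vectors (training documents).
#' @param y integer 0/1 vector, 1 meaning the positive/risk class.
#' @param tokens_val,y_val optional validation documents and labels.
#' @param L sequence length for the NN families (default 1500).
#' @param pretrained optional `redsup_embedding` loaded with
#'   [load_pretrained()], required for GLOVE combinations.
#' @return object of class `redsup_classifier` exposing [predict()] with the
#'   score orientation 0 = positive/risk.
#' @export
train_classifier <- function(spec, tokens, y, tokens_val = NULL,
                             y_val = NULL, L = 1500L, pretrained = NULL) {
  stopifnot(inherits(spec, "redsup_model_spec"),
            length(tokens) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("training labels are single-class")
  pp <- utils::modifyList(default_hyperparams(spec$family), spec$params)
  cmb <- parse_combination(spec$combination)
  if (cmb$glove && is.null(pretrained))
    stop("combination ", spec$combination,
         " requires a pretrained embedding table")
  y <- as.integer(y)

  obj <- list(family = spec$family, combination = spec$combination,
              params = pp, seed = spec$seed, L = as.integer(L))

  # shared transformers
  if (cmb$tfidf) obj$tfidf <- fit_tfidf(tokens, D = pp$tfidf_D %||% 100L)
  if (cmb$char) obj$char_table <- char_embedding_table(
    d = pp$d %||% 100L, seed = spec$seed)
  # W2V for the traditional families means mean-pooled skip-gram vectors
  # trained in-pipeline; the sequence models learn their own embedding
  # layer from random initialization (GLOVE supplies the initial values)
  emb_table <- NULL
  if (cmb$w2v && spec$family %in% c("LR", "RF", "SVM"))
    emb_table <- train_word_embeddings(tokens, d = pp$d %||% 100L,
                                       seed = spec$seed)
  if (cmb$glove) emb_table <- pretrained
  obj$embeddings <- emb_table

  if (spec$family %in% c("LR", "RF", "SVM")) {
    X <- assemble_documents(tokens, spec$combination, tfidf = obj$tfidf,
                            embeddings = emb_table,
                            char_table = obj$char_table)
    obj$fit <- switch(spec$family,
      LR = {
        lambda <- pp$lambda %||% (1 / length(y))
        glmnet::glmnet(X, y, family = "binomial", alpha = pp$alpha,
                       lambda = lambda, standardize = FALSE)
      },
      RF = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                          num.trees = pp$num_trees, probability = TRUE,
                          seed = spec$seed, num.threads = 1L),
      SVM = with_seed_(spec$seed,
        e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                   kernel = pp$kernel, cost = pp$cost, probability = TRUE)))
  } else if (spec$family == "FAST") {
    obj$fit <- fit_fast(tokens, y, d = pp$d, ngram = pp$ngram,
                        min_count = pp$min_count, epochs = pp$epochs,
                        lr = pp$lr, batch = pp$batch,
                        max_features = pp$max_features, seed = spec$seed)
  } else {
    obj$vocab <- build_vocabulary(tokens)
    X <- encode_matrix(tokens, obj$vocab, L)
    emb_init <- seq_embedding_init(obj$vocab, emb_table)
    have_val <- !is.null(tokens_val) && length(tokens_val) > 0L
    if (spec$family == "CNN") {
      side <- if (cmb$tfidf) tfidf_transform(obj$tfidf, tokens)
              else matrix(0, length(tokens), 0)
      cm <- if (cmb$char) char_matrix_for_vocab(obj$vocab, obj$char_table)
            else matrix(0, 0, 0)
      Xv <- if (have_val) encode_matrix(tokens_val, obj$vocab, L)
            else matrix(0L, 0, L)
      sv <- if (have_val && cmb$tfidf) tfidf_transform(obj$tfidf, tokens_val)
            else matrix(0, if (have_val) length(tokens_val) else 0, ncol(side))
      obj$fit <- cpp_cnn_train(
        X, as.numeric(y), side, emb_init, cm, vocab_size(obj$vocab),
        as.integer(pp$d), as.integer(pp$filter_sizes),
        as.integer(pp$n_filters), as.integer(pp$hidden), pp$dropout,
        as.integer(pp$batch), as.integer(pp$epochs), pp$lr, spec$seed,
        Xv, as.numeric(y_val %||% numeric(0)), sv)
    } else {
      lens <- pmin(lengths(tokens), L)
      obj$fit <- cpp_lstm_train(
        X, as.numeric(lens), as.numeric(y), emb_init,
        vocab_size(obj$vocab), as.integer(pp$d), as.integer(pp$hidden),
        spec$family == "ATTENTION", spec$family == "ATTENTION",
        as.integer(pp$batch), as.integer(pp$epochs), pp$lr, spec$seed,
        matrix(0L, 0, L), numeric(0), numeric(0))
    }
  }
  class(obj) <- "redsup_classifier"
  obj
}

encode_matrix <- function(token_lists, vocab, L) {
  m <- vapply(token_lists, encode, integer(L), vocab = vocab, L = L)
  t(matrix(m, nrow = L))
}

#' @export
print.redsup_classifier <- function(x, ...) {
  cat("<redsup_classifier> ", x$family, " / ", x$combination, "\n", sep = "")
  invisible(x)
}

#' Score documents with a trained classifier
#'
#' Scores follow the orientation convention used throughout the pipeline: a
#' score near 0 indicates the positive/risk class and a score near 1 the
#' negative class; `predicted_class` is 1 when `score < 0.5`.
#'
#' @param object a `redsup_classifier`.
#' @param tokens list of token vectors to score.
#' @param ids optional post ids for the output records.
#' @param ... unused.
#' @return data frame with `id`, `score`, `predicted_class`.
#' @export
predict.redsup_classifier <- function(object, tokens, ids = NULL, ...) {
  p_risk <- predict_risk_prob(object, tokens)
  data.frame(id = ids %||% seq_along(tokens),
             score = 1 - p_risk,
             predicted_class = as.integer((1 - p_risk) < 0.5),
             stringsAsFactors = FALSE)
}

predict_risk_prob <- function(object, tokens) {
  pp <- object$params
  if (object$family %in% c("LR", "RF", "SVM")) {
    X <- assemble_documents(tokens, object$combination,
                            tfidf = object$tfidf,
                            embeddings = object$embeddings,
                            char_table = object$char_table)
    return(switch(object$family,
      LR = drop(stats::predict(object$fit, newx = X, type = "response")),
      RF = {
        pr <- stats::predict(object$fit, data = X,
                             num.threads = 1L)$predictions
        pr[, "1"]
      },
      SVM = {
        pr <- attr(stats::predict(object$fit, newdata = X,
                                  probability = TRUE), "probabilities")
        pr[, "1"]
      }))
  }
  if (object$family == "FAST") return(predict_fast(object$fit, tokens))
  X <- encode_matrix(tokens, object$vocab, object$L)
  if (object$family == "CNN") {
    cmb <- parse_combination(object$combination)
    side <- if (cmb$tfidf) tfidf_transform(object$tfidf, tokens)
            else matrix(0, length(tokens), 0)
    cm <- if (cmb$char) char_matrix_for_vocab(object$vocab,
                                              object$char_table)
          else matrix(0, 0, 0)
    return(drop(cpp_cnn_predict(object$fit, X, side, cm)))
  }
  lens <- pmin(lengths(tokens), object$L)
  drop(cpp_lstm_predict(object$fit, X, as.numeric(lens)))
}

#' Evaluation metrics for oriented scores
#'
#' Computes accuracy, precision, recall, F1 for the positive/risk class, and
#' AUC from the rank statistic on the oriented scores (score < 0.5 predicts
#' the positive class).  With a single-class label vector the AUC is
#' reported as `NA`.
#'
#' @param scores numeric scores in \[0, 1\], orientation 0 = positive class.
#' @param labels integer 0/1 vector, 1 = positive class.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `auc`.
#' @export
eval_report <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(scores >= 0 & scores <= 1))
  labels <- as.integer(labels)
  pred <- as.integer(scores < 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f1 = f1,
       auc = auc_rank(1 - scores, labels))
}

#' Rank-statistic AUC
#'
#' @param risk_scores numeric vector, larger = more positive.
#' @param labels 0/1 vector.
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
auc_rank <- function(risk_scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(risk_scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run a grid of classifier families and input combinations
#'
#' Trains every requested (family, combination) pair on a shared stratified
#' split and evaluates on the held-out test set, producing a metric grid.
#' Incompatible or unrunnable pairs are skipped with the reason recorded.
#'
#' @param tokens list of token vectors.
#' @param labels integer 0/1 vector (1 = positive class).
#' @param families subset of [classifier_families()].
#' @param combinations subset of [feature_combinations()].
#' @param L sequence length for NN families.
#' @param seed integer seed (split and model seeds derive from it).
#' @param pretrained optional pretrained embedding table for GLOVE.
#' @param params named list: per-family hyperparameter overrides.
#' @return data frame with one row per pair: metrics or a skip reason.
#' @export
grid_run <- function(tokens, labels, families = classifier_families(),
                     combinations = feature_combinations(), L = 1500L,
                     seed = 1L, pretrained = NULL, params = list()) {
  sp <- split_corpus(labels, seed = seed)
  rows <- list()
  for (fam in families) {
    for (cmb in combinations) {
      ok <- combination_supported(fam, cmb)
      skip <- NULL
      if (!isTRUE(ok)) skip <- ok
      else if (grepl("GLOVE", cmb) && is.null(pretrained))
        skip <- "no pretrained embedding table supplied"
      if (!is.null(skip)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, combination = cmb, accuracy = NA_real_,
          precision = NA_real_, recall = NA_real_, f1 = NA_real_,
          auc = NA_real_, skipped = skip, stringsAsFactors = FALSE)
        next
      }
      spec <- model_spec(fam, cmb, params = params[[fam]] %||% list(),
                         seed = derive_seed(seed, paste0(fam, cmb)))
      fit <- train_classifier(spec, tokens[sp$train], labels[sp$train],
                              tokens[sp$validation], labels[sp$validation],
                              L = L, pretrained = pretrained)
      rec <- predict(fit, tokens[sp$test])
      ev <- eval_report(rec$score, labels[sp$test])
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, combination = cmb, accuracy = ev$accuracy,
        precision = ev$precision, recall = ev$recall, f1 = ev$f1,
        auc = ev$auc, skipped = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
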