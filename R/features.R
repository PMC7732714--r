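#' Supported input feature combinations
#'
#' The named combinations of document representations used across the
#' classifier grid: a 100-dimension TF-IDF over in-sample unigrams and
#' bigrams, word embeddings trained in-pipeline (`W2V`), word embeddings
#' loaded from a pretrained file (`GLOVE`), and character-derived token
#' embeddings (`CHAR2VEC`), alone or concatenated.
#'
#' @return character vector of combination names.
#' @export
feature_combinations <- function() {
  c("TFIDF", "W2V", "TFIDF+W2V", "TFIDF+GLOVE", "TFIDF+W2V+CHAR2VEC")
}

parse_combination <- function(combination) {
  parts <- strsplit(combination, "+", fixed = TRUE)[[1]]
  known <- c("TFIDF", "W2V", "GLOVE", "CHAR2VEC")
  if (!length(parts) || !all(parts %in% known))
    stop("unknown feature combination: ", combination)
  list(tfidf = "TFIDF" %in% parts,
       w2v = "W2V" %in% parts,
       glove = "GLOVE" %in% parts,
       char = "CHAR2VEC" %in% parts)
}

doc_ngrams <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) return(character(0))
  if (n == 1L) return(tokens)
  c(tokens, paste(tokens[-n], tokens[-1]))
}

#' Fit a TF-IDF model on training documents
#'
#' Selects the `D` most frequent in-sample unigrams and bigrams (ties broken
#' lexicographically) and computes smoothed inverse document frequencies
#' `log((1 + N) / (1 + df)) + 1`.  Transformed vectors are term counts
#' weighted by idf and L2-normalized, matching the convention most text
#' pipelines in this area use.
#'
#' @param token_lists list of token vectors (training split only).
#' @param D number of n-gram features (default 100).
#' @return object of class `redsup_tfidf` with fields `ngrams`, `idf`, `D`.
#' @export
fit_tfidf <- function(token_lists, D = 100L) {
  stopifnot(length(token_lists) > 0L)
  grams <- lapply(token_lists, doc_ngrams)
  total <- table(unlist(grams, use.names = FALSE))
  if (length(total) == 0L) stop("no n-grams in the training corpus")
  if (D > length(total)) {
    warning("only ", length(total), " n-grams available; using all")
    D <- length(total)
  }
  ord <- order(-as.integer(total), names(total), method = "radix")
  selected <- names(total)[ord][seq_len(D)]
  df <- integer(length(selected))
  names(df) <- selected
  for (g in grams) {
    hit <- unique(g)
    hit <- hit[hit %in% selected]
    df[hit] <- df[hit] + 1L
  }
  N <- length(token_lists)
  idf <- log((1 + N) / (1 + df)) + 1
  structure(list(ngrams = selected, idf = unname(idf), D = D),
            class = "redsup_tfidf")
}

#' Transform documents into TF-IDF vectors
#'
#' @param model a `redsup_tfidf` from [fit_tfidf()].
#' @param token_lists list of token vectors.
#' @return dense matrix, one row per document, `model$D` columns; a document
#'   containing none of the selected n-grams maps to the zero vector.
#' @export
tfidf_transform <- function(model, token_lists) {
  stopifnot(inherits(model, "redsup_tfidf"))
  out <- matrix(0, length(token_lists), model$D,
                dimnames = list(NULL, model$ngrams))
  for (i in seq_along(token_lists)) {
    g <- doc_ngrams(token_lists[[i]])
    g <- g[g %in% model$ngrams]
    if (!length(g)) next
    tf <- table(g)
    j <- match(names(tf), model$ngrams)
    v <- as.integer(tf) * model$idf[j]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) out[i, j] <- v / nrm
  }
  out
}

new_embedding_table <- function(vectors, source, oov_vector = NULL) {
  if (is.null(oov_vector)) oov_vector <- numeric(ncol(vectors))
  structure(list(vectors = vectors, dim = ncol(vectors), source = source,
                 oov_vector = oov_vector),
            class = "redsup_embedding")
}

#' @export
print.redsup_embedding <- function(x, ...) {
  cat("<redsup_embedding> ", nrow(x$vectors), " tokens, dim ", x$dim,
      " (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Train word embeddings on the in-sample corpus
#'
#' Skip-gram with negative sampling, single-threaded and deterministic given
#' the seed.  Out-of-vocabulary tokens map to the zero vector at lookup
#' time.
#'
#' @param token_lists list of token vectors.
#' @param d embedding dimension (default 100).
#' @param window maximum context window (dynamic, as usual for skip-gram).
#' @param epochs passes over the corpus.
#' @param min_count minimum token frequency to receive a vector.
#' @param negative negative samples per positive pair.
#' @param alpha initial learning rate.
#' @param seed integer seed.
#' @return a `redsup_embedding` table.
#' @export
train_word_embeddings <- function(token_lists, d = 100L, window = 5L,
                                  epochs = 5L, min_count = 1L,
                                  negative = 5L, alpha = 0.025, seed = 1L) {
  lens <- lengths(token_lists)
  if (!length(token_lists) || max(lens) < 2L)
    stop("corpus too small to train embeddings (need documents with at ",
         "least 2 tokens)")
  vocab <- build_vocabulary(token_lists, min_count = min_count)
  tok <- names(vocab$index)
  ids <- stats::setNames(seq_along(tok), tok)  # 1-based, frequency order
  docs <- lapply(token_lists, function(tt) {
    v <- unname(ids[tt])
    as.integer(v[!is.na(v)])
  })
  emb <- cpp_sgns_train(docs, length(tok), as.integer(d), as.integer(window),
                        as.integer(epochs), as.integer(negative), alpha,
                        as.integer(seed))
  rownames(emb) <- tok
  new_embedding_table(emb, source = "trained")
}

#' Load pretrained embeddings from a word-per-line text file
#'
#' Each line holds a token followed by its vector components, whitespace
#' separated.  Tokens missing from the file are mapped to a single fixed
#' random vector drawn once from `oov_seed`.
#'
#' @param path file path.
#' @param oov_seed seed for the shared out-of-vocabulary vector.
#' @return a `redsup_embedding` table.
#' @export
load_pretrained <- function(path, oov_seed = 1L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty embedding file: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop("line 1 of ", path, " has no vector components")
  toks <- character(length(parts))
  m <- matrix(0, length(parts), d)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) - 1L != d)
      stop("inconsistent embedding dimension on line ", i, ": expected ",
           d, ", got ", length(p) - 1L)
    toks[i] <- p[1]
    m[i, ] <- as.numeric(p[-1])
  }
  if (anyDuplicated(toks))
    stop("duplicate token in embedding file: ", toks[duplicated(toks)][1])
  rownames(m) <- toks
  oov <- with_seed_(oov_seed, stats::runif(d, -0.5, 0.5) / d)
  new_embedding_table(m, source = "pretrained", oov_vector = oov)
}

#' Write an embedding table in word-per-line text format
#'
#' @param table a `redsup_embedding`.
#' @param path output path.
#' @export
write_embeddings <- function(table, path) {
  stopifnot(inherits(table, "redsup_embedding"))
  v <- table$vectors
  lines <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], formatC(v[i, ], format = "g", digits = 8)),
          collapse = " "), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Look up per-token embedding vectors
#'
#' @param tokens character vector.
#' @param table a `redsup_embedding`.
#' @return matrix `length(tokens)` x `table$dim`; unknown tokens get the
#'   table's OOV vector.
#' @export
embed_tokens <- function(tokens, table) {
  stopifnot(inherits(table, "redsup_embedding"))
  out <- matrix(rep(table$oov_vector, each = length(tokens)),
                nrow = length(tokens))
  hit <- tokens %in% rownames(table$vectors)
  if (any(hit)) out[hit, ] <- table$vectors[tokens[hit], , drop = FALSE]
  out
}

#' Mean-pooled document vectors from an embedding table
#'
#' @param token_lists list of token vectors.
#' @param table a `redsup_embedding` or `redsup_char_embedding`.
#' @return matrix, one row per document (zero vector for empty documents).
#' @export
doc_embedding_mean <- function(token_lists, table) {
  d <- table$dim
  out <- matrix(0, length(token_lists), d)
  for (i in seq_along(token_lists)) {
    tt <- token_lists[[i]]
    if (!length(tt)) next
    m <- if (inherits(table, "redsup_char_embedding"))
      char_embed(tt, table) else embed_tokens(tt, table)
    out[i, ] <- colMeans(m)
  }
  out
}

#' Character embedding table
#'
#' A fixed random vector per character (letters, digits and the retained
#' punctuation).  Token vectors are the mean of their character vectors, so
#' the representation is robust to slang variants and misspellings that
#' share most characters; its dimension equals the word-embedding dimension
#' so the two can be concatenated position-wise.
#'
#' @param d token-level output dimension (default 100).
#' @param seed integer seed for the character vectors.
#' @return object of class `redsup_char_embedding`.
#' @export
char_embedding_table <- function(d = 100L, seed = 1L) {
  chars <- c(letters, as.character(0:9), "'", ".", ",", "!", "?")
  m <- with_seed_(seed,
                  matrix(stats::runif(length(chars) * d, -0.5, 0.5) /
                           sqrt(d), length(chars), d))
  rownames(m) <- chars
  structure(list(vectors = m, dim = d, chars = chars),
            class = "redsup_char_embedding")
}

#' Character-derived token vectors
#'
#' @param tokens character vector.
#' @param table a [char_embedding_table()].
#' @return matrix `length(tokens)` x `table$dim`: mean of the character
#'   vectors of each token (characters outside the table contribute zero
#'   vectors).
#' @export
char_embed <- function(tokens, table) {
  stopifnot(inherits(table, "redsup_char_embedding"))
  out <- matrix(0, length(tokens), table$dim)
  for (i in seq_along(tokens)) {
    ch <- strsplit(tokens[i], "", fixed = TRUE)[[1]]
    if (!length(ch)) next
    hit <- ch[ch %in% table$chars]
    v <- matrix(0, length(ch), table$dim)
    if (length(hit)) {
      idx <- which(ch %in% table$chars)
      v[idx, ] <- table$vectors[ch[idx], , drop = FALSE]
    }
    out[i, ] <- colMeans(v)
  }
  out
}

# char2vec vectors for every vocabulary id 0..V-1 (pad and oov rows zero);
# used as the fixed character channel of the sequence models
char_matrix_for_vocab <- function(vocab, char_table) {
  tok <- names(vocab$index)
  m <- matrix(0, length(tok) + 2L, char_table$dim)
  if (length(tok)) m[vocab$index + 1L, ] <- char_embed(tok, char_table)
  m
}

#' Assemble the per-position input sequence for the neural models
#'
#' One row per token position: the word vector, concatenated with the
#' character-derived token vector when a character table is supplied — the
#' same position-wise layout the sequence classifiers consume internally.
#'
#' @param tokens character vector of tokens.
#' @param embeddings a `redsup_embedding`.
#' @param char_table optional [char_embedding_table()] (its dimension must
#'   equal the word dimension).
#' @return matrix `length(tokens)` x `d` (or `2d` with characters).
#' @export
assemble_sequence <- function(tokens, embeddings, char_table = NULL) {
  out <- embed_tokens(tokens, embeddings)
  if (!is.null(char_table)) {
    stopifnot(char_table$dim == embeddings$dim)
    out <- cbind(out, char_embed(tokens, char_table))
  }
  out
}

#' Assemble a document-level feature matrix for the traditional classifiers
#'
#' Concatenates, per the requested combination: the TF-IDF vector, the
#' mean-pooled word-embedding vector (trained or pretrained), and the
#' mean-pooled character-derived token vector.
#'
#' @param token_lists list of token vectors.
#' @param combination one of [feature_combinations()].
#' @param tfidf a fitted `redsup_tfidf` (required when the combination
#'   includes TFIDF).
#' @param embeddings a `redsup_embedding` (required for W2V/GLOVE).
#' @param char_table a [char_embedding_table()] (required for CHAR2VEC).
#' @return dense numeric matrix, one row per document.
#' @export
assemble_documents <- function(token_lists, combination, tfidf = NULL,
                               embeddings = NULL, char_table = NULL) {
  cmb <- parse_combination(combination)
  parts <- list()
  if (cmb$tfidf) {
    if (is.null(tfidf)) stop(combination, " requires a fitted TF-IDF model")
    parts$tfidf <- tfidf_transform(tfidf, token_lists)
  }
  if (cmb$w2v || cmb$glove) {
    if (is.null(embeddings))
      stop(combination, " requires an embedding table")
    parts$emb <- doc_embedding_mean(token_lists, embeddings)
  }
  if (cmb$char) {
    if (is.null(char_table))
      stop(combination, " requires a character embedding table")
    parts$char <- doc_embedding_mean(token_lists, char_table)
  }
  if (!length(parts)) stop("combination selects no features: ", combination)
  do.call(cbind, unname(parts))
}
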