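#' Detect collocation bigrams
#'
#' Scores every adjacent token pair with the pointwise collocation score
#' `(count(ab) - delta) * N / (count(a) * count(b))` where `N` is the total
#' token count and `delta = min_count` discounts rare pairs; pairs scoring
#' at or above `threshold` are merged into a single `a_b` token by
#' [apply_phrases()].
#'
#' @param token_lists list of token vectors.
#' @param min_count discount and minimum pair frequency (default 5).
#' @param threshold merge threshold (default 10; `Inf` merges nothing).
#' @return object of class `redsup_phrase_model` with the scored bigram
#'   table.
#' @export
detect_phrases <- function(token_lists, min_count = 5L, threshold = 10) {
  if (!length(token_lists) || !sum(lengths(token_lists)))
    stop("cannot detect phrases in an empty corpus")
  tokens <- unlist(token_lists, use.names = FALSE)
  N <- length(tokens)
  uni <- table(tokens)
  pair_list <- lapply(token_lists, function(tt) {
    n <- length(tt)
    if (n < 2L) return(character(0))
    paste(tt[-n], tt[-1], sep = "\u0001")
  })
  pairs <- table(unlist(pair_list, use.names = FALSE))
  if (length(pairs)) {
    ab <- strsplit(names(pairs), "\u0001", fixed = TRUE)
    a <- vapply(ab, `[`, "", 1L)
    b <- vapply(ab, `[`, "", 2L)
    score <- (as.numeric(pairs) - min_count) * N /
      (as.numeric(uni[a]) * as.numeric(uni[b]))
    bigrams <- data.frame(a = a, b = b, count = as.integer(pairs),
                          score = score, stringsAsFactors = FALSE)
  } else {
    bigrams <- data.frame(a = character(0), b = character(0),
                          count = integer(0), score = numeric(0))
  }
  merged <- bigrams[is.finite(bigrams$score) &
                      bigrams$score >= threshold, , drop = FALSE]
  structure(list(bigrams = bigrams, merged = merged,
                 min_count = min_count, threshold = threshold),
            class = "redsup_phrase_model")
}

#' @export
print.redsup_phrase_model <- function(x, ...) {
  cat("<redsup_phrase_model> ", nrow(x$merged), " merged bigrams (of ",
      nrow(x$bigrams), " observed)\n", sep = "")
  invisible(x)
}

#' Merge detected phrases in a token sequence
#'
#' Greedy left-to-right, non-overlapping: whenever a pair of adjacent
#' tokens is in the model's merge set, it becomes a single
#' underscore-joined token.
#'
#' @param tokens character vector.
#' @param model a [detect_phrases()] model.
#' @return character vector with merged bigrams.
#' @export
apply_phrases <- function(tokens, model) {
  stopifnot(inherits(model, "redsup_phrase_model"))
  if (length(tokens) < 2L || !nrow(model$merged)) return(tokens)
  keys <- paste(model$merged$a, model$merged$b, sep = "\u0001")
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (i < n && paste(tokens[i], tokens[i + 1L], sep = "\u0001") %in% keys) {
      out <- c(out, paste(tokens[i], tokens[i + 1L], sep = "_"))
      i <- i + 2L
    } else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

#' Most similar tokens to a query in an embedding table
#'
#' Ranks the vocabulary by cosine similarity to the query vector, excluding
#' the query itself; ties are broken lexicographically.
#'
#' @param table a `redsup_embedding`.
#' @param query query token (default `"suicidal"`).
#' @param k number of neighbors (default 15).
#' @return data frame `rank`, `token`, `similarity`.
#' @export
top_similar <- function(table, query = "suicidal", k = 15L) {
  stopifnot(inherits(table, "redsup_embedding"))
  V <- table$vectors
  if (!(query %in% rownames(V))) {
    d <- utils::adist(query, rownames(V))
    near <- rownames(V)[order(d)][seq_len(min(3L, nrow(V)))]
    stop("query token '", query, "' is not in the vocabulary; nearest ",
         "matches: ", paste(near, collapse = ", "))
  }
  q <- V[query, ]
  qn <- sqrt(sum(q^2))
  nrm <- sqrt(rowSums(V^2))
  sim <- as.numeric(V %*% q) / (nrm * qn)
  sim[!is.finite(sim)] <- -Inf
  df <- data.frame(token = rownames(V), similarity = sim,
                   stringsAsFactors = FALSE)
  df <- df[df$token != query, , drop = FALSE]
  df <- df[order(-df$similarity, df$token, method = "radix"), , drop = FALSE]
  df <- utils::head(df, k)
  data.frame(rank = seq_len(nrow(df)), token = df$token,
             similarity = df$similarity, stringsAsFactors = FALSE)
}

#' Nearest neighbors of a query in a phrase-merged embedding of predicted
#' posts
#'
#' Convenience wrapper over the content-analysis chain: detect collocation
#' bigrams in the supplied documents (typically the posts one model
#' predicted positive), merge them, train a skip-gram embedding on the
#' merged tokens, and query the top-`k` most similar tokens.
#'
#' @param token_lists list of token vectors.
#' @param query query token.
#' @param k neighbors to return.
#' @param d embedding dimension.
#' @param min_count phrase and embedding frequency floor.
#' @param threshold phrase merge threshold.
#' @param epochs,window,seed embedding training parameters.
#' @return list with `neighbors` (data frame), `phrases` (the phrase
#'   model), and `embeddings`.
#' @export
content_neighbors <- function(token_lists, query = "suicidal", k = 15L,
                              d = 100L, min_count = 5L, threshold = 10,
                              epochs = 5L, window = 5L, seed = 1L) {
  phr <- detect_phrases(token_lists, min_count = min_count,
                        threshold = threshold)
  merged <- lapply(token_lists, apply_phrases, model = phr)
  emb <- train_word_embeddings(merged, d = d, window = window,
                               epochs = epochs, min_count = min_count,
                               seed = seed)
  list(neighbors = top_similar(emb, query = query, k = k),
       phrases = phr, embeddings = emb)
}
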