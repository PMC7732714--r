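#' Normalize raw post text
#'
#' Lowercases, strips URL spans, removes all punctuation except periods,
#' commas, exclamation marks, question marks and apostrophes, and pads the
#' retained punctuation marks with spaces so that each becomes a standalone
#' token.  Apostrophes inside words (contractions such as `"i'm"`) are left
#' attached.  The transformation is idempotent.
#'
#' @param x character vector of raw post texts.
#' @return character vector of cleaned texts.
#' @examples
#' clean_text("See https://example.org NOW!!")
#' @export
clean_text <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- tolower(x)
  # normalize typographic apostrophes before punctuation handling
  x <- gsub("’", "'", x)
  # URL spans: scheme://... or www.... up to the next whitespace
  x <- gsub("(?i)\\b[a-z][a-z0-9+.-]*://\\S+", " ", x, perl = TRUE)
  x <- gsub("(?i)\\bwww\\.\\S+", " ", x, perl = TRUE)
  # drop every punctuation/symbol character except . , ! ? '
  x <- gsub("[^\\p{L}\\p{N}\\s.,!?']", " ", x, perl = TRUE)
  # retained marks become standalone tokens
  x <- gsub("([.,!?])", " \\1 ", x)
  # apostrophes not flanked by word characters are noise, not contractions
  x <- gsub("(?<![\\p{L}\\p{N}])'|'(?![\\p{L}\\p{N}])", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Tokenize cleaned text
#'
#' Splits on whitespace.  Assumes the input went through [clean_text()], so
#' retained punctuation is already space-separated and each mark comes out as
#' its own token while contractions stay whole.
#'
#' @param x a single cleaned text string.
#' @return character vector of tokens (length 0 for empty input).
#' @export
tokenize <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(trimws(x), "\\s+")[[1]]
}

#' Prepend the post title to its body
#'
#' The title is usually a condensed statement of the post's content, so it is
#' joined in front of the body with a single space before any downstream
#' processing.
#'
#' @param title,body character scalars (either may be empty).
#' @return single string.
#' @export
join_title_body <- function(title, body) {
  title <- if (is.null(title) || is.na(title)) "" else title
  body <- if (is.null(body) || is.na(body)) "" else body
  if (!nzchar(title)) return(body)
  if (!nzchar(body)) return(title)
  paste(title, body)
}

#' Count the words of a post
#'
#' Words are whitespace-separated chunks of the raw title+body text;
#' chunks made purely of punctuation do not count.  This is the quantity the
#' 30--500-word evaluation-sampling window is applied to.
#'
#' @param title,body character scalars.
#' @return integer word count.
#' @export
word_count <- function(title, body = "") {
  text <- join_title_body(title, body)
  if (!nzchar(trimws(text))) return(0L)
  chunks <- strsplit(trimws(text), "\\s+")[[1]]
  sum(grepl("[\\p{L}\\p{N}]", chunks, perl = TRUE))
}

#' Build a token-to-index vocabulary
#'
#' Index 0 is reserved for padding and index 1 for out-of-vocabulary tokens.
#' Real tokens are assigned indices from 2 upward by descending corpus
#' frequency, ties broken lexicographically, so the mapping is deterministic.
#'
#' @param token_lists list of character vectors (one per document).
#' @param min_count minimum corpus frequency for a token to be kept.
#' @return object of class `redsup_vocab`: list with `index` (named integer
#'   vector token -> index), `frequency`, and the reserved indices `pad_index`
#'   (0) and `oov_index` (1).
#' @export
build_vocabulary <- function(token_lists, min_count = 1L) {
  stopifnot(is.list(token_lists))
  if (length(token_lists) == 0L) stop("cannot build a vocabulary from an empty corpus")
  tokens <- unlist(token_lists, use.names = FALSE)
  if (length(tokens) == 0L) stop("cannot build a vocabulary from an empty corpus")
  freq <- table(tokens)
  freq <- freq[freq >= min_count]
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  kept <- names(freq)[ord]
  idx <- if (length(kept)) seq_along(kept) + 1L else integer(0)
  names(idx) <- kept
  structure(
    list(index = idx,
         frequency = stats::setNames(as.integer(freq)[ord], kept),
         pad_index = 0L, oov_index = 1L),
    class = "redsup_vocab"
  )
}

#' @export
print.redsup_vocab <- function(x, ...) {
  cat("<redsup_vocab> ", length(x$index),
      " tokens (+ pad 0, oov 1)\n", sep = "")
  invisible(x)
}

#' Vocabulary size including reserved indices
#' @param vocab a `redsup_vocab`.
#' @return integer, number of distinct indices (tokens + pad + oov).
#' @export
vocab_size <- function(vocab) length(vocab$index) + 2L

#' Encode a token sequence to a fixed-length index vector
#'
#' Tokens are mapped through the vocabulary (unknown tokens to the OOV
#' index), truncated to the first `L` positions, and right-padded with the
#' padding index 0 to length exactly `L`.
#'
#' @param tokens character vector of tokens.
#' @param vocab a `redsup_vocab`.
#' @param L target length (default 1500, the full-post window).
#' @return integer vector of length `L`.
#' @export
encode <- function(tokens, vocab, L = 1500L) {
  stopifnot(inherits(vocab, "redsup_vocab"), L >= 1L)
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- vocab$oov_index
  n <- min(length(idx), L)
  out <- integer(L)
  if (n > 0L) out[seq_len(n)] <- idx[seq_len(n)]
  out
}

#' Encode a corpus into an integer matrix
#'
#' Convenience wrapper applying [clean_text()], [tokenize()] and [encode()]
#' to each post's joined title+body.
#'
#' @param posts a posts data frame (see [read_corpus()]).
#' @param vocab a `redsup_vocab`.
#' @param L sequence length.
#' @return integer matrix with one row per post, `rownames` = post ids.
#' @export
encode_corpus <- function(posts, vocab, L = 1500L) {
  toks <- corpus_tokens(posts)
  m <- vapply(toks, encode, integer(L), vocab = vocab, L = L)
  m <- t(matrix(m, nrow = L))
  rownames(m) <- posts$id
  m
}

#' Tokenized title+body for each post
#'
#' @param posts posts data frame.
#' @return named list of token vectors (names = post ids).
#' @export
corpus_tokens <- function(posts) {
  texts <- mapply(join_title_body, posts$title, posts$body,
                  USE.NAMES = FALSE)
  toks <- lapply(clean_text(texts), tokenize)
  names(toks) <- posts$id
  toks
}

#' Serialize / load a vocabulary as TSV
#'
#' Three columns: token, index, frequency.  Reserved indices are implicit.
#'
#' @param vocab a `redsup_vocab`.
#' @param path file path.
#' @return `read_vocabulary` returns a `redsup_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- data.frame(token = names(vocab$index),
                   index = unname(vocab$index),
                   frequency = unname(vocab$frequency[names(vocab$index)]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  idx <- stats::setNames(as.integer(df$index), df$token)
  structure(
    list(index = idx,
         frequency = stats::setNames(as.integer(df$frequency), df$token),
         pad_index = 0L, oov_index = 1L),
    class = "redsup_vocab"
  )
}
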