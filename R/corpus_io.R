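#' Default community-to-group map
#'
#' The four experiment groups and the communities mapped into them: the
#' suicide-watch community, the depression community, eight opioid-related
#' communities (active use, recovery, and specific substances), and a diverse
#' 20-community control set chosen to model ordinary, mentally healthy
#' language.  The map is configuration, not code: pass your own named list to
#' [read_corpus()] to extend it.
#'
#' @return named list of character vectors, names are the groups
#'   `control`, `suicidewatch`, `depression`, `opiates`.
#' @export
default_group_map <- function() {
  list(
    depression = "depression",
    suicidewatch = "suicidewatch",
    control = c("askdocs", "askscience", "books", "careerguidance",
                "fitness", "frugal", "jokes", "lifeprotips", "offmychest",
                "parenting", "personalfinance", "productivity",
                "randomkindess", "relationships", "showerthoughts",
                "talesfromretail", "theoryofreddit", "wholesometextposts",
                "writing", "youshouldknow"),
    opiates = c("benzodiazepines", "benzorecovery", "heroin", "methadone",
                "opiates", "opiatesrecovery", "quittingkratom", "suboxone")
  )
}

#' Resolve a community name to its experiment group
#'
#' A pure function of the community name; communities not present in the map
#' resolve to `"unassigned"`.
#'
#' @param community character vector of community names.
#' @param group_map named list of character vectors (see
#'   [default_group_map()]).
#' @return character vector of group names.
#' @export
assign_group <- function(community, group_map = default_group_map()) {
  all_comms <- unlist(group_map, use.names = FALSE)
  if (anyDuplicated(all_comms))
    stop("group map is not disjoint: ",
         paste(unique(all_comms[duplicated(all_comms)]), collapse = ", "))
  lookup <- rep(names(group_map), lengths(group_map))
  names(lookup) <- all_comms
  out <- unname(lookup[community])
  out[is.na(out)] <- "unassigned"
  out
}

post_fields <- c("id", "community", "author", "title", "body", "created")

validate_posts <- function(posts) {
  stopifnot(is.data.frame(posts))
  missing <- setdiff(post_fields, names(posts))
  if (length(missing))
    stop("posts are missing fields: ", paste(missing, collapse = ", "))
  if (anyDuplicated(posts$id))
    stop("duplicate post id: ", posts$id[duplicated(posts$id)][1])
  both_empty <- !nzchar(posts$title) & !nzchar(posts$body)
  if (any(both_empty))
    stop("post ", posts$id[both_empty][1], " has empty title and empty body")
  invisible(posts)
}

#' Read a JSON Lines corpus
#'
#' One post per line with fields `id`, `community`, `author`, `title`,
#' `body`, `created` (epoch seconds).  Every post gets a `group` column
#' resolved through the map; posts whose community is not in the map are kept
#' and flagged `"unassigned"` rather than dropped.
#'
#' @param path path to a JSON Lines file.
#' @param group_map named list mapping groups to community vectors.
#' @return data frame with the post fields plus `group`.
#' @export
read_corpus <- function(path, group_map = default_group_map()) {
  if (!file.exists(path)) stop("corpus file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- data.frame(id = character(0), community = character(0),
                      author = character(0), title = character(0),
                      body = character(0), created = integer(0),
                      group = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e)
                      stop("malformed JSON on line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    missing <- setdiff(post_fields, names(rec))
    if (length(missing))
      stop("line ", i, " is missing fields: ",
           paste(missing, collapse = ", "))
    recs[[i]] <- data.frame(
      id = as.character(rec$id), community = as.character(rec$community),
      author = as.character(rec$author %||% ""),
      title = as.character(rec$title), body = as.character(rec$body),
      created = as.integer(rec$created), stringsAsFactors = FALSE)
  }
  posts <- do.call(rbind, recs)
  validate_posts(posts)
  posts$group <- assign_group(posts$community, group_map)
  posts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus as JSON Lines
#'
#' Inverse of [read_corpus()]; the `group` column (a pure function of the
#' community) is not serialized.
#'
#' @param posts posts data frame.
#' @param path output path.
#' @export
write_corpus <- function(posts, path) {
  validate_posts(posts)
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(list(id = posts$id[i], community = posts$community[i],
                          author = posts$author[i], title = posts$title[i],
                          body = posts$body[i],
                          created = posts$created[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read per-post prediction records
#'
#' Scores follow the pipeline's orientation convention: a score near 0 means
#' the positive (risk) class, a score near 1 the negative class, and
#' `predicted_class` is 1 when `score < 0.5`.  Scores are stored at 6
#' decimals and round-trip losslessly at that precision.
#'
#' @param records data frame with columns `id`, `score`, and optionally
#'   `true_label`.
#' @param path CSV path.
#' @return `read_predictions` returns the records data frame.
#' @export
write_predictions <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "score") %in% names(records)))
  if (nrow(records) && (any(records$score < 0) || any(records$score > 1)))
    stop("prediction scores must lie in [0, 1]")
  out <- data.frame(id = records$id,
                    score = sprintf("%.6f", records$score),
                    predicted_class = as.integer(records$score < 0.5),
                    stringsAsFactors = FALSE)
  if (!nrow(records))
    out <- data.frame(id = character(0), score = character(0),
                      predicted_class = integer(0))
  if ("true_label" %in% names(records))
    out$true_label <- records$true_label
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  df$score <- as.numeric(df$score)
  df
}
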