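# Shared fixtures: small corpora built in code at test time.

small_corpus <- function(seed = 1L, n = 50L, sep = 0.7, ...) {
  generate_corpus(generator_config(
    seed = seed,
    n_posts_per_group = c(control = n, suicidewatch = n,
                          depression = n, opiates = n),
    separability = sep, ...))
}

# four tiny fully disjoint lexicons (and disjoint from the keyword lists),
# for tests that need exact control over which words can occur where
toy_lexicons <- function() {
  w <- function(x) stats::setNames(rep(1, length(x)), x)
  list(
    suicidal = w(c("hopelessx", "despairx", "darknessx", "burdenx",
                   "emptyx")),
    opioid = w(c("dopex", "nodx", "scorex", "stashx", "habitx")),
    withdrawal = w(c("detoxx", "sweatsx", "cravingx", "relapsex")),
    control = w(c("gardenx", "recipex", "budgetx", "workoutx", "bookx",
                  "coffeex", "weekendx")),
    negative = w(c("angryx", "messx", "stressx"))
  )
}

# posts data frame built directly from texts (no generator involved)
posts_from_texts <- function(texts, titles = NULL, community = "opiates") {
  n <- length(texts)
  data.frame(id = sprintf("t%04d", seq_len(n)),
             community = rep_len(community, n),
             author = "a", title = titles %||% rep("", n),
             body = texts, created = 0L,
             group = assign_group(rep_len(community, n)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Box 1 worked example: raw post text and its expected processed forms
box1_raw <- paste("Question. What's the best otc med to OD on?",
                  "I'm so over the day to day grind.",
                  "I'm a failure at life and ready to check out...")
box1_clean <- paste("question . what's the best otc med to od on ?",
                    "i'm so over the day to day grind .",
                    "i'm a failure at life and ready to check out . . .")
box1_tokens <- c("question", ".", "what's", "the", "best", "otc", "med",
                 "to", "od", "on", "?", "i'm", "so", "over", "the", "day",
                 "to", "day", "grind", ".", "i'm", "a", "failure", "at",
                 "life", "and", "ready", "to", "check", "out", ".", ".",
                 ".")
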