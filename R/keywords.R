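#' Default keyword lists for the two transfer cases
#'
#' `keywords_c1()` returns the suicide-related key phrases used when sampling
#' opioid-community posts for evaluation; `keywords_c2()` returns the
#' drug-related keywords used when sampling suicide-watch posts.  Matching is
#' done on cleaned tokens, case-insensitively, with multi-word phrases
#' requiring a contiguous token sequence (see [contains_keyword()]).
#'
#' The C1 entry `"want to do"` is preserved verbatim from the source
#' configuration; `"want to od"` is a plausible intended variant and can be
#' supplied by the caller instead.
#'
#' @return character vector of keywords/phrases.
#' @export
keywords_c1 <- function() {
  c("commit suicide", "suicide", "suicidality", "suicidal",
    "want to die", "want to do", "want to overdose")
}

#' @rdname keywords_c1
#' @export
keywords_c2 <- function() {
  c("benzodiazepines", "benzos", "cocaine", "codeine", "fentanyl",
    "heroin", "hydrocodine", "hydrocodone", "hydromorphone", "hydros",
    "kratom", "methadone", "morphine", "narcotic", "narcotics", "opiates",
    "opioid", "oxycodone", "oxycontin", "oxycottin", "oxycotton",
    "oxymorphone", "suboxone")
}
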