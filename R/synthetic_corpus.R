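#' Default topic lexicons for the synthetic corpus generator
#'
#' Five weighted word lists drive word emission: `suicidal` (ideation and
#' despair vocabulary), `opioid` (drug names, dosing, use), `withdrawal`
#' (recovery, relapse, withdrawal symptoms — including the joy register of
#' clean-time milestones, so the opioid group mixes sentiments), `control`
#' (diverse everyday vocabulary plus function words), and `negative`
#' (profanity and negative affect common to distressed posts of any kind).
#' Weights are relative sampling frequencies within a topic.
#'
#' @return named list of numeric vectors; names of each vector are the words.
#' @export
default_lexicons <- function() {
  w <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }
  list(
    suicidal = w(
      suicide = 4, suicidal = 4, die = 5, dying = 2, death = 3, end = 4,
      ending = 2, kill = 3, overdose = 3, od = 2, pain = 4, hopeless = 4,
      worthless = 3, burden = 3, alone = 4, empty = 3, tired = 4,
      exhausted = 2, goodbye = 2, note = 2, rope = 1, pills = 2,
      courage = 2, attempt = 2, cutting = 1, harm = 2, crying = 3,
      pointless = 2, darkness = 2, numb = 3, grieving = 1, failure = 3,
      ashamed = 2, trapped = 2, escape = 2, anymore = 4, nothing = 4,
      nobody = 3, cares = 2, ready = 2, peace = 2, depressed = 4,
      depression = 3, anxiety = 3, therapy = 2, meds = 2, insomnia = 2,
      ptsd = 1, bipolar = 1, diagnosed = 2, severe = 2, irritable = 1,
      paranoid = 1, isolated = 2, unbearable = 2, thoughts = 3
    ),
    opioid = w(
      heroin = 4, dope = 4, oxy = 3, oxycodone = 2, hydrocodone = 2,
      hydros = 2, percs = 2, fentanyl = 3, fent = 2, methadone = 2,
      suboxone = 3, subs = 2, kratom = 2, benzos = 2, morphine = 2,
      codeine = 1, opiates = 4, opioid = 2, tolerance = 3, dose = 4,
      dosing = 2, mg = 5, bag = 2, shot = 2, snort = 2, nod = 3,
      nodding = 2, high = 5, rush = 2, plug = 2, dealer = 3, score = 2,
      cop = 2, stash = 2, habit = 3, grams = 2, needle = 2, vein = 1,
      iv = 2, pills = 3, script = 2, pharmacy = 2, refill = 1, euphoria = 2,
      potent = 1, batch = 2, cut = 1, taper = 2
    ),
    withdrawal = w(
      withdrawal = 4, withdrawals = 2, paws = 2, clean = 4, sober = 4,
      sobriety = 2, relapse = 4, relapsed = 2, recovery = 3, rehab = 2,
      detox = 3, cold = 2, turkey = 2, sweats = 2, shakes = 2, nausea = 2,
      nauseous = 1, restless = 2, legs = 2, aches = 2, craving = 3,
      cravings = 2, days = 4, weeks = 3, months = 3, milestone = 1,
      proud = 2, finally = 3, free = 2, grateful = 2, meetings = 2,
      sponsor = 1, program = 2, quit = 3, quitting = 2, jump = 1,
      kicked = 1, fighting = 2
    ),
    control = w(
      the = 10, a = 8, and = 8, to = 8, of = 6, `in` = 5, it = 5, is = 5,
      that = 4, `for` = 4, on = 4, with = 4, was = 4, but = 3, have = 3,
      you = 4, we = 3, they = 3, this = 3, what = 2, when = 2, how = 2,
      work = 3, job = 3, book = 3, books = 2, reading = 2, recipe = 2,
      garden = 2, money = 3, savings = 2, budget = 3, career = 2,
      interview = 2, workout = 2, running = 2, training = 2, movie = 2,
      game = 2, weekend = 3, family = 3, kids = 2, dog = 2, cat = 2,
      house = 2, apartment = 2, car = 2, coffee = 3, dinner = 2,
      question = 2, advice = 3, thanks = 3, funny = 2, joke = 2,
      shower = 1, thought = 2, science = 2, study = 2, learn = 2,
      project = 2, team = 2, city = 2, travel = 2, trip = 2, great = 3,
      good = 4, nice = 2, today = 3, tomorrow = 2, morning = 2
    ),
    negative = w(
      fucking = 4, fuck = 3, shit = 4, damn = 2, hate = 4, angry = 3,
      anger = 2, pissed = 2, sick = 4, awful = 3, terrible = 3, worst = 3,
      miserable = 3, broke = 2, lost = 3, wasted = 2, ruined = 2,
      stupid = 2, useless = 2, screwed = 2, crap = 2, hell = 3, mess = 2,
      stress = 3, stressed = 2, tired = 2, done = 3, over = 2
    )
  )
}

first_person_singular <- c("i", "i'm", "me", "my", "myself", "i've", "i'll")

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates four community groups with group-specific
#' vocabularies and known latent risk flags, so every downstream stage can be
#' tested against ground truth.  Each post samples a topic mixture
#' conditioned on its group and latent flags, then emits words from the
#' weighted lexicons; suicidal/opioid posts additionally receive a key phrase
#' from the corresponding keyword list at rate `keyword_rate`.
#'
#' @param seed integer RNG seed; the same config is guaranteed to produce a
#'   byte-identical corpus.
#' @param n_posts_per_group named integer vector over the four groups.
#' @param length_distribution list with `min_words`, `max_words`, `mean`,
#'   `dispersion` (log-normal sd on the log scale) for body word counts.
#'   Defaults span the 30--1500-word range with some posts shorter than 30,
#'   so the evaluation sampler's word-count window is exercised.
#' @param lexicons named list of weighted word lists (see
#'   [default_lexicons()]).
#' @param intersection_rate_opiates fraction of opiates-group posts that also
#'   carry suicidal content.
#' @param intersection_rate_sw fraction of suicide-watch posts that also
#'   carry opioid content.
#' @param depression_suicidal_rate fraction of depression-group posts whose
#'   latent suicidal flag is true.
#' @param control_contamination_rate fraction of control posts carrying
#'   suicidal content (default 0: control communities are assumed mentally
#'   healthy).
#' @param separability scalar in (0, 1]: weight of the group's signature
#'   topics in the emission mixture; the remainder comes from the shared
#'   control vocabulary.  As it approaches 1 the groups become lexically
#'   disjoint (given disjoint lexicons) and the Bayes error of group
#'   classification approaches 0.
#' @param pronoun_shift extra per-slot probability of emitting a first-person
#'   singular pronoun in suicide-watch/depression posts, reflecting the
#'   elevated first-person singular usage reported for suicidal language.
#' @param keyword_rate probability that a post with a latent flag receives an
#'   inserted key phrase from the matching keyword list.
#' @return object of class `redsup_generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_posts_per_group = c(control = 1000L, suicidewatch = 1000L,
                          depression = 1000L, opiates = 1000L),
    length_distribution = list(min_words = 15L, max_words = 1500L,
                               mean = 120, dispersion = 0.7),
    lexicons = default_lexicons(),
    intersection_rate_opiates = 0.15,
    intersection_rate_sw = 0.10,
    depression_suicidal_rate = 0.25,
    control_contamination_rate = 0,
    separability = 0.7,
    pronoun_shift = 0.08,
    keyword_rate = 0.6) {
  rates <- c(intersection_rate_opiates, intersection_rate_sw,
             depression_suicidal_rate, control_contamination_rate,
             pronoun_shift, keyword_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            separability > 0, separability <= 1,
            length_distribution$min_words >= 1,
            length_distribution$min_words < length_distribution$max_words,
            all(c("suicidal", "opioid", "withdrawal", "control",
                  "negative") %in% names(lexicons)))
  for (nm in names(lexicons))
    if (length(lexicons[[nm]]) == 0L)
      stop("lexicon for topic '", nm, "' is empty")
  groups <- c("control", "suicidewatch", "depression", "opiates")
  stopifnot(all(groups %in% names(n_posts_per_group)))
  structure(
    list(seed = as.integer(seed),
         n_posts_per_group = n_posts_per_group[groups],
         length_distribution = length_distribution,
         lexicons = lexicons,
         intersection_rate_opiates = intersection_rate_opiates,
         intersection_rate_sw = intersection_rate_sw,
         depression_suicidal_rate = depression_suicidal_rate,
         control_contamination_rate = control_contamination_rate,
         separability = separability,
         pronoun_shift = pronoun_shift,
         keyword_rate = keyword_rate),
    class = "redsup_generator_config")
}

with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

sample_weighted <- function(lexicon, n) {
  names(lexicon)[sample.int(length(lexicon), n, replace = TRUE,
                            prob = lexicon)]
}

# topic mixture over lexicons for one post, given group and latent flags
topic_mixture <- function(group, suicidal, opioid, sep) {
  sig <- switch(group,
    control = c(control = 1),
    suicidewatch = c(suicidal = 0.85, negative = 0.15),
    depression = c(suicidal = 0.45, negative = 0.55),
    opiates = c(opioid = 0.60, withdrawal = 0.25, negative = 0.15))
  # latent flags pull in the other condition's vocabulary regardless of group
  if (suicidal && group %in% c("control", "opiates"))
    sig <- c(sig * 0.6, suicidal = 0.4 * sum(sig))
  if (opioid && group %in% c("suicidewatch", "depression"))
    sig <- c(sig * 0.6, opioid = 0.4 * sum(sig))
  sig <- c(tapply(sig, names(sig), sum))
  mix <- sig / sum(sig) * sep
  base <- if ("control" %in% names(mix)) mix[["control"]] else 0
  mix[["control"]] <- base + (1 - sep)
  mix[mix > 0]
}

emit_words <- function(n, mix, lexicons, pronoun_rate) {
  if (n <= 0L) return(character(0))
  topics <- names(mix)[sample.int(length(mix), n, replace = TRUE, prob = mix)]
  words <- character(n)
  for (tp in unique(topics)) {
    sel <- topics == tp
    words[sel] <- sample_weighted(lexicons[[tp]], sum(sel))
  }
  if (pronoun_rate > 0) {
    pron <- stats::runif(n) < pronoun_rate
    words[pron] <- first_person_singular[
      sample.int(length(first_person_singular), sum(pron), replace = TRUE)]
  }
  words
}

insert_phrase <- function(words, phrase) {
  ptoks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  pos <- sample.int(length(words) + 1L, 1L)
  append(words, ptoks, after = pos - 1L)
}

punctuate <- function(words) {
  n <- length(words)
  if (n == 0L) return("")
  out <- character(0)
  i <- 1L
  while (i <= n) {
    len <- sample(6:14, 1L)
    j <- min(n, i + len - 1L)
    mark <- sample(c(".", ".", ".", "!", "?"), 1L)
    out <- c(out, words[i:j], mark)
    i <- j + 1L
  }
  paste(out, collapse = " ")
}

#' Generate a synthetic Reddit-style corpus with known latent truth
#'
#' @param config a [generator_config()].
#' @return list with `posts` (data frame as from [read_corpus()]) and
#'   `truth` (data frame `post_id`, `is_suicidal`, `is_opioid`).  Latent
#'   flags are assigned before the community, so intersection posts exist in
#'   both directions.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "redsup_generator_config"))
  gm <- default_group_map()
  ld <- config$length_distribution
  with_seed_(config$seed, {
    n_total <- sum(config$n_posts_per_group)
    col_id <- col_comm <- col_author <- col_title <- col_body <-
      character(n_total)
    col_created <- integer(n_total)
    col_suicidal <- col_opioid <- logical(n_total)
    k <- 0L
    for (group in names(config$n_posts_per_group)) {
      n <- config$n_posts_per_group[[group]]
      if (n == 0L) next
      is_suicidal <- switch(group,
        control = stats::runif(n) < config$control_contamination_rate,
        suicidewatch = rep(TRUE, n),
        depression = stats::runif(n) < config$depression_suicidal_rate,
        opiates = stats::runif(n) < config$intersection_rate_opiates)
      is_opioid <- switch(group,
        control = rep(FALSE, n),
        suicidewatch = stats::runif(n) < config$intersection_rate_sw,
        depression = rep(FALSE, n),
        opiates = rep(TRUE, n))
      lens <- pmin(ld$max_words, pmax(ld$min_words, round(stats::rlnorm(
        n, meanlog = log(ld$mean) - ld$dispersion^2 / 2,
        sdlog = ld$dispersion))))
      comms <- gm[[group]][sample.int(length(gm[[group]]), n, replace = TRUE)]
      for (i in seq_len(n)) {
        k <- k + 1L
        mix <- topic_mixture(group, is_suicidal[i], is_opioid[i],
                             config$separability)
        pr <- if (group %in% c("suicidewatch", "depression") ||
                  is_suicidal[i]) config$pronoun_shift else 0
        body_words <- emit_words(lens[i], mix, config$lexicons, pr)
        if (is_suicidal[i] && stats::runif(1) < config$keyword_rate) {
          kw <- keywords_c1()
          body_words <- insert_phrase(body_words,
                                      kw[sample.int(length(kw), 1L)])
        }
        if (is_opioid[i] && stats::runif(1) < config$keyword_rate) {
          kw <- keywords_c2()
          body_words <- insert_phrase(body_words,
                                      kw[sample.int(length(kw), 1L)])
        }
        title_words <- emit_words(sample(3:8, 1L), mix, config$lexicons, pr)
        col_id[k] <- sprintf("p%06d", k)
        col_comm[k] <- comms[i]
        col_author[k] <- sprintf("user%04d", sample.int(5000L, 1L))
        col_title[k] <- paste(title_words, collapse = " ")
        col_body[k] <- punctuate(body_words)
        col_created[k] <- as.integer(stats::runif(1, 1496275200,
                                                  1529884800))
        col_suicidal[k] <- is_suicidal[i]
        col_opioid[k] <- is_opioid[i]
      }
    }
    posts <- data.frame(id = col_id, community = col_comm,
                        author = col_author, title = col_title,
                        body = col_body, created = col_created,
                        stringsAsFactors = FALSE)
    posts$group <- assign_group(posts$community, gm)
    truth <- data.frame(post_id = col_id, is_suicidal = col_suicidal,
                        is_opioid = col_opioid, stringsAsFactors = FALSE)
    list(posts = posts, truth = truth)
  })
}

#' Configuration for simulated annotators
#'
#' Models a panel of independent crowd workers: each annotator marks a post
#' positive with probability `sensitivity` when the relevant latent flag is
#' true and with probability `1 - specificity` when it is false, independently
#' across posts and annotators.
#'
#' @param n_annotators number of annotators per post (default 3).
#' @param sensitivity,specificity per-annotator accuracy rates in \[0, 1\].
#' @param seed integer RNG seed.
#' @return object of class `redsup_annotator_config`.
#' @export
annotator_config <- function(n_annotators = 3L, sensitivity = 0.8,
                             specificity = 0.8, seed = 1L) {
  stopifnot(n_annotators >= 1L,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  structure(list(n_annotators = as.integer(n_annotators),
                 sensitivity = sensitivity, specificity = specificity,
                 seed = as.integer(seed)),
            class = "redsup_annotator_config")
}

#' Simulate noisy annotator votes for each post
#'
#' @param posts posts data frame.
#' @param truth latent truth data frame (`post_id`, `is_suicidal`,
#'   `is_opioid`), covering every post.
#' @param config an [annotator_config()].
#' @param question which latent flag the annotators are asked about:
#'   `"suicide_risk"` or `"opioid_addiction"`.
#' @return data frame with `post_id` and one 0/1 column per annotator
#'   (`vote1` ... `voteN`).
#' @export
simulate_annotations <- function(posts, truth, config,
                                 question = c("suicide_risk",
                                              "opioid_addiction")) {
  stopifnot(inherits(config, "redsup_annotator_config"))
  question <- match.arg(question)
  flag_col <- if (question == "suicide_risk") "is_suicidal" else "is_opioid"
  m <- match(posts$id, truth$post_id)
  if (anyNA(m))
    stop("latent truth missing for posts: ",
         paste(utils::head(posts$id[is.na(m)], 3), collapse = ", "))
  flag <- truth[[flag_col]][m]
  n <- length(flag)
  with_seed_(config$seed, {
    p <- ifelse(flag, config$sensitivity, 1 - config$specificity)
    votes <- matrix(stats::rbinom(n * config$n_annotators, 1L,
                                  rep(p, config$n_annotators)),
                    nrow = n)
    out <- data.frame(post_id = posts$id, stringsAsFactors = FALSE)
    for (j in seq_len(config$n_annotators))
      out[[paste0("vote", j)]] <- votes[, j]
    out
  })
}

#' Summarize a (possibly annotated) corpus
#'
#' Reports post counts per group, word-count quantiles, prevalence of the C1
#' and C2 keyword lists, and — when annotations are supplied — the empirical
#' pairwise agreement between annotators (fraction of posts on which the two
#' votes coincide, for every pair).
#'
#' @param posts posts data frame.
#' @param truth optional latent truth data frame.
#' @param annotations optional votes data frame from
#'   [simulate_annotations()].
#' @return list of summary components.
#' @export
corpus_report <- function(posts, truth = NULL, annotations = NULL) {
  wc <- mapply(word_count, posts$title, posts$body, USE.NAMES = FALSE)
  rep <- list(
    n_posts = nrow(posts),
    posts_per_group = table(posts$group),
    word_count_quantiles = stats::quantile(
      wc, c(0, 0.25, 0.5, 0.75, 0.9, 1)),
    keyword_prevalence = c(
      c1 = mean(contains_keyword(posts, keywords_c1())),
      c2 = mean(contains_keyword(posts, keywords_c2()))))
  if (!is.null(truth)) {
    m <- match(posts$id, truth$post_id)
    rep$latent_rates <- c(suicidal = mean(truth$is_suicidal[m]),
                          opioid = mean(truth$is_opioid[m]))
  }
  if (!is.null(annotations)) {
    vote_cols <- grep("^vote", names(annotations), value = TRUE)
    if (length(vote_cols) >= 2) {
      pairs <- utils::combn(vote_cols, 2)
      agr <- apply(pairs, 2, function(pr)
        mean(annotations[[pr[1]]] == annotations[[pr[2]]]))
      names(agr) <- apply(pairs, 2, paste, collapse = "-")
      rep$pairwise_agreement <- agr
    }
  }
  rep
}

#' Write the latent-truth sidecar file
#'
#' JSON Lines with fields `post_id`, `is_suicidal`, `is_opioid`.
#'
#' @param truth truth data frame.
#' @param path output path.
#' @return `read_truth` returns the truth data frame.
#' @export
write_truth <- function(truth, path) {
  lines <- vapply(seq_len(nrow(truth)), function(i)
    jsonlite::toJSON(list(post_id = truth$post_id[i],
                          is_suicidal = truth$is_suicidal[i],
                          is_opioid = truth$is_opioid[i]),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(post_id = vapply(recs, `[[`, "", "post_id"),
             is_suicidal = vapply(recs, `[[`, TRUE, "is_suicidal"),
             is_opioid = vapply(recs, `[[`, TRUE, "is_opioid"),
             stringsAsFactors = FALSE)
}
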