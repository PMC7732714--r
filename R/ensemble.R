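# Discrete AdaBoost over decision stumps on weak-learner score columns.
# Each round fits the best weighted stump (column, threshold, polarity),
# reweights, and accumulates alpha-weighted votes; per-column contribution
# is the alpha-weighted share attributed to each learner's column.

best_stump <- function(X, y_pm, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xv <- X[ord, j]; yv <- y_pm[ord]; wv <- w[ord]
    # predict +1 for x > thr: err(thr) = sum w[y=+1, x<=thr] + w[y=-1, x>thr]
    cum_pos <- cumsum(wv * (yv == 1))
    total_neg <- sum(wv * (yv == -1))
    cum_neg <- cumsum(wv * (yv == -1))
    # threshold after position i (between xv[i] and xv[i+1]); i = 0 => all +1
    errs <- c(total_neg, cum_pos + (total_neg - cum_neg))
    cand <- c(-Inf, xv)
    keep <- c(TRUE, xv != c(xv[-1], Inf))  # last distinct value per run
    for (flip in c(1, -1)) {
      e <- if (flip == 1) errs else sum(w) - errs
      e[!keep] <- Inf
      i <- which.min(e)
      if (e[i] < best$err)
        best <- list(err = e[i], col = j, thr = cand[i], polarity = flip)
    }
  }
  best
}

stump_predict <- function(stump, X) {
  p <- ifelse(X[, stump$col] > stump$thr, 1, -1)
  p * stump$polarity
}

adaboost_fit <- function(X, y, n_rounds = 50L) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("AdaBoost requires both classes present")
  y_pm <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    st <- best_stump(X, y_pm, w)
    h <- stump_predict(st, X)
    err <- sum(w[h != y_pm])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[t]] <- st; alphas[t] <- alpha
    w <- w * exp(-alpha * y_pm * h)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  structure(list(stumps = stumps, alphas = alphas, p = ncol(X)),
            class = "redsup_adaboost")
}

predict_adaboost <- function(fit, X) {
  agg <- numeric(nrow(X))
  for (t in seq_along(fit$stumps))
    agg <- agg + fit$alphas[t] * stump_predict(fit$stumps[[t]], X)
  as.integer(agg > 0)
}

adaboost_contributions <- function(fit) {
  contrib <- numeric(fit$p)
  for (t in seq_along(fit$stumps))
    contrib[fit$stumps[[t]]$col] <- contrib[fit$stumps[[t]]$col] +
      fit$alphas[t]
  if (sum(contrib) > 0) contrib / sum(contrib) else contrib
}

#' Boost weak learners' probability scores against reference labels
#'
#' Runs discrete adaptive boosting with depth-1 decision stumps over the
#' columns of a weak-learner score matrix.  Each run re-randomizes an 8:2
#' train/test split, and the held-out accuracy is averaged over runs.
#' Per-learner contribution shares are the normalized alpha-weighted
#' attribution to each learner's column, averaged over runs.
#'
#' @param scores matrix of probability scores in \[0, 1\] (rows = posts,
#'   columns = weak learners, column names = learner labels).
#' @param labels reference 0/1 labels (length `nrow(scores)`).
#' @param runs number of shuffled runs (default 5).
#' @param n_rounds boosting rounds (default 50).
#' @param seed integer seed.
#' @return object of class `redsup_ensemble_result`: list with
#'   `mean_accuracy`, `run_accuracies`, `contributions` (shares summing
#'   to 1), `n_rows`.
#' @export
fit_boosted <- function(scores, labels, runs = 5L, n_rounds = 50L,
                        seed = 1L) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) >= 2L, nrow(scores) >= 50L,
            all(scores >= 0 & scores <= 1), !anyNA(scores))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("reference labels are single-class")
  n <- nrow(scores)
  with_seed_(seed, {
    accs <- numeric(runs)
    contribs <- matrix(0, runs, ncol(scores))
    for (r in seq_len(runs)) {
      repeat {  # re-draw in the rare case a split ends up single-class
        idx <- sample(n)
        n_test <- round(0.2 * n)
        test <- idx[seq_len(n_test)]
        train <- idx[(n_test + 1):n]
        if (length(unique(labels[train])) == 2L) break
      }
      fit <- adaboost_fit(scores[train, , drop = FALSE], labels[train],
                          n_rounds = n_rounds)
      pred <- predict_adaboost(fit, scores[test, , drop = FALSE])
      accs[r] <- mean(pred == labels[test])
      contribs[r, ] <- adaboost_contributions(fit)
    }
    contrib <- colMeans(contribs)
    if (sum(contrib) > 0) contrib <- contrib / sum(contrib)
    names(contrib) <- colnames(scores)
    structure(list(mean_accuracy = mean(accs), run_accuracies = accs,
                   contributions = contrib, n_rows = n),
              class = "redsup_ensemble_result")
  })
}

#' @export
print.redsup_ensemble_result <- function(x, ...) {
  cat("<redsup_ensemble_result> mean accuracy ",
      sprintf("%.3f", x$mean_accuracy), " over ",
      length(x$run_accuracies), " runs\n", sep = "")
  invisible(x)
}

#' Boosted-ensemble accuracy across label ratios
#'
#' For each positive-label ratio, resamples the labeled evaluation set with
#' replacement to that ratio (as in [ratio_curve()]) and fits the boosted
#' ensemble on the resample, yielding the ensemble accuracy curve and
#' per-ratio learner contributions.
#'
#' @param scores weak-learner score matrix.
#' @param labels reference 0/1 labels.
#' @param ratios positive ratios to sweep.
#' @param n_rows resample size (default 500).
#' @param runs boosting runs per ratio.
#' @param n_rounds boosting rounds.
#' @param seed integer seed.
#' @return list with `curve` (data frame `ratio`, `mean_accuracy`) and
#'   `results` (per-ratio `redsup_ensemble_result` objects).
#' @export
ratio_ensemble_sweep <- function(scores, labels,
                                 ratios = seq(0.1, 0.9, by = 0.1),
                                 n_rows = 500L, runs = 5L, n_rounds = 50L,
                                 seed = 1L) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg))
    stop("ratio sweep requires both classes present")
  results <- list()
  curve <- list()
  for (k in seq_along(ratios)) {
    r <- ratios[k]
    take <- with_seed_(derive_seed(seed, paste0("ratio", k)), {
      n_pos <- round(r * n_rows)
      c(sample(pos, n_pos, replace = TRUE),
        sample(neg, n_rows - n_pos, replace = TRUE))
    })
    res <- fit_boosted(scores[take, , drop = FALSE], labels[take],
                       runs = runs, n_rounds = n_rounds,
                       seed = derive_seed(seed, paste0("boost", k)))
    results[[as.character(r)]] <- res
    curve[[k]] <- data.frame(ratio = r, mean_accuracy = res$mean_accuracy)
  }
  list(curve = do.call(rbind, curve), results = results)
}
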