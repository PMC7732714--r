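# redsup

Distant supervision for detecting posts that combine **suicidal ideation**
with **opioid misuse** in Reddit-style forum corpora.

Clinically, people with opioid use disorder are at elevated suicide risk,
and the posts where both signals co-occur are the ones worth surfacing —
but no labeled corpus of that intersection exists.  `redsup` implements a
complete, reproducible pipeline built on *distant supervision*: the
community a post was filed under serves as its training label, and
classifiers trained in one context are transferred out of context to find
the intersection.

* **C1** — train *suicide-watch vs. control communities*, predict
  suicidality on opioid-community posts.
* **C2** — train *opioid communities vs. depression*, predict opioid
  misuse on suicide-watch posts.

Because the original communities cannot be redistributed, the package
includes a first-class synthetic corpus generator with known latent truth
(group-conditioned topic mixtures, configurable lexical separability,
intersection rates, first-person pronoun shift, simulated noisy
annotators), so every stage is testable end to end.

## What is inside

| Stage | Functions |
|---|---|
| Corpus I/O (JSON Lines), group maps | `read_corpus`, `write_corpus`, `default_group_map`, `write_predictions` |
| Synthetic corpora + annotators | `generator_config`, `generate_corpus`, `simulate_annotations`, `corpus_report` |
| Preprocessing | `clean_text`, `tokenize`, `join_title_body`, `build_vocabulary`, `encode`, `word_count` |
| Features | `fit_tfidf`, `train_word_embeddings` (skip-gram, compiled), `load_pretrained`, `char_embedding_table`, `assemble_documents` |
| Classifiers | `model_spec`, `train_classifier`, `predict`, `eval_report`, `grid_run` — LR, RF, SVM, FAST, RNN (LSTM), ATTENTION (bi-LSTM + additive attention), CNN; the neural nets are implemented in RcppArmadillo inside the package |
| Transfer cases | `case_config`, `run_case`, `keyword_sample`, `contains_keyword`, `majority_label`, `heuristic_labels`, `stratified_accuracy`, `ratio_curve` |
| Ensemble | `fit_boosted` (AdaBoost over weak-learner scores), `ratio_ensemble_sweep` |
| Content analysis | `detect_phrases`, `apply_phrases`, `top_similar`, `content_neighbors` |
| CLI / config | `redsup_cli` (`exec/redsup`), `derive_seed`, `read_run_config` |

Scores follow one orientation convention everywhere: **a score near 0
means the positive/risk class**; `predicted_class = 1` when
`score < 0.5`.

The model at the core of the transfer experiments is the convolutional
text classifier of the Kim-style single-convolution-layer family: a
learned 100-dimensional embedding (dropout 0.5), parallel convolutions
with filter sizes {3, 8}, ReLU and max-over-time pooling, an optional
TF-IDF side vector concatenated before one dense layer, sigmoid output,
cross-entropy loss, batch size 512, 6 epochs.

## Worked example

```r
library(redsup)

# a synthetic corpus: four community groups, known latent truth
gen <- generate_corpus(generator_config(
  seed = 42,
  n_posts_per_group = c(control = 600, suicidewatch = 600,
                        depression = 600, opiates = 600),
  separability = 0.9))

# C1: train suicide-watch vs control, score the opioid group
res <- run_case(case_config("C1"), gen$posts,
                list(model_spec("LR", "TFIDF", seed = 1)),
                spec_sample = sample_spec(min_words = 10, max_words = 1500),
                L = 200, seed = 1)
preds <- res$predictions[["LR/TFIDF"]]

# compare with the latent truth the generator recorded
truth <- gen$truth$is_suicidal[match(preds$id, gen$truth$post_id)]
unlist(stratified_accuracy(preds$score, as.integer(truth)))
#>                 all_data            positive_only            negative_only
#>                0.8250000                1.0000000                0.7883065
#> predicted_positive_count
#>              209.0000000
```

`positive_only` is the accuracy on the posts whose hidden suicidal flag
is true — the intersection C1 exists to find.  On this corpus the C1
model recovers every one of them (score below 0.5), but it also flags 209
of the 600 opioid-analog posts overall (`negative_only` 0.79): opioid
posts share negative-affect vocabulary with suicidal language, so an
out-of-context classifier over-flags.  That false-positive/false-negative
trade-off between model families is exactly what the stratified
accuracies, the label-ratio curves (`ratio_curve`) and the boosted
ensemble over weak-learner scores (`fit_boosted`) are there to quantify.

## Command line

```sh
redsup generate --seed 7 --out corpus.jsonl --truth truth.jsonl
redsup case --name C1 --corpus corpus.jsonl --truth truth.jsonl \
       --families LR,SVM --out-dir runs/c1 --length 200
redsup sample --corpus corpus.jsonl --name C1 --out manifest.csv
redsup annotate-sim --corpus corpus.jsonl --truth truth.jsonl \
       --question suicide_risk --out votes.csv
```

(The installed script lives at `exec/redsup` inside the package; any
subcommand is also callable in-process via `redsup_cli()`.)

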