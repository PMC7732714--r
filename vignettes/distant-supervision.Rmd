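---
title: "Distant supervision for detecting suicidality and opioid misuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distant supervision for detecting suicidality and opioid misuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the design

People who struggle with opioid use disorder are at elevated risk of
suicidal ideation, and posts that combine both signals are exactly the ones
a surveillance system should surface.  Hand-labeling enough social-media
text to train a classifier for this intersection is impractical, so the
pipeline in `redsup` uses *distant supervision*: the community a post was
filed under stands in for a label.  Posts from a suicide-watch community
are treated as suicidal language, posts from a diverse set of everyday
communities as healthy language, posts from opioid communities as the
language of opioid use, and posts from a depression community as
emotionally similar but drug-free contrast material.

Two transfer experiments build on these proxies:

* **C1** trains suicide-watch versus control, then scores posts from the
  opioid communities.  Low scores flag opioid-community posts whose
  language resembles suicidal language.
* **C2** trains opioid communities versus depression, then scores
  suicide-watch posts, flagging suicidal posts whose language suggests
  opioid misuse.

Because the communities that motivated the design cannot be redistributed,
the package ships a synthetic corpus generator with known latent truth.
All statistical claims verified by the test suite are claims about this
generator's output; the section on limitations discusses what that does
and does not establish.

## The synthetic corpus generator

`generator_config()` / `generate_corpus()` emulate four community groups
with a group-conditioned topic mixture over five weighted lexicons
(suicidal, opioid, withdrawal, everyday/control, negative-affect).  Each
post first draws latent flags — is the author's content suicidal, is it
opioid-related — and only then a community, so intersection posts exist in
both directions and both transfer cases are exercisable.  Key knobs, with
the defaults and why:

* `separability` (default 0.7): the weight of the group's signature topics
  in the emission mixture; the remainder comes from the shared everyday
  vocabulary.  At 1.0 with disjoint lexicons the groups become lexically
  disjoint and the Bayes error of group classification goes to zero, which
  is what the classifier acceptance property relies on (it uses 0.9).
* `intersection_rate_opiates` (0.15) and `intersection_rate_sw` (0.10):
  the fraction of opioid-community posts carrying suicidal content and
  vice versa.  No public estimate exists for these rates; they were chosen
  once as plausible minority fractions and are deliberately asymmetric.
* `depression_suicidal_rate` (0.25): depression-community posts whose
  latent suicidal flag is true; depression language is the nearest
  neighbor of suicidal language, and some of it is suicidal.
* `pronoun_shift` (0.08): extra per-word probability of a first-person
  singular token in suicide-watch and depression posts, reproducing the
  elevated first-person singular usage that corpus studies report for
  suicidal writing.
* `keyword_rate` (0.6): probability that a post with a latent flag
  receives one inserted key phrase from the corresponding screening list
  (the suicide phrases for suicidal posts, the drug terms for opioid
  posts).  At 1.0 with lexicons disjoint from the keyword lists, keyword
  presence recovers the latent opioid flag exactly, which is the
  parameter-recovery check in the test suite.
* `length_distribution`: log-normal body lengths with mean 120 words,
  clamped to 15–1500.  The lower clamp sits *below* the evaluation
  sampler's 30-word floor on purpose, so the word-count window is a real
  filter in tests.
* Posts in the opioid group mix registers — active use, withdrawal misery,
  and clean-time joy — because the real communities span all three; this
  is what makes C1 transfer genuinely hard rather than a vocabulary
  lookup.
* `control_contamination_rate` defaults to 0: the control communities are
  assumed mentally healthy.  No contamination estimate exists, so the
  clean default keeps the ground truth exact; the knob is there for
  robustness experiments.

Simulated annotators (`annotator_config()`, default three per post) vote
independently: a true-positive post is marked positive with probability
`sensitivity`, a negative with probability `1 - specificity`.  Majority
vote of three annotators with sensitivity = specificity = p has accuracy
`3p²(1−p) + p³` and pairwise agreement `p² + (1−p)²`; the tests check both
closed forms.  Correlated annotator errors are out of scope.

## Preprocessing

`clean_text()` lowercases, deletes URL spans (`scheme://…` and `www.…`),
removes all punctuation except periods, commas, exclamation marks,
question marks and apostrophes, and pads the retained marks with spaces so
each becomes its own token; apostrophes stay inside contractions.
Ellipses therefore tokenize as repeated `"."` tokens.  Disallowed
punctuation is replaced by a space rather than deleted outright, so
hyphenated compounds split into their parts instead of fusing.  Cleaning
is idempotent, which the suite asserts on generated text.

Titles are prepended to bodies with a single space before any processing.
The 30–500-word eligibility window for evaluation sampling counts
whitespace-separated words of the *raw* title+body (punctuation-only
chunks excluded) — the conservative reading of a "word" — and the counting
rule is its own function (`word_count()`) so a different convention can be
swapped in.

Vocabulary indices are assigned by descending corpus frequency with
lexicographic tie-breaks, index 0 reserved for padding and 1 for
out-of-vocabulary tokens; the default `min_count` is 1 (no pruning).
`encode()` truncates or zero-pads every document to exactly `L` indices,
default 1500 — long enough to keep entire posts.  Reruns restricted to
long posts are a corpus filter, not a separate pipeline.

## Feature combinations

The grid of document representations mirrors the usual fusion choices for
this kind of classifier comparison:

* **TFIDF** — 100 features over in-sample unigrams+bigrams chosen by
  corpus frequency (lexicographic tie-break), smoothed idf
  `log((1+N)/(1+df)) + 1`, L2-normalized vectors.  The "100-dimension"
  constraint is read as the top-100 max-features idiom; a rank-100 SVD
  would be the alternative reading and is intentionally not the default.
* **W2V** — for the traditional classifiers, mean-pooled skip-gram
  vectors (negative sampling, single-threaded, deterministic per seed)
  trained on the training split; for the sequence models, the learned
  embedding layer itself (see below).
* **GLOVE** — vectors loaded from a word-per-line text file; tokens
  missing from the file share one fixed random vector drawn from the run
  seed.  Dimension defaults to 100 to match the learned embeddings.
* **CHAR2VEC** — per-character random vectors mean-pooled per token, with
  the token-level dimension tied to the word dimension so the two can be
  concatenated position-wise.  Mean pooling makes anagrams collide; that
  is accepted, since the representation exists to absorb slang variants
  and misspellings, and character n-grams are out of scope.

For the convolutional model the TF-IDF vector plays the role of the
document-level "domain knowledge" side input, concatenated before the
dense layers — it is the only document-level linguistic feature the
pipeline defines, and that identification is a deliberate interpretation.

## The seven classifiers

`LR`, `RF` and `SVM` are fitted with glmnet (ridge logistic regression,
penalty equivalent to the common C = 1 convention), ranger (100 trees,
probability forest) and e1071 (RBF kernel, Platt-scaled probabilities).
Their hyperparameters are not pinned down by the reference configuration;
the defaults above are the field's standard ones and all are overridable
through `model_spec()`.

The four neural families are implemented in compiled code inside the
package (no deep-learning framework is required):

* **FAST** — a fastText-style model: averaged bag-of-n-gram embeddings
  (orders 1–2, hashing omitted at this scale) into a linear sigmoid
  classifier, trained by plain SGD with a linearly decaying rate.
* **CNN** — the reference architecture: a learned 100-dimensional
  embedding initialized randomly (random initialization and pretrained
  vectors perform equivalently for this architecture, so random is the
  default), dropout 0.5 on the embedded sequence, parallel convolutions
  with filter sizes 3 and 8, ReLU, max-over-time pooling, one dense layer
  before the sigmoid output, batch size 512, 6 epochs, cross-entropy
  loss.  The number of filters per size is not a printed constant; 100 is
  the default here.  Fig-style layer counts between pooling and output are
  not fully specified; one hidden dense layer is assumed.
* **RNN** — a single LSTM layer (hidden size 100) over the embedded
  sequence, reading out the final hidden state.
* **ATTENTION** — a bidirectional LSTM with additive attention pooling
  over all positions.

For the sequence models the "W2V" combination denotes this learned-from-
scratch embedding; "GLOVE" initializes the embedding from a pretrained
file instead.  The recurrent families take sequence input only, so
TF-IDF-bearing combinations are reported as skipped for them in the metric
grid; the CNN accepts the TF-IDF side vector, matching its architecture.

Learning rates and the per-architecture batch/epoch settings for the
non-CNN networks are implementation choices made by monitoring validation
loss on synthetic corpora of a few thousand posts (the scale every shipped
experiment uses): Adam at 2e-3 for the CNN and the recurrent models, SGD
at 2.0 for FAST.  There is no early stopping anywhere — epoch counts are
fixed and validation loss is logged only.  Training stops with an error
naming the epoch and batch if the loss goes non-finite.

Every family exposes the same score convention: a score near **0** means
the positive/risk class, near 1 the negative class, and class assignment
thresholds at 0.5 (the pipeline never states a tuned threshold, so the
neutral one is fixed).  Reported precision/recall/F1 are positive-class
metrics (macro averaging is available by computing the report on flipped
labels); AUC is the rank statistic on the oriented scores.

## Splits, transfer protocol, and evaluation sampling

`split_corpus()` splits 8:2 into train+validation versus test, then 8:2
again within the training side (64/16/20 overall), stratified by label and
deterministic per seed; a label with fewer than five items cannot satisfy
both ratios and is an error.

`run_case()` trains each requested model on the case's two source groups
(positive group labeled 1) with the target group entirely excluded, then
scores every target-group post inside the 30–500-word window.
`keyword_sample()` draws the 500-post evaluation sample: at most 250 posts
uniformly from those containing a screening keyword, the rest uniformly
from the remainder.  Keyword matching operates on cleaned tokens with
phrases as contiguous token sequences — substring matching is rejected
because the screening lists mix single words and multi-word phrases, and a
token-boundary rule keeps "hydrostatic" from matching "hydros".  The C1
list ships the entry `"want to do"` verbatim from its source
configuration; `"want to od"` is a plausible intended variant, and since
the list is configuration the caller can substitute it — the package
chooses neither silently.

`ratio_curve()` resamples the labeled evaluation set with replacement to a
given positive-label ratio and measures accuracy; its expectation is
`r·a⁺ + (1−r)·a⁻` for class-conditional accuracies `a⁺`, `a⁻`, and the
suite checks the empirical mean against this identity within three
binomial standard errors at 200 repetitions.  The default `n_reps` is 1,
matching single-draw replication; property testing uses 200.

## The boosted ensemble

`fit_boosted()` runs discrete adaptive boosting with depth-1 decision
stumps (50 rounds by default) over the columns of a weak-learner score
matrix — raw probabilities, not thresholded votes.  Each of the default
five runs re-randomizes the 8:2 split, as implied by averaging over data
shuffles, and the mean held-out accuracy is reported.  "Contribution" of a
learner is the normalized alpha-weighted attribution to its column — the
standard impurity-style importance reading for stump ensembles, adopted
because the quantity is plotted but never defined.  The tests verify that
boosting two learners whose thresholded votes must be ANDed together beats
either one alone, that an oracle column dominates both accuracy and
contribution, and that duplicating a column changes nothing beyond noise.

## Content analysis

`detect_phrases()` scores adjacent token pairs with the pointwise
collocation score `(count(ab) − δ)·N / (count(a)·count(b))`, δ tied to
`min_count`, and `apply_phrases()` merges scoring pairs greedily left to
right without overlap.  `content_neighbors()` then trains a skip-gram
embedding on the phrase-merged tokens of the posts one model predicted
positive — one embedding per model, since neighbor lists are reported per
model — and returns the top-k cosine neighbors of a query term (default
"suicidal", the inflected form that co-occurs with first-person language;
ties break lexicographically, the query is excluded).

## Reproducibility and numerical choices

A single global seed fans out to stage-specific seeds via
`derive_seed(seed, stage_name)`, so any stage can be rerun in isolation.
The corpus generator is byte-identical per seed; the compiled trainers use
their own deterministic PRNG (xorshift64*) and are single-threaded, so
model training is bit-reproducible given a seed — run-to-run jitter only
enters through explicit seed changes, and the acceptance workflow
tolerates F1 jitter of at most 0.02 across reruns.  Other numeric
conventions: smoothed idf with L2 normalization; probability clamping at
1e-10 in the cross-entropy; forget-gate bias initialized to 1; AdaBoost
stump errors clamped to [1e-10, 1−1e-10]; ties in vocabulary, TF-IDF
feature selection and neighbor ranking broken lexicographically; an AUC on
a single-class test set is reported missing rather than invented.

## Problem sizes used by the shipped experiments

The acceptance workflow trains all seven families on a 4,000-post
synthetic corpus (2,000 suicide-watch-analog, 2,000 control-analog,
separability 0.9) with sequences capped at 200 tokens — sizes chosen so
the full suite runs comfortably on a single CPU while leaving every model
non-trivially trained.  Statistical property checks use 4,000–10,000
simulated annotation draws and 200 resampling repetitions.

## Limitations

The corpus schema covers submissions only (title plus body); comments are
excluded by design.  Passing the synthetic-analog properties shows that
the pipeline's machinery — preprocessing, features, optimizers, transfer
protocol, aggregation — behaves as specified on corpora whose lexical
structure matches the generator's assumptions.  It does not show that the
classifiers would reach comparable scores on real forum text, whose
vocabulary is heavier-tailed, whose communities overlap far more, and
whose annotators disagree for reasons beyond independent noise.  The
generator makes no attempt to mimic real vocabulary statistics beyond the
properties listed above, and no language-model text generation is used.
Live scraping and crowdsourcing integrations are likewise out of scope;
annotation ingestion is file-based.
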