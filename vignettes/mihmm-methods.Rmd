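---
title: "Modelling motivational dynamics in counseling sessions with mihmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motivational dynamics in counseling sessions with mihmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mihmm)
```

## The problem

Motivational interviewing (MI) is a counseling style whose effectiveness
hinges on eliciting *change talk* (client statements moving toward behavior
change) and containing *sustain talk* (statements defending the status quo).
Session quality is traditionally assessed by trained human coders, which is
slow, expensive and subjective. `mihmm` implements a quantitative pipeline
for this assessment: each client utterance carries an integer *strength
score* in $[-5, +5]$ (positive = toward change, $0$ = neutral, negative =
resistance), the score sequence of a session is treated as the output of a
latent motivational process, and quality inference is performed on the
dynamics of that process rather than on utterance counts.

The pipeline has three statistical stages.

1. **Latent dynamics.** A 3-state hidden Markov model with Gaussian
   emissions is fitted to client score sequences by Baum-Welch (EM). States
   are interpreted through their emission means and labelled, in descending
   order of mean, *Towards Change*, *Non-Determined*, *Away From Change*.
2. **Group comparison.** Transition matrices fitted separately to
   high-quality and low-quality session groups are compared with the
   Frobenius norm of their element-wise difference, $D = \lVert A_H - A_L
   \rVert_F$, and significance is assessed by shuffling session quality
   labels (group sizes preserved), refitting both models per shuffle, and
   reporting $p = \#\{D^{(b)} \ge D\}/B$.
3. **Quality prediction.** Because single sessions are too short for stable
   HMM estimation, bundles ("subgroups") of 7 same-quality sessions are
   sampled, one transition matrix is fitted per subgroup, its 9 flattened
   entries become features, and a logistic regression classifies subgroup
   quality under leave-one-subgroup-out cross-validation (LOOCV), repeated
   over fresh subgroup resamples to yield mean ± SD metrics.

Utterance scoring itself is pluggable: production use would delegate to a
large language model honouring the sequential-context contract (an utterance
may be scored only from the dialogue up to that point). The package ships a
deterministic lexicon scorer (`mock_scorer()`) implementing the same
interface so that every downstream stage is testable offline, plus
agreement statistics (accuracy, Cohen's $\kappa$, Fleiss' $\kappa$) for
validating any scorer against expert annotations.

## The model

For a session with client scores $x_1, \dots, x_T$, the HMM is

$$z_1 \sim \pi, \quad z_t \mid z_{t-1} \sim A_{z_{t-1}\cdot}, \quad
x_t \mid z_t \sim \mathcal{N}(\mu_{z_t}, \sigma_{z_t}^2),$$

with $K = 3$ hidden states. Multiple sessions are treated as independent
realizations: EM sufficient statistics are summed across sequences and every
sequence restarts from $\pi$. Sessions are never concatenated — a
transition across a session boundary is never counted. (Concatenation is
deliberately not offered; it would manufacture spurious transitions.)

Although scores are integers, the default emission family is Gaussian
because state interpretation rests on emission means; a categorical
alternative over the 11 score values (`emission_family = "categorical11"`)
is available when the discreteness matters. Integer rounding inflates the
emission variance by roughly $1/12$ and leaves means essentially unbiased,
so Gaussian fits on rounded data recover generator parameters well (the
parameter-recovery tests quantify this).

### Numerical choices

* **Initialization** is deterministic: $\mu^{(0)} = (+3, 0, -3)$,
  $\sigma^{(0)} = 1.5$, uniform $\pi$ and $A$. This spans the score scale in
  the expected motivational gradient order and makes every fit reproducible
  without a seed. Optional seeded random restarts (`n_restarts`) keep the
  best final log-likelihood.
* **Convergence**: relative log-likelihood change below `tol` ($10^{-6}$ by
  default) or `max_iter` (500). The per-iteration log-likelihood trace is
  retained and is non-decreasing (a property the tests assert to $10^{-8}$).
* **Variance floor**: emission variances are floored at $10^{-2}$ to
  prevent collapse on near-constant data.
* **Scaling**: the forward/backward recursions use per-step normalization
  (scaled algorithm), so likelihoods are exact in log space at any session
  length that occurs in practice.
* **Viterbi tie-break**: at every backtrack step ties go to the lower state
  index, so decoding is deterministic even for uninformative models.
* **Start distribution**: $\pi$ is estimated by EM by default. When an
  external scorer asserts the initial motivational state, the option
  `fix_start_from_first_score = TRUE` instead pins $\pi$ to the empirical
  distribution of first-utterance score signs and holds it fixed. Both
  readings are exposed because neither is canonical.

### State labelling and the gradient flag

`label_states()` sorts states by descending emission mean and permutes
$\pi$ and $A$ into (Towards, Non-Determined, Away) order; ties break toward
the lower raw index, so canonicalization is deterministic and
permutation-invariant. `gradient_valid` is `TRUE` only when the sorted
means are *strictly* decreasing. A violation (tied or collapsed means)
blocks motivational interpretation of the states but not matrix comparison
— it is a flag, never an error. Note that after sorting, the flag can only
fail through ties/collapse: labelling is what *imposes* the ordering, and
the flag records whether the data actually support three distinct
motivational levels.

## The permutation test

`permutation_test()` recomputes the full statistic per shuffle: both group
HMMs are refitted from scratch and re-canonicalized before differencing, so
the null distribution reflects every source of estimation variability. The
p-value convention is the plain proportion $\#\{D^{(b)} \ge D\}/B$; a
`smoothed` option gives the bias-corrected $(\#+1)/(B+1)$. Degenerate
permuted fits (gradient-invalid or non-converged) are counted and reported,
never discarded — discarding them would bias the null.

Refitting ~2 models per shuffle is expensive, so simulation studies use
`relaxed_hmm_config()` (tol $10^{-3}$, max 50 iterations) for *both* the
observed and the permuted fits. Using identical settings everywhere is what
keeps the p-value exactly valid under exchangeability, whatever the EM
depth. The package's calibration study (`permutation_calibration()`)
verifies this: with both groups drawn from the same generator profile (a
true null), 200 simulated datasets × 99 permutations give a rejection rate
at $\alpha = 0.05$ inside the binomial band and near-uniform p-values.
These sizes — 200 simulations, 99 permutations, 30 + 10 sessions of 40–120
utterances — are the package's chosen desk-scale study design; a production
analysis of one dataset would use the default 1000 permutations.

## Quality prediction

Each iteration of `loocv_classify()` resamples `n_subgroups` subgroups of
`size = 7` sessions per class (without replacement within a subgroup,
freely across subgroups), fits one HMM per subgroup, and runs
leave-one-subgroup-out CV with a ridge-penalized logistic regression
(`glmnet`, $\alpha = 0$, $\lambda = 1/(C \, n_{\text{train}})$ with $C = 1$
by default). The ridge matters: the 9 features are rows of a stochastic
matrix, hence exactly collinear (each row sums to 1), and ~59 training rows
cannot support an unpenalized fit reliably. Features are not standardized
by default — they are already probabilities on a common scale — but a flag
exists.

Iteration-to-iteration variability comes from subgroup resampling: LOOCV
itself is deterministic given a feature table, which is why the function
takes the session set rather than a fixed feature table (a fixed-table
entry point, `loocv_predict()`, is exported separately). Reported metrics
are the mean ± SD over iterations of accuracy, rank-statistic ROC AUC
(equal to the trapezoidal area; ties get mean ranks, so constant scores
give 0.5), and per-class precision, recall (sensitivity), specificity and
F1, plus a row-normalized confusion matrix. The positive class for AUC is
"low" — the clinically critical minority under the imbalanced design — but
all metrics are reported for both classes.

Two designs are provided: `balanced` (equal subgroup counts per class) and
`imbalanced_3to1` (3:1 high:low, mirroring a 30/10 session pool). Sessions
recur across subgroups by design; this mirrors the methodology the package
implements and slightly flatters performance through shared composition
between folds. Evaluation at the subgroup level (never splitting a subgroup
across train and test) is enforced structurally, and the chance-level
control — permuting subgroup labels relative to features — lands inside the
binomial chance band, which is the leakage check the acceptance tests run.

## The synthetic generator

`generate_dataset()` draws sessions from known 3-state profiles so that
every stage can be validated against ground truth. The defaults emulate a
40-session study (30 high-, 10 low-quality) with 40–120 client utterances
per session. The high-quality profile is *fluid* (every off-diagonal
transition $\ge 0.1$); the low-quality profile is *sticky-Away* (Away
self-transition $0.8$), reproducing the qualitative contrast between
dynamic engagement and persistent resistance. Emissions are $\mu = (+3, 0,
-3)$, $\sigma = (1, 1, 1)$; scores are `round(clip(draw, -5, 5))` —
clipping before rounding keeps emission means near state means. All of
these values are invented testing conventions chosen once for realism (score
sign structure, modest state separation, plausible session lengths); they
are not estimates from any corpus.

What the generator does **not** emulate: utterance text (synthetic sessions
carry scores only), therapist behavior, scorer noise or bias,
session-length/score autocorrelation structure of real transcripts, or
ambiguous-quality sessions. Passing tests therefore demonstrate correctness
of the *statistical machinery* under the stated generative assumptions, not
clinical validity on field data — scorer quality against expert annotation
must be established separately (the agreement module exists for exactly
that).

## Cleaning and data handling

Two mechanical transcript-cleaning rules are implemented: removal of
repetitive "n/a" filler (default pattern `^(n/a){2,}$`, case-insensitive
after whitespace stripping — configurable, since real corpora vary) and
removal of exact consecutive duplicates that lack a talk-type annotation.
Cleaning is idempotent, order-preserving, re-indexes survivors from 0 and
logs every removal. Exclusions that require human judgment (e.g. noise that
obscures meaning) are out of scope by design.

Sessions round-trip through JSONL (native, preserves nulls) and a flat CSV
dialect; transcript-corpus CSVs are read through a configurable column map
rather than a hard-coded schema. Only client utterances feed the modeling
stages.

## Reproducibility

Every stochastic stage derives a child seed from one global seed via
`derive_seed(seed, stage_label)`, so stages can be re-run in isolation and
whole CLI runs are byte-identical given the same config and seed. Fitted
models serialize to JSON with doubles rendered at 17 significant digits,
which round-trips exactly.

## Known limitations

* The Gaussian emission family ignores score discreteness; the categorical
  family is available but less interpretable through means.
* With the default emission noise (sigma = 1 on means 3 apart, plus integer
  rounding), adjacent states genuinely overlap, so individual transition
  entries estimated from a few thousand observations carry errors of a few
  hundredths — partly sampling noise, partly soft-assignment bias that no
  EM implementation avoids (a reference implementation reaches the same
  likelihood and no smaller error on identical data). Recovery checks
  against generator truth must budget for this; the acceptance script
  reports the realized error.
* Group fits pool sessions, so heterogeneous dynamics within a quality
  group are averaged; per-session fitting needs longer sessions than the
  emulated design provides.
* Subgroup overlap induces mild dependence between CV folds (see above); a
  stricter disjoint design requires a larger session pool than 30 + 10.
* The lexicon mock scorer is a testing device, not a clinical instrument.

## A worked example

```{r, eval = FALSE}
library(mihmm)
set <- generate_dataset(synthetic_spec(n_high = 30, n_low = 10, seed = 42))

fit_group(set, "high")$labeled_hmm

perm <- permutation_test(set, n_permutations = 199,
                         config = relaxed_hmm_config(),
                         perm_config = relaxed_hmm_config(), seed = 42)
perm

loocv_classify(set, design = "balanced", n_subgroups = 30, size = 7,
               n_iterations = 10, seed = 42)
```
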