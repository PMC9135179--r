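---
title: "Models and methods behind eegdeep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eegdeep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

eegdeep implements two pipelines for binary classification of short EEG
segments — seizure (ictal) versus background, or schizophrenia versus
healthy — together with the synthetic data, readers and evaluation harness
needed to exercise them end to end without any external download. This
vignette explains the models, the choices we made where the design was open,
and what the synthetic experiments do and do not demonstrate.

## Data model and segmentation

The single-channel benchmark layout is 100 recordings per condition, 4097
samples each at 173.61 Hz (23.6 s). `segment_recording()` splits a recording
into 23 non-overlapping chunks of `floor(4097/23) = 178` samples and drops
the 3-sample tail; the chunk inherits the recording's class. Equal-length
chunks with floor division match the common published treatment of this
layout and give the canonical "about 2300 segments per category" when 100
recordings are pooled. The multichannel layout mirrors a 19-channel clinical
matrix stored as `segments x 5000 x 19`.

Every pipeline sees per-segment z-scored data (`normalize_segments()`).
Within-segment standardization removes amplitude leakage between recording
sessions, which is standard practice for EEG deep networks; it also makes the
synthetic classification problems shape-based rather than trivially
amplitude-based.

## The synthetic generator

`generate_bonn_like()` emulates the two-class structure the pipelines are
evaluated on:

* **background**: AR(2)-filtered Gaussian noise scaled to unit variance, with
  the AR poles placed to give a broad alpha-like spectral peak near 10 Hz;
* **seizure-like**: the same background plus Poisson-timed 3–5 Hz spike-wave
  bursts. A burst is a windowed fundamental-plus-harmonic waveform scaled to
  an RMS amplitude of 4 background standard deviations. The default rate is
  5 bursts/s with durations of 0.8–1.2 s, so discharge activity is
  quasi-continuous: across an entire 2300-segment study the expected number
  of one-second seizure segments without any discharge is well below one.
  Real ictal EEG is continuously abnormal, and the clean separability of the
  healthy-versus-ictal contrast in the classic benchmark is what these
  defaults emulate.

`generate_multichannel_like()` draws independent AR(2) sources per channel
and mixes them through a class-specific mixing matrix, so the classes differ
in cross-channel covariance rather than marginal power.

The generator is deliberately minimal: there are no eye-blink or muscle
artifacts, no inter-subject variability, no non-stationarity beyond the
bursts, and the two classes differ only in low-frequency rhythmic content.
Passing the synthetic experiments therefore demonstrates that the
implementations learn and evaluate correctly on a separable spectral
contrast — not that the pipelines reach any particular accuracy on clinical
recordings.

## Sparse autoencoder

The autoencoder minimizes

$$J(W,b) = \frac{1}{N}\sum_i \tfrac12\lVert h_{W,b}(x^i)-x^i\rVert^2
 + \frac{\lambda}{2}\sum_{l,i,j} (W^l_{ji})^2
 + \beta \sum_j \mathrm{KL}(p\,\Vert\,\hat p_j),$$

with ReLU hidden units, a linear reconstruction layer (so centred signals
can be reproduced), and the Bernoulli form
$\mathrm{KL}(p\Vert\hat p) = p\log(p/\hat p) + (1-p)\log((1-p)/(1-\hat p))$
on the mean bottleneck activation $\hat p_j$ over the batch. Defaults follow
the published operating point: $p = 0.08$, $\lambda = 0.01$, $\beta = 4$,
50 epochs of Adam at batch size 10.

Numerical choices:

* ReLU means are unbounded above, so $\hat p_j$ is clipped to
  $[10^{-8}, 1-10^{-8}]$ inside the KL term and its gradient is zeroed
  outside that range; this keeps the cost finite without changing the
  penalty where it is meaningful.
* Encoder and decoder weights are untied — the most general reading of the
  per-layer sums in the cost.
* The narrowest interior layer is the bottleneck. Over-complete bottlenecks
  (wider than the input, like the published 9000-unit layer) are allowed;
  rectified codes lose the sign of each projection, so a code roughly as
  wide as the input is typically needed before the features carry the full
  linear information of the segment. This observation sets the test
  profile's 128-unit bottleneck for 178-sample segments.
* All gradients are analytic and are verified against central differences in
  the test suite (relative error below $10^{-4}$ on toy models; in practice
  around $10^{-9}$).

Because Adam normalizes per-parameter step sizes, the sparsity penalty moves
$\hat p$ toward $p$ at a roughly constant rate per epoch rather than
proportionally to $\beta$; demonstrating the pull of a large $\beta$
therefore uses a few hundred epochs on a small model.

## Swarm wrapper selection

Bottleneck features are selected by one of three population optimizers over
continuous positions, decoded to a mask by taking the top-$m$ coordinates
(ties toward the lower index). Top-$m$ decoding keeps the optimizers'
arithmetic valid, is scale-invariant, and guarantees exactly the published
9000 to 4500 reduction in the paper profile.

* **PSO** uses the published constants: inertia 0.64, accelerations
  $c_1 = c_2 = 1.524$, 30 particles, 30 generations, with fresh
  $r_1, r_2 \sim U(0,1)$ per particle and dimension and strict-improvement
  best updates. Velocities are not clamped; decoding is scale-invariant.
* **Cuckoo search** uses 20 nests, abandonment fraction $p_a = 0.45$ and
  step factor $\alpha = 1.5$ with Mantegna Lévy steps of tail exponent 1.5.
  Structure per generation: every nest spawns a cuckoo by a Lévy flight
  scaled by $0.01\,\alpha$ times its distance to the best nest; the first
  cuckoo is dropped into a randomly chosen nest and replaces it if fitter,
  the rest compete greedily with their source nest; then the worst
  $\lceil p_a n\rceil$ nests (never the best — elitism) are rebuilt by a
  difference walk $x + U(0,1)(x_{p1}-x_{p2})$ accepted greedily. The greedy
  acceptance in both phases is what makes the population contract; plain
  unconditional re-initialization either stalls or collapses prematurely,
  and the scaled Lévy step with pairwise greedy selection is the canonical
  published implementation of this algorithm family.
* **Bat algorithm** uses 40 bats, frequency range $[0, 2]$, initial loudness
  $A^0 = 1$ and pulse rate $r^0 = 0.5$. With probability $1-r_i$ a
  candidate is replaced by a local walk around the best scaled by the mean
  loudness; acceptance requires $U(0,1) < A_i$ *and* strict improvement, and
  decays loudness by 0.9 while growing the pulse rate as
  $r^0(1-e^{-0.9 t})$ — the canonical constants for this family. The global
  best is only updated from accepted solutions, so a silent colony
  ($A^0 = 0$) never moves.

The wrapper fitness of a mask is the validation accuracy of a small
fixed-budget classifier (one 8-unit hidden layer, 5 epochs) on an inner
stratified 80/20 split of the training fold, memoized per mask. The
population is seeded around standardized per-feature Welch $t$ statistics
(the first individual sits exactly at the filter solution), so the search
refines a sensible starting mask instead of ranking random half-masks with a
noisy critic. Seeding, like the critic's hidden size and learning rate, is a
design choice of this package; the optimizer constants above are the
published ones.

## Softmax DNN classifier

The classifier is a ReLU multilayer perceptron with a softmax head trained
by Adam on cross-entropy plus weight decay, inverted dropout after each
hidden layer, and published head sizes 2250/500/2 in the paper profile.
During the final fine-tuning epochs (20 of 50 by default) the hidden layers
are frozen and only the softmax head moves — the only reading of
"fine-tuning the classifier so the softmax cost is minimized" that makes
those epochs distinct. The dropout rate and learning rate are not fixed by
the source description; the defaults (0.5, $10^{-3}$) are conventional.
Prediction takes the class of maximum probability with ties toward class 0.

## The recurrent decision agent

The second pipeline frames each segment into 8 contiguous frames (a
sequence length that keeps backpropagation through time cheap while
preserving within-segment dynamics) and builds two decision states:

* $s_1$: a peephole BiLSTM (gates see the previous cell state; the output
  gate sees the current one; the backward direction mirrors time) pooled
  over time by additive attention,
  $s_1 = \sum_t a_t [h_t; h'_t]$ with
  $a = \mathrm{softmax}_t(v^\top\tanh(W[h_t;h'_t]))$.
  The stage-1 class prediction applies the per-step softmax head to the
  attention-pooled state, which equals the attention-weighted average of the
  per-step logits — the single reading that uses both the per-step head and
  the attention state in one decision, and lets pre-training fit the
  recurrent weights, the attention scorer and the head jointly.
* $s_2$: a child-sum Tree-LSTM over a balanced binary tree of depth 2 whose
  four leaves embed contiguous chunks of the frame sequence; children's
  hidden states are summed into the gate inputs with one forget gate per
  child, and $s_2$ is the root state with its own softmax head. This is the
  simplest tree structure honouring leaf-to-root recursive composition over
  a signal.

The agent's episode has at most two decisions: commit at stage 1 (action
$a_1$, predict from the recurrent head; terminal) or defer ($a_2$) to the
tree state, then predict class 0 or 1 ($a_3$/$a_4$; terminal). Rewards are
not numerically fixed by the source description; we use $\pm 1$ for
correct/incorrect terminal predictions and $+0.1$ for deferral — a symmetric
terminal signal with a small positive deferral reward that avoids degenerate
always-commit policies.

Training is two-phase. Phase 1 pre-trains both state builders by supervised
cross-entropy with RMSprop, a max-norm constraint of 3 on weight rows, and
dropout on the pooled states (published operating point: state size 250,
hidden dimension 100, dropout 0.75, learning rate 0.002, mini-batch 25).
Phase 2 freezes the builders, precomputes $s_1$, $s_2$ and the stage-1
prediction for every signal, and runs epsilon-greedy Q-learning
(epsilon decaying linearly 0.5 to 0.05) over epochs of episodes. The
Q-network is a two-layer tanh perceptron over the zero-padded state vector
plus state-kind and action one-hots, updated by RMSprop on the squared error
to the running-average target
$$Q_\pi(s,a) = \tfrac{1}{t}\,\big(r + \max_{a'}Q_\eta(s',a')\big) +
  \tfrac{t-1}{t}\,Q_\eta(s,a),$$
where $t$ counts visits to the (state-kind, action) pair and the bootstrap
is zero at the terminal state. Interpreting the $(t-1)/t$ weight as applying
to the pair's own current estimate makes the update a visit-count running
average of bootstrapped returns — a first visit returns the reward itself,
and a constant reward converges to that constant — which is the only reading
consistent with a terminal-state bootstrap of zero. A tabular specialization
(`q_agent_tabular()`) reproduces this average exactly and is checked against
a value-iteration oracle on a three-state toy decision process.

Whether the state builders should be fine-tuned during Q-learning is left
open by the source description; they are frozen here (the default), which
keeps phase 2 cheap enough to precompute all states once.

## Evaluation harness

Problems are composed from labelled pools (`A`–`D` negative, `E` positive,
or healthy versus schizophrenia), preserving imbalance for multi-pool
negatives. Cross-validation is stratified 10-fold: within each class,
indices are dealt round-robin after shuffling, so every fold's class ratio
is within one sample of the global ratio. Stratification is a mild
strengthening of plain random folds that stabilizes small test runs; with
balanced classes it matches the plain protocol in expectation. Every fitted
component — autoencoder, mask, classifier, state builders, agent — sees
training folds only; the inner selection split is nested inside the
training fold. Aggregates are unweighted means over folds.

Metrics are sensitivity $100\,TP/(TP+FN)$, specificity $100\,TN/(TN+FP)$,
accuracy, good detection rate and error rate. GDR is reported but never
defined in the source description; we take GDR = sensitivity (the standard
"good detection rate" of seizure-detection work — the fraction of true
events detected) and error rate = 100 − accuracy. Degenerate denominators
yield `NA` for the affected metric only.

## Profiles and problem sizes

Two built-in profiles exist. `"paper"` carries the published sizes
(9000-unit bottleneck, 4500 selected features, 2250/500 hidden units, LSTM
state 250); it defines the method at its published operating point and is
impractical on a laptop. `"test"` shrinks every dimension roughly 30-fold:
a 128-unit bottleneck for 178-sample segments (about 0.72 times the input;
narrower rectified codes measurably lose class information), 96 selected
features (3/4 of the code — a small code of raw segments is far less
redundant than the published 9000-unit code, so the published 1/2 ratio
costs accuracy at this scale), a 32/16 classifier, and LSTM state 12 with
8 frames. The test suite and the acceptance script use the test profile on
50 synthetic recordings per class (the canonical 2300 segments) for the
swarm pipeline and 15 per class for the agent and the permutation null —
sizes at which a full 10-fold cross-validation of either pipeline completes
in minutes on a single core.

## Known limitations

* The synthetic classes are separable by low-frequency band power; none of
  the experiments here say anything about accuracy on clinical EEG.
* The wrapper fitness is a noisy estimate (one inner split, 5 epochs);
  selection quality depends on the filter seeding at small population
  budgets.
* The EDF reader supports plain continuous EDF only (no EDF+ annotations,
  no montage logic).
* Binary problems only; the softmax head generalizes trivially but nothing
  else in the harness does.
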