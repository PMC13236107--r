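---
title: "Quantum ensemble classifiers: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum ensemble classifiers: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qensemble)
```

# Scope

`qensemble` implements a family of quantum ensemble binary classifiers in
exact statevector simulation, aimed at the small-sample regime typical of
clinical transcriptomics (a hundred-odd patients, thousands of genes, a
binary response label). Three model families are provided:

* the **quantum cosine classifier (QCC)**, a non-variational weak learner
  built on the swap test;
* the **quantum ensemble cosine classifier (QEC)** and its random-unitary
  variant (**QECRU**), which bag `2^d` transformations of the training data
  in superposition through a `d`-qubit control register and read the
  *average* ensemble prediction from a single ancilla;
* **variational circuit ensembles** (soft voting, bagging, boosting) of
  shallow parameterized learners trained with Adam on parameter-shift
  gradients.

Classical baselines (random forest via `ranger`, gradient boosting via
`xgboost`) and an evaluation harness (accuracy, weighted F1, Brier score,
paired one-sided t-tests, single-class pathology detection) complete the
benchmark protocol.

# The statevector backend

Everything runs on a dense complex statevector engine. Qubit ordering is
**little-endian**: qubit 0 is the least significant bit of the amplitude
index, and every module follows this convention. Gates are either dense
unitary matrices or basis permutations (used for X, CNOT, SWAP, and the
sample-slot shuffles, which would otherwise materialize very large 0/1
matrices); both are applied with a gather/scatter over the target-qubit
axis, conditioned on optional control qubits.

Numerical contracts: states must be normalized to within `1e-8` on
construction (and are renormalized exactly); each gate application preserves
the norm to within `1e-10`; unitarity of dense operators is checked to
`1e-9` (a full Gram check up to dimension 512, a sampled-column check
above). Amplitude encoding zero-pads feature vectors to the next power of
two *before* normalization; all-zero and negative inputs are rejected,
which is safe because every pipeline min-max scales features to `[0, 1]`
first. Simulation is capped at 24 qubits (256 MiB of amplitudes) and Haar
sampling at 12 qubits; both fail fast with a resource error.

# The cosine classifier

One training sample `x_train` with label `y_train` and one test sample
`x_test` are amplitude-encoded into two registers of `log2(f)` qubits; a
Hadamard–controlled-SWAP–Hadamard block on a prediction ancilla implements
the swap test, and a CNOT from the basis-encoded label qubit conditionally
flips the ancilla. The resulting readout satisfies

    Pr(y_hat = y_train) = 1/2 + D(x_train, x_test)^2 / 2,

where `D` is the **cosine similarity** (for nonnegative, min-max-scaled
features `D` lies in `[0, 1]`, so the probability lies in `[1/2, 1]`). With
two features this is a 4-qubit circuit. Note one consequence of the closed
form: a lone QCC with a class-1 training sample never emits a class-0 label
at the 0.5 threshold — it is deliberately a high-variance weak learner whose
value comes from aggregation. Ties at `p = 0.5` go to class 1, always.

# The superposition ensemble

The QEC register layout is: `n_train` amplitude-encoded data subregisters of
`log2(f)` qubits, `n_train` basis-encoded label qubits, a test register, `d`
control qubits, and one prediction ancilla, for a total width of

    n_train * log2(f) + n_train + log2(f) + d + 1.

This layout is what reproduces all of the published hardware widths
(7, 56, 47 qubits) and the configuration-grid extrema (7 for the swap
variant, 23 for the Haar variant) computed by `qec_parameter_grid()`.

After a Walsh–Hadamard on the control register, control qubit `i` is
entangled with two random transformations `U(i,1)`, `U(i,2)` of the train
register (controlled application on control 1, then an X-conjugated
controlled application for control 0). After `d` such steps the state holds
`2^d` trajectories, each carrying a differently transformed training set.
The QCC interference block then compares sample slot 0 against the test
register, with slot 0's label qubit controlling the final ancilla flip.
Because the control-register branches are orthogonal and the interference
block never touches the controls, the ancilla probability is *exactly* the
arithmetic mean of the per-trajectory probabilities — this is the package's
core correctness oracle, checked by `enumerate_trajectories()`, which
composes the selected transformations per branch by direct
permutation/matrix algebra, entirely outside the circuit simulator.

Two transformation families are supported:

* **swap variant**: each `U(i,j)` is a composition of `n_swap` SWAPs of
  uniformly drawn sample-slot pairs, moving each slot's data subregister
  and label qubit together (a basis permutation). Every trajectory then
  holds a complete training sample in slot 0, and its probability equals
  the closed form for that sample.
* **Haar variant (QECRU)**: each `U(i,j)` is drawn from the Haar measure on
  the joint data register (QR decomposition of a complex Ginibre matrix
  with phase-normalized diagonal), leaving the label qubits fixed. The
  support of the random unitaries is a genuinely open design point; acting
  on all data subregisters jointly (capped at 12 qubits) is the choice
  implemented here, with labels untouched so that trajectory labels remain
  well defined. Trajectories are then entangled across slots, and the
  oracle evaluates the swap-test POVM on the reduced slot-0 state — the
  natural generalization of the closed form, to which it reduces exactly
  for permutation branches.

The measured register is the prediction ancilla. The transformations of a
configuration are drawn deterministically from the configuration seed, so
circuit and oracle always see identical unitaries and full runs are
bit-reproducible.

# Variational learners and ensembles

A learner on `n` qubits amplitude-encodes up to `2^n` features, applies a
parameterized RZ–RY–RZ rotation to each qubit, a linear CNOT chain between
qubits `(i, i+1)` when `n > 1` (for a single qubit the chain is empty; the
chain is also what makes a 2-qubit learner entangling), a second rotation
layer, and reads class probabilities from qubit 0 — `6n` trainable
parameters, 18 at the 3 qubits needed for 8 features. Training minimizes
binary cross entropy (probabilities clipped at `1e-12`) by mini-batch
gradient descent with Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`;
constants are a conventional choice, configurable nowhere because nothing
in the protocol varies them). Gradients of the circuit outputs are exact
parameter-shift evaluations at `theta +/- pi/2`, chained classically
through the loss; they agree with central finite differences to `1e-5`.
Batches are drawn without replacement each epoch under a seeded shuffle;
the default epoch budget is 30 with no early stopping (the loss traces on
the benchmark datasets flatten well before that).

Aggregation:

* **soft voting** averages member probabilities; the members are trained
  *jointly* on the full training set against the cross entropy of the
  ensemble mean, since that loss couples the learners. For resource
  accounting, `instantiate_joint()` sizes the tensor-product circuit that
  prepares all members at once: `n * l` qubits for `l` learners of `n`
  qubits (12 qubits for four 3-qubit learners).
* **bagging** partitions the training set into `k` disjoint subsets whose
  sizes differ by at most one (remainder to the earliest subsets, seeded
  shuffle); learner `k` sees only subset `k`; inference is a weighted mean
  with uniform default weights (the weighting is exposed as a hook since
  the aggregation rule is otherwise unconstrained).
* **boosting** follows AdaBoost: uniform initial sample weights `1/N`,
  rounds of `floor(N/k)` samples drawn without replacement proportionally
  to weight, learner coefficient `0.5 log((1 - eps)/eps)` with `eps`
  clipped to `[1e-6, 1 - 1e-6]`, multiplicative reweighting of mistakes,
  renormalization every round. A round with weighted error at or above 0.5
  stops the loop with a warning and keeps the completed rounds (keeping the
  lone first learner if no round completed, so prediction stays defined).

Hyperparameter search uses 4-fold stratified cross-validation over the full
grid of 3 learning rates x 5 batch sizes x 7 ensemble sizes = 105
configurations (`default_variational_grid()`), ranking by median validation
accuracy.

# Synthetic data

The blob benchmark enumerates 18 configurations (`cluster_std` in
{0.3, 0.5}; `p1`, `p2` in {0.3, 0.5, 1.0}) with class-0 center `(p1, p2)`
and class-1 center `(p2, p1)`, 100 samples drawn evenly per class. Draws
are not truncated to any domain; each dataset is min-max rescaled per
feature to `[0, 1]`. Ten distinct stratified 80/20 train/test splits are
generated per dataset; stratification prevents single-class test sets at
these sample sizes. Scaling (and optional PCA to `f` components for the
quantum classifiers) is always fit on the training portion only, with
out-of-range test values clipped to `[0, 1]` — the conservative no-leakage
choice.

The expression generator emulates a variance-stabilized transcriptomic
cohort directly on the log scale (count-level normalization of real data is
out of scope): 150 samples by default, gene-specific baselines
`Normal(mu_g, sigma_g)` with `mu_g ~ U(4, 12)` and `sigma_g ~ U(0.5, 1.5)`,
a responder fraction of 0.35 (a plausible immunotherapy response rate;
configurable), and 8 planted informative genes receiving a class-conditional
mean shift of `effect_size` within-class SDs — mirroring a curated 8-gene
immune marker panel. The default of 2000 genes is a computational stand-in
for a whole transcriptome; the informative-gene recovery tests are
insensitive to the null-gene count at these effect sizes. What the generator
deliberately does *not* emulate: gene–gene correlation, batch effects, and
library-size artifacts — so passing tests demonstrate correctness of the
pipeline and learnability of planted signal, not clinical performance on
real cohorts.

# Evaluation protocol

Per split: accuracy, support-weighted F1 (undefined per-class F1 counts as
0, matching the common implementation default), and the Brier score
`mean((p_i - y_i)^2)` computed from shot-frequency probabilities when shots
are finite. Per classifier: mean and standard error over splits, with
max-mean reporting across configurations. Classifier comparisons use a
one-sided t-test **paired by split id** (the splits are shared, so pairing
is the higher-powered valid choice); a zero-variance difference is reported
as p = 0/0.5/1 by sign rather than NaN. The 0.05 threshold is used without
multiplicity correction, which is a reporting convention, not a strength of
evidence — noted as a limitation.

The random-forest baseline maps the randomized search space
(`n_estimators`, `max_depth`, `min_samples_split`, `min_samples_leaf`,
`max_features`) onto `ranger`'s `num.trees`, `max.depth`, `min.node.size`,
`min.bucket`, and `mtry`; 50 candidates are drawn with internal 4-fold CV
(candidate count and fold choice mirror the variational protocol; the
search function itself states no values). XGBoost uses the exhaustive
486-combination grid. Baselines always see the unreduced feature space.

# Problem sizes and numerical choices

The bundled tests and the acceptance script run entirely on synthetic data
at desk scale: trajectory-oracle equivalence is checked on configurations up
to 16 qubits (the exact-equality contract is width-independent, so small
widths are fully informative); the soft-voting learnability check trains
three 1-qubit learners for 30 epochs under 4-fold CV on one 100-sample blob
dataset, which completes in seconds and reaches median validation accuracy
around 90–96% across seeds, comfortably above the 70% claim it verifies.
Degenerate inputs are handled by explicit contracts: all-zero feature
vectors refuse encoding, constant features scale to 0, `p = 0.5` classifies
as 1, zero-variance paired tests report by sign, and oversize circuits fail
fast before any computation.

# Known limitations

* No noise models, transpilation, or hardware execution — exact simulation
  only, so hardware-reported depths are out of scope by construction.
* The QECRU design space (which distribution, which support) is sampled at
  a single point: Haar on the joint data register.
* Weak learners are genuinely weak: a lone QCC is near-chance on many
  benchmarks, by design.
* The expression generator's independence assumptions understate the
  difficulty of real transcriptomic prediction.
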