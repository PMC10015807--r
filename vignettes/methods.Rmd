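---
title: "Methods: multi-view DDI prediction in mvddi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view DDI prediction in mvddi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mvddi)
```

## The prediction problem

Given a set of approved drugs with SMILES structures, a biomedical
knowledge graph (KG) of triples $(h, r, t)$ over entities that include
those drugs, and a table of labeled drug pairs, `mvddi` learns a function
from a pair of drugs to either an interaction probability (binary task) or
a distribution over $N_c$ typed interaction classes (multi-class task).
The premise of the multi-view design is that the two information sources
are complementary: molecular structure captures what a drug *is*,
KG connectivity captures what it *does* (targets, diseases, side effects),
and interactions depend on both.

## Structure view: GIN over heavy-atom graphs

SMILES are parsed (Open Babel via ChemmineR) into hydrogen-suppressed
graphs; every bond contributes two directed edges. The default `"minimal"`
featurization is a one-hot element indicator over C/N/O/S/P/F/Cl/Br/I plus
a reserved "other" slot, concatenated with a one-hot heavy-atom degree
(0–6); directed edges carry a one-hot bond order. Aromatic rings arrive
Kekulized (alternating single/double bonds), so aromaticity is expressed
through the bond pattern rather than a dedicated flag. The scheme is
deliberately self-contained: it fixes no external weight conventions, and
any scheme that distinguishes the atoms of interest would serve, since
what the package tests about the encoder is structural (injectivity,
invariance), not chemical accuracy.

The encoder is a $K$-layer GIN. Layer $k$ updates each atom $v$ as
$$h_v^{(k)} = \mathrm{MLP}^{(k)}\!\big((1+\epsilon^{(k)})\,h_v^{(k-1)} +
\textstyle\sum_{u \in N(v)} (h_u^{(k-1)} + e_{u \to v})\big),$$
where the edge feature is linearly projected to the node width and added
to the source message. The aggregation is a *sum* — the choice that makes
the update injective on neighbor multisets: mean cannot tell $\{x\}$ from
$\{x, x\}$ and max cannot tell apart any two multisets with equal extremes,
while the sum separates both (these separations are asserted in the test
suite against mean/max oracles). The whole-graph embedding is the
concat-over-depth readout $h_G = \mathrm{concat}_k \sum_v h_v^{(k)}$,
$k = 0, \dots, K$, followed by a single linear projection to the shared
100-dimensional space. A learned convolution could perform this width
adaptation instead; the linear map was chosen because the subsequent
fusion module already owns the convolutional machinery, and a projection
keeps the encoder a fixed, easily-reasoned-about function.

Two deliberate simplifications: the GIN runs with **frozen random
weights** (fan-in-scaled Gaussians drawn from the master seed) rather than
pretrained or jointly-trained ones — at desk scale a random injective
encoder already separates the molecular graphs, and freezing keeps the
joint stage's credit assignment on the fusion block; and $K = 5$,
hidden width 32, chosen to give the readout enough depth diversity while
staying cheap. Both are configurable (`gin_layers`, `gin_hidden`).

## KG view: RotatE in complex space

Entities are complex vectors of dimension $d_c$; each relation is a vector
of phases $\theta$, realized as unit-modulus rotations
$e^{i\theta} = \cos\theta + i\sin\theta$. A triple is scored by the
distance
$$score(h, r, t) = \lVert e_h \circ e_r - e_t \rVert_2,$$
zero exactly when rotating the head reproduces the tail. The norm is not
further specified in the lineage this follows; the Euclidean norm is used
here (the analytic test cases are norm-agnostic at $d_c = 1$). Because the
relation is *stored as phases* and only the phases are updated, the
unit-modulus constraint is conserved exactly at every training step —
asserted as an identity, not a tolerance, in the tests.

**Dimension.** The shared fusion space is 100-dimensional, and the
flattened entity vector `real ‖ imag` must land there, so $d_c = 50$.
The alternative ($d_c = 100$ with a learned projection to 100 reals) was
rejected for parsimony.

**Loss.** Two conventions are implemented behind
`kg_config(loss_convention = )`:

* `"rotate-standard"` (default, used for training):
  $-\log\sigma(\gamma_1 - s_{pos}) - \frac{1}{k}\sum_i \log\sigma(s_{neg,i} - \gamma_1)$,
  which rewards small positive-triple distances, consistent with the
  distance semantics of the score.
* `"as-printed"`:
  $-\sum_i \log\sigma(s_{pos} - s_{neg,i} - \gamma_1)$. Read literally,
  this form *rewards larger* positive scores, contradicting
  lower-is-more-plausible; it is kept for fidelity testing and exercised
  by scalar oracles in the suite, but not used to train.

The margin $\gamma_1$ defaults to 12 (a conventional choice for
rotation-based embeddings; the source material calls it fixed without
stating a value) and may be any non-negative number — the analytic loss
examples use $\gamma_1 = 0$. Negative sampling corrupts head or tail with
a fair coin, draws replacements uniformly, filters collisions with known
positives, and defaults to 128 corruptions per positive. Training is Adam
(default rate 0.05) on the entity coordinates and phases with analytic
gradients; negatives are resampled every epoch.

## Fusion: five latents and one attention block

With $h_G, e_h \in \mathbb{R}^{n \times 100}$ (column-standardized so the
views enter on comparable scales):

* **Concatenate level.** Per drug, the two views are stacked into a
  $2 \times 100$ image (`row_stack`) or a $1 \times 200$ signal
  (`col_stack`); a 2-D convolution (kernel $2 \times 10$ or
  $1 \times 10$, 1→8 channels, stride 1, no padding) is followed by a 1-D
  convolution (kernel 5, 8→1 channels) and 1-D adaptive average pooling
  to length 20, yielding LF1 and LF2. An alternative reading would stack
  *all drugs* into a $2n \times 100$ matrix before convolving, but a
  $2 \times 10$ kernel would then mix adjacent unrelated drugs; the
  per-drug reading is the only one in which the kernel spans the two views
  of the *same* drug, and is the one implemented. Channel counts, stride
  and padding are this package's choices (nothing canonical fixes them);
  the adaptive pool absorbs the resulting length differences, so the
  20-dim contract holds for any kernel geometry.
* **Scalar level.** The elementwise sum and product of the views each pass
  through their own autoencoder ($100 \to 60 \to 20 \to 60 \to 100$, ReLU
  hidden activations, linear latent and output); the middle-layer
  activation is the latent (LF3, LF4). The autoencoders are trained
  *jointly* with the task, their mean-squared reconstruction error added
  to the loss with weight `lambda_ae` (default 0.1) — joint training
  avoids a separate pretraining schedule and lets the latent trade
  reconstruction against task usefulness.
* **LF5 and attention.** LF5 = LF1+LF2+LF3+LF4;
  $X = [\mathrm{LF1} \| \cdots \| \mathrm{LF5}] \in \mathbb{R}^{n \times 100}$
  passes through one standard encoder block: per-head
  $\mathrm{softmax}(Q K^\top / \sqrt{d_k})\,V$ with $Q/K/V = X W$,
  heads concatenated and projected, then residual + layer norm, a
  position-wise feed-forward net (width 200), and a second residual +
  layer norm. $d_k = d_v = d_{in}/h$: 25 at 4 heads (multi-class default),
  50 at 2 heads (binary default). The **attention tokens are the drugs**
  in the processed matrix — the only reading consistent with $Q = XW$ —
  which makes $X_{att}$ depend on batch composition; the package therefore
  always attends over the *full* drug matrix, during training and at
  inference, making predictions deterministic. Tokens are unordered, so no
  positional encoding is used, and one block suffices (stacking is out of
  scope).

## Classifier and losses

$D = [X_{att} \| h_G \| e_h] \in \mathbb{R}^{n \times 300}$. A pair
$(i, j)$ is scored by a dense net on $[d_i \| d_j]$
($600 \to 2048 \to$ 1 or $N_c$). Concatenation is ordered, so training
presents every labeled pair in both orders and inference averages the two
— removing order artifacts without constraining the head to be symmetric.

The binary loss is standard single-sigmoid cross-entropy on the logit. A
literal reading of the printed classifier/loss pair would apply the
sigmoid twice (once in the prediction, again inside the loss), making zero
loss unattainable; that variant is available as
`binary_loss(double_sigmoid_fidelity = TRUE)` and tested, but not used.
The multi-class loss is label-smoothing cross-entropy
$$l_m = (1-\epsilon)\,ce(i) + \epsilon \sum_{j \ne i} \frac{ce(j)}{N_c-1},
\qquad ce(c) = -\log p_c,$$
with $\epsilon = 0.15$ by default; it is implemented for training as
$-\sum_j T_j \log p_j$ with the smoothed target row
$T_i = 1-\epsilon,\ T_{j \ne i} = \epsilon/(N_c-1)$, which reproduces the
scalar form exactly (asserted to $10^{-12}$). Probabilities inside logs
are floored at $10^{-12}$; the training path avoids the floor entirely via
log-softmax.

Metrics follow the per-class one-vs-rest macro convention: accuracy is the
mean over classes of $(TP_i+TN_i)/n$ (equal to plain accuracy for two
classes), precision and recall are macro means, and F1 is the harmonic
mean *of the macro precision and recall* (not a per-class F1 average).
Plain sample accuracy is reported separately as `accuracy_plain`. A $0/0$
ratio contributes 0 with a warning.

## Training orchestration

`ddi_train()` stages: (1) RotatE pretraining on the full triple set;
(2) GIN encoding of all resolvable drugs (drugs with unparsable SMILES or
no KG node are dropped, with their pairs, under a warning); (3) joint
Adam training of fusion + classifier on minibatches of symmetrized pairs.
Task defaults: learning rate 0.0015 / batch 3072 / 2 heads (binary),
0.001 / 1000 / 4 heads (multi-class), 200 epochs, 20% stratified test
split, 1:1 pseudo-negative sampling when a binary table has positives
only. The joint stage runs on a small tape-based reverse-mode autodiff
engine written for this package (matrix-valued tensors, analytic
vector-Jacobian products, gradient-checked against central finite
differences); the KG stage uses hand-derived analytic gradients for
speed. All randomness flows from `config$seed` / `config$kg$seed`, and
the suite asserts bitwise-identical embeddings, checkpoints and metrics
across repeated runs.

## What the synthetic world emulates — and what it does not

`generate_toy_world()` mirrors the *shape* of the real inputs: a drug
table (SMILES from programmatic alkane/alcohol/amine/acid/aromatic
template pools, all valid and mutually non-isomorphic), a KG (per-drug
`binds` edges to target entities, planted symmetric / inverse-pair /
composition-triangle relations, generic padding to exactly 300 triples at
defaults), and labeled pairs. The planted binary rule — interact iff the
drugs share a KG target *and* both carry an aromatic ring — is chosen so
that **neither view alone separates the classes**: the target cluster is
invisible in the SMILES and aromaticity is invisible in the KG, so the
single-view ablations are handicapped by construction. Negative pairs are
drawn across the rule's failure modes; positives are capped at half the
pair budget, putting the default positive rate near 0.45. The four-class
variant refines the same rule ($2 \cdot \mathrm{shared} +
\mathrm{both aromatic}$).

A nearest-neighbor baseline over the concatenated raw views exceeds 0.7
accuracy on the default world (tested), so end-to-end success measures the
pipeline functioning, not an impossible task. What passing does **not**
show: anything about real pharmacology. The toy world has no label noise,
no cold-start drugs (test pairs recombine training drugs), a KG five
orders of magnitude smaller than production graphs, and a rule far
simpler than real interaction mechanisms. Results on it validate the
machinery, not transfer.

## Numerical choices and problem sizes

* Initialization: fan-in-scaled Gaussians for weights, zeros for biases,
  uniform $[-0.5, 0.5]$ entity coordinates, uniform $[-\pi, \pi]$ phases.
* Degenerate inputs: single-atom molecules (no edges: the neighbor sum is
  empty), $n = 1$ fusion batches (softmax over one token is 1), zero
  distances in the KG gradient (guarded at $10^{-12}$), constant view
  columns (unit scale substituted during standardization).
* Ties: multi-class prediction takes the first maximal class
  (`max.col` on the order-averaged probabilities).
* Test problem sizes are the package's own choices for a laptop-class
  run: end-to-end acceptance trains 80 joint epochs on the default world
  (KG stage: 60 epochs, 32 negatives), where the planted rule is
  recovered at ≥ 0.85 held-out accuracy while label-shuffled training
  stays at chance; the relation-pattern suite trains 150 epochs at
  $d_c = 20$ on 30-entity KGs; the symmetric-phase concentration
  tolerance (median $|\sin\theta| < 0.35$) was fixed from a pilot run
  before the tests were frozen (observed ≈ 0.04).

## Known limitations

Pure-R training limits scale to hundreds of drugs and thousands of pairs.
Stereochemistry, 3-D conformers and multi-fragment SMILES are out of
scope (largest-fragment behavior follows the parser backend). Binary
negatives are unlabeled pairs, not verified non-interactions, so binary
metrics inherit that censoring. Multi-label interaction typing (a pair
with several simultaneous mechanisms) is not supported.
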