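---
title: "Message passing architectures for molecular property prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Message passing architectures for molecular property prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the preprocessing and evaluation protocol around them, the
numerical choices that matter, and what the synthetic test bed does and
does not demonstrate.

## The modelling problem

Quantitative structure-activity/property modelling predicts a
biological or physical-chemical endpoint from molecular structure.
Instead of engineered descriptors, the models here consume only the
molecular graph: atoms as nodes with a fixed feature vector $x_v$
(element, degree, implicit valence, formal charge, radical electrons,
hybridization, aromaticity, hydrogen count), bonds as edges with a
4-class one-hot feature $e_{vw}$ (single, double, triple, aromatic).
Hydrogens are implicit; every bond is stored as the two directed edges
$(v,w)$ and $(w,v)$.

## Message passing skeleton

All three architectures share the same skeleton. Each node carries a
hidden state $h_v^{(t)} \in \mathbb{R}^D$, initialized from the atom
feature vector (zero-padded to $D$, or linearly projected when the
feature width exceeds $D$). For $K$ rounds, every node aggregates
messages from its neighbourhood and updates its state; a readout then
collapses the node states into one molecule vector, which a
feed-forward stack maps to the per-task outputs:

$$m_v^{(t)} = \sum_{w \in N(v)} M_t\!\left(h_v^{(t)}, h_w^{(t)}, e_{vw}\right),
\qquad
h_v^{(t+1)} = U_t\!\left(h_v^{(t)}, m_v^{(t)}\right),
\qquad
\hat y = R\!\left(\{h_v^{(K)}\}\right).$$

Because the readout is a sum over nodes and the aggregation is a sum
(or normalized weighted sum) over neighbours, the whole forward pass is
invariant to atom relabeling — the property the test suite checks
explicitly against random permutations.

**SELU-MPNN.** The baseline message function is one feed-forward
network per bond class applied to the neighbour state,
$M = f^{(e_{vw})}(h_w^{(t)})$, summed over the neighbourhood. All
activations throughout the package are SELU (scaled exponential linear
units with the standard $\alpha = 1.6733$, $\lambda = 1.0507$), whose
self-normalizing property replaces explicit batch/layer normalization;
weights are initialized $\mathcal N(0, 1/\mathrm{fan_in})$ accordingly.

**AMPNN.** The plain sum is a cardinality bottleneck: it weighs every
neighbour equally per element. The attention variant computes, per bond
class, an embedding network $f^{(e)}$ and a weighting network
$g^{(e)}$ with equal output width, and takes the elementwise
softmax-weighted sum over the neighbour axis:

$$m_v^{(t)} = \sum_{w \in N(v)} f^{(e_{vw})}\!\left(h_w^{(t)}\right) \odot
\frac{\exp g^{(e_{vw})}(h_w^{(t)})}{\sum_{w'} \exp g^{(e_{vw'})}(h_{w'}^{(t)})}.$$

The softmax runs along the neighbour axis independently for every
output element, so each element of the message has its own attention
distribution; for every element the weights over $N(v)$ sum to one.

**EMNN.** The edge-memory network moves the hidden state onto
*directed* edges. Before message passing, each directed edge gets a
static embedding $e'_{vw} = f^{\mathrm{emb}}\big((e_{vw}, x_v,
x_w)\big)$ — order-sensitive, so $e'_{vw} \ne e'_{wv}$ in general. Edge
states start at zero and update from the edges arriving at their tail,
*excluding the reverse edge*:

$$S_{vw}^{(t)} = \{h_{kv}^{(t)} : k \in N(v), k \ne w\}, \qquad
m_{vw}^{(t)} = \mathrm{attend}\!\left(S_{vw}^{(t)} \cup \{e'_{vw}\}\right),$$

with a single shared $f/g$ attention pair (edge identity already lives
in $e'$). Excluding $(w,v)$ prevents information from flowing straight
back along a bond: on a path A–B–C the update of $\overrightarrow{BC}$
sees $\overrightarrow{AB}$ but never $\overrightarrow{CB}$. The tests
assert this *bitwise*. Because the attention set always contains
$e'_{vw}$, it is never empty. After $K$ rounds node states are
recovered by summing the states of edges leaving each node,
$h_v^{(K)} = \sum_{w} h_{vw}^{(K)}$, so the standard readout applies
unchanged. The edge state width equals the edge embedding size, which
is why the message-size hyperparameter does not exist for this
architecture.

**Update and readout.** All state updates are a gated recurrent unit
(GRU) with the message as input and the state as hidden, weights shared
across nodes/edges and across the $K$ rounds. The readout is the gated
sum

$$R = \sum_{v} p(h_v^{(K)}) \odot \sigma\!\left(q\big(h_v^{(K)}, h_v^{(0)}\big)\right),$$

followed by a three-layer SELU stack whose widths shrink geometrically
(`out_hidden_dim`, then two applications of `out_layer_shrinkage`),
with dropout between layers, and a final linear layer with one output
per task. Classification outputs are pre-sigmoid scores; regression
outputs live in the normalized target space.

## Differentiation and optimization

No automatic-differentiation framework is assumed: the package
implements a small tape-based reverse-mode engine over dense matrices
(`R/autodiff.R`) with exactly the operations the models need — matrix
product, broadcast bias, elementwise algebra, SELU/sigmoid/tanh, row
gather, segment sum, concatenation, and fused masked losses whose
gradient is identically zero at missing cells. Gradients for all three
architectures are validated against central finite differences in the
test suite. Training uses the adaptive-moment (Adam) optimizer at the
configured learning rate with no schedule; batch size defaults to 50
and the epoch cap and early-stopping patience are configuration.

Two numerical details are deliberate. First, the softmax stabilizer
subtracts the per-group, per-column maximum (a constant under
differentiation), not a global maximum — this keeps each aggregation
set's result a function of its own rows only, so locality invariants
(no-backflow, receptive field) hold bitwise rather than to rounding.
Second, pre-activations of zero-initialized edge states sit exactly at
the SELU kink, where one-sided derivatives differ; the engine takes the
left derivative there, and the finite-difference tests jitter biases
off the kink before probing.

## SMD preprocessing

Public bioactivity tables often store salts/complexes and impute
unlabelled molecule-task cells as "inactive". SMD (Standardised
Missing Data) preprocessing does two things:

1. **Charge-parent standardization** — each SMILES is replaced by the
   neutralized largest organic covalent unit (counterions dropped,
   charges neutralized where chemically possible; a quaternary
   nitrogen keeps its charge and is flagged). The operation is
   idempotent and delegated to the RDKit standardizer, the direct
   descendant of the MolVS implementation. "Organic" means
   carbon-containing; rows whose standardization fails are dropped and
   counted rather than aborting the run.
2. **Missing-label masks** — empty cells become explicit missing
   values. The masked losses (binary cross-entropy / squared error
   averaged over observed cells only) exclude them from both the value
   and the gradient, so unlabelled pairs never backpropagate; metrics
   are computed over observed cells only.

The `census()` operation reports exact active/inactive/missing counts
and both active-fraction conventions (imputed-as-inactive vs
observed-only). On heavily sparse screening panels (~84% missing) the
two conventions differ by nearly an order of magnitude, which is the
accounting rationale for masking.

## Splits, normalization, evaluation

Datasets split 80/10/10 into train/validation/test, either uniformly at
random under a fixed seed or by Bemis-Murcko scaffold: molecules are
grouped by their framework (ring systems plus linkers, side chains
removed; acyclic molecules form the empty-scaffold class) and whole
groups are assigned greedily, largest first with ties broken by
scaffold string, to train, then validation, then test under cumulative
cutoffs. No scaffold ever spans two sets — the hard invariant — which
means realized sizes can deviate from the ratios when group sizes do
not tile them (a 8/2 two-group example realizes as 8/0/2); a group
larger than the whole train target goes to train with a warning.

Regression targets are normalized per task to zero mean and unit
(sample) standard deviation using observed *training* cells only, and
predictions are transformed back before any metric is computed, so
reported errors are in original units. Classification tasks are never
normalized. Metrics are ROC-AUC (delegated to pROC), PRC-AUC computed
as average precision — the step-wise integral of the precision-recall
curve, chosen over trapezoidal interpolation, which is known to be
optimistic — RMSE and MAE. A task whose observed test cells contain a
single class is reported as non-computable and excluded from the
aggregate.

The repeat protocol trains three models: under random splitting, three
split seeds give three memberships; under scaffold splitting the single
deterministic membership is reused and only weight initialization
varies. Test metrics are taken at the best-validation epoch and
summarized as mean ± sd over the three repeats. Training is fully
deterministic given (seed, configuration, split) on a fixed platform.

## Hyperparameter search

The search domains are per-architecture: learning rate log-uniform on
$[10^{-6}, 10^{-4}]$, message passes an integer range (capped at 8 for
the edge-memory network), dropout and output shrinkage continuous, and
the width parameters discrete choice lists, slightly tightened for the
edge-memory network. The surrogate is Gaussian-process regression with
an RBF kernel over the encoded space (continuous dimensions scaled to
the unit interval, the learning rate in log space, discrete choices
one-hot encoded), a small lengthscale grid selected by marginal
likelihood, Expected Improvement as the acquisition function, and
local penalization of already-chosen points for batch suggestion.
Because no Bayesian-optimization package is available to the package's
dependency set, the GP posterior algebra (Cholesky solves) is done
in-package; the space-filling initial design (five points) comes from
a Latin hypercube. Objective failures are recorded at a worst-case
score and the search continues; the incumbent best is monotone by
construction. AUC metrics are maximized, error metrics minimized by
internal negation.

One deviation from the stated configuration contract is deliberate:
the width/learning-rate domains above are enforced for every point the
*search* touches, but `model_config()` itself accepts out-of-domain
numeric values. Desk-scale experiments (tiny fixtures, hundreds of
molecules) need learning rates around $5\times10^{-3}$ to converge
within a 200-epoch budget, far above the search domain intended for
full-scale training; hard-coupling the config object to the search
domain would make such experiments unexpressible.

## The synthetic test bed

`gen_molecules()` assembles SMILES from a small fragment grammar — a
ring scaffold (benzene, pyridine, furan, pyrrole, cyclohexane,
cyclopentane, tetrahydrofuran, or none) with up to two side chains from
a fixed set, capped at 12 heavy atoms, canonicalized and deduplicated —
plus an optional salt-pair mode that emits charged multi-fragment
species for exercising standardization. `gen_labels()` computes labels
by deterministic graph rules (atom counts, aromatic-atom counts, ring
or substructure indicators, and an additive per-element property) and
samples missing-value masks at a requested rate, emulating the sparsity
regime of public screening panels (e.g. 84% missing).

Because every rule is a deterministic function of the graph, the
generating rule is the recovery oracle: a model that learns it must
drive the test error toward zero. The acceptance suite trains a tiny
attention model on the additive property (300 molecules, 200-epoch cap,
learning rate $5\times10^{-3}$ — problem sizes chosen so the run is
robust across generator seeds; with 200 molecules some draws overfit)
and a tiny edge-memory model on an aromatic-ring indicator (150
molecules, 40 epochs), asserting test RMSE below 20% of the label
standard deviation and ROC-AUC above 0.95 respectively.

What passing these tests shows: the architectures, gradients, masking,
splitting and protocol machinery are correct, and the models can
recover graph-computable structure from small data. What it does not
show: predictive performance on real assay data. The grammar's
chemistry is a toy — a dozen fragments, no stereochemistry, no
conformations, label noise only if requested — and real endpoints are
not deterministic functions of the 2D graph.

## Known limitations

- Chemistry perception requires a Python interpreter with rdkit on the
  PATH (`MOLMPNN_PYTHON` overrides); results are memoised per session.
- The engine is dense and single-threaded; it is sized for desk-scale
  graphs (tens of atoms, hundreds of molecules), not GPU-scale
  benchmark training.
- Ionic bonds are not modelled as edges: a salt's fragments are
  disjoint components whose information meets only in the readout sum.
- Stereochemistry, 3D geometry, and tautomer canonicalization are out
  of scope; bond types outside {single, double, triple, aromatic} are
  rejected rather than coerced.
- The QM8-style normalization exception mentioned in benchmark
  protocols is not reproduced; all regression tasks use the same
  train-set standardization.
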