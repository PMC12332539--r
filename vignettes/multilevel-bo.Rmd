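---
title: "Multi-level Bayesian optimization over coarse-grained chemical spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level Bayesian optimization over coarse-grained chemical spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgfunnel)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the tunable parameters, what the synthetic
data generator does and does not emulate, and the numerical and design
choices a maintainer should know about. Code chunks are illustrative and
not evaluated when the package is built.

## 1. Chemical spaces at three coarse-graining resolutions

A CG molecule here is a connected simple graph of one to four typed beads:
no self-loops, no parallel edges, and no bond-length or angle attributes
in the graph identity, because bond lengths are taken as bead-size
dependent constants and angle terms are neglected for molecules this
small. Enumeration of molecules is then enumeration of vertex-colored
graphs. The package counts them in closed form by Burnside orbit counting
over the ten connected unlabeled shapes on up to four nodes and, where
feasible, materializes them by canonical labeling (minimum of a serialized
type-sequence/edge-set encoding over all node permutations — exact and
cheap at four nodes). For the packaged alphabets of 15, 45 and 96 bead
types this yields 89,960, 6,742,680 and 136,870,880 molecules, i.e. about
90 thousand, 6.7 million and 137 million.

The high-resolution alphabet follows the Martini-style palette with
classes Q (charged), P (polar), N (intermediate), C (apolar) and X (halo)
in three bead sizes, without hydrogen-bonding/polarizability labels and
without water or divalent ions: per size P1–P6, N1–N6, C1–C6, X1–X4 and
Q1–Q5 split by charge sign, i.e. 32 types per size. The published
resolution hierarchy derives its merged alphabets by averaging
interactions; the tables that prescribe the exact 45- and 15-type
groupings are not part of the public record this package is built from,
so the package uses the simplest grouping reproducing those counts:
adjacent polarity bands merge pairwise at level 2 (with Q1–2 and Q3–5 per
sign), and each class collapses to one type per size at level 1. Each
type carries a logP-like hydrophobicity proxy, linear in the polarity
index within a class and attenuated for smaller beads; lower-level values
are child means. Only the ordering and relative spacing of this proxy
matter: it is the one continuous node feature the embedding can use to
tell polarity bands apart.

## 2. Latent embedding

Each resolution is embedded separately by a regularized autoencoder. The
encoder is a two-round message-passing network with sum aggregation
(hidden width 64) over node features (one-hot class, size, charge, scalar
standardized logP), read out to a 5-dimensional latent vector; it is
permutation invariant by construction. The decoder is a fully connected
network (hidden width 192) reconstructing, from the latent vector alone,
the node count, the per-slot categorical features (cross-entropy), the
logP proxy (squared error) and the padded 4×4 adjacency (binary
cross-entropy with logits over the six node pairs), all masked by node
presence. Because the decoder is not permutation invariant, reconstruction
is scored against the canonical node order each molecule is stored in.
The regularized-autoencoder recipe appears as an L2 penalty on latent
codes (1e-4) plus weight decay on the decoder (1e-6). Training uses Adam
(learning rate 3e-3, batch 512 by default) with analytic gradients that
are verified against numerical differentiation in the test suite.

Problem sizes are chosen for a desk-scale build: the reconstruction test
trains on the complete up-to-three-bead low-resolution space (2,615
molecules, 400 epochs, about two minutes) where exact graph
reconstruction exceeds 99%. Training the full 89,960-molecule space to
the same accuracy is the same computation at roughly 40× the cost and is
left to users with more patience; spaces above a configurable size are
represented by seeded stratified subsamples (shape drawn proportionally
to its exact class count, types uniform, deduplicated).

The cross-resolution latent map takes a latent point to its nearest
indexed molecule, maps that molecule down the type hierarchy and encodes
it with the lower level's encoder; for materialized molecules this is
exact by construction, and because the type map is many-to-one the latent
map is a well-defined function.

## 3. Gaussian-process surrogates with lower-resolution priors

Each level `l` models the objective with a GP using the squared
exponential kernel `exp(-r²/2ξ_l²)` with unit signal variance. The
observation noise `σ_n` is fixed (not optimized); the default matches the
oracle's observation noise. Delta learning enters through the prior mean:
at level `l > 1` it is the posterior mean of level `l-1` evaluated at the
mapped latent point, recursively down to the additive single-bead model
`f0` (the sum of each bead's observed single-bead objective) at level 1.
With no training data at a level, the posterior therefore reduces exactly
to the mapped lower-level posterior.

Numerical choices: Cholesky solves with a single 1e-8-jitter retry;
posterior variances clipped at zero; the lengthscale maximizes the log
marginal likelihood of the prior-mean residuals over a 25-point log grid
on [0.01, 100] refined by golden-section search. Inside the optimization
loop the refit waits until a level has five observations and is bounded
to [s/8, 3s] where `s` is the median pairwise latent distance of the
level's indexed space, which is also the pre-fit default. The reason is
practical: with two or three points the marginal likelihood is
uninformative and collapses to the search floor, and a collapsed
lengthscale makes the distance-based down-switch rule fire on every
candidate. The independent per-level refits used by the neighborhood
analysis use the unconstrained fit.

## 4. Acquisition and resolution switching

Expected improvement in the minimization convention drives selection,
maximized over discrete candidate pools. At level 1 the pool is the whole
unevaluated space (optionally a seeded subsample above a cap). At levels
above 1 a candidate is admissible when its mapped lower-level point (a)
has negative lower-level posterior mean and (b) lies within
`down_factor·ξ_{l-1}` of an evaluated lower-level input; if nothing
passes both, (b) alone decides. Pools are truncated to `pool_cap` by
ascending mapped posterior mean; the incumbent `y*` is the best
observation at the current level (the mapped prior informs the mean, not
the improvement baseline; a fresh level starts from the best observation
seen anywhere).

Initialization selects `n_init` molecules by weighted k-medoid clustering
of the embedded space with weights `exp(-f0(x))`. The implementation uses
alternating (Voronoi-style) medoid updates with exact per-cluster
minimization, random restarts and seeded subsampling above 5,000 points —
a standard k-medoids heuristic chosen over full PAM swaps for
tractability; the clustering cost is checked against random subsets in
the tests.

Switching policy: up one resolution after three consecutive evaluations
whose out-of-sample prediction error `|μ_pre − y|` is below
0.12 kcal/mol; down one resolution when the EI-selected candidate is
strictly farther than `2ξ_l` from every evaluated point at the level (the
rejected candidate is discarded). Three loop-engineering details matter
in practice and are deliberate: an up-switch requires at least one
evaluation since arriving at the level (otherwise a retained error
history could bounce levels without spending evaluations); a down-switch
into a fully evaluated level is skipped; and a stall guard terminates the
rare pathological case of transitions that consume no budget.

## 5. The synthetic oracle and what it emulates

The oracle stands in for MD-based thermodynamic-integration evaluations.
Every molecule receives four positional free energies (bilayer center,
interface, bulk water, DLiPC-bilayer center) as sums of per-bead
contributions plus pairwise edge couplings plus Gaussian observation
noise. The score is `ΔΔG = ΔG_center − ΔG_DLiPC`,
`S = w_a·max(ΔG_center − ΔG_interface, 0) + w_b·max(ΔG_interface −
ΔG_water, 0)` and `y = min(ΔΔG, 0) + S`; the published description of
`S` specifies only which differences enter a conditional weighted sum, so
this rectified form — zero exactly for center-localizing molecules and
increasing as the interface or water is preferred — is the package's
stand-in, with configurable weights. Molecules whose noiseless center
free energy does not undercut water are classed non-inserting: the
interface and DLiPC positions are skipped (as the MD workflow skips them)
and the only available penalty term `w_a·max(ΔG_center − ΔG_water, 0)`
is used.

Per-type contributions are seeded draws structured around the
hydrophobicity proxy: hydrophobic types favor the bilayer center and the
DLiPC phase (negative `ΔΔG`), hydrophilic types favor water, and the
coefficients are calibrated so one-to-four-bead molecules span roughly
−1.5 to +3 kcal/mol — the magnitude regime the free-energy threshold
parameters (0.12 kcal/mol, noise ~0.1) are meaningful for. Lower-level
tables are child averages of higher-level ones (as lower-resolution
interactions are averages of higher-resolution ones), so single-bead
values are exactly hierarchy-consistent and multi-bead values lie in the
span of their preimages.

The deviation structure encodes the central assumption being exercised —
landscapes get smoother as resolution decreases:

* top-level per-type scatter (`node_sd`) is centered within sibling
  groups, so it averages out exactly one level down;
* the intermediate level adds a group-level scatter (centered within the
  lowest-level classes) plus a smooth refinement proportional to each
  type's logP offset from its class mean;
* the lowest-resolution landscape follows the smooth trend alone;
* center and water share their scatter so the insertion decision follows
  the trend at every resolution — otherwise insertion-regime flips
  between a molecule and its coarse image make the intermediate residual
  effectively unlearnable, which is a property of the scoring kinks, not
  of the free-energy surfaces the generator is meant to imitate.

What the generator does *not* emulate: real Lennard-Jones energetics,
conformational entropy, many-body packing effects, correlated TI noise,
or the actual published free-energy values — passing tests show the
machinery behaves as designed on landscapes with the assumed hierarchical
smoothness, not that any specific molecule prediction is right.

## 6. The multi-level vs standard comparison

The comparison study uses the toy hierarchy `make_toy_hierarchy(2, 6, 12)`
— spaces of 65, 2,765 and 37,960 molecules — rather than the full
hierarchy, so twenty complete optimization runs fit in minutes. Its
defaults are the study conditions and were designed once, before the
comparison was scored, to reproduce the regime the funnel strategy is
meant for:

* `node_sd = 0.4`, `coupling_sd = 0.05`: a genuinely rugged
  high-resolution landscape over a smooth low-resolution one;
* `sigma_obs = 0.05` kcal/mol (and `sigma_n` to match): the switching
  threshold of 0.12 kcal/mol must sit comfortably above the noise floor,
  as it did in the workflow that chose it from repeated evaluations;
* budget 80 evaluations with 10 initialization molecules: the budget
  covers ~0.2% of the high-resolution space, a miniature of the published
  coverage asymmetry (hundreds of evaluations against 10⁸ molecules); a
  small high-resolution space lets standard BO saturate and makes the
  comparison uninformative;
* `pool_cap = 300`: pools are compact neighborhoods, which is what keeps
  the distance-based down-switch rule from rejecting every fresh
  candidate at a new level.

Under these conditions the multi-level runs reach a lower mean final
objective than matched standard BO over paired seeds; the test suite
performs that comparison. On deliberately easy landscapes (small spaces,
mild roughness, generous budgets) standard BO matches or beats the
funnel — consistent with the caveat that the approach needs sufficiently
complex high-resolution problems to pay off.

## 7. Analyses

`neighborhood_size` measures the mean number of neighbors within
`α·ξ` (α = 0.5) of evaluated molecules, with `ξ` refit independently per
level (zero-mean prior) to avoid borrowing smoothness from below;
`project_neighborhood` scales a neighborhood count by the ratio of total
space sizes (equal-average-density assumption). `extract_rules` builds
count features — single bead types and unordered *bonded* type pairs —
over evaluated molecules with `ΔΔG < 0`, fits an L1-regularized
regression with 5-fold cross-validated penalty (glmnet) and bootstraps
coefficients for uncertainties. Pair features are restricted to bonded
pairs by choice; with four-bead molecules, non-bonded pairs add little
beyond composition counts.

## 8. Known limitations

* The full 137-million-molecule space is never materialized; level-3
  candidate indexing uses stratified subsamples plus preimages of
  promising lower-level molecules, so a full-scale run searches a
  representative, not exhaustive, high-resolution candidate set.
* The latent spaces distinguish sibling types only through the logP
  proxy; alphabets whose siblings are energetically very different but
  logP-close violate the embedding's separability assumption (the toy
  generator spreads sibling logP for exactly this reason).
* Reported toy results are specific to the packaged study conditions;
  the comparison outcome is regime-dependent, as discussed above.
* The switching thresholds are taken as given (0.12 kcal/mol, three
  consecutive, factor 2); no attempt is made to tune them per problem.
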