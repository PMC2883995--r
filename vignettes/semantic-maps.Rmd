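---
title: "Semantic maps from synonym-antonym graphs: models and methods"
author: "semap developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic maps from synonym-antonym graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dictionaries of synonyms and antonyms describe, pair by pair, whether two
words mean nearly the same thing or nearly opposite things. `semap` turns
such a dictionary into a *semantic map*: an assignment of a coordinate
vector to every word such that synonym vectors point the same way,
antonym vectors point opposite ways, and the principal axes of the
resulting cloud carry interpretable meanings (in natural-language corpora
the leading axes read as good-bad, calming-exciting, and open-closed).
Unlike co-occurrence methods (LSA, LDA and relatives), which represent
dissimilarity and struggle to represent antonymy at all, the construction
here treats antonymy as first-class geometric information: it is what
anchors the origin and gives coordinates a meaningful sign.

## From dictionary to core graph

A lexicon is a list of word records with listed synonyms and antonyms.
`build_signed_graph()` distills it into a signed graph $W$ with
$W_{ij} = +1$ for synonym pairs and $-1$ for antonym pairs:

1. every directed listing is symmetrized ($A$ lists $B$ implies the
   $B$--$A$ link);
2. a pair listed with both signs, in either direction, is contradictory
   and is removed entirely. Conflicts are resolved after full
   symmetrization so the outcome does not depend on listing order;
3. `largest_component()` keeps the dominant connected cluster (size ties
   are broken toward the component holding the lexicographically
   smallest word, for determinism);
4. `extract_core()` removes words with fewer than two links or with no
   antonym link. Removing a word can drop a neighbor below the
   threshold, so pruning and component selection are iterated to a fixed
   point; the fixed point is what guarantees the advertised core
   property (every retained word has degree at least 2, at least one
   antonym, and the graph is connected). The iteration can legitimately
   empty the graph, which is reported rather than treated as an error.

Tokens are compared after trimming surrounding whitespace only; no case
folding is applied, because dictionaries distinguish entries and folding
is a caller decision.

The package also provides `capture_recapture()`, the two-sample overlap
estimator $\hat N = n_1 n_2 / m$ for the size of the "true" synonym set
given two independently sampled dictionaries with $n_1$ and $n_2$ links
and $m$ common links. Since common links are in practice more likely to
be listed in both sources, the implied coverages $n_i/\hat N$ should be
read as upper bounds.

## The energy model

Words start at random positions in a $d$-dimensional unit ball
(default $d = 26$; results are insensitive over roughly 10-100) and are
moved to minimize

$$H(x) = -c_p \sum_{i<j} W_{ij}\,\langle x_i, x_j\rangle
        + c_q \sum_i \lVert x_i \rVert^4 .$$

The pairwise term is the simplest expression that rewards parallel
synonyms and antiparallel antonyms; the quartic term is the lowest
symmetric power that keeps the cloud compact (a quadratic term would
only renormalize the pairwise part). Rescaling $(c_p, c_q)$ rescales the
minimizing configuration without changing its shape, so the defaults
$c_p = 1$, $c_q = 1/4$ fix only the overall scale; both are exposed in
`energy_params()`.

### Optimization

Two optimizers are provided behind `minimize_energy()`:

* **Annealed gradient descent** (default, compiled): plain gradient
  steps plus additive Gaussian "thermal" noise whose scale decays
  geometrically, `noise_scale0 * noise_decay^step` (defaults 0.1 and
  0.99, i.e. roughly 1,600 noisy steps before the scale falls below the
  `1e-8` floor). The noisy phase lets the configuration escape shallow
  minima; afterwards the descent is deterministic with a backtracking
  line search (step halved until the energy decreases, then grown by
  1.5x), which makes the deterministic phase provably monotone in
  energy.
* **Damped Newton**: the analytic Hessian with Levenberg-style diagonal
  damping whenever it is not positive definite (far from a minimum the
  raw Hessian is indefinite). The Hessian is dense, so this path is
  restricted to small problems; in the test suite it serves as an
  independent check that both optimizers reach the same minimum.

Convergence is declared when any of three monitors falls below the
tolerance (default $2\times10^{-6}$): the gradient infinity-norm, the
relative energy change $|\Delta H| / (|H| + 10^{-12})$, or the maximum
row displacement divided by the maximum row norm ($+10^{-12}$). The
monitors are only evaluated in the deterministic phase. Non-finite
energy aborts with an error naming the step.

In practice the converged configuration is macroscopically
seed-independent: pairwise-angle matrices across seeds agree within a
couple of degrees, which the test suite asserts on small graphs with
exact antipodal solutions.

## Post-processing

`rotate_to_pcs()` centers the cloud at its mean and rotates it to
principal components by SVD. Centering is stated for determinism; the
energy is symmetric about the origin so the mean is near zero anyway,
and the rotation preserves all centered pairwise angles.

**Axis signs.** The energy is invariant under $x \mapsto -x$ per
principal axis, so PC signs are arbitrary. `standardize_signs()` orients
each axis by anchor words: the axis is negated when the mean coordinate
of the positive-pole anchors minus the negative-pole anchors is
negative. The shipped `default_anchors()` orient the four leading axes
toward "good", "exciting", "open" and "elaborate", using the words that
characterize these poles in English dictionary cores; the lists are
plain data and are meant to be replaced for other languages or corpora.
Synthetic maps (e.g. the color sphere) skip this step with
`anchors = NULL`.

**Scale.** `normalize_map()` applies one global factor so the mean
squared vector length equals a target. The natural-language convention
"rescale to unit variance per meaningful direction" is ambiguous (a
unit-ball cloud already has mean squared length near 1); the convention
adopted here sets the target to the number of retained significant
dimensions $k$, so that when the $k$ leading PCs share the variance
evenly each has standard deviation near 1. The target is an explicit
parameter; uniform scaling changes no angles and is idempotent at a
fixed target.

### How many dimensions are significant?

`significant_dimensions()` runs a parallel analysis against a
sign-permutation null: the graph topology is kept, the $\pm 1$ edge
labels are permuted, the embedding is refitted (19 null maps by
default), and dimension $k$ counts as significant while its fitted-scale
PC variance exceeds the 95th percentile of the index-matched null
variances. The null preserves degree structure while destroying the
coherent sign signal, and it is correctly calibrated in the
null-vs-null sense (a sign-shuffled graph tested against its own null
shows zero significant dimensions about 95% of the time).

One caveat, documented because it matters for the color-sphere
validation below: for relation graphs sampled from metric neighborhoods
the *unsigned* topology alone (who is linked to whom, regardless of
sign) already sustains a structured embedding, so null variances are not
small, and a true-but-weak trailing dimension can fail the comparison.
On the sphere simulator at the default sparsity (mean degree 3.5) the
third dimension's variance is comparable to a null graph's third
eigenvalue even though the trailing seven dimensions collapse to
numerical zero, and we verified that harsher degree-preserving nulls
(topology rewiring plus sign shuffling) have essentially the same
spectra. The reported count is therefore conservative at high sparsity:
on the simulator it reads 2 on some instances and 3 on others. We kept
the sign-permutation construction rather than substituting an ad-hoc
spectral-gap rule, and the reconstruction pipeline normalizes to the
sphere's known three dimensions by convention (`target_dims = 3` in
`reconstruct_color_map()`).

## Per-word analytics

All analytics operate on the fitted `semantic_map` object:

* `word_angle()` / `classify_onym()`: the dot product of two word
  vectors predicts their relation — synonym if positive, antonym if
  negative, abstention exactly at zero.
* `rank_words()` scores words on axis $k$ by
  $x_{ik} / \sqrt{\lVert x_i \rVert}$, the geometric mean of the
  *projection on* the axis ($x_{ik}$) and the *alignment with* it
  ($x_{ik}/\lVert x_i\rVert$); vector length here is the Euclidean norm,
  which is what makes that identity exact. `rank_antonym_pairs()` is
  the pairwise analog, $|x_{ik} - x_{jk}| / \sqrt{\lVert x_i - x_j\rVert}$.
* `onyms_of_onyms()` is the two-step neighborhood; with
  `include_listed = TRUE` it retains direct onyms, which is the variant
  needed for `oo_prediction_correlation()` (listed labels exist only for
  them), while the angle-histogram class excludes them.
* `oo_prediction_correlation()` correlates cosines against the listed
  $\pm 1$ labels; significance uses the t-distribution test for a
  Pearson coefficient.
* `connotation_octant()` labels the (PC1, PC2) projection by eight
  45-degree sectors centered on the semi-axes and diagonals; boundary
  ties go to the counter-clockwise sector, a pure determinism choice.
* `frequency_weighted_mean()` computes the frequency-weighted average
  position ("concept mean"). Standard errors come from a word-level
  bootstrap (words resampled with replacement), and the weighted-minus-
  unweighted difference is tested per axis with a two-sided bootstrap
  z-test; both are conventions chosen here, since error bars on such
  means admit several constructions.

## Comparing maps

`align_common_words()` pairs two maps over their shared vocabulary; an
optional translation table is applied first, and several source words
mapping to one target are collapsed by unweighted averaging of their
coordinate rows. `pc_correlation_matrix()` gives the PC-to-PC Pearson
matrix with t-test p-values. `map_cca()` wraps canonical correlation
analysis with Bartlett's sequential chi-squared test at $\alpha = 0.001$
for the number of significant components.

`overall_correlation()` generalizes $|R|$ to multidimensional variables
through covariance-matrix norms,

$$\mathrm{OC} = \frac{\lVert \mathrm{Cov}(A,B)\rVert}
  {\sqrt{\lVert \mathrm{Cov}(A)\rVert\,\lVert \mathrm{Cov}(B)\rVert}}.$$

The norm is a genuine design choice and the default is the **spectral**
(operator 2-) norm, for two reasons a user can rely on: (i) in one
dimension OC is exactly $|R|$; (ii) with each side expressed in its own
PC basis, OC provably satisfies
$|\mathrm{corr}(\mathrm{PC1}_A, \mathrm{PC1}_B)| \le \mathrm{OC} \le
\rho_1$, where $\rho_1$ is the first canonical correlation (lower bound:
the spectral norm of the cross-covariance is at least its $(1,1)$ entry
while the denominator uses the largest variances; upper bound: the
maximizing directions of the cross-covariance are feasible but not
optimal for CCA). The Frobenius alternative violates the lower bound —
take $A$ two-dimensional and isotropic, $B_1 = A_1$, $B_2$ independent
noise: Frobenius-OC is $1/\sqrt 2$ while the PC1 correlation is 1 — so
it is available (`norm = "frobenius"`), but not the default. Because
every unitarily invariant norm is unchanged by orthogonal rotation of
either side, OC needs no alignment of the two maps.

## The color-sphere validation

The simulator provides ground truth the pipeline can be scored against.
`sample_color_sphere()` draws $n$ points uniformly on $S^2$, each
tagged with the color whose RGB channels are its Cartesian coordinates
mapped affinely from $[-1,1]$ to $[0,1]$ (colors are labels only).
`generate_onym_graph()` makes every pair within the threshold angle a
synonym candidate and every pair within the same angle of the antipode
an antonym candidate (for thresholds below 90 degrees no pair can be
both), then admits each candidate independently with one acceptance
probability calibrated analytically: for uniform sphere pairs
$P(\theta \le t \text{ or } \theta \ge 180^\circ - t) = 1 - \cos t$, so
the probability is the target edge count divided by the expected
candidate count. Ten replicate worlds at the defaults land within a few
percent of the target degree.

Defaults — 1000 points, threshold 20 degrees, mean degree 3.5,
embedding dimension 10 — mirror the sparsity of real thesaurus cores,
where a word typically lists a handful of onyms out of a much larger
true set. What the simulator deliberately does *not* emulate: polysemy
(one token, several senses pulling its vector in different directions),
the heavy-tailed degree distributions of real dictionaries, and listing
biases (frequent words are more completely covered). Passing the
simulator therefore demonstrates that the machinery recovers a known
geometry from sparse signed relations; it does not bound the noise that
word-sense ambiguity adds in natural corpora.

`reconstruct_color_map()` runs core extraction, embedding, PC rotation
and normalization on the sampled graph alone;
`evaluate_reconstruction()` reports the overall correlation between the
original sphere coordinates and the first three reconstructed PCs (no
alignment needed, by the rotation invariance above). At the defaults the
reconstruction is strong: OC around 0.95, and the dot product classifies
essentially every listed pair correctly.

A known limitation, found while validating and worth stating plainly:
at mean degree 3.5 the energy minimum itself is mildly anisotropic
across the three recovered dimensions. Descending from the ground-truth
configuration reaches the same energy and the same per-PC amplitudes as
descending from random starts, so this is a property of the sparse
graph's minimum, not an optimization failure; with only ~3.5 constraints
per point the spherical shell is floppy enough that instance-specific
sampling noise deforms it. After normalization to mean squared length 3
the three leading standard deviations average close to (1.2, 1.0, 0.7)
rather than (1, 1, 1), while the remaining dimensions stay at numerical
zero. Denser graphs tighten the shell and the anisotropy shrinks.

`reconstruction_sweep()` re-runs the full loop over grids of the four
simulation parameters with replicates, recording per-cell failures
(e.g. an empty core at extreme sparsity) without aborting the sweep.

## Problem sizes and numerical choices

The test suite exercises the full default-scale simulation (five
reconstructions at 1000 points with 19 null refits each) plus property
tests on graphs of 2-20 words where brute-force oracles are exact;
gradient checks use central finite differences at relative error
$10^{-5}$, energy rotation-invariance is asserted to $10^{-9}$, and the
one-dimensional OC identity to $10^{-12}$. Degenerate inputs are
handled explicitly: empty lexicons parse to empty objects, an all-equal
configuration is a degeneracy error in PCA, zero-length word vectors
are excluded from angle computations with a warning, and an empty core
is a reported outcome rather than a crash.
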