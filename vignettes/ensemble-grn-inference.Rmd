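---
title: "Ensemble bounds for signed gene regulatory networks from knock-out data"
author: "grnbounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble bounds for signed gene regulatory networks from knock-out data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnbounds)
```

## The inference problem

Steady-state transcriptional profiles from gene knock-out (KO) experiments
are a classic substrate for gene regulatory network (GRN) inference, but the
problem is underdetermined: deleting a transcription factor perturbs its
direct targets *and* everything downstream of them, so steady-state data can
at best resolve the *accessibility relation* — which genes are reachable
from which — never, on their own, which of those influences are direct.
Many signed digraphs are therefore consistent with any finite KO compendium.

Instead of committing to one network, this package brackets the whole
consistent ensemble by two signed digraphs:

* the **upper bound** `G^U`, the largest network in the ensemble (it
  contains every direct or indirect influence supported by the data, each
  with a sign: `+` activation, `-` repression);
* the **lower bound** `G^L`, the edges that *every* consistent network must
  contain.

Edges in `G^U` but not `G^L` are **uncertain**: their existence cannot be
decided from the available data. The number of uncertain edges quantifies
the residual underdetermination, and — crucially — each uncertain edge
prescribes which further KO experiments would decide it.

## From a single-KO compendium to the bounds

Given the complete single-gene KO design (wild type plus one deletion per
gene, `R` technical replicates), the pipeline in `grn_ensemble()` is:

1. **Differential expression z-scores.** Per replicate and per gene *j*,
   an outlier-corrected mean and standard deviation of *j* across the
   experiments are computed (`corrected_stats()`); values deviating by more
   than `z_cutoff` (default 3) initial-scale units are excluded in a single
   pass, so that the retained values estimate *j*'s unperturbed
   distribution. The z-score `z(i, j) = (g_ij - mu_j) / s_j` measures gene
   *j*'s response to the KO of gene *i*; `Z(i, j)` averages it over
   replicates.

   *Numerical choice*: the initial location/scale estimates are the median
   and scaled MAD, not the plain mean/SD. With only `n + 1` experiments a
   handful of strong KO responses inflate a plain SD enough to mask
   themselves (no 3-SD rule could ever exclude them), whereas median/MAD
   stay anchored to the unperturbed majority. A second choice: when the
   retained values are exactly constant (noise-free data), `s_j` is floored
   at a tiny positive value (`1e-8 * max(1, |mu_j|)`) instead of producing
   `z = 0` for everything; a truly constant gene still yields `z = 0`
   through its zero numerator, but a genuine response yields a very large
   finite z-score.

2. **Signed accessibility = upper bound.** `Acc(i, j) = 1` iff
   `|Z(i, j)| > z_threshold` (default 2, strict), with sign `+` when
   `Z(i, j) <= 0` (the target falls when its regulator is deleted) and `-`
   otherwise (`accessibility_from_z()`). The diagonal is meaningless
   (deleting *i* trivially zeroes *i*) and is forced to 0.

3. **Edge weights.** `W(i, j)` is the replicate-averaged `|Pearson|`
   correlation between genes *i* and *j* across the single-KO experiments,
   excluding the KO-of-*j* experiment, whose value of *j* is an artifact of
   the deletion (`edge_weights()`). Pearson is used because perturbations
   propagate approximately linearly around the operating point.

4. **Sign-consistent local transitive reduction = lower bound.**
   `signed_ltr()` removes an edge `(i, j)` whenever some length-2 path
   `i -> k -> j` inside `G^U` explains it: the path's sign product equals
   the edge sign, and `w_cut * W(i, j) < W(i, k) * W(k, j)` (strict; ties
   retain the edge). Restricting to length-2 paths avoids the
   negative-cycle ambiguity (a cycle traversed twice gives a longer path),
   and every test is evaluated against the *original* upper bound, so the
   result is independent of edge-processing order. `w_cut = 0` disables the
   weight condition; raising `w_cut` makes removals harder, so the lower
   bound grows monotonically with it (at the price of more retained
   shortcuts, i.e. false positives).

The sign-agnostic baseline (`contrex_reduction()`) condenses strongly
connected components, transitively reduces the quotient DAG and expands
back, dropping every edge incident to a component of two or more genes
except the two edges of each two-gene cycle. Because it ignores signs, a
shortcut whose only indirect explanations are sign-*inconsistent* is still
removed — information the signed reduction retains. This is why the signed
bounds leave systematically fewer uncertain edges (compare
`example_bounds("signed")` and `example_bounds("unsigned")`).

```{r worked}
summary(example_bounds())
```

## Verifying uncertain edges with multi-gene KOs

For an uncertain edge `(i, j)`, a **separatoid** is a node set whose
deletion eliminates every indirect path from *i* to *j*; in that background
a response of *j* to additionally deleting *i* can only flow through the
direct edge. `compute_separatoids()` evaluates three cheap candidates from
the current upper bound `G^U` and the frozen initial one `G^U0`
(children/ancestors, descendants/parents, descendants/ancestors
intersections); enumerating *all* separatoids would amount to a
longest-path search, which is NP-hard.

`update()` on a fitted ensemble then searches the performed experiments for
pairs `(V_k, V_k + {i})` with a separatoid inside `V_k`, runs a two-tailed
pooled two-sample t-test (`alpha = 0.01`) on gene *j* between the pair, and
votes: a majority of rejections moves the edge into `G^L` (sign `+` if the
test-side mean is more often below the background mean, `-` otherwise;
sign ties keep the upper bound's sign), a majority of non-rejections
removes it from `G^U`, and an exact tie leaves it uncertain. All verdicts
within a round are taken against the round-start bounds and applied
together, and rounds repeat until nothing changes. When both samples are
exactly constant — which happens on noise-free simulated data — the test
degenerates and rejects exactly when the means differ beyond a relative
tolerance of `1e-8`.

`greedy_design()` proposes the next experiments: a greedy set cover over
candidate (background, test) pairs, each step choosing the pair that
completes verification for the most still-uncovered uncertain edges (ties:
smaller background, then lexicographic). The experiment-pair convention is
deliberate — verification needs both halves. `multiplexed_design()` re-runs
the greedy step, removing covered edges from the objective, until no
uncertain edge remains coverable, mimicking how a multiplexed assay
consumes a ranked list. The KO-size constraint starts at 2 genes and
`escalate_constraint()` raises it by one exactly when no feasible proposal
exists. `iterative_inference()` closes the loop against the bundled
simulator until the bounds converge (`G^U = G^L`, a unique network) or no
design can help.

## The bundled simulator

`kinetic_model()` + `generate_compendium()` emulate a stochastic
steady-state KO compendium. mRNA `x_i` and protein `y_i` follow
chemical-Langevin kinetics,

$$\mathrm{d}x_i = \big[m_i f_i(y) - \lambda^{RNA}_i x_i\big]\mathrm{d}t +
  \sigma_{int}\,\mathrm{d}W, \qquad
\mathrm{d}y_i = \big[r_i x_i - \lambda^{Prot}_i y_i\big]\mathrm{d}t +
  \sigma_{int}\,\mathrm{d}W,$$

integrated by Euler–Maruyama with non-negativity clipping; a KO zeroes the
maximal transcription rate `m_i`. The steady state is the time average of
the trailing 20 % of the horizon (damping the Langevin fluctuations), and
each measured value is multiplied by log-normal measurement noise
`exp(N(0, sigma_meas^2))`. Trajectories start at the unregulated
deterministic fixed point, which shortens transients enough that a horizon
of 30 time units with step 0.05 settles all cascades.

The regulation input is a gated Hill model,
`f_i(y) = (b_i + (1 - b_i) A) R` with `A` the noisy-OR of the activators'
Hill occupancies and `R` the product of the repressors' complements.  Two
properties drove this choice over a single joint product:

* *independent activator inputs* — deleting one activator changes the
  target even when co-activators remain, and a regulator's direct input
  stays measurable in KO backgrounds that remove other inputs (with a pure
  AND gate, a separatoid background that contains a co-activator silences
  the target and makes the direct edge untestable);
* *repressors act on basal transcription too* — a repressor remains
  measurable even in backgrounds where every activator of its target is
  deleted.

Parameter defaults (all configurable): `m, r ~ U(0.5, 2)`,
`lambda ~ U(0.5, 1.5)`, Hill exponent `h` drawn from {1, 2}, basal fraction
`b = 0.01`, `sigma_int = sigma_meas = 0.05` (measurement noise of a few
percent, intrinsic fluctuations of comparable stationary magnitude). Each
half-saturation constant `K` is calibrated to the regulator's wild-type
*operating* protein level by iterating the deterministic fixed point: every
present regulation then sits at its most sensitive (half-max) point, so each
gain or loss of a regulator produces a strong response — without the
calibration, regulated regulators drift far from a fixed `K` and entire
cascades become silent. `random_grn()` draws reference topologies in which
only a designated regulator subset (default 25 % of genes) has outgoing
edges, mirroring the transcription-factor fraction of real genomes and of
benchmark gold standards. This bounds each gene's ancestor cone by the
regulator count, which matters at desk scale: the z-score baseline of a
gene is estimated from the experiments that do *not* perturb it, and a gene
whose ancestors cover half the design has no uncontaminated majority for
any robust estimate to anchor on.

**What the simulator does not emulate**: thermodynamic promoter models with
synergistic (AND-like) transcription-factor cooperation, autoregulation,
time-series read-outs, and the deep, dense regulatory cascades of
genome-scale networks. Passing tests on these synthetic data therefore
demonstrate the correctness of the inference machinery under the method's
stated assumptions (detectable, sign-faithful KO responses), not
performance on real expression compendia, where fan-in compensation and
baseline contamination produce the false negatives discussed below.

## Problem sizes and noise regimes used in validation

The test suite and the acceptance script run at sizes a laptop handles in
minutes, chosen as the package's study conditions:

* *bounds comparison*: 20 seeded 20-gene networks (alternating acyclic and
  cyclic), 10 replicates, default noise; the signed reduction must leave a
  median number of uncertain edges no larger than the unsigned baseline at
  `w_cut` 0 and 0.3.
* *convergence*: the full iterative loop on noise-free 15-gene DAGs must
  end with `G^U = G^L`.
* *exact recovery*: on 20-gene DAGs the loop must return exactly the signed
  reference network in at least 90 % of seeds. This property is validated
  in the noise-free limit (`sigma_int = sigma_meas = 0`) with `w_cut = 0`,
  and deliberately so: with any nonzero measurement noise the t-test's
  type-I rate `alpha = 0.01` caps the probability of a perfect run at about
  `0.99^k` for `k` testable spurious edges (~15 per network, i.e. a ~14 %
  irreducible failure rate), and the weight condition at `w_cut = 0.3`
  occasionally retains a shortcut whose indirect correlations are weak —
  the same false-positive trade-offs the method exhibits on noisy data by
  design. The noise-free limit isolates what this property is meant to
  check: that the separatoid search, the vote logic and the greedy design
  jointly identify every uncertain edge correctly.
* *oracle checks*: the separatoid formulas are cross-checked against
  exhaustive simple-path enumeration on digraphs with up to 8 nodes, and
  the DAG transitive reduction against an exhaustive minimum-subgraph
  search.

## Degenerate inputs and tie-breaks

* Duplicate ordered edges, self-loops and out-of-range weights are
  constructor errors; reading a network with conflicting duplicate signs is
  a parse error with the offending pair named.
* `corrected_stats()` falls back to the uncorrected moments (with a
  warning) if the exclusion rule would discard every value.
* A zero-variance gene contributes weight 0 (with a warning) to the
  correlation matrix, and z-score 0 through its zero numerator.
* The weight tie `w_cut * W(i,j) = W(i,k) * W(k,j)` retains the edge
  (strict inequality, as the removal condition is printed).
* Sign ties in the update vote keep the upper bound's sign; vote ties leave
  the bounds untouched, and a full round of ties terminates the update
  loop.
* `update()` is idempotent, never removes a lower-bound edge, and never
  resurrects an edge removed from the upper bound.

## Known limitations

* False negatives are the dominant error on noisy data — fan-in targets
  whose remaining regulators compensate the deleted one can stay below the
  z-threshold, and an edge missing from the initial upper bound can never
  be recovered by later experiments. This mirrors the behaviour the method
  is known for; lowering `z_threshold` trades these against false
  positives.
* Incoherent path interference can flip the sign of an edge in the upper
  bound; the update stage corrects the sign only for edges that become
  uncertain and verified.
* Only the three printed separatoid candidates are computed; edges whose
  indirect paths none of them can block (given the current bounds) stay
  uncertain until escalation makes larger backgrounds feasible.
* The greedy design is a surrogate for a constrained-optimization design;
  it guarantees feasible proposals, not globally minimal experiment counts.
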