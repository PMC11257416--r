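---
title: "CP tensor factorization with missing values: methods and design"
author: "censoredCP maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CP tensor factorization with missing values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censoredCP)
```

## The model

A tensor is a multidimensional numeric array; each axis is a *mode* (for
example sample × antigen × receptor in a systems-serology study). The
canonical polyadic (CP, also PARAFAC) decomposition approximates an N-mode
tensor $\mathcal{T}$ by a sum of $R$ rank-one tensors,

$$\mathcal{T} \approx \widehat{\mathcal{T}}
  = \sum_{r=1}^{R} \mathbf{a}^{(1)}_r \circ \cdots \circ \mathbf{a}^{(N)}_r,$$

where $\circ$ is the outer product and the vectors
$\mathbf{a}^{(n)}_r$ stack into per-mode factor matrices
$\mathbf{A}^{(n)} \in \mathbb{R}^{I_n \times R}$. Fitting minimizes the
squared Frobenius error between $\mathcal{T}$ and
$\widehat{\mathcal{T}}$. Because the reconstruction is always complete,
a CP fit doubles as an imputation of whatever cells were never measured —
and the quality of that imputation on deliberately hidden cells is a
practical cross-validation signal for both the solver and the rank.

Biological tensors are rarely complete: merging assays measured on
different sample subsets, or expanding a matrix-shaped study into a tensor,
leaves cells with no measurement. The package represents this with
`MaskedTensor`: a dense value array plus a logical observation mask
(`NA` in the values exactly where the mask is `FALSE`).

## Three solvers

All solvers start from the same deterministic initialization
(`initializeFactors`: i.i.d. standard normal entries, a pure function of
shape, rank and seed), so they can be compared from a shared starting
point. All use the same stopping rule: stop when the relative change of the
fitting error between iterations falls below `tolerance`
(default $10^{-6}$), or at the iteration cap.

**Censored alternating least squares (`fitCALS`).** Classical ALS updates
one mode at a time: the mode-$n$ factor matrix is the least squares
solution of the mode-$n$ unfolding against the Khatri-Rao product of the
other factor matrices. With missing data the unfolding has holes, so the
censored update solves each *row* of the factor matrix against only the
columns where that row is observed — the minimum-norm solution via a
rank-revealing pseudoinverse (singular values below
$\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_{\max}$ are dropped).
Rows that miss the same set of columns share the same reduced design
matrix, so they are grouped by missingness pattern and solved in one
batched call per pattern; grouping changes cost, not results. A row with no
usable entries at all (possible under heavy chordwise masking) is set to
zero — the minimum-norm solution of an empty system — with a warning.

**ALS with single imputation (`fitALSSI`).** The expectation-maximization
style alternative: missing cells are filled from the current
reconstruction, one complete-data ALS sweep runs on the filled tensor, and
the fill is refreshed from the new reconstruction — once per full sweep,
not per mode. Filled cells have zero residual, so the complete-data loss
the sweep minimizes upper-bounds the observed-cell loss, which therefore
descends monotonically. Fitting and imputation errors are always computed
on the original observed and held-out entries, never on filled values.
On a complete tensor the fill is empty and `fitALSSI` and `fitCALS`
execute the identical algorithm — the package routes both through the same
pseudoinverse solve, so their iterates agree bitwise.

**Direct optimization (`fitDO`).** All factor matrices are flattened into
one parameter vector and the masked loss
$\sum_{\text{observed}} (\mathcal{T}_p - \widehat{\mathcal{T}}_p)^2$
is minimized with L-BFGS-B. Missing cells contribute exactly zero to the
loss and gradient. The analytic gradient block for mode $n$ is
$-2\,[\mathbf{M}_{(n)} * (\mathbf{T}_{(n)} -
\mathbf{A}^{(n)}\mathbf{W}^\top)]\,\mathbf{W}$ with $\mathbf{W}$ the
Khatri-Rao chain of the other modes; it is tested against central finite
differences. R's optimizer has no per-iteration callback, so error and
time traces are recorded at gradient evaluations and `iterationCount`
counts gradient evaluations. The iteration cap is configurable
(`doMaxIter`); the strict historical budget of 50 is available, but the
default is 500 because gradient descent needs far more iterations than the
least-squares sweeps to converge. Optimizer status is surfaced through the
convergence flag. Box constraints are off by default — the loss is
unconstrained — but bounds can be passed through.

### Conventions that make the algebra line up

* **Unfolding**: mode $n$ on the rows; remaining modes in ascending order
  with the lowest-index one varying fastest (for 3 modes, the familiar
  concatenation of frontal slices).
* **Khatri-Rao chains**: for the mode-$n$ subproblem the remaining factors
  are multiplied in *descending* mode order, which makes the chain's row
  ordering match the unfolding's column ordering for any number of modes.
* **Indexing**: 1-based inside R, matching array semantics; 0-based in all
  on-disk formats, stated in every file header.

## Held-out masking and the error split

`maskEntries` hides exactly $\mathrm{round}(f \cdot \#\text{observed})$
randomly chosen observed cells (half-away-from-zero rounding).
`maskChords` hides whole fibers along a chosen mode: chords with at least
one observed entry are sampled without replacement until the held-out
entry count first reaches the same target, so the achieved count can
overshoot by at most one chord (the overshoot is logged). Both masks are
deterministic in their seed, never touch pre-existing missing cells, and
serialize to coordinate CSV for audit.

Errors are normalized squared residuals restricted to an evaluation
subset: $\sum_p (\mathcal{T}_p - \widehat{\mathcal{T}}_p)^2 / \sum_p
\mathcal{T}_p^2$ with both sums over the subset. *Fitting error* evaluates
the observed, non-held-out cells; *imputation error* evaluates the
held-out cells. Restricting the denominator to the same subset keeps the
two directly comparable and scale-free; pre-existing missing cells are
never scored, as they have no ground truth. Divergence between a
plateauing fitting error and a rising imputation error is the overfitting
signature to watch for, particularly under heavy chordwise masking.

## The benchmark protocol

`runBenchmark` is the full evaluation loop: per replicate it derives a
(mask seed, init seed) pair from the base seed, draws one held-out mask,
and runs every requested method at every rank from that shared mask and
initialization — so method comparisons are paired. Defaults follow the
protocol the package is built around: rank sweeps 1–10 for 3-mode and
1–20 for 4-mode tensors, 20 replicates, shared tolerance $10^{-6}$.
Per (method, rank) the final errors are reduced to medians and quartiles
(linear-interpolation convention; the convention is not standardized
across software, so it is fixed here once). `bestImputedRank` picks the
rank minimizing the median imputation error, falling back to fitting error
when nothing was held out, with ties broken toward the smaller rank —
preferring the more parsimonious model. Wall time is recorded per
iteration with the elapsed-time clock and reported, but never asserted in
tests: it is hardware, BLAS and load dependent. Solver failures are
recorded per record rather than aborting a sweep.

## The synthetic generator

`simulateCPTensor` draws ground-truth factors with i.i.d. standard normal
entries, adds i.i.d. Gaussian noise of chosen standard deviation, and
applies entrywise or chordwise pre-existing missingness. Standard normal
factors give signal entries a standard deviation of about $\sqrt{R}$, so
"5% noise" in the package's own tests means `noiseSD = 0.05 * sqrt(R)`.
An optional collinearity level mixes each component with a shared
direction per mode, producing the ill-conditioned fixtures useful for
stress testing. What the generator deliberately does *not* emulate:
heteroscedastic assay noise, non-Gaussian value distributions,
systematically structured (non-random) missingness, and model
misspecification — real data are never exactly low rank. Tests passing on
these fixtures therefore validate the algebra and the protocol, not
field performance on any particular assay.

`factorMatchScore` quantifies recovery: per component matching, the
product over modes of absolute cosine similarities, averaged over
components and maximized over component permutations (exhaustively up to
rank 6, greedily above). It is invariant to the CP model's inherent
indeterminacies — component order, paired sign flips, and compensating
rescaling across modes.

## Numerical choices and degenerate inputs

* Stopping compares successive fitting errors, the only quantity common to
  all three solvers; a run whose fitting error reaches machine epsilon is
  declared converged outright, because relative changes of a
  $10^{-30}$-sized error are floating-point noise.
* For `fitDO` the shared relative-change tolerance maps onto L-BFGS-B's
  `factr` as `tolerance / .Machine$double.eps`.
* The pseudoinverse cutoff ($\max(\mathrm{dim}) \cdot \varepsilon \cdot
  \sigma_{\max}$) handles rank-deficient censored subproblems, which occur
  whenever a row retains fewer observed columns than components.
* Test problem sizes are kept deliberately modest (largest benchmark:
  $40 \times 20 \times 15$ at rank 4 with 20 replicates) — large enough
  for the asymptotics that matter, small enough that the whole suite runs
  in about a minute.

## Known limitations

* **Degenerate trajectories.** Unregularized CP-ALS — censored or plain —
  can enter a degenerate regime from an unlucky random start (roughly
  5–10% of inits in our recovery setting): the fitting error plateaus
  above zero while factor norms diverge and reconstructions at unobserved
  cells explode. This is a well-known CP pathology, and it is exactly why
  the benchmark protocol aggregates over many random initializations with
  median summaries rather than trusting any single run. Practical advice:
  inspect the convergence flag, rerun non-converged fits from a different
  seed, and treat per-run recovery claims with suspicion.
* **Near-ties on exact low-rank data.** On synthetic tensors that are
  exactly low rank with light noise and entrywise masking at the true
  rank, censored ALS and single-imputation ALS converge to the same fixed
  points (the single-imputation iteration is an EM scheme whose stationary
  points are stationary points of the observed loss). Their imputation
  errors then tie to within a fraction of a percent, and which one
  measures marginally lower is decided by the stopping rule: the damped
  single-imputation trajectory stops slightly less converged, i.e.
  slightly less overfit to noise on held-out cells. The practical
  advantages of censoring appear under model misspecification, higher
  ranks and structural (chordwise) missingness — conditions of real data,
  not of an exactly low-rank simulation.
* Sparse-tensor storage, nonnegativity and other constrained CP variants,
  and regularized censored solves are out of scope.

## A worked run

```{r example, eval = FALSE}
inst <- simulateCPTensor(c(20, 15, 10), rank = 3, noiseSD = 0.05 * sqrt(3),
                         seed = 42)
held <- maskEntries(inst@tensor, 0.1, seed = 43)
bm <- runBenchmark(inst@tensor, methods = c("cals", "als-si"), ranks = 1:5,
                   maskStyle = "entry", fraction = 0.1, nReplicates = 20,
                   baseSeed = 44)
benchmarkSummaries(bm)
bestImputedRank(bm, "cals")
plotErrorVsRank(bm)
```
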