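---
title: "Detecting selective shifts with non-equilibrium mutation-selection models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective shifts with non-equilibrium mutation-selection models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

mutselshift implements a codon substitution model in which the rate of
substitution factors into a mutation process and a population-genetic
fixation process.  Mutations arise by an HKY nucleotide process with
transition/transversion ratio $\kappa$ and target-base frequencies
$\theta_{A,C,G,T}$, restricted to single-nucleotide changes among the 61
sense codons of the universal code.  A new mutant codon $b$ arising on a
wild-type background $a$ carries a selection coefficient determined by
the Darwinian fitnesses of the encoded amino acids,
$s_{ab} = f_b / f_a - 1$, and fixes with the Wright-Fisher diffusion
probability

$$P_{fix}(a,b) = \frac{1 - e^{-2 s_{ab}}}{1 - e^{-4 N_p s_{ab}}},$$

evaluated *without* the usual log-linearisation of the numerator.  The
substitution rate is $q_{ab} = 2 N_p \mu \cdot
\theta(\mathrm{target}) \kappa^{[\mathrm{ti}]} \cdot P_{fix}(a,b)$ for
single-nucleotide neighbours and $0$ otherwise; synonymous changes are
neutral and fix with probability $1/(2N_p)$.  Keeping the exact
diffusion numerator makes the $61 \times 61$ generator asymmetric: the
process violates detailed balance ($\pi_a q_{ab} \ne \pi_b q_{ba}$) and
is not time-reversible, which is what permits non-equilibrium behaviour
such as adaptive episodes and distinct root codon frequencies.  One
amino acid (tyrosine, last in alphabetical order) has its fitness
anchored at 1; the 19 remaining fitnesses are free parameters shared by
all sites.

Every generator is rescaled so that one unit of branch length equals
one expected substitution per site under the *neutral* counterpart of
the model (all fitnesses 1, same mutation parameters); the individual
mutation rate $\mu$ cancels in this scaling.

Two extensions relax equilibrium assumptions:

* **Free root frequencies.** A separate 61-vector of codon frequencies
  (60 free parameters) may apply at the root instead of the model's
  stationary distribution.
* **Selective shifts.** The fitness profile may change at the top of
  any branch; the new profile (19 new parameters) governs that branch
  and all its descendants until another shift intervenes.  Shifts on
  both basal branches are not permitted, so the root process survives
  on at least one side.

## Likelihood and fitting

The likelihood is computed by Felsenstein pruning over site patterns,
with each branch propagated by the transition matrix $e^{Qt}$ of its
own model, and the root closed by either the root model's stationary
distribution or the free root frequencies.  Partial likelihoods are
rescaled per pattern whenever their column sums approach the underflow
floor.

The exported `transition_probabilities()` uses scaling-and-squaring
Padé approximation (`Matrix::expm`), which is valid for asymmetric and
even non-diagonalisable generators.  Inside the fitting loops the
engine instead computes one eigendecomposition per model and builds all
branch propagators from it, falling back to Padé whenever the
eigenvector matrix fails a reconstruction check (error above $10^{-8}$
relative); tests assert the two routes agree to $10^{-10}$.  The
stationary distribution is obtained as the left null vector of $Q$ by a
direct solve with one step of iterative refinement — no reversibility
shortcut is available or used.

Maximum-likelihood fitting uses the bounded derivative-free optimiser
`minqa::bobyqa` over transformed coordinates: fitnesses as
$(f - 1) \times 10^5$ inside a box $|f - 1| \le 10^{-4}$, $\kappa$ on
the log scale, $\theta$ as additive log-ratios.  Free root frequencies
never enter the outer search: for fixed values of the other parameters
their maximum-likelihood values solve a concave mixture-weight problem,
so an inner EM loop profiles them out exactly at every objective
evaluation (they are still counted as 60 free parameters wherever
parameter counts matter).  Fitness start values are neutral ($f = 1$),
$\theta$ starts at the observed nucleotide frequencies, $\kappa$ at 2,
and the root EM at the observed codon frequencies.  Fits are
deterministic given identical starts and settings, and the best
log-likelihood recorded during a fit never decreases.

### Identifiability and the local refinement mode

A single alignment of a few hundred codons identifies only part of a
fitness profile: amino acids that the stationary distribution makes
rare or absent contribute directions in which the likelihood is flat to
machine precision (observed Hessian eigenvalues span $10^3$ down to
$10^{-9}$).  Derivative-free search leaves such coordinates at
essentially arbitrary values.  `fit(local = TRUE)` therefore provides a
deterministic cyclic coordinate-quadratic refinement that moves only
coordinates whose estimated curvature exceeds a threshold and leaves
unidentifiable ones exactly where they started.
`compare_fixation_forms()` builds on it for the comparison between the
diffusion and linearised fixation probabilities: both forms are refined
from the *same* warm start (the non-reversible optimum), so the
reported difference measures what the fixation form changes in the
directions the data inform, rather than optimiser noise in directions
they do not.  Under this protocol the two forms agree to well below
$10^{-6}$, i.e. they are numerically indistinguishable on data of this
size — consistent with the observation that the two likelihood
surfaces themselves differ by a fraction of a log unit.

## The greedy AICc shift search

`greedy_shift_search()` infers the number and positions of shifts:

1. Fit the shift-free model.
2. For every candidate branch (all branches except those already
   carrying a shift and, when one basal branch carries a shift, the
   other basal branch), estimate a provisional set of 19 new fitnesses
   for that branch and its descendants *with everything else frozen*.
   The provisional objective reuses the incumbent's transition matrices
   outside the candidate clade through an exact outside-weights
   identity, so each candidate costs only the clade's own
   recomputation; tests verify the identity against the full engine.
3. Select the branch with the lowest provisional AICc (ties break
   toward the smallest branch id).
4. Re-optimise all free parameters of the augmented model jointly
   (`refit_scope = "frequencies"` restricts this to
   $\kappa$, $\theta$ and root frequencies instead).
5. Accept the shift iff the re-optimised AICc is strictly below the
   incumbent's; repeat until a rejection or `max_shifts`.

AICc is $-2\log L + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of codon
columns — the only sample size the likelihood sees.  The parameter
count $k$ comprises $19 \times (\text{profiles})$ fitnesses plus the
shared parameters actually freed ($\kappa$: 1, $\theta$: 3, free root:
60), counted once; shared terms cancel in AICc differences except
through the small-sample correction, so the convention is fixed and
stated.  Optimisation failures on a branch exclude it from selection;
if every candidate fails, the search reports
`optimisation_failure` as its outcome.  A settings hook multiplies the
penalty term for sanity checks (an astronomically large penalty must
always return zero shifts).

Per-stage optimiser budgets (`search_settings()`) default to
`maxfun = 2500, rhoend = 3e-3` for the initial fit, a warm-started
`rhobeg = 0.4, rhoend = 4e-3` re-optimisation, and
`maxfun = 350, rhoend = 0.06` for provisional candidate fits, which
only need to rank branches.  After the search terminates, the accepted
model's reported estimates receive a short deterministic
identifiable-coordinate refinement (two sweeps), which can only
improve the likelihood and reduces derivative-free wander in the
returned fitness values.  These budgets keep a full search on a
20-taxon, 300-codon data set under a minute of CPU while leaving
search decisions (AICc differences of tens of units) far above the
residual optimisation error.

## The simulator

`simulate_tree()` generates random ultrametric pure-birth trees whose
topology follows the Aldous beta-splitting family: a clade of $n$ tips
splits $i$ against $n-i$ with weight
$\Gamma(\beta+i+1)\Gamma(\beta+n-i+1)/(i!\,(n-i)!)$.  $\beta = 0$
reproduces the Yule topology distribution exactly (verified against the
exact Colless-index recursion), $\beta = 1.9$ gives the balanced and
$\beta = -0.7$ the imbalanced regime.  Waiting times with $k$ lineages
are Exponential($k\lambda$) with birth rate $\lambda$ and death rate 0;
tips sit one further waiting time after the last split, so tree age is
random.  Event times are attached root-down, each successive time to a
uniformly chosen internal node whose parent is already timed.

Study-condition defaults are built into `simulation_spec()`: fitness
profiles draw their 19 free values i.i.d. Uniform$(1 \pm 5\times
10^{-5})$; $N_p = 10^5$; simulation uses $\kappa = 1$ and uniform
$\theta$; ASHIFT blocks use $\beta = 0$ and birth rate 0.5 with
equilibrium root frequencies and 0 or 1 shifts; RFREQ blocks draw root
codon frequencies from a symmetric Dirichlet with $\alpha = 1$ (the
least-informative choice on the simplex; the concentration is
configurable because only "symmetric" is prescribed).  Shift positions
are drawn in two stages — first a node depth (in edges from the root)
uniformly among the depths present, then a node uniformly within that
depth — which spreads shifts over time depths.  Sequence evolution is
exact continuous-time Markov-chain simulation along each branch
(waiting times and jump probabilities from the branch's own scaled
generator), with an alternative mode that samples transitions from
$e^{Qt}$; the two agree in distribution by construction and by test.

With selection coefficients up to $10^{-4}$ and $N_p = 10^5$,
population-scaled coefficients $4 N_p s$ reach $\pm 40$: stationary
distributions concentrate strongly on the fittest amino acids, and
rates into deleterious states carry factors as small as $e^{-40}$.
Two practical consequences are documented in the tests: chains mix
astronomically slowly between fitness basins (so "long branch reaches
stationarity" examples use weak-selection profiles), and single
alignments identify only the fitness differences among amino acids the
data actually visit.

What the generator does *not* emulate: indels, rate variation across
sites, site-specific fitness profiles, multi-nucleotide mutations, and
non-ultrametric trees.  Passing tests on these simulations therefore
demonstrate correct recovery of the model's own process, not robustness
to real-data violations of it.

## Numerical choices

* `1 - e^{-x}` is always computed via `expm1`; the naive form loses all
  relative precision at the $x \sim 10^{-5}$ arguments this model
  produces.  The fixation probability matches 50-digit reference values
  to better than $10^{-8}$ relative error across the supported range.
* $|s| < 10^{-12}$ triggers the exact neutral limit $1/(2N_p)$ (the
  defining expression is 0/0 at $s = 0$).
* The supported selection-coefficient ceiling defaults to
  $5 \times 10^{-4}$, comfortably covering profiles drawn within
  $1 \pm 5\times10^{-5}$ and the $\pm 10^{-4}$ search box; larger
  $|s|$ raises an error naming the offending coefficient.
* Codon order is alphabetical (A < C < G < T) lexicographic; amino
  acids are alphabetical by one-letter code with tyrosine anchored.
* Branches are addressed by the index of their child node, stable
  across Newick round-trips.
* AICc ties in candidate selection break toward the smallest branch id.
* Non-ultrametric node ages are measured against the deepest tip
  (maximum root-to-leaf length minus root-to-node length).

## Problem sizes used by the test suite

The packaged checks run scaled-down versions of the full simulation
study: 10 replicates of the 10-taxon/300-codon one-shift block and of
the 20-taxon/300-codon no-shift block, 5 replicates per RFREQ cell at
birth rates 0.5 and 10, and small-instance exhaustive-enumeration
oracles for the likelihood.  Full-size blocks (20 replicates, up to
900 codons) reproduce the complete study on a workstation via
`run_block()` and `greedy_shift_search()` but are not part of the
default suite.

## Limitations

The method assumes one fitness profile for all sites, a fixed tree
with meaningful branch-length units, weak mutation and small selection
coefficients.  The greedy search is conservative near the tips of the
tree (recent shifts leave few substitutions to detect) and can add a
spurious second branch when the true shift is ancient.  Root-frequency
co-estimation degrades when the birth rate is far from the neutral
substitution rate, in opposite directions for root and tree
parameters.
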