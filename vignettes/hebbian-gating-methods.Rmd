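---
title: "Hebbian gating and the analysis of compositional cue-location learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hebbian gating and the analysis of compositional cue-location learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebbgate)
```

## The task and its geometry

`hebbgate` models a supervised spatial learning task: on each trial a
symbolic cue (one of five colors crossed with five shapes, 25 cues in all)
indicates a target location inside a circular arena of radius 265 px, and
the learner places a cursor at the location it predicts. Under the **grid**
mapping one cue dimension sets the horizontal and the other the vertical
coordinate of a 5 x 5 lattice; under the **polar** mapping one dimension
sets the ring (radius) and the other the spoke (angle). An experiment has 14
blocks; each block queries 9 training cues with feedback and then the 16
held-out test cues without feedback, so generalization requires composing
the two spatial factors for cue combinations never trained.

Curricula manipulate which 9 cues are trained and in what order:

* *aligned*: one full level of each cue dimension (a spatial row + column,
  or the central ring + one spoke), so consecutive training trials change
  one factor at a time;
* *misaligned*: the two diagonals of the cue lattice, so both factors change
  on every trial;
* *blocked* vs *interleaved* (always axis-aligned): one axis queried in
  trials 1-4, the shared cue at trial 5, the other axis in trials 6-9, with
  the leading axis alternating between blocks — versus a fully random order.

The exact pixel geometry of the targets is not a published quantity; the
package uses 5 grid levels at offsets $\{-2,\dots,2\}\times 90$ px (corners
at $180\sqrt2 \approx 254.6$ px, inside the wall) and rings at
$\{53, 106, 159, 212, 245\}$ px with spokes $72^\circ$ apart, rotated by a
random per-participant angle. These choices maximise separation subject to
containment and are exposed as arguments of `make_mapping()`.

## Response models and the LLR

All behavioural scoring uses proper probability densities over the arena
disk, normalised numerically on a shared 2 px Cartesian lattice so that
truncation at the wall and the polar product form are handled uniformly and
every model competes on identical support:

* **random**: uniform over the disk;
* **bilateral**: a narrow distribution centred on the ground truth — an
  isotropic Gaussian in Cartesian coordinates (grid) or the product of a
  Gaussian in radius and a wrapped Gaussian in angle (polar), following the
  task's native geometry;
* **unilateral**: correct on one dimension, uniform over the other — a
  Gaussian ridge along a row, column, ring or spoke.

The headline measure is the log-likelihood ratio
$\mathrm{LLR} = \log p(\text{responses} \mid \text{bilateral}) -
\log p(\text{responses} \mid \text{random})$, summed over trials;
positive values signal generalization, and a *generalizer* is a participant
or network whose mean per-block test LLR over blocks 8-14 is positive.

The dispersion defaults to $\sigma = 20$ px (the full-reward radius of the
points rule) for Cartesian and radial components, with angular dispersion
$\min(\sigma/\rho, 0.3)$ rad at truth radius $\rho$; a per-participant
maximum-likelihood $\sigma$ (`fit_sigma_ml()`) is available when the fixed
default is not wanted. The 2 px lattice keeps every density's integral at 1
to machine precision by construction, and agrees with the analytic Gaussian
normalisation to about $10^{-3}$ relative error whenever the truth is at
least $4\sigma$ from the wall.

## The two learning agents

Both agents are linear read-outs of a two-hot cue encoding (5 color + 5
shape slots) onto four spatial effectors: horizontal translation, vertical
translation, expansion $\rho$ and rotation $\phi$, composed into a screen
position as $p = R(\phi)\,(t_x + \rho,\; t_y)$. A pure grid solution uses
the translations; a pure polar solution uses expansion and rotation. The
**vanilla network** trains its weights $W$ with online SGD. The **Hebbian
gating network** multiplies $W$ elementwise with a binary gate
$g_\tau(U)$ and trains the gate weights $U$ with a Hebbian rule driven by
trial-to-trial *surprise*: comparing the current feedback trial with each
earlier feedback trial of the same block (weighted by a discount
$\lambda^{t-i}$, normalised), with input surprise the absolute difference of
the two-hot inputs and output surprise the indicator of a change in each
effector coordinate of the feedback location.

The gate update implements symmetric coincidence detection:

* **excitation** toward 1 when an input and an output change together;
* **preactivated depression** toward 0 whenever the input changes,
  whatever the output does — so a pair whose output always follows its
  input settles at the fixed point 0.5 of $(1-U) - U$;
* **converse depression** toward 0 when an output changes while the whole
  input dimension is static.

The converse term is the package's reading of "changing together" as a
symmetric relation. It is what makes the gate pattern mapping-sensitive: in
the polar task the translation coordinates of the feedback change whenever
*either* cue dimension changes, so without the converse term the
translation gates open everywhere and the gated network inherits the
vanilla network's non-compositional solution. With it, promiscuous
couplings are driven to fixed points at or below $a/(1+a) \le 1/2$ (for an
input-change rate $a$), well under the threshold, while exclusive couplings
sit at 0.5.

### Hyperparameters

One shared set serves all eight condition cells, as the behavioural
comparison requires. Internally all channels are unit-scaled (translations
and expansion in arena radii, rotation in half-turns) so a single learning
rate fits all four effectors.

| parameter | default | role and rationale |
|---|---|---|
| `sgd_rate` | 0.025 | online learning rate; with `steps_per_trial` it sets the 126-trial budget so that training accuracy saturates (positive late-block training LLR) while test behaviour still separates the agents |
| `steps_per_trial` | 3 | gradient steps per feedback trial |
| `tau` | 0.43 | gate threshold; sits between the 0.5 fixed point of cleanly coupled gates, the ~0.44 equilibrium of ambiguously coupled gates under interleaved orderings, and the $\le 0.40$ equilibria of incidental couplings. Interleaving therefore degrades gate selectivity — the mechanism behind the blocked-over-interleaved advantage |
| `alpha_U` | 0.25 | Hebbian rate: fast enough to open correct gates within the first blocks, slow enough that within-run streaks do not flip gates across the threshold |
| `lambda` | 0.5 | comparison discount; recent trials dominate, as within-block runs are the informative unit |
| `rho_init` | 0.4 | positive initial bias of the expansion channel (an outward reach prior). The composed effector map has a sign symmetry — $(-\rho, \phi + \pi)$ lands on the same point — and training from symmetric small weights lets different cues settle in different sign basins, deadlocking the shared weights; a positive bias keeps all cues in one basin |
| `w_init_sd` | 0.01 | initial weight scale |

The SGD loss is squared error in the task's native geometry: plain
Euclidean for the grid mapping; squared radial error plus squared
arc-length error (angular residual wrapped to $(-\pi,\pi]$, tangential pull
evaluated at the feedback radius so it stays bounded at the centre) for the
polar mapping. The two losses agree to second order near the target; the
polar form unrolls the circle so that rotation errors near half a turn
still produce a useful gradient — under a raw Euclidean loss the rotation
gradient carries a $\sin(\Delta\phi)$ factor that vanishes exactly where the
error is largest, and the polar solution is not reachable within the
experiment's 126 feedback trials. The same dual geometry defines the
bilateral response density, so agent training and behavioural scoring use
one notion of error.

Responses are confined to the arena (radial clamp), as the task display
confines the cursor.

With these defaults, across independent seeds: vanilla networks end with
positive late-block training LLR but negative total test LLR in all four
Experiment-1 cells and essentially no generalizers; Hebbian networks show
higher mean test LLR aligned-vs-misaligned and blocked-vs-interleaved in
both mappings; and under grid-aligned training the end-of-run open-gate set
equals the ground-truth factorisation (each cue dimension gating exactly its
own effector) in virtually every seed. Exact cohort LLR magnitudes depend on
unpublished training details and are not reproduction targets.

## Stagewise policy fits and model selection

Test behaviour is modelled as a monotone sequence of policies — random,
unilateral (one dimension learned; which one is a fitted parameter), then
bilateral — with changes allowed only at block boundaries, where the 16
test trials per block make trial-level switching unidentifiable. The seven
admissible stage sets are all ascending subsequences of
random ≺ unilateral ≺ bilateral. `fit_policy_sequence()` searches all
block-to-stage assignments exhaustively (stages may be empty, so larger
models nest smaller ones and adding a stage never lowers the maximised
likelihood); evidence is approximated by $-\mathrm{BIC}/2$ with one free
parameter per switch point plus one when the unilateral dimension is
fitted. `rfx_bms()` turns per-participant evidences into population model
frequencies with the variational Dirichlet scheme for random-effects
Bayesian model selection (uniform prior concentration, convergence at
$10^{-6}$); its symmetric and decisive limits have closed forms that the
tests check exactly.

Two controls diagnose whether an interim unilateral stage is real rather
than an artefact of gradual improvement:

* `build_matched_cohort()` simulates, for each participant and block, a
  mixture $w\cdot\text{bilateral} + (1-w)\cdot\text{random}$ whose expected
  block LLR equals the observed one. The expected LLR is exactly linear in
  $w$, so the matching weight is solved in closed form (clamped to $[0,1]$,
  with a message when a block exceeds the pure-bilateral expectation).
  Matched cohorts lie on the random-to-bilateral axis by construction, so
  their unilateral attribution rate is the false-positive benchmark.
* `crossval_inflection()` fits a descending four-parameter sigmoid to each
  dimension's error magnitude over time on odd trials, labels the
  dimensions earlier/later by inflection point, measures the difference on
  even trials under those labels, and averages over the two fold
  directions. Parallel learning predicts differences centred on zero.
  Sigmoid fitting is multi-start bounded least squares (`optim`, L-BFGS-B,
  five starts across the trial range, $k > 0$); flat trajectories are
  flagged degenerate and assigned the midpoint.

## Cohort statistics

Generalizer proportions are compared with the uncorrected 2 x 2 Pearson
chi-square (the printed statistics reproduce only without the continuity
correction), group LLRs with a one-sided bootstrap test on the difference
in means (10,000 resamples), and participants are excluded when second-half
training accuracy (fraction of blocks 8-14 training responses within 60 px)
falls more than 3 scaled MADs (constant 1.4826) below their condition
median. Exclusion is one-sided; a zero MAD triggers a conservative fallback
(below median *and* below 0.5 accuracy) that is flagged loudly.

## Synthetic cohorts

`simulate_cohort()` generates participants whose test responses are drawn
from the stage densities of a known policy schedule by exact rejection
sampling (for polar product densities the radial/angular proposal is
accepted with probability $\rho/R$, cancelling the Jacobian), with training
responses following a simple learning ramp (random in block 1, bilateral
thereafter) or a non-learner profile for exercising the exclusion rule.
Every true parameter is recorded in a manifest for recovery scoring. The
generator emulates the statistical structure the analyses assume — stagewise
policies, isotropic response noise, the exact block design — and none of the
features of real behaviour it does not model: reaction times, motor
autocorrelation, drifting attention, or heterogeneous per-participant noise.
Passing recovery tests therefore validates the pipeline's correctness, not
the psychological truth of the stage model.

## Problem sizes and numerical choices

The test suite and the acceptance script use scaled-down cohorts chosen as
the smallest sizes at which the qualitative contrasts are stable across
seeds: 15-20 networks per condition cell (the study used ~60 per cell), 50
single-participant recovery runs, cohorts of 15-25 for attribution and
matching. Densities use a 2 px lattice (~55,000 support points);
normalisations are cached per truth point. Angular residuals are always
wrapped to $(-\pi,\pi]$; the angle of the exact arena centre is defined as
0; score bands are half-open so the points function is total; boundary
clamps keep responses strictly inside the disk to avoid zero-density
evaluations at the wall.

## Known limitations

* The Hebbian agent's gate dynamics depend on the converse-depression
  reading described above; under the narrower update (depression only on
  input change) the model cannot factorise the polar task.
* BIC is a coarse evidence approximation at 224 trials; the package exposes
  the evidence field so another criterion can be substituted.
* The sigmoid inflection fit is only as identifiable as the error
  trajectory allows; with 112 trials per fold its variance is large, which
  is why fold-averaged differences and cohort medians are reported.
* Agent LLR magnitudes are sensitive to the SGD budget; only orderings
  across conditions and sign patterns are treated as reproducible.
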