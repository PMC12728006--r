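---
title: "Models and methods behind moanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind moanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moanet)
```

`moanet` turns a directed protein–protein interaction network into a
trainable signal-propagation model of drug action on a disease, and
provides the analytics used to read mechanisms of action out of such a
model. This vignette explains the model, the choices that were genuinely
open when building it, and what the synthetic benchmarks do and do not
demonstrate.

## The propagation model

Every protein `v` carries an activity $a_v \in [-1, 1]$: positive values
mean functional activation, negative inactivation. A *stimulus* clamps the
drug's targets (and pseudotargets — proteins not physically bound but
clamped to represent a blocked interaction, e.g. an adhesion-molecule
ligand) at `effect_sign × magnitude`. Signal spreads by iterating

$$a_v \leftarrow (1 - d)\,a_v + d\,\tanh\!\Big(g \sum_{u \to v} \omega_{u\to v}\, a_u\Big)$$

for non-clamped nodes, with clamped nodes held fixed.

**Why this scheme.** The model family this implements is described in the
literature as "similar to a multilayer perceptron over the interaction
network", which leaves the semantics on a *cyclic* graph open. We chose a
synchronous, damped fixed-point iteration because it is well defined on
cycles, reduces exactly to feed-forward evaluation on acyclic networks,
and makes determinism trivial. The hyperbolic tangent is the canonical
sigmoid with range exactly $[-1, 1]$ and slope `gain` at the origin
(default 1).

**Numerical choices.** Default tolerance `1e-6` on the maximum absolute
per-sweep change, `max_iter = 200`, damping `0.5`. On acyclic networks the
converged profile is damping-invariant (damping only changes the iteration
count); on cyclic networks strong negative feedback can oscillate, in
which case the profile is returned with `converged = FALSE` — analyses
surface this flag rather than hiding it. Nodes never reached by the
stimulus sit exactly at the zero fixed point. Whether stimulated nodes are
clamped throughout or injected once is not specified by the model family;
we clamp (the alternative would decay to zero on most networks and make
"the drug is present" ill-defined), and treat pseudotargets identically to
targets at propagation time — their special status is metadata.

## Training by simulated annealing

A *training rule* pairs a stimulus with expected signs at response
proteins. A solution complies with an expectation $(p, s)$ when
$\mathrm{sign}(a_p) = s$ and $|a_p| \ge 0.1$ after propagating the rule's
stimulus; *accuracy* is the fraction of expectations complied with, pooled
over rules. We count per-expectation rather than per-rule — the printed
phrase "sum of all the rules complied with" is ambiguous, and
per-expectation counting gives a finer-grained, better-conditioned
metric. The 0.1 compliance threshold deliberately reuses the analysis
layer's reversion threshold so "trained to do X" and "observed to do X"
mean the same thing.

Weights start uniform in $[-1, 1]$ and are optimised by Metropolis
simulated annealing under geometric cooling. Three details matter:

* **Objective.** The discrete accuracy is a poor annealing objective (flat
  almost everywhere). The continuous surrogate is the capped margin
  $\frac{1}{E}\sum_e \min(s_e a_{p_e}, c)/c$ with cap $c = 0.3$: each
  expectation earns score up to the cap and nothing beyond, and wrong
  signs are charged linearly. An uncapped hinge ($\max(0, s\,a)$) stalls
  far below the gate on desk-scale systems: the optimizer saturates easy
  expectations at $|a| = 1$ and the hinge never charges for the sign
  violations that remain. The cap (three times the compliance threshold)
  removes that failure mode. Discrete accuracy remains the reported and
  gating metric.
* **Proposals.** One uniformly chosen edge weight is perturbed by Gaussian
  noise whose width shrinks with temperature (floored at 5 % of
  `proposal_sigma`), reflected at $\pm w_{\max}$; with probability 0.15
  the proposal is a sign flip $\omega \to -\omega$. Sign structure is the
  hard combinatorial part of the fit, and shrinking Gaussian steps can
  never cross zero late in the schedule; the flip move is what lets the
  annealer escape wrong-sign basins and reach the gate reliably.
* **Sign priors.** Known activation/inhibition edges are enforced softly:
  edges whose fitted weight opposes the prior add $|\omega|$ to a penalty
  averaged over all edges and weighted by $\lambda = 0.1$. Soft rather
  than hard, because curated interaction signs are probabilistic evidence,
  not constraints; averaging keeps $\lambda$ on the same scale as the
  margin regardless of network size.

The default schedule (initial temperature 0.02, cooling 0.9, 450 steps
per temperature, minimum temperature $10^{-5}$, `proposal_sigma` 0.4) was
tuned on desk-scale synthetic systems for reliable gate passes in a few
seconds per solution; during annealing, propagation runs with a relaxed
tolerance (`1e-3`, 20 sweeps, warm-started from the previous iterate)
because compliance needs only signs and a 0.1 magnitude, and the returned
solution is re-evaluated from a cold start so its reported accuracy is
exactly what `evaluate_accuracy()` computes.

An *ensemble* collects solutions whose accuracy exceeds the 0.90 gate,
training with consecutive seeds until `n_solutions` members pass or a
retry budget (5 runs per requested solution) is exhausted — then it fails
loudly, carrying the best accuracy found. The ensemble's spread across
equally valid solutions is the model's analogue of interpatient
variability; analyses average over it.

## Mechanism analytics

* **fSignal** is the mean signal arriving at the effector assignments in
  scope. The default *disease-oriented* mode averages
  $-\mathrm{disease\_sign} \times a$, so positive fSignal means net
  reversion; `raw` mode keeps the literal mean activity. Whether the
  average should run over unique proteins or (protein, motive) pairs is
  not fixed by the definition; we average over assignment pairs in scope,
  which makes per-motive and overall values mutually consistent.
* **Reverted effectors** require the sign opposite the disease sign with
  $|a| \ge 0.1$; the boundary is inclusive ("at least"). Reversion
  percentages count *unique proteins* in numerator and denominator — a
  protein reverted in three motives is one reverted protein — because
  headline counts in this field are protein counts while motive breakdowns
  may double-count.
* **Combination decomposition** classifies the proteins reverted by the
  combination: *convergent* (reverted by each drug alone, and at least as
  strongly by the combination — the "greatly reversed" notion made
  operational as $|a_{AB}| \ge \max(|a_A|, |a_B|)$, since no formula is
  given in the literature), *exclusive* to either drug, *emergent*
  (combination only), and *attenuated* (reverted by both drugs but more
  weakly under the combination). The attenuated class exists so that the
  five sets genuinely partition the combination's reverted proteins; on
  the packaged tables it is empty.
* **Bioflags** (literature-reported downstream protein changes under a
  drug) corroborate a model when the predicted activity has the reported
  sign at threshold magnitude; sign-correct but sub-threshold predictions
  are reported separately, as are bioflags absent from the network.
* **Sobol sensitivity** treats the clamp values of the stimulated proteins
  as uncertain inputs (uniform within $\pm 0.25$ of nominal, truncated to
  $[-1,1]$) and the fSignal as output. Estimation uses a Saltelli
  $A/B/AB_i$ design with Latin-hypercube base samples and Jansen
  estimators; indices are computed per ensemble member and averaged. The
  implementation is validated against the analytic indices of an additive
  two-input toy and the structural zero of a disconnected input.
* **Mechanism subnetworks** keep the stimulated proteins, the reverted
  effectors and the intermediates on directed paths between them with mean
  activity at threshold; edges are annotated by the sign of
  (mean weight × mean upstream activity) and exported as DOT.

## The synthetic-data generator

The generator exists because the disease characterizations, interaction
networks and curated rule compendia this kind of analysis runs on are
typically proprietary. It emulates their *statistical shape*, not their
content:

* **Topologies**: preferential-attachment (edges reversed so hubs
  broadcast downstream — a stimulus must be able to reach a large set),
  rewired ring lattice with random orientation, and random DAG. Mean
  out-degree defaults to 3.
* **Targets and effectors**: drug targets are placed on high-reachability
  nodes (drugs hit upstream regulators); draws that cannot reach enough
  nodes to host the effectors are resampled. Effectors are drawn from the
  reachable set and distributed over motives to hit an exact unique-protein
  count (each protein gets one primary motive; remaining quota slots
  become shared memberships), e.g. motive sizes 50/24/45/59 overlapping
  to exactly 148 unique proteins at the published scale. An optional *detached*
  motive has every incoming edge severed, emulating a process the drugs
  cannot reach (its effectors are then disjoint from the other motives').
* **Ground truth and rules**: planted weights are signed with magnitudes
  in $[0.4, 1]$ (weights below ~0.4 rarely move anything past the 0.1
  threshold); about half the edges carry a sign prior consistent with the
  planted weight. Training rules record the signs of effectors receiving
  $|a| \ge 0.1$ when the planted model is stimulated — by each drug, their
  combination, and random stimuli — so the rule set is exactly satisfiable
  at zero noise; `rule_noise` flips that fraction of expected signs.
  Random stimuli are drawn from a bounded pool (the drug targets plus 8
  high-reachability nodes): curated input–output compendia probe a
  limited target space, and a generator whose every rule hit fresh random
  nodes would make generalization from 20 rules to held-out rules
  information-theoretically impossible.
* **Planted synergy** builds the two-drug decomposition ground truth
  explicitly: drug A's targets feed one hub, drug B's another; each hub
  drives its exclusive effector block with strong weights (0.9) and both
  drive a shared convergent block with weaker ones (0.7), so each single
  drug reverts its own block plus the convergent block, and the
  combination reverts the convergent block at least as strongly (inputs of
  equal sign add before the sigmoid). Filler nodes never feed back into
  the mechanism.

**What passing the synthetic suites does and does not show.** The planted
benchmarks demonstrate that the pipeline's machinery is correct: training
recovers systems that are recoverable, decompositions recover planted
truth exactly, percentages and counts match independent recomputation.
They do not show that any real network is identifiable from any real rule
compendium — real characterizations are noisier, interactomes are
incomplete, and rule sets are not generated by the network they constrain.
The packaged mechanism tables are transcriptions of published results used
as classification fixtures, not model outputs.

## Problem sizes and reproducibility

The test and acceptance workloads use a desk-scale default — 120 nodes,
motive sizes 12/6/10/14, 2 drugs × 3 targets, 25 rules (30 when a 20/10
train/held-out split is needed) — chosen so a full train-analyse cycle
runs in seconds and whole seed-sweeps in minutes on one CPU; published-scale
characterization shape (900 nodes, 148 unique effectors) is exercised
where only generation, not training, is required. All randomness flows
from explicit seeds: the annealer carries its own deterministic RNG keyed
by `seed`, generators are reproducible bit for bit from `spec$seed`, and
pipeline reports contain no timestamps, so identical configs give
byte-identical reports.

## Known limitations

* Signal magnitude attenuates only through sigmoid saturation; no explicit
  path-length decay is modelled.
* Non-convergent propagation (possible under strong negative feedback) is
  flagged, not resolved; analyses must decide what to do with flagged
  profiles.
* The annealer fits weights only; network topology is taken as given.
* Bioflag corroboration and reversion share one threshold (0.1); there is
  no per-protein uncertainty on either.
* `fsignal` pair-averaging weights a protein once per motive membership;
  protein-level averaging would differ for multi-motive proteins.
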