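---
title: "Inferring sparse combinatorial regulatory networks by message passing"
author: "grnbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sparse combinatorial regulatory networks by message passing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnbp)
```

## The model

Transcriptional regulation is directed, sparse, and often combinatorial: a
target gene responds to the joint activity of a few regulators rather than
to any single one. `grnbp` infers such regulation from expression data under
a deliberately minimal model. For one target gene 0 with candidate
regulators $i = 1, \dots, N$ and expression patterns
$\mu = 1, \dots, M$ (log-ratios $x_i^\mu$ against a reference condition),
each regulator carries a ternary coupling $J_{i\to 0} \in \{-1, 0, +1\}$
(repressor, absent, activator), and the target's expression sign is
predicted by the *local field*

$$\Lambda^\mu = \sum_i J_{i\to 0}\, x_i^\mu ,$$

through $\hat{x}_0^\mu = \mathrm{sign}(\Lambda^\mu + \tau)$. Measurement
noise is modelled as additive Gaussian noise of standard deviation
$\sigma$ on the target value, which turns the hard threshold into the
probit likelihood

$$P(x_0^\mu \mid \mathbf{x}^\mu, \mathbf{J}) =
  \Phi\!\left(\hat{x}_0^\mu\,(\Lambda^\mu + \tau)/\sigma\right),$$

recovering the deterministic rule as $\sigma \to 0$. Sparsity enters
through the prior $P(\mathbf{J}) \propto e^{-h N_\mathrm{eff}}$, where
$N_\mathrm{eff}$ counts nonzero couplings and the *diluting field* $h$
penalizes each of them; this is an $\ell_0$-type regularization that is
meaningful on a ternary alphabet. Everything is computed in the
zero-temperature limit; a finite inverse temperature is not implemented.
Because the network is directed, the problem factorizes over targets:
each target gene is an independent subproblem.

Two likelihood variants exist: the default uses only the sign of the
observed target value, a `magnitude_weighted` switch in
`pattern_likelihood()` and `log_posterior()` multiplies the field by the
raw log-ratio instead, so strongly expressed observations count more. The
sign form is the default because it makes the Gaussian message integral
exact and treats all usable patterns equally.

### Conventions for degenerate cases

* A zero local field makes no prediction. The deterministic cost
  `cost_h0()` counts it as a violation (conservative); the probit
  likelihood automatically assigns it probability $1/2$.
* A target log-ratio of exactly zero carries no sign information, so the
  pattern is dropped for that target.
* Missing regulator inputs are imputed as 0 — the reference level, which
  contributes nothing to the field. Missing target values drop the
  pattern.
* In sign assignment for reported links, an exact tie
  $P_i(+1) = P_i(-1)$ is not a prediction: the edge is excluded and
  counted.

## Belief propagation

The posterior over $\mathbf{J}$ defines a dense factor graph: one variable
node per candidate coupling, one factor per pattern. BP exchanges messages
$\rho_{\mu\to i}(J)$ (how strongly pattern $\mu$ constrains coupling $i$)
and $P_{i\to\mu}(J)$ (the coupling's distribution without pattern $\mu$).
The factor update nominally sums over $3^{N-1}$ cavity configurations; for
a dense graph the cavity field is a sum of many weak, nearly independent
terms, so it is replaced by a Gaussian with matched cavity mean
$t_{\mu\to i}$ and variance $\Delta^2_{\mu\to i}$. Under the probit
likelihood that integral is exact:

$$\rho_{\mu\to i}(J) \propto
  \Phi\!\left(\frac{\hat{x}_0^\mu\,(J x_i^\mu + t_{\mu\to i} + \tau)}
  {\sqrt{\sigma^2 + \Delta^2_{\mu\to i}}}\right).$$

Per-pattern totals are formed once and each regulator's single term
subtracted, so a sweep costs $O(MN)$. Convergence requires the largest
message change to fall below $10^{-8}$ (500 sweeps cap). Updates can be
damped; oscillation (no improvement over 30 sweeps) raises the damping
factor automatically to 0.5 and then 0.8, and non-convergence is always
reported via the `converged` flag and a warning.

Marginals $P_i(J)$ combine the prior with all factor messages, and a
link's *confidence* is $1 - P_i(0)$, the posterior probability that the
coupling is nonzero. The package never decodes a single best coupling
vector: the marginals summarize the whole high-posterior ensemble, which
is what makes the ranking robust when data are scarce.

### Entropy and the cooling of the diluting field

The Bethe entropy approximates the log-number of high-posterior coupling
vectors. `bethe_entropy()` evaluates it from converged messages as

$$S = \ln Z_{\mathrm{Bethe}} + h\,\mathbb{E}[N_\mathrm{eff}]
      - \sum_\mu \langle \ln W_\mu \rangle,$$

with $\ln Z_{\mathrm{Bethe}}$ the standard factor-graph Bethe
log-partition (factor, variable and edge normalizers) and the
pattern-likelihood average $\langle \ln W_\mu \rangle$ computed under the
Gaussian representation of the field by Gauss–Hermite quadrature. This is
algebraically the factor-degree-corrected Bethe form
$S = \sum_\mu S^\mu + (1 - M)\sum_i S_i$; the package validates it against
exhaustive enumeration on small instances (within 15% relative) and uses
the exact limits $S = N\ln 3$ ($M = 0$, $h = 0$) and $S \to 0$
($h \to \infty$) as anchors.

$h$ is conjugate to the number of effective links, so either can be fixed.
`tune_h()` implements two stopping rules:

* **Target $N_\mathrm{eff}$** — after every BP sweep, $h$ is multiplied or
  divided by $(1 + \varepsilon)$, $\varepsilon = 0.05$, depending on
  whether $\mathbb{E}[N_\mathrm{eff}] = \sum_i (1 - P_i(0))$ is above or
  below the target; once the target has been bracketed the step shrinks
  and a short bisection refines $h$ after messages are frozen and
  converged (tolerance: one link). Interleaving the $h$ updates with the
  sweeps matters beyond bracketing: it keeps BP away from frozen,
  overconfident fixed points that plain fixed-$h$ iteration falls into on
  hard instances (we verified against exhaustive enumeration that those
  frozen states are artifacts of the iteration, not features of the
  posterior).
* **Zero entropy** — $h$ is ramped up by $\varepsilon$ steps, converging
  BP at each value, until the Bethe entropy first drops to zero, i.e.
  until the solution set becomes sub-exponential. This needs no guess for
  the signature size.

One field can be shared across all targets of a run (`h_mode = "global"`,
cooled so the summed expected $N_\mathrm{eff}$ hits the target) or tuned
per target. Global is the default for the cell-cycle reproduction because
the target of ~30 effective links there is a property of the whole
11-gene network, larger than any single target's candidate count.

## The in-silico validation system

`cellcycle_network()` loads the 11-node Boolean model of budding-yeast
cell-cycle control (Cln3, MBF, SBF, Cln1/2, Cdh1, Swi5, Cdc20&Cdc14,
Clb5/6, Sic1, Clb1/2, Mcm1/SFF) with 15 activating and 19 repressing
signed couplings, five of the latter being self-degradation loops. The
synchronous dynamics (`boolnet_step()`) activate a gene on positive input
sum, deactivate on negative, and keep the current state on a tie;
self-degradation encoded as a $-1$ self-loop is exactly equivalent to the
explicit decay rule "an active gene with zero input switches off", and
both variants ship (`selfdeg = "selfloop"` / `"decay"`). The fixture is
not trusted by transcription: the test suite re-derives its published
attractor statistics (7 fixed points on $2^{11}$ states, largest basin
1764, identified with G1) by exhaustive enumeration.

```{r cellcycle}
net <- cellcycle_network()
att <- enumerate_attractors(net)
nrow(att$fixed_points); att$basin_sizes
```

`cellcycle_dataset()` flips Cln3 on in G1 and records the 13 distinct
states traversed back to G1; `perturbed_cellcycle_dataset()` adds the
trajectories from all 11 single-bit perturbations of G1. States are
encoded $\{0,1\} \to \{-1,+1\}$ (the signed model needs signed values) and
paired into time-series patterns: inputs at $t$, target at $t+1$, with the
terminal fixed point's self-transition included by default (observed
stationarity is itself a transition; `include_stationary = FALSE` gives
the $K-1$ pairs of a $K$-state path). Under this construction the
perturbed dataset holds 29 distinct states — every state reachable from
the Hamming-1 shell of G1. Published accounts of this experiment quote 70
distinct states; no construction we tried (perturbing every trajectory
state, every fixed point, counting with duplicates, delayed decay rules)
reproduces that count without breaking the attractor statistics that are
pinned exactly, so the package ships the literal construction and reports
its own numbers.

In time-series mode the target's own lagged profile is a legitimate
candidate input and is kept (the tie-keep dynamics make several noiseless
subproblems contradictory without it); self-pairs are nevertheless never
reported as links, and evaluation uses the 29 non-self couplings of the
generator as truth. In steady-state mode the target is excluded from its
own candidate set outright.

## The synthetic benchmark generator

`generate_planted_dataset()` draws data from exactly the model the
inference assumes: ternary couplings with a chosen number of nonzeros per
target, i.i.d. $\pm 1$ (or Gaussian) inputs, and targets
$\mathrm{sign}(\Lambda + \sigma_\mathrm{gen}\eta)$, so the flip rate
relative to the noiseless rule is $\Phi(-|\Lambda|/\sigma_\mathrm{gen})$
(checked by Monte Carlo against the closed form). The recovery benchmark
uses 20 candidate regulators, 3 true links per target, 100 patterns and
$\sigma_\mathrm{gen} = 0.2$ — scarce-data conditions (5 patterns per
candidate) with mild noise, the regime the method is designed for. An odd
number of true links keeps the field away from zero on $\pm 1$ inputs;
with an even count half the patterns are pure noise, which is a much
harder (and less identifiable) task.

What the generator does *not* emulate about microarray data: correlated
regulator profiles, heteroscedastic and non-Gaussian noise, missingness
patterns that track expression level, and regulation that is not a
threshold function (XOR-like logic is outside the model class). Passing
tests on planted data therefore demonstrate correctness of the machinery
and identifiability under the model's own assumptions, not performance on
real compendia.

## Evaluation layer

Links from all targets are pooled and ranked by confidence
(`rank_links()`), with exact ties broken by gene order — regulator first,
then target — for reproducibility. `precision_recall()` scores a ranking
against a signed gold standard (sign agreement required by default;
sign-agnostic and direction-agnostic comparisons are available for
unsigned references), and `links_before_first_error()` reports the length
of the error-free prefix. `pearson_baseline()` is the co-expression
control: rank pairs by $|r|$ with the sign of $r$, lagged for time-series
data. `degree_stats()` fits the in-degree distribution of regulated
targets with a maximum-likelihood exponential rate $\gamma = 1/\bar{k}$;
`null_model_overlap()` assesses overlap with a reference network against
an in-degree-preserving scramble (each target keeps its regulator count,
regulators redrawn uniformly without self-loops), reporting the z-score
and both the Gaussian upper-tail p-value (the convention of the original
analysis, despite the discreteness of the overlap count) and the empirical
tail frequency. `regulator_independence()` quantifies combinatorial (as
opposed to redundant) control as $1 - |r|$ between co-regulators of a
common target.

## Reproducing the cell-cycle experiment

```{r fig1, eval = FALSE}
net <- cellcycle_network()
truth <- network_edges(net)          # 29 signed non-self couplings
ds <- cellcycle_dataset(net)         # 13 states, sigma = 0
run <- infer_network(ds, model_params(sigma = 0), h_mode = "global",
                     n_eff_target = 30, confidence_threshold = 0, seed = 1)
links_before_first_error(run, truth)
links_before_first_error(pearson_baseline(ds), truth)
```

On the 13-state dataset the BP ranking places 10 true couplings ahead of
the first error versus 0 for the Pearson baseline, and the distance to
the published 11 for this experiment is a literal coin flip: MBF and SBF have
identical expression columns in these 13 states, so the links
MBF→Cln1/2 (spurious) and SBF→Cln1/2 (true) receive *exactly* equal
confidence and occupy ranks 11–12 in tie-break order; resolving the tie
the other way yields 11. The same two-fold degeneracy floods the top of
the Pearson ranking (five $|r| = 1$ links, one spurious, so any tie order
gives 0–4 correct; the published 2 is the mean over random orders). We keep the deterministic gene-order tie-break rather than pick
the resolution that flatters the result.

## Numerical choices and known limitations

* **Problem sizes.** The validation suite runs the 11-gene cell-cycle
  system, planted problems up to 20 candidates and 100 patterns, and
  exhaustive enumerations up to $3^9$ couplings; these sizes keep the full
  test suite and the acceptance script in the minutes range while
  exercising every code path at the study's own scales.
* **Messages** are floored at $10^{-300}$ before taking logs so that
  strictly excluded states at $\sigma = 0$ stay representable; a vanishing
  denominator $\sigma^2 + \Delta^2 = 0$ degenerates the probit to the
  tie-ruled step.
* **Small dense problems.** Loopy BP on graphs with a handful of
  couplings and patterns can converge to fixed points that polarize
  degenerate or clustered posteriors (an exactly symmetric 0.5/0.5
  marginal may come out 1/0). This is a property of the Bethe
  approximation on short loops, not of the implementation: BP is exact on
  tree topologies here, matches enumeration to $<10^{-5}$ on
  well-determined instances, and its Gaussian factor messages match the
  exact exhaustive-sum messages to total-variation $<0.05$ from $N = 6$
  up. Confidence *rankings* are far more robust than the marginals
  themselves, which is why the method is used as a ranker.
* **Thresholds in the wild.** The activation threshold $\tau$ defaults to
  0 (expression log-ratios are symmetric around the reference); a
  per-target constant input whose ternary coupling acts as an inferable
  intercept can be enabled with `include_bias = TRUE` in
  `infer_network()`.
* **Genome-scale runs.** The filters (`filter_genes()`: variance below
  three times the minimal measured variance, or more than 10 missing
  points) and the evaluation machinery support compendium-scale analyses,
  but the package bundles no microarray compendium or curated reference
  network; those analyses are out of scope at desk scale.
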