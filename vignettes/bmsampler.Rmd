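---
title: "Sampling models of causal probability judgment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling models of causal probability judgment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsampler)
```

## The modeling problem

When people judge conditional probabilities over a small causal system —
"Y is present, X2 is absent; how likely is X1 to be present?" — their
responses are variable, multimodal, and systematically displaced from the
answer a causal Bayesian network would give. This package implements two
generative process models of such judgments, the machinery to simulate full
response distributions from them, and a likelihood-free pipeline to fit them
to trial-level data.

All networks have three binary variables: terminals `X1` and `X2` and a
middle variable `Y`, connected as a chain (X1→Y→X2), a common cause
(Y→X1, Y→X2) or a common effect (X1→Y←X2). Under the default taught
parameters (base rates .5; effects present with probability .75/.25 given
parent present/absent; noisy-OR strengths .5 with zero leak for the common
effect) the chain and common-cause joints coincide state by state, which is
what licenses collapsing them in the response analyses. The common-effect
middle variable has base rate 0.4375.

## The sampling process

A judgment starts a Metropolis–Hastings chain at one of the two prototype
states — all present or all absent, equiprobably — and at each step proposes
one of the three single-variable mutations uniformly, accepting with
probability min(1, P(proposal)/P(current)); rejected proposals re-record the
current state. Two commitments matter:

* **The chain length counts the start state.** A chain of length n is the
  start plus n−1 transitions. This convention is pinned analytically: with
  chain length 2 and the conflict query P(X1=1|Y=1,X2=0), exact enumeration
  of start × proposal × accept outcomes gives default-response probabilities
  25/27 (at 50%), 1/18 (at 100%) and 1/54 (at 0%), and the package's
  simulations reproduce these. Counting n transitions after the start would
  not.
* **No burn-in or thinning.** The prototype-start bias and the short chain
  *are* the psychological content; removing them would remove the model.

With an unlimited chain the visit frequencies converge to the joint (the
test suite checks total variation < 0.02 at length 10^5), so all
non-normativity comes from limited, biased sampling.

## Judgment rules

For a query, `N_match` sums visits to states consistent with the
conditioning where the target takes the queried value and `N_other` those
where it takes the opposite value; unknown non-queried variables are
marginalized, so both of their values contribute. The relative-frequency
rule returns `N_match / (N_match + N_other)` with every state's tally
initialized at 1e-10: when a required state set is unvisited, this yields
default responses at exactly 0, 0.5 or 1. The Bayesian rule returns the
Beta-posterior mean `(N_match + β)/(N_match + N_other + 2β)`. β is the
single new parameter: β = 0 is the relative-frequency rule; β = 1 is a
uniform prior; large β pins responses to 50%. For any β > 0 and finite
chains, responses can never reach 0 or 100 — the model's signature
prediction. Responses are kept continuous on [0, 100]; participant rounding
is not modeled.

The linearly scaled mapping `s · p` is provided (`scaled_estimate()`,
deliberately unclipped) but excluded from the default model menu.

## The query set and inference groups

A trial assigns each variable one of {present, absent, unknown} and asks
about an unknown variable at value "present". Crossing the three possible
targets with the 3 × 3 roles of the other two variables gives 27 inferences:
12 with two known conditioning variables, 12 "ambiguous" ones with one known
(each unknown queried in its own trial), 3 base rates. This is the only
reading we found that reproduces the canonical per-group observation counts
{24, 12, 48, 24, 24, 12, 18} per participant (2 structures × 3 deadlines),
which the test suite asserts.

For distributional analyses the 27 inferences collapse into 7 groups by
symmetry (terminal exchange, presence/absence reflection via 100 − response,
unknown-variable symmetry), with canonical normative values
{75, 50, 75, 62.5, 75, 90, 50}%. "Adjacent" in the ambiguous groups is
graph adjacency ignoring edge direction, under which Y is adjacent to both
terminals in both collapsible structures, so the grouping is
structure-invariant. Queries whose exact normative probability is below 50%
are flipped; those at exactly 50% never are (a flip would be ambiguous and
is a no-op on the normative value). Common-effect trials are excluded from
this analysis. Variability is summarized by Gini's mean difference (mean
absolute difference over unordered pairs, computed by the sorted-values
identity); group-level predictions pool the constituent distributions with
equal weight and estimate the GMD from 10,000 draws, which the tests check
against the closed-form pairwise expectation on discrete mixtures.

## Fitting: synthetic likelihood on a grid

Neither model has a closed-form likelihood, so fitting uses probability
density approximation: per grid cell, simulate responses per query, fit a
Gaussian kernel density, and sum log densities of the observed responses.
Choices, each exposed in `kde_options()`:

* bandwidth: Silverman's rule of thumb (`stats::bw.nrd0`), the standard
  default for this method; fallback 2.0 percent points when the simulated
  responses are nearly degenerate (e.g. β = 100, where all responses sit at
  50 and the rule collapses);
* density floor 1e-10, keeping log-likelihoods finite for observations far
  from the simulated support;
* no boundary reflection at 0/100 — the simplest dialect; it slightly
  depresses densities near the scale ends, identically across cells, and is
  documented as a knob because it shifts likelihoods near the edges.

The default grid crosses chain lengths 2, 4, …, 70 with 21 β values: 0,
0.1–0.9, 1, the nine β > 1 whose symmetric Beta priors match the sub-unit
values in total variation distance from the uniform (1.11, 1.26, 1.45, 1.73,
2.14, 2.83, 4.14, 7.35, 21.54, found by quadrature-free root-solving on the
exact Beta CDF), and 100 as the finite stand-in for the degenerate
counterpart of β = 0. Ties in the grid argmax break toward the smaller chain
length, then the smaller β — prefer the simpler process. BIC is
k·ln(n) − 2·logL with k = 2 (Bayesian) or 1 (plain) and n the 27 responses
of the fitted participant × structure × deadline unit; BIC weights
exp(−Δ/2), normalized, approximate posterior model probabilities, averaged
arithmetically over a participant's nine units. Because chains depend only
on the joint and the chain length, one simulation batch per chain length
serves every β and every query, and the plain model's fit is read off the
β = 0 row of the same likelihood grid — the nesting is structural.

## Synthetic data and parameter recovery

`generate_participant()` emulates the full 27 × 3 × 3 design: one chain and
one Bayesian judgment per trial. Deadlines are labels without behavioral
effect by default (fitted priors do not differ across deadlines); an
optional hook maps deadlines to chain lengths, and an optional contamination
rate injects uniform random responses — both off by default and used only
for robustness tests. The generator emulates the response *process*, not
response modality, response times, rounding to focal values, or
guessing mixtures; passing tests therefore validate the pipeline's
internal consistency, not those aspects of real data.

The recovery study draws true (chain length, β) uniformly from the cells of
a coarse grid — every other chain length (2, 6, …, 70) and 11 β values kept
symmetric in total variation about the uniform prior — generates 27
responses per synthetic participant, refits on the same grid with 2,000
simulations per cell, and reports Pearson correlations between true and
estimated parameters against the conventional 0.75 bound for good recovery.
At the package defaults (40 participants) both correlations exceed 0.85.
Identifiability degrades at long chain lengths, where predictions change
ever more slowly in the chain length; the tests assert that recovery on the
sub-grid of chain lengths ≤ 40 is at least as tight as on the full range.

## Problem sizes and numerical conventions

Distributional summaries use 10,000 simulated chains per condition
(Monte-Carlo standard error about 0.005 on a proportion); recovery uses
2,000 simulations per grid cell and 30–40 synthetic participants; the
convergence checks use single chains of length 10^5. States are indexed by
the (X1, Y, X2) bit triple; conditioning on a zero-probability event raises
an error rather than returning a default (defaults belong to the sampler,
not to exact inference). All stochastic entry points accept a seed, and the
command-line runs write a manifest (seed, config, versions) sufficient to
replay a run bit-identically.

## Known limitations

Fits to real data additionally reflect guessing/mixture strategies, spikes
at 50% for base-rate queries, and possible inference-dependent chain
lengths, none of which are modeled here. The kernel density estimate is
unreflected at the scale boundaries. Networks are fixed to three binary
variables with taught parameters; causal parameters are not estimated
jointly with the sampler parameters.
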