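---
title: "Methods: tag-based kin recognition under host-parasite coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based kin recognition under host-parasite coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`kintags` iterates an exact genotype-frequency recursion for an infinite
haploid population with four freely recombining loci:

* **Resist** — a tag locus that also determines parasite resistance
  (up to `L_resist` alleles);
* **Neutral** — a tag locus with no function other than its possible use in
  kin recognition (up to `L_neutral` alleles);
* **Choice** — two alleles selecting which tag locus an individual inspects
  before helping (use-Resist vs use-Neutral);
* **Trait** — two alleles: conditional helping vs defection.

The population is viscous: each social encounter is with a full clone with
probability $\theta$, otherwise with a nonrelative. An individual whose tag
(at its chosen locus) has population frequency $X$ ends up in a tag-matched
interaction with probability

$$P(X) = \frac{\theta + (1-\theta)X}{1 - \alpha(1-X)(1-\theta)},$$

where $\alpha$ is the probability that a mismatched pair dissolves and the
search restarts. Helpers that interact pay fecundity cost $c$ and deliver
benefit $b$ to their matched partner. Parasites track the Resist
composition of the host population with a delay: a host carrying Resist
allele $i$ loses fecundity $d Z_i$, where $Z_i$ is that allele's population
frequency `lag` generations ago (`lag = 0`: perfectly adapted parasites).
Fecundity is the product of the social and parasite payoffs; generations
are discrete — selection, then free recombination (random gamete fusion),
then symmetric mutation at Trait and Choice at rates $\mu_{Trait}$,
$\mu_{Choice}$.

The relatedness of a tag-matched partner (genetic similarity at the Trait
locus, standardized against the population mean $\bar p$) is

$$R_{tag} = \frac{\frac{\theta + (1-\theta)Xp}{\theta + (1-\theta)X} - \bar p}{1 - \bar p},$$

with $p$ the helper fraction among carriers of the actor's tag. With
$p = \bar p$ it falls from 1 (a vanishingly rare tag is only matched by
clones) to $\theta$ (a fixed tag is uninformative). Conditional helping is
favored where $R_{tag}\, b > c$ (Hamilton's rule). Because more common tags
are matched — and therefore helped — more often, helping erodes the very
tag diversity it relies on (Crozier's paradox); the package exists to
quantify when lagged parasite-driven balancing selection, multiple social
encounters, and an evolvable recognition locus rescue it.

## Payoff bookkeeping

The per-genotype expected social payoff is $1 - c\,h\,P + b\,B$, with $h$
the helping indicator. Two bookkeeping choices are deliberate:

* **Perception is focal-centric.** An individual pays the cost whenever it
  perceives a match at *its own* chosen locus; when partners carry
  different Choice alleles their perceptions can disagree.
* **Benefit allocation is donor-centric.** Each donor's benefit lands on
  its realized matched partner: a clone (the donor's own genotype) with
  conditional probability $\theta/(\theta + (1-\theta)X)$, otherwise a
  uniform draw among carriers of the donor's chosen tag. This makes the
  help budget balance *exactly* (population-mean benefit received equals
  $b/c$ times population-mean cost paid, enforced to $10^{-14}$ in tests)
  and, at $\alpha = 0$, is algebraically identical to the focal-centric
  expectation. Reassociation is likewise focal-centric: being abandoned is
  not modeled separately, consistent with the closed-form $P(X)$ above.
* The conditional clone weight $\theta/(\theta+(1-\theta)X)$ is used
  unchanged for $\alpha > 0$: reassociation draws are independent, so the
  per-encounter conditional composition of matched partners is invariant.

Counterfactual genotypes (zero frequency) still receive well-defined
payoffs; only the frequency-weighted means enter the recursion.

## Numerical choices

* **Recombination** uses the 16-inheritance-mask marginal decomposition
  (free recombination means the offspring distribution is the equal mixture
  over masks of products of complementary joint marginals), reduced to 8
  distinct terms by mask/complement symmetry: $O(16G)$ per generation
  instead of the $O(16G^2)$ parent-pair double sum, which is retained in
  the test suite as an oracle. Grouped sums are precomputed
  (order + cumulative-sum boundaries) when the genotype space is built.
* **Round-off policy:** entries in $(-10^{-15}, 0)$ after a step are
  clipped to zero and the vector renormalized; anything below $-10^{-15}$
  raises an error — float noise is absorbed, logic bugs are not.
* **Convergence:** a run stops at a fixed point (L$_\infty$ one-step change
  $< 10^{-10}$), at a limit cycle (observable means of two consecutive
  1000-generation windows agree within $10^{-6}$ — the expected outcome
  under Red Queen oscillations), or at `max_generations`. Equilibrium
  summaries are always window means, so cycling runs are summarized stably.
  The window test cannot distinguish a genuine cycle from sufficiently slow
  drift (relevant at $\alpha$ near 1, where all selective differences are
  tiny); status labels should be read with that in mind.
* **Match probability at the boundary:** the denominator of $P(X)$ is
  computed as $num + (1-\alpha)(1-X)(1-\theta)$ so that $P = 1$ *exactly*
  at $\alpha = 1$, and the $\alpha = 0$ branch returns
  $\theta + (1-\theta)X$ directly.
* **Lag warm-up:** for generations earlier than `lag`, $Z$ is the initial
  Resist census (the buffer's oldest entry). One census is taken per
  generation, after mutation (post-lifecycle adults). Equilibrium
  statistics are insensitive to the warm-up policy.

## Observables

* **Tag diversity** is Simpson gene diversity $1 - \sum_i x_i^2$, scaled by
  its maximum under the genetic constraint, $1 - 1/L_{max}$, and clipped to
  $[0,1]$: 1 means all $L_{max}$ tags equifrequent, 0 means monomorphic.
  This is a stand-in for the source model's printed diversity scaling,
  chosen because it is monotone in evenness and matches the stated $[0,1]$
  normalization; results that depend on its precise curvature are compared
  qualitatively only.
* **Tag–trait association** is reported as the per-tag deviations
  $D_j = \mathrm{freq}(\text{tag } j \wedge \text{HELP}) - x_j \bar p$
  (summing to zero) and the scalar covariance $A$ between an individual's
  own-tag frequency and its helping indicator. $A < 0$ — helpers
  concentrated on rare tags — is the hitchhiking signature. This
  covariance is the minimal statistic that can "build up" between helping
  and rare tags and is exact given genotype frequencies; it likewise
  stands in for an unprinted definition.
* **Parasite susceptibility** is $\sum_i x_i(t) Z_i$ — the mean
  generational infection probability; with `lag = 0` it is the Simpson
  concentration, minimized by the uniform tag distribution. Both the
  instantaneous value and the window mean are available (the trajectory
  stores it per generation), covering either reading of an "equilibrium
  average".

## The stated world: defaults and initial conditions

Defaults follow the standard heatmap settings: $\theta = 0.25$, $b = 0.3$,
$c = 0.1$, $L_{max} = 10$, $\mu_{Trait} = \mu_{Choice} = 10^{-3}$.
$\mu_{Trait} > 0$ is kept on everywhere because a small amount of Trait
mutation is sometimes required for rare-tag/helper associations to
(re)build. Tags do not mutate: the lifecycle names mutation only at Trait
and Choice, and in the infinite-population recursion no tag frequency ever
reaches exactly zero, so diversity can rebuild by selection alone.

Runs start from a product measure over the four loci (uniform tags,
$p_0 = q_0 = 0.5$ unless a scenario pins Choice) with a seeded
multiplicative perturbation of relative magnitude $\varepsilon = 10^{-3}$.
The perfectly symmetric product state is an *unstable* fixed point of the
recursion; without the perturbation positive frequency dependence would
never express itself. `eps` must stay below the smallest positive product
frequency so no entry can be driven negative.

Two experiment framings matter:

* **Maintenance** runs (the lag × virulence sweeps) start from perturbed
  uniform tags and ask whether standing diversity survives.
* **Build-up** runs (the hitchhiking demonstrations, `preset("fig6")`)
  start Neutral nearly monomorphic (one tag at 0.91, nine at 0.01,
  $\varepsilon = 10^{-4}$) with Resist uniform, so that any equilibrium
  Neutral diversity had to be actively generated. A build-up framing is
  required at $\alpha = 0.99$: there the per-generation selective
  differences among tags are of order $1 - P \approx 10^{-2}$ times payoff
  terms, and a collapse *from* uniformity would take far longer than any
  desk-scale run, while build-up dynamics are driven by the much stronger
  helping sweep.

The agent-based oracle (`simulate_finite`) realizes the identical
lifecycle with explicit individuals: encounter retry loops (capped at
$10^4$ rounds; the cap is only reachable in no-match-possible corners),
Bernoulli infection with the lagged *empirical* Resist frequencies,
fecundity-weighted parent pairs, per-locus inheritance coin flips, and
mutation flips. Clone encounters instantiate an exact genotype copy of the
focal, and clone-directed help is credited to the focal itself (the same
bookkeeping as the deterministic recursion's clone term). It emulates
demographic stochasticity at constant $N$; it does not emulate mutation
raw-material limits (tags never mutate), population-size fluctuation, or
spatial structure. A green mean-field test therefore establishes that the
recursion is the correct $N \to \infty$ limit of this lifecycle — not that
the lifecycle is the right description of any particular organism. At
small $N$ the oracle loses tag diversity by drift faster than the
recursion; that divergence is expected and is itself asserted in the
suite.

## What a green suite establishes — and known limitations

The mechanics (recombination, mutation, budget-balanced payoffs, lagged
selection) are checked against independent oracles to near machine
precision, and the headline phenomena are reproduced qualitatively:
Crozier collapse without parasites; a lag × virulence region where
parasite-driven balancing selection stabilizes recognition at Resist;
one-step selection on Choice toward the more tag-diverse locus; and, at
$\alpha = 0.99$ with a build-up start, strictly more Neutral diversity
under an evolvable recognition locus than under a fixed one, with the
negative rare-tag/helper covariance during the build-up.

Two quantitative caveats:

* At the slow-parasite, low-virulence corner (`lag = 20`, `d = 0.1`,
  $\alpha = 0$) this implementation does not collapse below scaled
  diversity 0.1. The run settles into a slow rotation in which one tag is
  near-dominant (≈ 0.75) while parasites, twenty generations behind, crash
  it and promote a successor; the window-mean scaled diversity is ≈ 0.45
  (with susceptibility ≈ 0.6 against a 0.1 no-recognition baseline — the
  susceptibility cost is very visible there). The corresponding acceptance
  expectation (< 0.1) is deliberately left failing rather than weakened;
  the discrepancy plausibly traces to unprinted details of the source
  model's fitness bookkeeping, and the qualitative claim — too-slow
  coevolution cannot keep recognition precise — still holds in the form of
  severe tag-frequency oscillation and a large susceptibility excess.
* Stable interior cells converge to exactly uniform tags, so their
  susceptibility excess over the no-social-selection baseline is ≈ 0
  rather than merely "small"; positive excess appears only in
  partial-diversity (oscillating) cells.

Out of scope by design: diploidy, physical linkage (greenbeard
architectures), more than two candidate tag loci, tag mutation, explicit
parasite genetics (gene-for-gene or matching-allele), parasite demography,
and analytic stability/bifurcation analysis — the stability statements here
are numerical.

## Reproducing the headline analyses

```r
library(kintags)

# Relatedness falls with tag frequency; a fixed tag gives theta
head(preset("fig4b"))

# Lag x virulence sweep with Choice fixed on Resist (maintenance framing)
sw <- preset("fig3", overrides = list(max_generations = 20000))
sw[, c("lag", "d", "div_resist_scaled", "susceptibility",
       "susceptibility_baseline")]

# Hitchhiking at alpha = 0.99 (build-up framing)
preset("fig6", overrides = list(max_generations = 20000))
```

Every preset is also reachable from the command line
(`exec/kintags preset fig3 --out_dir=...`), and
`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes
the numeric acceptance targets from scratch.
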