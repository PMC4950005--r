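---
title: "Diversification models for mountain radiations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversification models for mountain radiations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodiv)
```

`paleodiv` fits birth--death diversification models to ultrametric
phylogenies of rapid radiations, with three ways of letting the rates vary:
with an abiotic covariate (paleoelevation, a temperature proxy), with a
binary species trait (BiSSE), and with standing species diversity (a
carrying capacity). It also implements the closed-form crown-group
estimator used to rank radiations by net diversification rate, and a
simulation module that generates data under every fitted model. This
vignette explains the models, the numerical choices, and what the
simulation-based tests do and do not establish.

## Time axis and tree contract

Throughout, time `t` is measured in Myr before the present: tips sit at
`t = 0` and the crown node at the crown age. Input trees must be rooted,
strictly bifurcating, ultrametric to a relative tolerance of `1e-6`
(posterior-sample Newick files carry rounding slop, which is absorbed into
the pendant edges), and free of polytomies -- resolving a polytomy is an
analysis decision the package refuses to make silently. Outgroups are the
caller's responsibility: every likelihood conditions on the crown age of
the tree it is handed.

## The paleoenvironment covariate

A discrete paleoenvironmental series (age, value) becomes a smooth
covariate `E(t)` by penalized cubic smoothing-spline regression
(`stats::smooth.spline`), with the penalty chosen by generalized
cross-validation unless given. Setting the penalty to zero gives a natural
interpolating spline. Outside the tabulated age range `E(t)` is clamped to
the boundary value: rate functions must be defined over the whole tree
depth, and constant extrapolation is the only choice that cannot
manufacture trends the data do not contain. Two template series are
bundled as generators: an Andean-type elevation history (monotone rise
from 0 m at 40 Myr to ~4500 m today, with most of the rise after 10 Myr
and steep pulses at 10--6 and ~4.5 Myr) and a Cenozoic cooling proxy
(mid-Miocene peak, noisy decline to the present). They are synthetic,
shaped to the geological consensus, and reproducible by seed.

## Environment-dependent birth--death models

The model family has ten members: Yule and constant-rate birth--death
nulls, then four exponential-dependency models
(`lambda(t) = lambda0 * exp(alpha * E(t))`, and similarly `mu` with
`beta`) and four linear ones (`lambda0 + alpha * E(t)`), letting
speciation only (with and without extinction), extinction only, or both
track the covariate. Linear dependencies can go negative; evaluated rates
are clamped at zero by default (a fit that relied on clamping is visible
in its rate-through-time curve), with a switch to hard-fail instead.

The likelihood is the time-inhomogeneous birth--death likelihood for a
crown-conditioned ultrametric tree with uniform sampling fraction `f`:
with `r(u) = lambda(u) - mu(u)`, `g(s) = exp(int_0^s r)`, and
`J(s) = int_0^s g lambda`, each lineage segment contributes
`Psi(s) = g(s) (1 + f J(s))^-2`, each branching time a factor
`lambda(t_i)`, each tip a factor `f`, and the whole is divided by the
squared probability `f g(t1) / (1 + f J(t1))` that a crown lineage leaves
a sampled descendant. Conditioning on survival of both crown lineages is
the default (standard for crown-clade fits) and togglable. Labelled-history
constants common to all models are dropped; they cancel in every comparison
the package makes.

The two cumulative integrals are evaluated once per likelihood call on a
shared grid (2000 subintervals by default, augmented with the exact
branching times) by composite Simpson quadrature with an O(h^4) half-step
rule for midpoint values. On 100-tip trees this reproduces the closed-form
constant-rate likelihood when the dependency coefficients are zero, and
doubling the grid leaves log-likelihoods essentially unchanged -- the test
suite enforces these identities at 1e-6 and 1e-5 respectively.

Maximum likelihood uses multi-start bounded quasi-Newton (`nlminb`) in
transformed space: log scale for the base rates, identity with box bounds
for `alpha` and `beta`, the bounds scaled by the covariate's range so the
exponential form cannot overflow. Ten starts by default (one heuristic,
the rest jittered); fewer are adequate and faster for the smaller
simulated trees used in tests.

## Trait-dependent models

The BiSSE likelihood integrates the standard coupled extinction/data ODEs
along each branch in post-order, in compiled code with an adaptive
Cash--Karp Runge--Kutta scheme (relative tolerance 1e-8, absolute 1e-10),
rescaling the data variables per branch to avoid underflow. Tips start at
`D_i = f_i [state = i]`, `E_i = 1 - f_i`, where the state-specific
sampling fractions `f_i` come from a full trait table that includes
species not in the tree -- the correction for trait-biased sampling. At
the root the two subtree solutions are combined without a speciation
factor; state weighting follows the observed relative `D` values
(FitzJohn weighting) and conditioning divides by `(1 - E_i)^2`, both
togglable since neither choice is forced by theory. An unweighted-sum root
option exists because it makes exact likelihood identities available: with
state-equal rates the BiSSE likelihood factorizes into (constant-rate
birth--death) x (2-state Markov chain), which the test suite checks to
1e-5, alongside agreement with a fixed-step RK4 oracle on small trees.

Eight constrained variants form the model lattice: speciation, extinction
and transition rates each shared or free (k = 3..6). Fits cascade from
the all-equal model's estimates. Model selection everywhere uses AICc
(with `n` = number of branching times) and the decisiveness rule that the
best model must beat the runner-up by at least two units; anything closer
is reported as a tie set.

The posterior for the state-specific net diversification rates
`r_i = lambda_i - mu_i` comes from a Metropolis sampler over the free
parameters on the log scale, started at the ML estimates, under
independent exponential priors with rate `1/(2 r_hat)` by default. The
chain runs 20000 generations with a 2000-step burn-in by default;
proposal scales adapt toward ~30% acceptance during burn-in only, so the
retained chain is a valid time-homogeneous sampler. An acceptance rate
outside 0.05--0.9 sets a warning flag in the trace object.

Pairwise trait correlation uses the classic 4-state joint chain: the
independent model has four transition rates (each trait's gain and loss;
its likelihood provably factorizes into the two marginal chains), the
dependent model eight, double transitions disallowed, equal root weights.
Support is a df = 4 likelihood-ratio test, plus Bayes factors from short
MCMC runs estimated two ways: the harmonic mean (kept for comparability
with classical practice despite its notorious instability) and a
stepping-stone estimator over a power-posterior ladder
(`beta = (k/K)^(1/0.3)`, K = 8), which should be trusted when the two
disagree.

## Diversity-dependent models

Speciation declines linearly with standing diversity,
`lambda(N) = max(0, lambda0 - (lambda0 - mu) N / K)`, so that diversity
equilibrates at the carrying capacity `K`; extinction is constant (or
fixed at zero). Because `N` counts lineages that left no sampled
descendants, the likelihood evolves a probability vector over the number
`m` of hidden lineages along the tree (a master-equation ODE in compiled
code), multiplies by `lambda(k + m)` at each observed branching, and reads
out at `m = richness - n_tips` missing extant species at the present. The
birth inflow into state `m` carries the coefficient `2k + m - 1`: a hidden
daughter born to one of the `k` observed lineages counts both daughter
orderings. This is the coefficient that makes the hidden-lineage solution
collapse exactly onto the Nee per-lineage factors when `K` is effectively
infinite -- the package's strongest internal consistency check, enforced
to 1e-4 on 100-tip trees, together with a fixed-step RK4 oracle on small
trees.

Numerics: the truncation bound on `m` adapts. Mass at the boundary only
matters if those excess hidden lineages all die before the present, so the
boundary mass is discounted by `(mu/lambda0)^(M - m*)` and `M` doubles
until the discounted leak is below 1e-10; states above `N = K` are
unreachable (speciation is clamped to zero there), which caps `M` for
small `K`. The propagator is fixed-step RK4 with the step bounded by
`0.125 / (max total event rate)`, which holds the stiffness of the
tridiagonal generator well inside the stability region; halving the step
or doubling `M` moves log-likelihoods by under 1e-6.

Conditioning on crown survival divides by the squared survival probability
of a single lineage whose diversity-dependent rate is driven by its own
descendant count. This ignores the coupling between the two crown
families through the shared `K`; it is exact in the `K -> infinity` limit
and a documented approximation otherwise. Likewise, missing extant
species enter only through the terminal condition, not through
clade-specific placement.

`fit_dd()` starts the carrying capacity at the clade's current richness
and estimates it freely up to a bound of 1e6 species (arbitrary, recorded
in the fit). The fit reports a diversity-equilibrium verdict:
"not_reached" when the estimate exceeds five times the standing richness
or hits its bound -- the expected outcome for a young radiation still in
its expansion phase -- and "plausible" otherwise.

## Fixed-shift two-regime comparison

As a desk-scale stand-in for reversible-jump shift detection, the tree is
split at a designated clade: the clade subtree (conditioned on its crown
age) and the background tree with the clade collapsed to one
representative tip are each given constant-rate likelihoods, and shared
rates are tested against clade-specific rates by a df = 2 LRT and AICc.
Collapsing the clade to a single tip discards the information in its stem
-- the comparison is between nested models on the same decomposition, so
the test is internally valid, but the background rate estimate absorbs a
pendant branch whose history was not background. Clades and backgrounds
of fewer than three tips are refused.

## Crown-group net diversification

The closed-form crown estimator under a relative extinction fraction
`eps = mu/lambda` is

```
r = (1/t) * ( log( n/2 (1 - eps^2) + 2 eps
              + (1 - eps)/2 * sqrt(n (n eps^2 - 8 eps + 2 n eps + n)) )
            - log 2 )
```

which reduces to `log(n/2)/t` at `eps = 0`; a stem-age variant is also
provided. Ranking tables evaluate each clade at `eps = 0, 0.5, 0.9`, sort
by the middle column (published versions of such rankings contain minor
editorial inversions no single-column sort reproduces; the package sorts
deterministically and says so), and round for display to two decimals
with half-away-from-zero ties, the convention of printed tables. Age
confidence intervals propagate monotonically: the younger age bound gives
the upper rate. For the centropogonid-type record (n = 556, t = 5.02,
CI 3.95--6.13) the older age bound yields 0.918, i.e. 0.92 at two
decimals; published tables print 0.91 for this cell, a sub-rounding
discrepancy worth knowing about when comparing output against the
literature.

```{r}
crown_rate(556, 5.02, c(0, 0.5, 0.9))
rate_with_ci(556, 5.02, 3.95, 6.13, 0)
```

## The simulators, and what the tests do and do not show

Every fitted process has a forward generator: trees grow from two crown
lineages, with exact Poisson thinning against the covariate's running
maximum for time-varying rates (no Euler discretisation), per-lineage
Gillespie sampling for the state- and diversity-dependent processes, and
a one-off regime change on a random lineage for the shift model. Extinct
lineages are pruned; conditioning is on survival of both crown lineages
by rejection, never on the tip count, except that an acceptance band
(e.g. within 10% of a target size) can be requested -- a documented
approximation that avoids the biases of stopping a simulation at a fixed
size.

The simulated study conditions mirror an Andean-scale radiation: crown
ages of 5--16 Myr chosen so the expected richness is near 300 tips for
the recovery experiments, a 594-species trait table with 200 species in
the tree for sampling-fraction fixtures, elevation-driven speciation with
`lambda0 = 0.2` and `alpha = 4e-4` per metre (rates rising from 0.2
to ~1.2 events/Myr/lineage as the range gains 4500 m), a two-fold
state-dependent speciation contrast (0.4 vs 0.2), and a fixed-shift
contrast of 1.83 vs 0.5 events/Myr/lineage. Replicate counts in the test
suite are 50 for recovery experiments and 200 for the size studies of the
two likelihood-ratio tests; smaller trees (under ~120 tips) are used for
the pure numerical identities, where problem size only changes runtime,
not the property checked.

Passing these tests shows that the estimators recover the processes they
assume, at realistic sizes, and that the numerics are correct. It does
not show that real radiations follow these processes: the generators
produce clean binary traits without measurement error, a single true
regime or dependency, complete or uniformly-thinned sampling, and exact
ultrametry. State-dependent diversification inference in particular is
known to reject neutral-trait nulls too readily when the tree's rate
variation has other causes, and the classical df = 4 correlated-evolution
LRT is mildly liberal on single finite trees even under its own null --
the size experiments in the test suite measure both rejection rates
directly, and a practitioner should treat correlation p-values near the
threshold with corresponding caution.

## Reproducibility

All generators take explicit seeds; suite reports record the seed, a
configuration hash and the package version. Identical seeds and
configuration give byte-identical summaries.
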