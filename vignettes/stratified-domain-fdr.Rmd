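---
title: "Stratified FDR statistics for protein domain prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified FDR statistics for protein domain prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StratDomFDR)
```

## The problem and the model

Profile-HMM domain annotation scores every domain family against every
protein in a database: tens of thousands of families times millions of
proteins. Each comparison yields a p-value, and the conventional control
on this flood of tests is the E-value, `E = p * N`. E-values control the
expected *number* of false positives, which is the wrong currency when
millions of predictions are made and families differ enormously in how
much true signal they carry. `StratDomFDR` instead treats each family as
its own *stratum* of the multiple-testing problem and estimates, per
stratum, the three FDR-type quantities of the two-component model:

* the p-values of one stratum follow the mixture
  `F(t) = pi0 * t + (1 - pi0) * t^a`, a uniform null of mass `pi0` plus
  a Beta(a, 1) alternative peaked at zero (`mixtureEval()` implements
  the closed forms);
* the positive FDR at threshold `t` is `pFDR(t) = t * pi0 / F(t)`, the
  posterior probability that a prediction with `p <= t` is null;
* the local FDR is the density ratio `lFDR(t) = pi0 / f(t)`, the
  posterior probability that a prediction with `p = t` exactly is null;
* the q-value of a hit is the minimum pFDR incurred by accepting it.

Two features of real HMM search output shape all the estimators:

**Censoring.** Search tools only report hits below a cutoff (here
`c = 0.01`; when searches are run with both statistical-significance
normalizations forced to one, reported E-values equal p-values).
`qvaluesCensored()` therefore scales rank-k estimates by the *total*
number of tests `N` -- proteins scanned -- never by the reported count:
`q(k) = min over j >= k of p_(j) * pi0 * N / j`. No further correction
is needed, because every unreported test has `p > c` and could only
occupy larger ranks. `pi0` is fixed at 1 by default, which is slightly
conservative; an explicit `pi0` can be supplied in simulation studies.
No censored `pi0` estimator is provided.

**Overlap removal.** Evolutionarily related families (clans) hit the
same region of a protein; counting each overlapping hit as a separate
prediction would overstate the signal and bias the FDR down. The
pipeline (`stratifiedStats()`) ranks hits by p-value, greedily keeps
each hit unless it overlaps an already-kept hit (nesting-whitelisted
pairs excepted), estimates the statistics on the kept hits, and gives
removed hits interpolated q-values and lFDRs (piecewise-linear in
log10 p, per family) so that the empirical tests, which need to observe
overlaps, still have statistics for every hit.

## The equal-lFDR threshold theorem

Given per-stratum thresholds `t_i`, the combined FDR is
`sum(t_i * pi0_i * N_i) / sum(F_i(t_i) * N_i)`. Maximizing the expected
prediction count `sum(F_i(t_i) * N_i)` subject to a combined-FDR budget
leads, via the Lagrangian stationarity condition, to the requirement
that every participating stratum sit at the *same local FDR*:
`lFDR_i(t_i) = lambda'` for all i with `t_i > 0`. The same holds when
the combined E-value is constrained instead.

`equalLfdrThresholds()` exploits the monotonicity of both maps: for
mixtures with `a < 1` the lFDR is strictly increasing in `t` and has
the closed-form inverse
`t = [pi0 (1 - lambda) / (lambda (1 - pi0) a)]^(1/(a-1))`, so the
solver only needs a bisection on `lambda'` against the combined FDR
(tolerance 1e-10). We use the analytic inverse rather than an inner
numeric root search because it is exact and removes one tolerance from
the stack; degenerate strata (constant lFDR: `pi0` equal to 0 or 1, or
`a = 1`) are handled all-or-nothing, and strata whose minimum
attainable lFDR exceeds `lambda'` get `t_i = 0` rather than failing --
that matches the constrained optimum when a stratum has no sufficiently
confident tail. A collection that is entirely pure-null makes any
budget below 1 infeasible and errors.

`bruteForceThresholds()` is the independent oracle: an exhaustive
search over a log-spaced grid (1e-8 to 1, plus exactly 0) for at most
4 strata. Its testable content is the theorem itself: at the grid
optimum the per-stratum lFDRs agree within the lFDR movement of one
grid step, and the continuum (equal-lFDR) solution always attains at
least the grid optimum's expected predictions.

## Local FDR estimation

`lfdrCensored()` estimates the p-value density on the score scale
`s = -log10(p)`, where the alternative is nearly log-uniform and
kernel estimation is stable: a Gaussian kernel (Silverman bandwidth by
default) on the reported scores, reflected about the censoring boundary
`s0 = -log10(c)` to kill edge bias, scaled by the estimated reported
mass `m/N`, and mapped back through `f(p) = g(s) / (p ln 10)`. The raw
`pi0 / f(p)` values are clamped to [0, 1] and made non-decreasing in p
by a running maximum, since the true lFDR of a monotone
likelihood-ratio mixture is non-decreasing and thresholding needs
monotonicity. Ties in p share the largest rank throughout (the standard
step-up convention); q-values are capped at 1, E-values are not.

## Empirical FDR tests

Because no external ground truth exists for real predictions, the
package implements label-based empirical FDR tests:

* **ClanOv** (clan overlap): overlapping predictions should be
  evolutionarily related. Scanning in rank order, a hit overlapping a
  kept higher-ranking hit of the *same* clan is REMOVED (not a separate
  prediction, does not block later hits); overlapping a kept hit of a
  *different* clan makes it an FP. FP hits stay in the kept set and
  block later hits -- each domain is compared against all retained
  higher-ranking domains regardless of their own label. Clanless
  families act as singleton clans; nesting-whitelisted pairs never
  trigger removal or FP.
* **ContextC** (context coherence): the top-ranking hit of a protein
  is always a TP; a later hit is a TP iff *some* higher-ranking hit's
  family pairs with its family in the observed-together list L
  (self-pairs cover repeats). The higher-ranking partner's own label is
  deliberately ignored -- the rule requires only that such a domain
  exist.
* **RevSeq / MarkovR** (decoy sequences): `reverseSequences()` writes
  reversed decoys; `trainMarkov()` / `generateMarkovSequences()` fit
  and sample a second-order Markov model (with order-1/0 fallbacks for
  unseen contexts). `decoyFdr()` converts passing counts into an FDR
  estimate, scaling decoy counts by the real-to-decoy *sequence-count*
  ratio (residue-count scaling would be the alternative; the choice is
  exposed through the arguments).

The method-level summary is the mean per-protein empirical FDR
(`FP/(TP+FP)` per protein, REMOVED excluded), which weights a
thousand-domain protein the same as a single-domain one, plus the
empirical E-value (total FP count).

## Per-family noise classes

At a fixed q-threshold (1e-2 by default) each family's labeled counts
give a pseudocounted empirical FDR `efFDR = (1+FP)/(1+TP+FP)`, its
log-deviation `LD = log2(efFDR/q)`, and a two-tailed Poisson p-value of
the FP count against the expectation `q * (TP+FP)` (pseudocount
excluded; the two-tailed p is the doubled one-sided minimum capped at
1 -- simple and conservative). Benjamini-Hochberg across families gives
`q_Poisson`; a family is significant at `q_Poisson <= 1e-3` and then
classed by effect size (|LD| vs 2). `classifyFamilies()` applies the
majority rule over several tests (three votes by default): increased,
decreased, or as-expected noise, where the as-expected vote counts
families that are statistically insignificant *with* small |LD| as well
as significant-but-small ones, and precedence runs
increased > decreased > as_expected.

## Tiered (sequence then domain) q-values

Sequence p-values pool every domain of a family on a protein, so
repeat families whose individual units are weak can still be strongly
significant at the sequence level. Tier 1 thresholds the per-(protein,
family) sequence q-values at `Q_seq`; tier 2 recomputes domain q-values
*only over the surviving hits* and thresholds at `Q_dom|seq`. The
combined FDR is approximately `Q_seq + Q_dom|seq` for small thresholds
under independence, and the implementation warns when either threshold
reaches 0.1. Tiered output is experimental: more powerful than
domain-only q-values, with less accurate FDR estimates.

One design point was genuinely open: the effective test count for tier
2. Keeping the full database size `N` would make every tier-2 q-value
at least its domain-only counterpart (on a subset of the hit list,
ranks shrink and the step-up suffix has fewer candidates), so the tiers
could never gain power -- contradicting their purpose. The package
therefore treats the surviving candidate set as the conditional
multiple-testing burden: tier 2 is the classical step-up over the
surviving domain p-values (an `nTotal` override is available). With a
vacuous gate (`Q_seq = 1`) there is no conditioning and tier 2 reduces
exactly to plain censored domain q-values over the full database.

## The synthetic-data generator

`generateDataset()` produces ground-truthed inputs that exercise every
module without any external download. Design choices, fixed once:

* Per family j, presence is Bernoulli(`1 - pi0_j`); null domain
  p-values are Uniform(0,1), alternatives Beta(`a_j`, 1); only
  `p <= c` is reported. The Beta(a, 1) family is the canonical monotone
  p-value alternative and gives closed forms for every oracle.
* Defaults emulate a heterogeneous database at desk scale: 1000
  proteins per stratum, `pi0` drawn in [0.8, 0.95] for ordinary
  families, `a` in [0.15, 0.35], censoring at 0.01. Repeat families
  (25% of families by default) are rare (`pi0` in [0.95, 0.99]) and
  truly-present proteins carry 4 units drawn from the Beta(0.6, 1)
  alternative *conditioned on being reported* -- individually weak
  (median p about 3e-3, far from domain-level significance) while
  their Fisher combination, which defines the sequence p-value of
  every (protein, family) pair, is strong. Rarity matters: the tiers
  gain exactly when the conditional candidate set is much smaller than
  the database.
* Families are interleaved into co-occurrence modules of about four
  families; where the marginal presence probability permits, a family
  occurs only on its module's proteins (the within-module probability
  is scaled up so the marginal `1 - pi0_j` is preserved). True
  co-occurrence is therefore sparse, the context list L -- built from
  truly co-occurring pairs, plus self-pairs of repeat families -- is
  far from complete, and cross-module null hits are detectable by
  ContextC. Families too common to fit one module occur globally.
* True domains are laid out in consecutive non-overlapping blocks;
  null hits land uniformly at random and may overlap anything. Clans
  group consecutive families (so clanmates usually sit in different
  modules); the nesting whitelist holds clan partners of repeat
  families. Protein lengths are gamma (shape 4, mean 400), grown when
  needed to fit the placed domains; FASTA sequences are i.i.d. draws
  from natural amino-acid background frequencies.
* One seed drives a single generator stream, so identical
  configurations are byte-identical.

What the generator does *not* emulate: p-value miscalibration (its
nulls are exactly uniform, whereas the repetitive-pattern families that
motivate the noise classes have broken nulls in real data), homology-
induced dependence between tests, composition biases linking sequence
content to hit probability, and alignment-level structure inside
domains. Passing tests therefore demonstrate the correctness and
calibration of the estimators under the stated model, not the accuracy
of any particular real-data annotation.

## Numerical choices and problem sizes

Solver bisections run to 1e-10 in the constrained quantity; the oracle
grid is 100-150 points per stratum for 3-stratum problems; calibration
checks use 100 strata of 1e4 tests, lFDR consistency 1e5 draws, the
family-noise simulations 1000 (calibration) and 150 x 4 (power)
families of 500 predictions, and the tiered comparison 8 families x
1000 proteins. These sizes make every distributional check
well-resolved (binomial/Poisson standard errors a few percent of the
quantities compared) while the whole suite stays interactive.

## A worked example

```{r example}
sim <- generateDataset(simConfig(nFamilies = 6, nProteins = 500,
                                 seed = 42, withSequences = FALSE))
ann <- stratifiedStats(sim$hits, nTotal = 500)
head(ann[, c("protein_id", "family_id", "p_domain", "evalue",
             "qvalue", "lfdr", "removed_overlap")])
```

```{r example2}
sc <- StratumCollection(list(MixtureSpec(0.9, 0.3, 1000),
                             MixtureSpec(0.5, 0.5, 500),
                             MixtureSpec(0.99, 0.2, 2000)))
equalLfdrThresholds(sc, budgetQ = 0.05)
```

## Limitations

* `pi0 = 1` everywhere is conservative; strata that are mostly
  alternative lose some power.
* The lFDR estimator needs a few hundred reported p-values per stratum
  to be useful; sparse families should rely on q-values.
* ClanOv underestimates noise on sparse data (a null hit that overlaps
  nothing is labeled TP), and ContextC cannot see a false positive
  that ranks first on its protein.
* The tiered combined-FDR report is an additive approximation, valid
  only for small thresholds under independence of the tiers.
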