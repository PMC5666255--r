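---
title: "Methods: haplotype diversity, neutrality, mismatch demography and structure for mitochondrial alignments"
author: "HaploPop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype diversity, neutrality, mismatch demography and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

HaploPop implements the classical single-locus phylogeography toolkit
for intraspecific mitochondrial alignments — the kind of analysis run on
a COI barcode fragment sampled across the geographic range of a species
to ask where populations survived past climate events and when they
expanded. This vignette is the package's own account of the models, the
estimators, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## Data model

The central container is the `HaploAlignment`: one aligned sequence per
individual (equal lengths enforced; alphabet `A/C/G/T/N/-`, `U` mapped
to `T` on input) plus a per-sample metadata table (population, region,
subregion, coordinates, depth). All statistics are computed per group
and pooled.

Two site-deletion policies exist. Pairwise distances default to
*pairwise deletion* (a site is dropped only for pairs in which either
member is ambiguous). The diversity statistics ($S$, $\Pi$, $\pi$) and
the mismatch histogram default to *complete deletion* (columns carrying
any `N`/gap are dropped once), so that all of these share one site set —
the convention of the standard desktop tools for this analysis. For
gap-free data the two coincide and $\pi = \Pi/L$ exactly; under pairwise
deletion the effective length is the mean per-pair complete-site count,
which preserves that identity.

Haplotype collapsing offers a *wildcard* policy (default: `N` and `-`
are compatible with any base; a sequence joins the first haplotype whose
representative it is compatible with, in input order) and a *strict*
policy (exact string identity). Wildcard matching is not transitive, so
the procedural first-match rule is part of the definition; it is
deterministic for a fixed input order. Haplotype ids are `H` plus the
1-based order of first appearance. Barcode submissions commonly carry
terminal `N` runs, which is why the tolerant policy is the default;
published haplotype counts rarely state which convention was used, so
both are provided.

## Diversity indices

For each group: sample size $n$, haplotype count $k$, private haplotypes
(observed in exactly one group) and their ratio to $k$, Nei's unbiased
gene diversity $H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$
(uncorrected form behind a flag), segregating sites $S$, mean pairwise
differences $\Pi$, per-site diversity $\pi$, and Watterson's
$\theta_W = S / a_1$ with $a_1 = \sum_{i=1}^{n-1} 1/i$ (per-locus
scale). Values are kept at full precision internally and rounded only by
the CSV writer (5 decimals).

## Neutrality tests

**Tajima's D** contrasts the two classical estimators of $\theta$:

$$D = \frac{\Pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}$$

with the standard constants ($b_1$, $b_2$, $c_1$, $c_2$, $e_1$, $e_2$
from $n$). $S = 0$ raises an explicit *statistic undefined* error rather
than silently returning 0.

**Fu's Fs** uses the Ewens sampling distribution of the number of
alleles: with $\theta$ estimated by $\Pi$,
$S' = P(K \ge K_{\mathrm{obs}})$ where
$P(K = k) = |s_1(n,k)|\,\theta^k / \theta^{(n)}$, and
$F_s = \ln\!\big(S'/(1-S')\big)$. The unsigned Stirling numbers of the
first kind are computed once per $n$ by the log-space recurrence
$|s(n{+}1,k)| = n|s(n,k)| + |s(n,k{-}1)|$ (cached; exact enough at
$n = 364$ where the linear-scale recurrence would overflow), and the
tail sums use log-sum-exp. $K_{\mathrm{obs}} = 1$ is the $S' = 1$
boundary and raises a guarded error.

**Significance** is by coalescent simulation: `neutralityTest()` draws
constant-size samples at $\theta = \Pi$ (the conditioning used by Fu),
recomputes each statistic, and reports the left-tail
$(r+1)/(B+1)$-corrected p-value, since negative values are the expansion
signal. Replicates where a statistic is undefined are dropped and
counted, with a warning flag above 10%. Following Fu's own analysis of
his statistic, Fs is *deemed significant at the 5% level when
p < 0.02*; the result reports this decision alongside the raw p-value.
Our null-calibration experiments reproduce the textbook picture: at a
raw 0.05 threshold the D test rejects at ~4–5% while Fs rejects at
~7–8%, and under the p < 0.02 convention Fs returns to ~4–5%. Default
replicate count is 1000 (raise to 10 000 for publication-scale runs).

## Mismatch distributions and expansion models

The observed mismatch distribution is the histogram of pairwise
difference counts over all $n(n-1)/2$ pairs; its mean equals $\Pi$ by
construction (a tested contract).

**Sudden demographic expansion.** A population at equilibrium scaled
size $\theta_0$ jumps to $\theta_1$ at $\tau$ mutational time units
before present ($\tau = 2ut$). With
$\hat F_i(\theta) = \theta^i/(\theta+1)^{i+1}$,

$$F_i(\tau, \theta_0, \theta_1) = \hat F_i(\theta_1) +
e^{-\tau(\theta_1+1)/\theta_1} \sum_{j=0}^{i}
\frac{\tau^{i-j}}{(i-j)!}\,\big(\hat F_j(\theta_0) - \hat F_j(\theta_1)\big).$$

The convolution kernel absorbs the exponential damping in log space so
large $\tau$ stays finite; $\theta_1 = 0$ takes its analytic limit. The
returned vector is truncated at `dMax` (observed maximum + 5 when
fitting — the truncated mass is negligible there) and renormalized.

**Spatial (infinite-island) expansion.** One sampled deme of scaled
size $\theta$ inside an effectively infinite island system that expanded
$\tau$ mutational units ago from a single ancestral deme of the same
size. Backwards in time a pair either coalesces within the deme before a
migration separates it (competing rates $1$ vs $M$), or survives the
recent epoch and coalesces in the ancestral deme. The mismatch is the
corresponding mixture

$$F_j = \int_0^{\tau/\theta} e^{-(1+M)t}\,
\mathrm{Pois}(j;\theta t)\,dt \;+\; S(\tau/\theta)\sum_{k \le j}
\hat F_k(\theta)\,\mathrm{Pois}(j-k;\tau),$$

with $S(T) = 1 - (1-e^{-(1+M)T})/(1+M)$ the probability of reaching the
ancestral phase; the integral is evaluated adaptively with the upper
limit clipped where the exponential underflows. As $M \to \infty$ this
converges to the sudden-expansion form with a large $\theta_1$, and at
$\tau = 0$ to the stationary distribution of the deme — both are tested
limits. Note that the common tabular outputs of desktop tools label the
spatial model's parameters $\theta_0/\theta_1$; the package exposes the
model's native $(\tau, \theta, M)$.

**Fitting** minimizes the sum of squared deviations (SSD) between
observed relative frequencies and the model — the same objective whose
value is the goodness-of-fit statistic — by bounded multi-start
L-BFGS-B: 8 starts crossing $\tau \in \{\bar d, \bar d/2\}$ (the
method-of-moments mean difference) with $\theta_0 \in \{0.01, 1\}$,
$\theta_1 \in \{10, 100\}$ (demographic) or $\theta \in \{0.01, 1\}$,
$M \in \{0.5, 10\}$ (spatial); box bounds $\tau \in [0, 50]$,
$\theta \in [0, 10^5]$, $M \in [0, 10^4]$. The returned optimum is never
above any start value (tested), and estimates on the upper bound are
flagged as effectively infinite, mirroring the "inf" entries customary
in published tables. A histogram with fewer than two occupied classes is
rejected as unidentifiable.

**Goodness of fit.** Harpending's raggedness
$r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2$ (with $x_{d+1} = 0$; a point
mass gives $r = 1$, a uniform over ten classes $0.01$) and the SSD are
tested by parametric bootstrap: `bootstrapGof()` simulates `B` coalescent
datasets under the fitted parameters with matching $n$, refits each
(warm-started from the parent estimate plus two spread starts), and
reports $p = \#\{\mathrm{SSD}_b \ge \mathrm{SSD}_{\mathrm{obs}}\}/B$ —
the raw-proportion convention of the standard tools, so a perfect fit
yields $p = 1$ — plus 5–95% percentile intervals of the refitted
parameters. Bootstrap replicates are simulated directly as
infinite-sites mismatch histograms (sequence strings are never needed),
which keeps the default `B = 1000` and the publication-scale 10 000
tractable.

## AMOVA and pairwise differentiation

The hierarchical partition follows the standard molecular-variance
mean-square equations with unequal-sample-size coefficients, using
pairwise mutational-difference counts in the role of squared Euclidean
distances (the sequence-level $\Phi$ design; a 0/1 haplotype metric for
conventional frequency-based $F_{ST}$ sits behind a flag). Two-level
designs yield $\Phi_{ST}$; three-level designs (populations in regional
groups) yield $\Phi_{ST}$, $\Phi_{CT}$, $\Phi_{SC}$. Significance is by
permutation — individuals among populations for $\Phi_{ST}$, individuals
within groups for $\Phi_{SC}$, whole populations among groups for
$\Phi_{CT}$ — with $(r+1)/(B+1)$ p-values. Negative variance components
are reported as computed (floor behind a flag). `pairwisePhiST()` runs
the two-level analysis on every population pair (identical, by a tested
contract, to `amova()` on that pair) and also reports
sequential-Bonferroni (Holm) adjusted p-values, since published
"corrected p-values" rarely name their procedure; pairs with fewer than
two samples per side are flagged undefined rather than guessed.

One property worth stating honestly: duplicating every individual does
*not* leave $\Phi_{ST}$ exactly invariant, because the unbiased
(df-corrected) mean squares do not scale back perfectly; the point
estimate is only asymptotically invariant, and the test suite asserts
approximate equality.

## Statistical-parsimony networks

The connection limit is the largest step count $j$ whose *parsimony
probability* is at least $\alpha$ (classically 0.95). We model a pair of
sequences of length $L$ differing at $j$ sites under a Jukes–Cantor site
model: with per-site divergence probability $q$ and expected mutation
count $\lambda(q) = -\tfrac{3}{4}\ln(1 - \tfrac{4q}{3})$, a connection is
parsimonious when each of the $j$ differing sites arose by exactly one
mutation. Averaging over the posterior of $q$ given $(j, L)$ under a
uniform prior on $(0, 0.75)$:

$$P_j = \frac{\int w(q)\,\big[\lambda e^{-\lambda}/q\big]^j\,dq}
{\int w(q)\,dq}, \qquad w(q) = q^j (1-q)^{L-j}.$$

The production routine integrates adaptively with the interval split
around the sharp posterior peak near $j/L$; an independent dense-grid
Riemann oracle is shipped alongside and equality is tested. At
$L = 554$, $\alpha = 0.95$ the limit is 8 steps (the 9-step probability
is 0.947), in the neighbourhood practitioners expect for ~550-bp
mitochondrial fragments.

Network construction connects haplotype pairs in non-decreasing
distance order, skipping any connection between already-connected nodes
(so the default output is a forest; edge count = nodes − components is a
tested identity). A connection at distance $d > 1$ inserts $d-1$
inferred intermediate nodes — the "haplotypes not collected but expected
to exist" — with mutations applied in ascending site index starting from
the higher-frequency endpoint, making inferred sequences deterministic.
Interactive ambiguity resolution in the original desktop tool is
under-specified; we replace it with a deterministic preference order
(higher pair frequency, then summed frequency, then id order), which is
required for reproducible tests. Inferred intermediates are always fresh
nodes, never spliced into existing ones.

The ancestral haplotype of each component is the observed node
maximizing a normalized product of relative frequency and relative
degree (+1 smoothing so isolated haplotypes score), with ties broken by
frequency then id and flagged. On star-like simulated expansions
(n = 50, $\tau = 3$, $\theta_0 = 0.01$, $\theta_1 = 20$) this
designation recovers the true simulated root in ~95% of replicates; the
regression test asserts ≥ 60%.

## Dating

$T = \tau / (2 \mu L)$ years, with $\mu$ the substitution rate per site
per year and $L$ the fragment length. The default
$\mu = 2\times 10^{-8}$ is the package constant consistent with its
worked examples at $L = 554$ and should be overridden per study. Because
short-term (pedigree) mutation rates exceed long-term substitution rates
by roughly an order of magnitude, a correction factor (default 10)
divides the raw time; both uncorrected and corrected values are always
reported side by side, since published tables are not always explicit
about which row carries the correction. Effective sizes invert
$\theta_0 = 2N_0 u$, $\theta_1 = 2N_1 u$ for a user-supplied per-locus
generational rate $u$.

## The coalescent simulator

Time is scaled in units of $N$ generations of the reference (present)
population, so $\theta = 2Nu$ per locus, pairs coalesce at rate 1 and
mutations fall at rate $\theta/2$ per lineage — giving the textbook
expectations $E[\Pi] = \theta$ and $E[S] = \theta a_1$, which the suite
verifies against 2000-replicate averages. Histories: constant size;
sudden expansion (ancestral size ratio $\theta_0/\theta_1$, switch at
$\tau/\theta_1$ — the bridge that makes simulated data match
`expectedSudden` in expectation, verified directly); exponential
growth; a finite island model (per-lineage migration rate $M/2$); and
the two-phase infinite-island spatial expansion used by the spatial
bootstrap. Mutations are Poisson on branch lengths; infinite-sites mode
gives every mutation its own column, finite-sites mode draws columns
with replacement and applies an HKY-like transition-biased change
(default transition/transversion ratio 3.99, the value typical of COI
datasets of this kind), stacking multiple hits in time order down the
tree. The root sequence is all-`A`: haplotype identity and every
statistic in the package depend only on differences, not on base
composition, so a neutral reference keeps the generator simple.

`makeStudyLikeDataset()` emulates the shape of a circum-Antarctic COI
study: 364 sequences of 554 bp in four regions with contrasting
histories — two old, diverse expansions (n = 227 at
$\tau = 3.4, \theta_1 = 29.4$; n = 95 at $\tau = 4.7, \theta_1 = 16.6$),
a recent low-diversity expansion (n = 29 at
$\tau = 0.9, \theta_1 = 0.95$) and a small founder-style sample (n = 13
at $\tau = 1.3, \theta_1 = 3.5$). The $\tau$ and $\theta_1$ values are
the demographic estimates published for such data (the two large-region
$\theta_1$ taken from the subsets that exclude the strongly diverged
local population, which better reproduce the observed haplotype
richness); with them the pooled haplotype count calibrates to the
85 ± 25 band in ~96% of seeds and the recent-expansion region shows
lower $H$ and $\Pi$ than the old-expansion region in essentially every
seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no recombination (fine for mtDNA), no
selection, no sequencing error or alignment artefacts, no geographic
substructure within regions, no shared haplotypes across regions beyond
chance identity, and finite-sites homoplasy only through the simple
transition-biased overlay rather than a fitted substitution model.

## Numerical choices and problem sizes

Explicit seeds everywhere; one pipeline seed derives per-stage seeds by
stage-name hashing so stages re-run identically in isolation. Permutation
and bootstrap p-values use the conventions stated above ($(r+1)/(B+1)$
for permutations and simulation tests; raw $r/B$ for the mismatch
bootstrap, matching the desktop tools). The test suite runs its
simulation experiments at deliberately moderate sizes chosen to make the
statistical assertions sharp but the suite quick: 1000 datasets × 100
null replicates for neutrality calibration, 100 datasets for mismatch
parameter recovery and 100 meta-replicates × B = 200 for bootstrap
uniformity, 500 replicates for the AMOVA type-I experiment, 100 seeds
for the study-like directional checks. Publication-scale replicate
counts (10 000 permutations/bootstraps) are a flag away.

## Known limitations

Single-locus inference inherits all the usual caveats: one realization
of the coalescent, mitochondrial effective size, and rate-calibration
uncertainty that dwarfs most statistical error in the dating step. The
wildcard collapse depends on input order in pathological overlap cases.
The spatial model assumes an effectively infinite number of demes and
equal deme sizes. The network's deterministic ambiguity rule is one
defensible choice among several that the original interactive tools left
to the user.
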