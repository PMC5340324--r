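---
title: "Scale-aware decomposition of high-order epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-aware decomposition of high-order epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiwalsh)
```

## The model

A combinatorially complete genotype–phenotype map assigns a measured
phenotype to every combination of states at $L$ mutated sites. For binary
sites the map has $2^L$ genotypes and can be decomposed *exactly* into
$2^L$ epistatic coefficients. `epiwalsh` uses the Walsh (Hadamard) basis:
each site is coded $-1$ for the wild-type state and $+1$ for the mutant,
and the design matrix $X$ holds the constant column plus the products of
site codes over every subset of sites. For the full-order binary design
$X^\top X = 2^L I$ holds in exact integer arithmetic, so

$$\vec{P} = X\vec{\beta}, \qquad \vec{\beta} = \frac{X^\top \vec{P}}{2^L}.$$

Coefficients on this basis measure effects relative to the geometric center
of the map: $\beta_0$ is the mean phenotype, first-order terms are half the
average mutational effects, and a $k$-th-order term is a $k$-way
interaction. Sites with four states (nucleotides) use the WYK tetrahedral
code — wild type at $(1,1,1)$, the remaining three states at tetrahedron
corners $(1,-1,-1)$, $(-1,1,-1)$, $(-1,-1,1)$ — contributing three bit
columns each; interaction columns are products of bit columns from distinct
sites. The resulting full design for a map with two 4-state and three
binary sites is $128 \times 128$ and invertible; truncated designs are
solved by ordinary least squares.

### Why the scale matters

The decomposition is linear: its only way to account for phenotypic
variation is through coefficients. If the measurement scale is a monotone
nonlinear function of an underlying additive trait — saturation,
multiplicative growth effects — that curvature is mis-assigned to
interaction terms, producing statistically robust but biologically empty
"epistasis" at third, fourth, even fifth order. The package therefore
estimates the scale first, removes it, and decomposes what is left.

The scale model is a power transform of the estimated additive phenotype.
With $\langle \Delta P_j \rangle$ the average effect of mutation $j$ over
all backgrounds and $x_{ij} \in \{0, 1\}$ its presence in genotype $i$,

$$\hat{P}_{add,i} = P_{wt} + \sum_j \langle \Delta P_j \rangle\, x_{ij},
\qquad
\tau(p) = a\,\frac{(p+A)^{\lambda} - 1}{\lambda\,GM^{\lambda-1}} + B,$$

where $GM$ is the geometric mean of $(\hat P_{add} + A)$ and the $\lambda
\to 0$ limit is $a\,GM\log(p+A) + B$. The observed phenotypes are then
**linearized** by the exact inverse,

$$P_{linear} = \left[\lambda\,GM^{\lambda-1}\,(P_{obs}-B)/a + 1
\right]^{1/\lambda} - A,$$

and the linearized vector is decomposed. The wild-type intercept in
$\hat P_{add}$ puts predictions and observations on a common scale, so the
$P_{obs}$ vs $\hat P_{add}$ cloud can be read against the identity line.

### The amplitude parameter

The classic geometric-mean-normalized Box–Cox form fixes $a = 1$. That
normalization has a consequence worth spelling out: the derivative of the
$a=1$ curve is $((p+A)/GM)^{\lambda-1}$, whose geometric mean over the data
is exactly 1 for *every* $(\lambda, A)$ — the curve can bend but cannot
change overall gain. Fitted to strongly saturating data this constraint
forces a visible lack of fit, and the unexplained curvature leaks back into
the interaction coefficients. Box–Cox modeling in regression practice pairs
the transform with a freely scaled linear predictor, and `epiwalsh` does
the analogous thing: the amplitude $a$ is estimated (profiled exactly,
together with $B$, by linear least squares inside the objective). A
hand-constructed `power_transform()` keeps $a = 1$, so all closed-form
identities of the normalized transform hold; a fitted transform reports its
estimated amplitude.

## Fitting: numerics and safeguards

The objective — sum of squared residuals of $\tau(\hat P_{add})$ against
$P_{obs}$, with $GM$ recomputed from $(\hat P_{add} + A)$ at every $A$ — is
reduced to two dimensions by profiling $a$ and $B$, then minimized by a
coarse grid over $\lambda \in [-4, 4]$ (step 0.1) and $A$ (log-spaced
shifts above the positivity bound $A > -\min \hat P_{add}$), followed by a
restarted Nelder–Mead polish. The grid exists because the surface is
multimodal: log-like ($\lambda \approx 0$) and hyperbola-like ($\lambda <
0$) branches compete, and local search from a single start point routinely
lands on the wrong one.

Three safeguards keep the *inverse* of the fitted curve usable, which the
plain least-squares problem does not guarantee:

* **Identifiability.** If $\hat P_{add}$ is (nearly) constant the scale is
  unidentifiable and the identity transform is returned; if a straight line
  already fits to machine precision the affine ($\lambda = 1$) member is
  returned. In either case downstream correlations are exactly what a
  no-transform analysis gives.
* **Asymptote margin.** Curves with $\lambda \ne 0$ have a finite asymptote
  where the back-transform's bracket hits zero. Candidates whose asymptote
  falls within 5% of the observed phenotype range are penalized, because
  observations near the asymptote linearize to arbitrarily extreme values.
* **Expansion guard.** $\hat P_{add}$ is computed *from* the observed
  phenotypes, so with little real curvature the flexible curve can chase
  correlated scatter; near-pole fits then map some observations to absurd
  linearized values. If the back-transform expands the additive range more
  than 3-fold the fit is redone with $\lambda \ge 0$ (whose inverse is
  bounded below, and always defined on the log branch); if even that
  expands the range a thousand-fold the affine member is used. A screening
  test (polynomial F-test for curvature) was evaluated as an alternative
  and rejected: under heavy epistatic scatter its power is too low, and it
  vetoed genuinely curved maps far more often than the guards mis-fire.

The pipeline linearizes with `clip = TRUE`: an observation outside the
fitted curve's image (possible for a handful of extreme genotypes after a
guarded fit) maps to the boundary value $-A$ rather than aborting the
analysis. Direct calls to `linearize()` default to a hard error that lists
the offending genotypes.

## Uncertainty: bootstrap, z-scores, Bonferroni

Measurement uncertainty is propagated by parametric pseudoreplicates: one
phenotype per genotype drawn from $\mathcal{N}(\text{mean}, \text{sd})$
using each genotype's replicate statistics, independently across genotypes;
each pseudoreplicate vector is (optionally) re-linearized and decomposed.
By default the power transform is *refit* to every pseudoreplicate —
propagating scale-fit uncertainty into the coefficients, warm-started from
the point estimate — with `refit_transform = FALSE` available to freeze the
point-estimate transform.

Convergence follows a batch rule: after every 50 pseudoreplicates the
running mean and variance of every coefficient are compared with the
previous batch's values; the run stops when all relative changes fall below
0.1%. Two things follow from the arithmetic of running means. For a
coefficient whose mean is near zero the relative change of the mean decays
like $\sqrt{50/n}/|z|$, so the rule often cannot bind at any practical
budget; runs then stop at `max_reps` (default 200,000) with
`converged = FALSE` and a warning, and the returned summaries are still
valid Monte-Carlo estimates. With all-zero measurement noise every
pseudoreplicate is identical and the rule fires at the second batch.

Significance: $z = \text{mean}/\text{sd}$ across the ensemble, two-sided
standard-normal p-value, Bonferroni multiplied by the number of
*non-constant* coefficients in the model (the constant has no null of
interest), flags at the chosen $\alpha$ and the usual star convention on
the corrected p-value (0.05 / 0.01 / 0.001). A coefficient with zero
bootstrap sd and nonzero mean is reported with $p = 0$ by convention.

## Variance partition by order

`partition_variance()` fits nested truncated models (columns of order $\le
k$) by ordinary least squares and measures each as the squared Pearson
correlation between fitted and observed phenotypes; the contribution of
order $k$ is the increase over order $k-1$. Squared correlation — rather
than the raw correlation — is used because fractions of variation must be
additive and bounded by 1. On complete binary maps the columns are
orthogonal, so these OLS fractions equal the normalized per-order sums of
squared Walsh coefficients (the test suite checks this equivalence), and
the full-order model fits exactly.

## The simulator and what it stands for

`random_coefficients()` draws one coefficient per design column from
zero-centered normals with per-order standard deviations, defaulting to 1
for first-order effects and 0.35 for every higher order — interactions
typically a third the size of main effects, with all orders present.
`build_map()` constructs $P = X\beta$, applies a scale, and adds replicate
noise (per-genotype mean, sd and count, as an experimentalist would record;
with a single replicate the generating noise sd is recorded, since one draw
cannot estimate it).

The saturating scale $(1+K)p/(1+Kp)$ has fixed points at 0 and 1 and is
applied after mapping the linear phenotypes affinely onto $[0.02S, S]$.
The span matters more than it looks: span $S$ at constant $K$ is exactly
equivalent to span 1 at constant $KS$, so "how nonlinear the map is" is the
product, not $K$ alone. The default $S = 8$ places the data across the
curve's full working range, where a shallow $K = 2$ already produces the
phenomenon of interest — spurious interaction coefficients at third order
and above that are a substantial fraction of the main effects, and a raw
analysis whose recovered coefficients correlate poorly with the generating
truth. With phenotypes confined to the unit interval the same $K$ is
nearly affine over the data and the phenomenon all but disappears; a span
of order ten corresponds to traits (fitness, growth rate, binding signal)
whose dynamic range spans an order of magnitude while the saturation
constant is of order one.

What the simulator does *not* emulate: non-Gaussian replicate error,
genotype-dependent error magnitude correlated with signal,
missing/censored genotypes (the package requires complete maps), linked or
correlated coefficients, and scales outside the monotone family. Passing
tests on simulated maps therefore demonstrates correctness of the
machinery and calibration under the stated error model, not robustness to
every failure mode of real assays.

## Study conditions used by the test suite

The suite exercises fixed, seeded problem sizes chosen to make every check
sharp but quick: maps of 3–5 binary sites (plus the 128-genotype
two-nucleotide-site layout), 20 seeded replicates for the
coefficient-recovery experiment, 200 simulated 4-site maps for the
bootstrap false-positive calibration, 100 maps for interval coverage, and
bootstrap budgets of $10^3$–$2\times 10^4$ pseudoreplicates where the
convergence rule cannot bind. The recovery experiment asserts a mean
with-transform $R^2 \ge 0.85$ and a mean advantage over the no-transform
control $\ge 0.3$; the scale-alone experiment asserts that linearization
drives every order-$\ge 2$ coefficient below 10% of the leading main
effect while the raw analysis leaves order-$\ge 3$ terms above that bound.

## Known limitations

* **Family mismatch.** The saturating curve is not a member of the power
  family, so even a perfect fit leaves a small systematic residue —
  typically a few percent of the leading main effect ends up in order-$\ge
  2$ coefficients of an additive map. Against measurement noise of
  realistic size this residue is invisible, but with *very* precise data it
  is a real bias, and a significance test will (correctly) flag it. When a
  scale is exactly in the family, the residue is at solver tolerance; the
  suite tests both situations separately.
* **Epistasis-dominated maps.** When interactions, not main effects,
  carry most of the variation, $\hat P_{add}$ is a weak axis and the scale
  is weakly identifiable; the guards then lean toward mild or affine
  transforms. This is a statement about the data, not the optimizer: no
  method can read a scale off a cloud with no additive trend.
* **Bonferroni is conservative**, deliberately so; with 31+ coefficients
  per map, weak genuine interactions will be missed at stringent corrected
  thresholds.
* The bootstrap samples each genotype's recorded replicate sd directly
  (not the standard error of its mean), matching how the uncertainty
  distributions are defined upstream; with many replicates per genotype
  this overstates uncertainty and is conservative.
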