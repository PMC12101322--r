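---
title: "Methods: disorder metrics, phase-space classification, and the disorder-LLPS regression"
author: "disphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder metrics, phase-space classification, and the disorder-LLPS regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disphase)
```

This vignette is the package's own account of the models it implements:
what each quantity means, which parameters matter and why their
defaults are what they are, the numerical choices made where the
methodology left room, what the synthetic generator does and does not
emulate, and the known limitations.

## Per-protein disorder metrics

Disorder predictors emit one score per residue in $[0,1]$, higher
meaning more likely disordered. For one protein and one predictor
track $s_1,\dots,s_L$:

- **ADS** (average disorder score) $= \frac1L \sum_i s_i$;
- **PPIDR** (percentage of predicted intrinsically disordered
  residues) $= \frac{100}{L}\,\#\{i : s_i > t\}$ with $t = 0.5$.

The PPIDR inequality is **strict**: a residue scoring exactly 0.5 is
not counted. The threshold is exposed as a parameter
(`compute_ppidr(values, threshold)`), but 0.5 is the standard
convention and is the default everywhere downstream.

Three-tier categories follow the established literature baselines:
highly ordered (PPIDR $<$ 10%), moderately disordered
(10% $\le$ PPIDR $<$ 30%), highly disordered (PPIDR $\ge$ 30%); for
ADS the cut points are 0.25 and 0.5, with the upper band inclusive of
0.5. The intervals are half-open so the three labels partition their
domain with no gap or overlap; this is property-tested over fine
grids.

When several predictors cover a protein, `summarize_disorder()`
averages ADS and PPIDR arithmetically across the selected sources and
classifies the **means**. Whether a cross-model tally should classify
averaged metrics or tally per-model classifications is genuinely
ambiguous in practice, so `disorder_category_counts()` emits both
readings (`by = "mean"`, `by = "source"`). The mean-based reading is
the default because the downstream regression also uses the averaged
PPIDR. The residue-wise mean across predictors is available as a
derived track (`mean_disorder_profile()`, source label `MDP`).

## CH-CDF phase space

Two sequence-level binary classifiers are combined into a quadrant
diagram.

**Charge-hydropathy (CH).** The protein is a point in (mean scaled
Kyte-Doolittle hydropathy, mean absolute net charge) space. The charge
model is the simplest consistent convention: K, R $= +1$; D, E
$= -1$; histidine 0 (configurable via `his_charge`); termini ignored.
Hydropathy is the whole-sequence mean of $(\mathrm{KD}(aa)+4.5)/9$
with no sliding window; the unknown residue X contributes the scale
midpoint 0.5. The boundary is the line
$q = 2.785\,h - 1.151$ — the standard constants of the CH
classifier — and $\Delta_{CH}$ is the signed vertical distance above
it, positive on the disordered side. Both constants are configurable
through the JSON boundary config.

**Cumulative distribution function (CDF).** For a score track, the
curve $F(s) = \#\{i: s_i \le s\}/L$ is evaluated at the boundary
abscissae and $\Delta_{CDF}$ is the mean of (curve $-$ boundary
ordinate); a curve **above** the boundary means most residues score
low, i.e. an ordered call, so positive $\Delta_{CDF}$ is the ordered
side. The canonical boundary coordinates used by the common web
implementation are not published, so the package ships an explicitly
non-canonical placeholder — seven points at abscissae $0.1,\dots,0.7$
on the line $f = s + 0.15$ — and reads replacement coordinates from
the same JSON config. Quadrant *counts* obtained with the placeholder
are therefore not comparable to published counts; the quadrant
*mechanics* are.

**Quadrants.** Q1: $\Delta_{CDF}\ge 0,\ \Delta_{CH}<0$ (ordered by
both); Q2: both negative (CH-ordered, CDF-disordered — putative molten
globules); Q3: $\Delta_{CDF}<0,\ \Delta_{CH}\ge 0$ (disordered by
both); Q4: both non-negative. Ties at exactly zero resolve to the
ordered side on the CDF axis and the disordered side on the CH axis; the
choice is arbitrary and documented, and the assignment is a total
function of the two signs.

Which predictor's track feeds the CDF is not dictated by the method;
`chcdf_classify()` defaults to the alphabetically first source and
accepts any other.

## Consensus disorder and domain overlap

A residue is consensus-disordered when the fraction of supplied tracks
scoring it above 0.5 is at least the agreement threshold (default
0.75, **inclusive**, so 3 of 4 tracks suffice). The denominator is the
number of tracks supplied for that protein, which generalizes across
proteomes where different predictors have different coverage.
Consensus is monotone: raising the agreement threshold never converts
a residue to disordered (property-tested across a grid).

Overlap counts are plain interval arithmetic on 1-based inclusive
coordinates. For superfamily totals, positions under two intervals of
the same superfamily count once per interval by default (a per-domain
reading of residue-impact tables); `dedupe = TRUE` switches to unique
positions per protein. The four-stage funnel counts proteins with
tracks, with at least one consensus-disordered residue, with at least
one domain, and with at least one consensus-disordered residue inside
a domain.

Set enrichment is the generic upper-tail hypergeometric test of a
query set against term sets over a universe, Benjamini-Hochberg
corrected across terms. No ontology graph traversal is performed; the
operation treats terms as opaque labels.

## LLPS profiling

Thresholds follow the droplet-state prediction literature and are all
**inclusive**:

| quantity | threshold | meaning |
|---|---|---|
| `p_llps` | $\ge 0.60$ | droplet-driver vs droplet-client |
| `p_dp` runs | $\ge 0.60$, length $\ge 5$ | droplet-promoting regions |
| hot-spots | `p_dp` $\ge 0.60$ and `s_bind` $\ge 2.2$ | aggregation-prone residues |
| context zones | `s_bind` $\ge 2.25$ | context-dependent interaction zones |

The two divergence thresholds (2.2 and 2.25) are deliberately kept as
two independently named parameters: the source methodology uses both
values for the two related but distinct calls, and the package does
not attempt to reconcile them. Runs truncated by the sequence ends
still count as regions if they reach the minimum length — there is no
edge penalty.

## Interaction networks

The average node degree is $2E/N$ over the **full node universe
including isolates**. This convention is forced by the arithmetic of
published network summaries (an average degree printed as $4.74$
equals $2\cdot 581/245$, the full universe, not the 209 interacting
nodes), and it is why `edge_list` objects carry their universe
explicitly rather than inferring it from edge endpoints. The average
local clustering coefficient is the mean over all universe nodes of
(triangles through the node) / (neighbour pairs), with degree-$<2$
nodes contributing 0 — included, not dropped, which affects
comparability with conventions that exclude them.

Edge-count enrichment uses an explicit binomial null: every one of the
$\binom{N}{2}$ pairs is independently an edge with a background
probability (user-supplied, or estimated as the density of a supplied
background edge list). The reported p-value is the binomial upper tail
$P(X \ge E_{obs})$ floored at $10^{-16}$, the conventional reporting
floor. This null is deliberately simple and *not* numerically
comparable to proprietary degree-corrected nulls used by interaction
databases; it answers the same qualitative question (are there more
edges than a random background would give?) with a fully documented
model.

## The disorder-LLPS regression

The association pipeline is: nudge $p_{LLPS}$ off the boundaries
($0 \to 10^{-6}$, $1 \to 1-10^{-6}$; interior values untouched), apply
the Box-Cox transform $(v^\lambda-1)/\lambda$ (log at $\lambda=0$)
with $\lambda$ estimated from the data, then fit
$y = \beta_0 + \beta_1 x + \beta_2 x^2$ by OLS where $x$ is the mean
PPIDR across the selected predictors.

$\lambda$ maximizes the standard Box-Cox profile log-likelihood
$-\tfrac{n}{2}\log\hat\sigma^2(\lambda) + (\lambda-1)\sum\log v_i$
over $[-2,2]$: a grid scan at step $10^{-3}$ brackets the optimum and
golden-section refinement narrows it to $10^{-5}$. The estimate is
treated as data-dependent — a published $\lambda \approx 0.0606$ on a
different dataset is not a constant to hard-code — but a fixed
$\lambda$ can be supplied (`fixed_lambda`) for exact reproduction
scenarios. The reported p-value is the overall F-test of the quadratic
model against the intercept-only model; a constant response yields a
flagged degenerate result ($R^2=0$, p `NA`) rather than an error.

Diagnostics sufficient for the four standard plots (residuals vs
fitted, normal Q-Q, scale-location, residuals vs leverage) are
returned per observation: fitted values, residuals, internally
standardized residuals, hat values and Cook's distances. $R^2$ is
checked in tests to equal $1-\mathrm{RSS}/\mathrm{TSS}$ recomputed
from that table to $10^{-10}$, and leverages sum to the number of
parameters.

## The synthetic proteome generator

`generate_proteome()` emulates the *statistical structure* of an
organellar disorder/LLPS study so that every pipeline stage can be
exercised and verified against planted truth without any downloads.

Per protein: a composition class (ordered / mixed / disordered) is
drawn with weights defaulting to $0.19/0.42/0.39$, targeting the
roughly $19/42/39\%$ ordered/moderate/high split reported for
acrosomal proteomes. Sequences (default 250 proteins of 100-1200
residues) are drawn i.i.d. from class-specific residue frequencies:
the disordered class is enriched in D, E, K, S, P, Q and depleted in
I, L, V, F, W, Y; the ordered class the reverse. A per-residue latent
disorder signal is the 15-residue windowed fraction of
disorder-promoting residues passed through a logistic map centred on
the per-protein quantile that puts a target fraction $u$ of residues
above 0.5, with $u$ drawn per class from $(0.01,0.07)$,
$(0.13,0.27)$, $(0.34,0.90)$. Those ranges sit strictly inside the
three-tier category bands, so with zero track noise the classification
of the mean PPIDR recovers the planted class exactly — a tested
invariant, and the reason the class ranges stop short of the 10% and
30% boundaries. Predictor tracks add independent
$\mathcal N(0,\sigma_{pred})$ noise (default 0.15) and clip to
$[0,1]$; more noise strictly lowers inter-predictor correlation.

LLPS propensity follows a logistic link
$p = \mathrm{logit}^{-1}(a_0 + a_1 d + a_2 d^2 + \varepsilon)$ with
$d$ the true disorder fraction,
$(a_0,a_1,a_2) = (-2.6,\ 10.5,\ -4.5)$ (positive and saturating in
$d$), and $\varepsilon \sim \mathcal N(0, 1.13)$. The noise SD was
fixed once by `scripts/calibrate_coupling.R`, which scans the planted
population $R^2$ of the full regression pipeline at $n=3000$ and
records the scan in the script; 1.13 plants a population $R^2$ of
about 0.65, matching the headline strength of the disorder-LLPS
relationship the pipeline is designed to detect. The `p_dp` track
scales the latent disorder signal toward the protein's $p_{LLPS}$;
`s_bind` is gamma-distributed (shape 1.3) with a configurable scale
controlling how many residues clear the 2.2/2.25 thresholds.

Domains are Poisson-many uniform intervals (30-200 residues) with
uniform superfamily labels. The interaction network places background
edges independently at probability 0.03 and multiplies that
probability by 8 within a planted module of 20% of the proteome;
confidences are uniform on $[0.15, 1]$ so the standard
0.15/0.4/0.7/0.9 threshold ladder is meaningful.

One master seed drives everything; per-protein sub-streams are derived
arithmetically from it, so enlarging the proteome leaves earlier
proteins' draws byte-identical (tested). `truth_table()` regenerates
the exact planted values for parameter-recovery tests.

**What the generator does not emulate:** real predictor error
profiles (noise is i.i.d. Gaussian, not structured), sequence
evolution or homology, length-composition correlations, degree
heterogeneity and hub structure of real interaction networks, and any
biophysics of condensate formation. Passing tests on synthetic data
therefore demonstrate the *correctness of the computations* and the
*recoverability of planted effects at realistic sizes*, not predictive
validity on real proteomes.

## Problem sizes and numerical choices

The test suite and the acceptance script run the regression on
proteomes of $n = 250$ proteins (the size of the motivating study),
with 20 replicate seeds for the headline relationship and 200
replicates for $\lambda$-recovery at each planted value
$\lambda^* \in \{0, 0.06, 0.5\}$; recovery data are generated as the
inverse Box-Cox transform of $\mathcal N(2,1)$ samples, a setting in
which the profile likelihood identifies $\lambda$ well. Exhaustive
oracles cover all hypergeometric universes up to 12 and all graphs up
to 5 nodes, with seeded random graphs at 6-7 nodes; full enumeration
of the $2^{21}$ seven-node graphs would add nothing but runtime, so a
sample is used there by choice. Calibration used $n = 3000$, where the
sampling noise of $R^2$ is a few thousandths.

Ties and degenerate inputs: PPIDR's strict inequality and the
inclusive thresholds elsewhere are stated per function; the windowed
composition signal receives sub-resolution jitter ($<10^{-9}$) to
break ties before quantile thresholding; empty tracks, empty
universes, constant responses and rank-deficient designs raise typed
errors or flagged results as documented.

## Known limitations

- The CDF boundary default is a placeholder; quadrant counts depend on
  it and on which predictor feeds the CDF.
- The binomial network null ignores degree structure; its enrichment
  p-values are not comparable to degree-corrected database values.
- The consensus denominator is the supplied track count, which matches
  per-residue-coverage semantics only when all tracks are full-length
  (enforced by the I/O validators).
- The generator's category mix is stochastic; exact planted counts per
  class vary around the configured weights by design.
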