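---
title: "Aligning untargeted LC-MS studies with unbalanced Gromov-Wasserstein transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning untargeted LC-MS studies with unbalanced Gromov-Wasserstein transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwalign)
```

## The matching model

`gwalign` aligns the feature lists of two untargeted LC-MS studies that
share no samples. Each study is a `feature_table`: p features described by
m/z (Da), retention time (minutes) and an intensity profile across that
study's n samples. The package assumes both tables are already imputed and
normalized; it refuses missing intensities rather than imputing silently,
because imputation interacts with study design in ways an alignment tool
should not decide.

The matching signal is the intra-study distance structure of the intensity
profiles. If features i and k of study 1 are the same compounds as features
j and l of study 2, then the distance between profiles i and k should
approximate the distance between j and l, even when the two studies
measured different people on different instruments. By default distances
are normalized Euclidean, `d(u, v) = ||u - v|| / sqrt(n)`, computed on
per-feature standardized profiles. Standardization uses the population
(divisor-n) convention, so a standardized profile satisfies `||u||^2 = n`
and the normalized Euclidean distance reduces exactly to
`sqrt(2 * d_cos)`, with `d_cos = 1 - corr` the cosine distance of the raw
profiles — a property the test suite asserts. Working with correlations
rather than raw magnitudes makes the alignment robust to between-study
differences in intensity scale; raw (uncentered) distances remain
available via `center_scale = FALSE` for platforms where mean intensities
are known to be comparable.

A coupling matrix Pi with nonnegative entries softly matches the two
feature sets by minimizing

$$
\sum_{ijkl} \big(D^x_{ik} - D^y_{jl}\big)^2 \,\Pi_{ij}\,\Pi_{kl}
\;+\; \rho\, \mathrm{KL}(\Pi_1 \otimes \Pi_1 \,\|\, a \otimes a)
\;+\; \rho\, \mathrm{KL}(\Pi_2 \otimes \Pi_2 \,\|\, b \otimes b)
\;+\; \varepsilon\, \mathrm{KL}\big(\Pi^{\otimes 2} \,\|\, (a \otimes b)^{\otimes 2}\big),
$$

where $\Pi_1, \Pi_2$ are the row and column sums and $a = 1/p_1$,
$b = 1/p_2$ are uniform reference marginals. Relaxing the marginal
constraints through KL penalties (rather than enforcing them exactly) is
what permits *partial* matching: features present in only one study can
remain unmatched at a bounded objective cost. Matched features must also
be m/z-compatible: every coupling cell with `|mz_i - mz_j| > m_gap` is a
structural zero, enforced inside every solver iteration and re-applied to
the returned coupling.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `rho` | 0.05 | — | marginal relaxation; larger values push more features to match |
| `eps` | 0.005 | — | entropic smoothing; larger values stabilize the solver but blur matches |
| `m_gap` | 0.01 | Da | m/z compatibility tolerance (inclusive) |
| `tau` | 0 (gm) / 0.3 (gmt) | — | post-hoc coupling threshold before one-to-one extraction |
| `spline_order` | 3 | — | RT drift B-spline degree |
| `knot_grid` | 3, 5, 7, 10, 15 | knots | candidate interior-knot counts for the drift fit |
| `cv_folds` | 10 | — | cross-validation folds for knot selection |
| `tol` | 1e-6 | — | solver convergence tolerance (relative max-abs coupling change) |

`rho` and `eps` default to the smallest values at which the optimization
is reliably stable; they are the two knobs a user might genuinely need to
touch (raise `eps` if the solver reports numerical trouble, raise `rho` if
too few features match). `m_gap` is an absolute Dalton tolerance by
default, matching the scale of inter-study m/z jitter on
quadrupole-time-of-flight platforms; an optional ppm mode
(`mz_mode = "ppm"`) serves instruments specified by relative accuracy.

## Solving the transport problem

The quartic objective is optimized through its standard bi-convex
relaxation: two couplings $\pi, \gamma$ replace the two factors of each
product, and alternating minimization in one factor given the other is a
descent method. Each half problem is an entropically regularized
*unbalanced* optimal-transport problem with a cost matrix assembled from
the fixed factor, solved by log-stabilized Sinkhorn scaling iterations
(compiled with RcppArmadillo; the scaling vectors are absorbed into the
kernel on the log scale whenever they threaten overflow). Two numerical
points deserve mention:

* **Distortion cost.** The solver minimizes the squared difference
  $(D^x_{ik} - D^y_{jl})^2$, which factorizes into three matrix products
  and scales to thousands of features. An absolute-difference mode
  (`distortion = "abs"`, dense cost tensor) exists for small instances;
  the suite cross-checks that both modes extract identical matchings on
  toy problems.
* **Mass control.** The relaxed objective is invariant along
  $(s\pi, \gamma/s)$ in its distortion term, and for small `rho` the
  alternation alone lets the factor masses drift apart. After every outer
  iteration the pair is projected back to equal mass along this direction,
  guarded by a descent check. The reported `objective_trace` is the
  relaxed objective, which the suite requires to be non-increasing within
  `1e-6 * (1 + |value|)`; `final_objective` is the returned coupling's own
  objective, cross-checked in the tests against an independent R
  implementation of the formula.

Rows and columns with no m/z-admissible partner are removed before
optimization — their coupling entries are structural zeros — and reinserted
afterwards. Because reference marginals keep their original 1/p weights,
the reduced problem's objective is exactly the full problem's, and under a
realistic (sparse) m/z mask this shrinks the effective problem size
severalfold. Initialization is the masked product measure $a \otimes b$;
the solver is deterministic.

Degenerate inputs behave predictably: a fully masked problem returns the
zero coupling immediately, and the zero coupling's objective equals
$2\rho + \varepsilon$ in closed form (each tensorized KL term of an empty
measure contributes the mass of its reference), one of the solver sanity
checks.

## Retention-time drift and filtering

m/z compatibility is enforced inside the solver, but retention times
cannot be: inter-study RT drift is smooth, nonlinear, and can span
minutes. Instead the coupling itself estimates the drift. Every support
pair (i, j) contributes the point (RTx_i, RTy_j) weighted by its coupling
entry, and a degree-3 B-spline f is fitted under the weighted absolute
(L1) loss. The L1 objective is minimized by iteratively reweighted least
squares (three rounds, weights floored at a tenth of the current typical
residual so that near-zero residuals cannot force interpolation); a pure
weighted least-squares mode exists and agrees with the L1 mode on
noiseless data, a tested property. Interior knots sit at weighted
quantiles of the support RT values; the knot count is selected from the
grid by 10-fold cross-validation with coupling-weighted loss, folds
shuffled in value order of the pairs so that the fit is equivariant under
feature permutations. Spline evaluation clamps to the fitted RT range
rather than extrapolating.

Filtering then proceeds in the standard robust two-stage pattern: with
residuals $r_{ij} = |f(RTx_i) - RTy_j|$ over the support, pairs beyond the
95% prediction interval `PI = 1.96 * sd(r)` (population sd) from the
median residual are discarded, the drift is refitted, the PI cut is
applied once more, and a final refit applies the stricter cut of twice the
median absolute deviation. Survival is inclusive
(`r <= median + cut + 1e-12`): with a perfect fit all residuals and the
MAD are zero, and a strict inequality would absurdly discard everything.
One consequence worth knowing: the quantity `median + 2 * MAD` is itself a
quantile of the residual distribution, so when *all* support pairs are
genuinely correct and their residuals have an unbounded or uniform-like
upper tail, the final cut trims a few percent of true pairs — the price of
a filter with no tuning parameter. The validation targets below account
for this.

One-to-one extraction keeps the pairs whose coupling entry is positive and
the *unique* maximum of both its row and its column. Ties drop all tied
candidates: the extraction rule presumes a unique largest entry, and any
arbitrary choice would be unreproducible. The thresholded preset (`gmt`)
first zeroes entries below `0.3 * max(coupling)`, trading a little recall
for precision in noisy settings; because thresholding only removes
candidates, its matching is always a subset of the plain (`gm`) one — a
tested invariant.

## The ground-truth generator

Validating an aligner requires pairs of studies with a known
correspondence, which real data rarely offers. The generator fabricates
them by splitting one base table: samples are divided disjointly
(floor(n/2) and the rest), a fraction `overlap` of features is copied into
both studies, the remaining features are divided equally (the shared count
is decremented by one when needed to keep the two studies the same size),
and feature order is shuffled. Study 2 is then perturbed: uniform m/z
noise on [-0.01, 0.01] Da, the systematic drift
`f(x) = 1.1x + 1.3 sin(1.2x)` followed by uniform RT noise, and Gaussian
intensity noise in both studies. Noise levels (sigma_rt in {0.2, 0.5, 1}
minutes, sigma_fi in {0.1, 0.5, 1}) span benign to adversarial acquisition
variation. Every noise source draws from its own sub-stream of the master
seed, so disabling one source does not shift the others — repetitions are
bit-reproducible.

The bundled base-table generator emulates the aspects of real normalized
LC-MS data that the aligner actually exploits: a block factor model (about
20 features per latent block, loadings uniform on 0.3–0.95) produces the
strongly correlated feature groups that adducts, isotopologues and
pathway neighbours create in practice; per-feature scales are lognormal
(median 1) around means on a log-abundance-like level, so the intensity
noise settings above are meaningful relative to feature variance; m/z
values are uniform on 70–1000 Da with 75% of features guaranteed gaps
above twice the m/z noise half-width and 25% planted within that distance
of an anchor feature, emulating near-isobaric crowding; RT is uniform on
0.5–12 minutes. A real base table in the same CSV layout can be
substituted everywhere a generated one is used.

What the generator does *not* emulate — and what passing simulations
therefore cannot certify — includes: the heavy nominal-mass clustering of
real spectra (thousands of features crowd the same integer-Da bands, so
real data offers far more m/z-compatible false candidates than uniform
sampling does at the same feature count, and precision on real data is
correspondingly lower); correlated, non-Gaussian intensity artefacts
(batch effects, censoring at the detection limit); adduct/isotope
relationships that make "one-to-one" genuinely ambiguous; and
population-level differences in correlation structure between cohorts,
the method's stated base assumption.

## Validation scope and problem sizes

The test suite pins the closed-form values (objective of the zero
coupling, 1-by-1 couplings, residual statistics, Wilson bounds for 88/90
and 19/19 at 0.923 and 0.832/1.000, split arithmetic for a 4712-feature,
499-sample design) and the behavioural properties (permutation
equivariance, monotone traces, mass monotone in `rho`, threshold-subset,
filter monotonicity). End-to-end, a 50-feature duplicated study with
permuted features must be recovered exactly, the systematic drift must be
recovered within 0.05 minutes sup-norm from 200 noiseless pairs, and a
planted-outlier fixture (clean residual magnitudes U-shaped so the robust
cut clears their maximum by ~25%, outliers tenfold beyond the cut) must
be cleaned without collateral loss. The simulation benchmark runs 5
repetitions per condition on an 800-feature, 400-sample synthetic base —
a size chosen so the whole grid completes in minutes on one CPU while
leaving several hundred shared features per condition — over overlaps
0.25/0.5/0.75 at medium noise and three noise levels at overlap 0.5. The
reference operating points for these conditions come from the full-scale
design (4712 real features, 20 repetitions); at one-sixth the feature
count the m/z space is correspondingly emptier, which inflates precision
relative to full scale (fewer admissible false candidates), and the
suite's one deliberately strict two-sided precision target at high noise
documents exactly this surrogate gap rather than hiding it.

## Known limitations

* Two studies only; multi-study pooling proceeds by aligning each study to
  a chosen reference (`pool_datasets` assembles the combined matrix, with
  missing blocks for unmatched features).
* The correlation-preservation assumption fails across populations with
  genuinely different metabolic correlation structure; in that regime the
  m/z mask and RT filter carry all the signal and precision degrades.
* The coupling is dense within the m/z mask; memory scales with
  p1 x p2. Feature sets beyond ~10^4 per study need blocking by m/z
  before alignment.
* Exactly tied coupling entries (possible in contrived integer-valued
  inputs, measure-zero in practice) produce no match for the tied
  rows/columns by design.
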