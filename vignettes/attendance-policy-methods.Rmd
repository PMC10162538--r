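---
title: "Methods: gender-aware planning of extension training events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gender-aware planning of extension training events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agritrain)
```

## The problem

Village-level agricultural extension events (video-based training sessions)
draw very different crowds depending on who runs them and when and where they
are held. Women attend far less often than men overall, but the factors that
raise female attendance — female trainers, sessions at farmers' houses, morning
slots — are largely the opposite of those that maximize total turnout —
male-led, marketplace, late-afternoon sessions. A planner who wants both high
turnout and better female participation therefore faces a genuine trade-off,
and `agritrain` implements a transparent, fully reproducible pipeline for
quantifying it:

1. **Ingest and audit** event records (one row per event: trainer gender, time
   bin, day of week, month, venue type, administrative division, male and
   female attendee counts), excluding incomplete rows whole and testing whether
   exclusions are attendance-biased.
2. **Select model inputs** per gender by grouped penalized regression with
   cross-validated regularization.
3. **Fit gender-specific quasi-Poisson models** on the selected inputs.
4. **Bootstrap** the fit-and-predict procedure to attach percentile confidence
   intervals to every prediction.
5. **Enumerate the mesh** of feasible event configurations, rank it by
   predicted total and female attendance, and **simulate mixing policies**
   that replace the lower X% of the top-total list with the top X% of the
   top-female list.

## Count models with overdispersion

Both attendance outcomes are event-level counts whose variance far exceeds
their mean (in the motivating data total attendance had mean 122 and SD above
100). We model each outcome with a log-link quasi-Poisson GLM: the conditional
mean is $\mu_i = \exp(x_i^\top \beta)$ and the variance is $\phi\,\mu_i$ with
a dispersion parameter $\phi \ge 1$ estimated from the Pearson statistic,

$$\hat\phi = \frac{1}{n - p} \sum_i \frac{(y_i - \hat\mu_i)^2}{\hat\mu_i}.$$

Point estimates are the ordinary Poisson maximum-likelihood estimates via
IRLS (`stats::glm.fit`); the dispersion rescales the coefficient covariance,
$\widehat{\mathrm{Cov}}(\hat\beta) = \hat\phi\,(X^\top W X)^{-1}$, but never
moves the point estimates — a quasi-likelihood property the test suite checks
directly. Fitted totals conserve observed totals whenever the design has an
intercept (the Poisson score equation), another tested identity.

We deliberately do **not** fit a separate "total attendance" model: the
predicted total at a configuration is the sum of the male- and female-model
predictions. The two-model decomposition is what makes the gender trade-off
expressible at all.

## Grouped input selection

Every candidate input is categorical, so variable selection must operate on
whole factors, not single dummy columns: a factor with $L$ levels contributes
$L-1$ treatment-coded columns forming one *group*, and a first-order
interaction of $L_1 \times L_2$ levels contributes $(L_1-1)(L_2-1)$ columns in
one group. The default candidate set is the six main factors plus the
division-by-time, division-by-venue and division-by-trainer-gender
interactions — nine penalized groups (the intercept is never penalized).

Selection minimizes the penalized least-squares objective

$$\frac{1}{2n}\lVert y - X\beta\rVert^2 + \sum_g p_\lambda\!\left(\sqrt{K_g}\,\lVert\beta_g\rVert_2\right)$$

where $p_\lambda$ is the group Lasso, group MCP (default concavity
$\gamma = 3$) or group SCAD ($\gamma = 4$) penalty. The solver is block
coordinate descent with warm starts along a decreasing grid of 100 log-spaced
$\lambda$ values from $\lambda_{\max}$ (the smallest value zeroing every
group) down to $0.001\,\lambda_{\max}$. Columns are orthonormalized within
each group before thresholding and back-transformed afterwards — the standard
device that makes the groupwise update an exact soft/firm/SCAD threshold on
the norm of the partial residual correlation. Rank-deficient groups (a level
absent from the data) simply contribute fewer orthonormal directions.

Three algorithmic checks anchor the implementation: at $\lambda = 0$ the
solution equals ordinary least squares to $10^{-8}$; on a centered
orthonormalized single-group design the group-Lasso solution equals the
closed-form groupwise soft threshold to $10^{-6}$; and as
$\gamma \to \infty$ MCP and SCAD paths converge to the group Lasso.

$\lambda$ is chosen by 10-fold cross-validation (the minimizer of mean
held-out squared error; no one-standard-error rule), the data having first
been split 80/20 into learning and testing sets (learning size
$\mathrm{round}(0.8\,n)$, half-up). Each of the three penalties is fitted on
the learning set and scored on the testing set by root-mean-square error on
the count scale — exposed as `evaluate_smse()`, with a variance-normalized
variant (`type = "nmse"`) also available since "standardized" is ambiguous;
the RMSE form matches the magnitudes such accuracy tables are usually
reported on. The most accurate method wins; ties break toward fewer selected
groups, then the fixed order MCP, SCAD, Lasso. Weak heredity is enforced
afterwards: a selected interaction pulls its parent main effects into the
final term set.

Selection runs **once**, on the original data. The bootstrap (below) refits
only the GLMs with the term sets held fixed: re-running 10-fold
cross-validated selection inside every bootstrap replicate would multiply the
cost a thousandfold while the confidence intervals are anyway attached to one
fixed model structure. This is a documented design choice, not a claim that
selection uncertainty is negligible.

Selection by Gaussian least squares followed by quasi-Poisson inference is a
deliberate separation: the penalized stage is a screening device on the raw
count scale, the GLM stage supplies the inferential model. A Poisson-loss
penalized path would be a natural extension but is out of scope.

One practical wrinkle: a selected interaction can be inestimable by the
*unpenalized* GLM when some level combination never occurs (the penalized
solver tolerates this via rank reduction; a plain GLM cannot).
`estimable_terms()` therefore drops, interaction by interaction, whichever
term repairs the most rank deficiency until the design has full column rank —
main effects are never dropped. The pipeline applies this between selection
and fitting and logs what it removed.

## Bootstrap uncertainty

Nonparametric bootstrap: $B = 1{,}000$ replicates (package default, matching
the study design) of $n$ events resampled with replacement, each refitted for
both genders with fixed terms. Replicates whose fit fails — typically a rare
factor level absent from the resample — are redrawn, and more than 5%
failures aborts with a diagnostic rather than silently biasing the ensemble.
Every mesh-point and scenario metric is summarized by the replicate mean and
the 2.5/97.5 empirical percentiles (linear-interpolation quantile rule,
`type = 7`). We use plain percentile intervals, not BCa or studentized ones.
The proportion of female attendance is computed per replicate as the ratio of
predictions and then summarized, never as a ratio of summaries.

## The mesh and mixing policies

The mesh is the Cartesian product of the level sets of every factor retained
by either gender model; factors selected by neither model are excluded. With
the default term sets the axes are trainer gender (2), time bin (3), venue
(8) and division (4): 192 configurations. **Month is not an axis**: when the
female model retains month (it acts as an effect modifier, female attendance
rising over the study window), predictions are evaluated at a fixed month —
by default the final one, where female attendance peaked — because a month is
not a plannable attribute of a future event the way a venue is. The fixed
level is exposed as `month_level=` for sensitivity analysis.

Mesh points are ranked twice — by bootstrap-mean predicted total attendance
and by predicted female attendance — with fully deterministic tie-breaks
(the other criterion, then lexicographic configuration order). The X% mixing
policy with list size $N$ keeps the top $N - k$ of the total list and adds
the top $k$ of the female list, $k = \mathrm{round}(XN/100)$ (half-up, so
$N = 10$, $X = 50$ gives $k = 5$). Configurations appearing in both parts
are deduplicated by backfilling from the female list's next ranks, preserving
both the list size and the female-emphasis intent of X. $X = 0$ and $X = 100$
reproduce the pure top-total and top-female lists element for element — an
exact, tested invariant, as are the monotonicity of mean female attendance in
X for disjoint top lists and the dominance of the pure top-total list on mean
total attendance.

`sweep_policies()` evaluates the default menu — $N \in \{100, 50, 10\}$,
$X = 0, 10, \dots, 100$ — yielding 33 scenarios, each with bootstrap means
and 95% intervals for mean total attendance, mean female attendance and the
attendance-weighted female share $\sum f / \sum t$ (the unweighted mean of
per-event shares is also emitted). `benchmark_compare()` flags whether a
scenario's *lower* confidence limits strictly exceed the observed per-event
averages under intuition-based scheduling (122 total, 23 female in the
motivating study): the planner's bar is not beating the average on average
but beating it with 95% confidence. `balanced_selection()` applies the same
mixing within each division under a quota (largest-remainder rounding),
addressing the concern that unconstrained optimization concentrates the
selected events in whichever division predicts best.

## The synthetic generator

The raw study data are not deposited, so the package ships a generator that
emulates their statistical structure with known ground truth:

* **Covariates** are sampled independently per factor from the study's
  printed marginal frequencies (90.3% male trainers; division shares
  49.4/27.6/18.9/4.0; and so on). The printed venue shares sum to 93.6%, an
  inconsistency in the source table, so the venue vector is renormalized; all
  other marginals are used as printed. A `joint_table` hook accepts a full
  joint distribution when one is known — independence is a simplification,
  not a claim about real event logistics.
* **Counts** are negative binomial in the NB1 parameterization
  ($\mathrm{Var} = \phi\,\mu$), matching the variance law the quasi-Poisson
  analysis assumes; $\phi = 1$ degenerates to exact Poisson sampling. Default
  dispersions (40 male, 12 female) are documented constants giving realistic
  overdispersion at these count magnitudes, not estimates of the real data.
* **Ground-truth coefficients** qualitatively echo the study's descriptive
  patterns — marketplaces, after-15:30 slots and male trainers raise male
  attendance; farmers' houses, female trainers and later months raise female
  attendance; day of week carries no signal (so selection should drop it).
  They are constants chosen once and documented in
  `default_true_model()`, not reverse-engineered estimates.
* **Excess female zeros**: each female count is replaced by a structural zero
  with probability 0.238, the study's observed share of events with no female
  participation. Whether real female counts are zero-inflated beyond
  quasi-Poisson cannot be resolved from published summaries, so the rate is a
  switch (`female_zero_excess = 0` turns it off). Note this makes the female
  GLM deliberately misspecified under the default generator — as it plausibly
  is for the real data — which is exactly the regime in which bootstrap
  rather than model-based intervals earn their keep.

What passing tests on this generator do and do not show: they validate the
estimation, selection, bootstrap and policy machinery under the stated
variance law and marginals; they cannot validate the independence of
covariates, the absence of spatial/temporal correlation between events, or
any claim about the real study's coefficient values.

## Numerical and design choices

* Sample SDs use the $n-1$ denominator; the SD of a single observation is
  reported as 0 and flagged rather than left undefined.
* The exclusion audit uses Welch's unequal-variance two-sample $t$-test per
  outcome; any missing field excludes the whole row.
* Block coordinate descent converges when the largest coefficient change in a
  sweep is below `tol` (default $10^{-8}$); non-convergence at a $\lambda$ is
  flagged and the path continues.
* IRLS: relative deviance tolerance $10^{-8}$, at most 100 iterations;
  rank-deficient GLM designs abort with the aliased columns named.
* All randomness flows from explicit integer seeds; one master seed fans out
  to stage-specific seeds by a fixed rule (`stage seed = (seed mod 2e6) * 1000
  + stage offset`), so any stage can be rerun in isolation and a full
  pipeline rerun is bitwise identical.
* Simulation-based checks in the test suite use deliberately reduced problem
  sizes (e.g. $B = 200$ bootstrap replicates, 50–200 simulation replicates at
  $n$ = 300–1,067) — chosen as the smallest scales at which the asymptotic
  properties under test are expected to hold cleanly.

## Known limitations

* The CV-minimum rule for $\lambda$ admits a spurious group in a sizeable
  minority of pure-noise datasets (roughly a third in our simulations); a
  one-SE rule would be more conservative but is not what this pipeline
  specifies. Downstream, a falsely selected factor inflates the mesh but
  barely moves predictions, since its fitted effects are near zero.
* Bootstrap means of mesh-point predictions sit slightly above point
  estimates at rare-cell configurations (log-scale resampling skew, about 2%
  at the worst of the 192 default mesh points at $B = 1{,}000$).
* Predictions at configurations never observed (the mesh deliberately
  includes them) are extrapolations under the main-effects-plus-selected-
  interactions structure; the bootstrap widens their intervals but cannot
  detect structural error there.
* Events are treated as independent; venue re-use, outreach campaigns and
  seasonal cycles are outside the model.

## A worked example

```{r example, eval = FALSE}
library(agritrain)

cfg <- pipeline_config(
  generator = generator_config(n_events = 1067, seed = 1),
  B = 1000, seed = 1, out_dir = "run"
)
report <- run_pipeline(cfg, verbose = TRUE)

# 192 configurations when selection keeps the reference axes; a spuriously
# selected factor (see Known limitations) multiplies the grid accordingly
report$mesh_size
report$tradeoff[report$tradeoff$N == 50 & report$tradeoff$X == 50, ]
```

The same end-to-end run is available from a shell via the thin wrapper in
`inst/cli/agritrain` (subcommands `generate`, `summarize`, `select`, `fit`,
`bootstrap`, `simulate`, `run`).
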