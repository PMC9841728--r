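---
title: "Aligning grouped survey responses across a questionnaire revision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning grouped survey responses across a questionnaire revision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamalign)
```

## The problem

An annual survey asks for a quantity such as weekly exercise duration with
a closed-ended question: each option corresponds to a numeric interval, and
the top option is open-ended ("7 hours or more"). The data are therefore
*grouped*: for each respondent only the interval is known, never the exact
value, and the tail of the distribution is hidden by the top-coded option.

Mid-series, the questionnaire is revised — the example built into this
package replaces a four-option scale (`ltpa_scale_1997()`, intervals
$[0,1), [1,2), [2,3), [3,\infty)$) with a five-option scale
(`ltpa_scale_1998()`). The raw post-revision options leave gaps between
interval boundaries (e.g. "1–2" followed by "3–4"); `smooth_gaps()` splits
each gap at its midpoint so the scale partitions $[0,\infty)$, giving
boundaries $\{1, 2.5, 4.5, 6.5\}$. After the revision, annual answer
distributions live on a different discretisation than before, and naive
comparisons of summary statistics across the break confound real change
with the mechanical effect of the new options.

The repair uses a *cohort*: individuals who answered in both the last
pre-revision year and the first post-revision year. Their paired responses
give a column-stochastic transition matrix $T$ ($d_2 \times d_1$,
`estimate_transition_matrix()`), whose $(i,j)$ entry is the probability of
answering target-scale option $i$ given source-scale option $j$ the year
before. $T$ mixes two effects, and the Version Alignment Method (VAM)
separates them.

## The model

VAM posits $T \approx B A$, where

* $A$ ($d_2 \times d_1$) is the *revision-related* factor: the option
  changes a respondent would make purely because the options changed, with
  no change in behaviour; and
* $B$ ($d_2 \times d_2$) is the *time-related* factor: genuine behavioural
  change between the two observation times, expressed on the target scale.

Both factors are constrained column-stochastic and non-negative. The
factorisation is not identifiable from $T$ alone, so each factor is
anchored to an external reference:

* $A$ is anchored to the **ideal revision matrix** $G$
  (`ideal_revision_matrix()`): under a latent distribution $F_\theta$
  fitted to the cohort's pre-revision grouped counts,
  $G_{ij} = \Pr(X \in I^{(2)}_i \mid X \in I^{(1)}_j)$ — the transition
  probabilities of a respondent who re-expresses the *same* latent value on
  the new options. If the two scales shared a boundary structure making
  every source interval a union of target intervals, $G$ would be the exact
  revision effect; in general it is the model-based reference.
* $B$ is anchored to a **reference time matrix** $B_{\mathrm{ref}}$, e.g.
  the cohort transition matrix of the first fully post-revision year pair,
  when both observations used the same options and the transition is purely
  temporal.

The estimate minimises a weighted sum of slack variables ("variables of
similarity"):

$$\min_{A, B, \gamma, \varepsilon, \beta, \alpha}\;
  \theta_1 \gamma + \theta_2 \varepsilon + \theta_3 \beta + \theta_4 \alpha$$

subject to column-stochasticity of $A$ and $B$ and

$$\|BA - T\|_\infty \le \gamma,\qquad
  \|BAu - v'\|_\infty \le \varepsilon,\qquad
  \|B - B_{\mathrm{ref}}\|_\infty \le \beta,\qquad
  \|A - G\|_\infty \le \alpha,$$

where $u$ and $v'$ are the cohort's observed distributions at the two
times. The "parameters of proportion" are ordered
$\theta_1 = \theta_2 > \theta_3 > \theta_4 > 0$ (defaults
$10^4, 10^4, 10^2, 1$ in `vam_control()`): reproducing the observed
transition data is paramount; staying near the anchors is secondary, with
the time anchor weighted above the revision anchor. Once $\hat A$ is
estimated, any pre-revision probability vector $p$ is aligned to the
target scale as $\hat A p$ (`align()`), and its mean re-estimated there by
the midpoint method or grouped MLE.

The assumption doing the real work is that the cohort and the population
react to the revision identically, so a cohort-estimated $\hat A$ may be
applied to the population vector.

## Grouped estimation

Two mean estimators for grouped data appear throughout:

* **Midpoint method** (`midpoint_mean()`): each interval is represented by
  its midpoint, the top-coded interval by its *lower bound*, and the mean
  is the frequency-weighted average. It is simple and deterministic but
  biased — the top-bound rule truncates the hidden tail.
* **Grouped MLE** (`fit_grouped_mle()`): a latent parametric family
  (gamma here) induces multinomial cell probabilities
  $F_\theta(b_i) - F_\theta(a_i)$, and $\theta$ maximises
  $\sum_i o_i \log\left(F_\theta(b_i) - F_\theta(a_i)\right)$. The
  likelihood is invariant to rescaling the counts, so probability vectors
  are accepted interchangeably. The fitted mean (shape × scale) uses the
  whole parametric tail and is the preferred estimator.

Numerically the likelihood is maximised over log-parameters
(positivity for free, better conditioning), from a method-of-moments start
on interval midpoints, with BFGS followed by a Nelder–Mead polish; the
delta method on the observed information gives a standard error for the
mean. A `fixed` argument pins parameters (e.g. a known shape), reducing to
one-dimensional search.

## The solver

The product constraint $\|BA - T\|_\infty \le \gamma$ is bilinear, so the
problem is not jointly convex. `vam_decompose()` alternates two linear
programs: with $A$ fixed, minimising over $(B, \gamma, \varepsilon,
\beta)$ is an LP; with $B$ fixed, minimising over $(A, \gamma,
\varepsilon, \alpha)$ is an LP. Each subproblem contains the previous
iterate as a feasible point, so the realised objective is non-increasing
across alternations (up to solver arithmetic); iteration starts from
$A^{(0)} = G$ and stops on relative objective change below `tol`.

Implementation notes:

* The LPs are solved with `boot::simplex()`. All absolute-value
  constraints are written as pairs of $\le$ rows ($r - s \le 0$,
  $-r - s \le 0$) plus equality rows for the column sums; variables are
  non-negative natively. This formulation deliberately avoids $\ge$-only
  constraint systems, which that solver mishandles.
* If the realised $\hat\gamma$ or $\hat\varepsilon$ exceeds the slack
  target ($10^{-4}$ by default), $\theta_1, \theta_2$ are escalated
  tenfold and the alternation restarted, up to five times; a persistent
  miss is flagged (`target_met = FALSE`, with a warning), never silently
  accepted.
* Inputs printed to three significant figures do not satisfy unit column
  sums exactly; the validation tolerance `input_tol` exists for such
  fixtures, and internal arithmetic is always full double precision.
* When $T$ is exactly factorable as $B_{\mathrm{ref}} G$, the solver
  recovers that factorisation to near machine precision — and this also
  marks the identifiability boundary: with all slacks at zero the anchors
  fully determine $\hat A = G$, so informative deviation of $\hat A$ from
  $G$ comes precisely from the data's refusal to factor through the
  anchors.

## The simulator and its realism

`sim_config()` / `build_scenario()` regenerate the study conditions so
every estimate can be checked against ground truth:

* Latent answers are Gamma(shape 1, scale 3) — mean 3 hours/week, a
  realistic right-skewed duration distribution; 57000 population samples
  with a 20000-strong cohort drawn uniformly from them.
* Both questionnaire versions bin the *same* latent draws
  (`assign_responses()`, half-open intervals, boundaries to the upper
  interval), so the revision effect is mechanically true by construction.
* Time-related matrices are generated from a reference set via
  `generate_time_matrix()`: each diagonal entry is drawn uniformly within
  that position's range across the references, and off-diagonals are a
  randomly weighted average of the references' off-diagonals, rescaled so
  columns sum to one. The default reference set is the published
  post-revision cohort matrix plus nine Dirichlet perturbations of it with
  concentration 1000 — calibrated so the pairwise $L_\infty$ variability
  within the set (mean ≈ 0.037) matches the variability observed among
  consecutive post-revision cohort matrices (0.02–0.06). The average
  pairwise $L_\infty$ among the generated matrices is reported as
  `beta_reference`, an external yardstick for the realised $\beta$ slack.
* Cohort members are evolved through the time matrix individually
  (preserving pairing, so $T$ can be re-estimated from pairs) or in
  expectation (`evolution = "expected-counts"`).

## Judging estimation error

How large an alignment error is consistent with pure sampling noise?
`bootstrap_distance_ci()` answers by construction: generate two groups of
1000 probability vectors, each the relative frequencies of $n$ multinomial
draws from the same fitted distribution, compute the $10^6$ cross-group
$L_\infty$ (or KL) distances, and report the central 95% interval. An
aligned-vs-truth distance inside the interval is indistinguishable from
the distance between two honest samples of the same law. For the KL
metric, pairs with a zero reference cell against positive mass are
undefined; they are excluded and counted, never averaged over.
`trend_regression()` offers an independent sanity check: extrapolating the
post-revision trend back to the revision year should land near the aligned
estimate.

## Limitations

* The cohort-equals-population reaction assumption is untestable from the
  data at hand; if the cohort differs systematically from the population
  in how the new options read, $\hat A$ transfers imperfectly.
* $G$ inherits the latent family: a badly misspecified family biases both
  the anchor and the grouped-MLE means. The gamma family suits
  non-negative right-skewed quantities; other families can be added to the
  internal registry.
* The decomposition is anchor-identified, not data-identified; with weak
  anchors (a poorly chosen $B_{\mathrm{ref}}$) the split between time and
  revision effects shifts accordingly, even while $BA$ reproduces $T$.
* The midpoint method is kept for comparability, but its top-coding rule
  is a known downward bias; treat it as a descriptive statistic.
* Alternating minimisation guarantees monotone objective descent, not a
  global optimum of the bilinear program; starting from $A^{(0)} = G$ is a
  deliberate, anchor-consistent initialisation.
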