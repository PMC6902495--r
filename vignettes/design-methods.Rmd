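---
title: "Group-sequential designs with early-endpoint augmented interim analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-sequential designs with early-endpoint augmented interim analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Trials of surgical and other procedural interventions usually follow
participants at several occasions — here 3, 6 and 12 months — with the
definitive (primary) outcome at the last visit. At an interim analysis most
recruited participants have early measurements but not yet the long-term
one, so a monitoring rule that looks only at long-term completers may have
too little information to stop a failing trial before recruitment ends.
`augseq` implements a two-arm group-sequential design in which the early
measurements *augment* the long-term comparison at interim analyses, plus
the machinery around it: information-based look scheduling, error-spending
stopping boundaries, interim decision rules with an overrunning final
analysis, and a trial simulator for operating characteristics.

## Outcome model and the augmented estimator

Outcomes $(X_{ij1},\dots,X_{ijK})$ for participant $i$ in arm $j$ (0 =
control, 1 = active) are multivariate normal with arm-specific means, SDs
$\sigma_k$ and correlations $\rho_{kk'}$; endpoint $K$ is the long-term one.
With $N_k$ participants per arm providing endpoint $k$ ($N_1 \ge \dots \ge
N_K$), the treatment-effect estimate is

$$B \;=\; \bar D_K \;+\; \sum_{k<K} \rho_{kK}\frac{\sigma_K}{\sigma_k}\,
\frac{\tilde N_{k\setminus K}}{\tilde N_K}\,
\big(\bar D_{k\setminus K}-\bar D_k\big),$$

where $\bar D_K$ is the difference of arm means among long-term completers,
$\bar D_k$ the difference of arm means of endpoint $k$ over everyone with it
observed, and $\bar D_{k\setminus K}$ the same restricted to participants
whose long-term outcome is still pending. Because each correction is
mean-centred its expectation is zero whatever the *early* treatment
effects, so $B$ is unbiased for the long-term difference; the corrections
only transfer precision. For equal arms this is algebraically identical to
the printed two-early-endpoint form (sums of paired differences), and its
variance has the closed form

$$\mathrm{var}(B)=\frac{2\sigma_K^2}{N_K}\Big[1-\rho_{1K}^2
\tfrac{N_1-N_K}{N_1}-\rho_{2K}^2\tfrac{N_2-N_K}{N_2}
+2\rho_{1K}\rho_{2K}\rho_{12}\big(1-\tfrac{N_K}{N_2}\big)\Big]$$

for $K=3$. For general $K$ the package evaluates the exact covariance
algebra of the per-participant weight decomposition over the layered
(monotone) observation pattern; at $K=3$ this reproduces the closed form to
machine precision, and at other $K$ it is validated against a Monte-Carlo
oracle in the test suite. The variance never exceeds the unaugmented
$2\sigma_K^2/N_K$ for any valid correlation matrix: augmentation cannot
lose information.

**Unequal arms.** The printed formulas assume equal per-arm counts. With
unequal arms the package replaces paired differences by differences of arm
means and each $N_k$ by the harmonic-mean effective per-arm size
$\tilde N_k = 2 n_{k0} n_{k1}/(n_{k0}+n_{k1})$. This is exact for equal
arms and Monte-Carlo-validated for modest imbalance; it is an
approximation, not the exact unequal-arm variance.

**Non-monotone missingness.** A participant may have a later early endpoint
observed but an earlier one missing. Each correction term uses exactly the
participants with that endpoint observed, partitioned by whether their
long-term outcome is available; the variance uses the smallest monotone
envelope of the observed counts, since the nested-set variance algebra
needs $N_1 \ge \dots \ge N_K$.

## Nuisance estimation

`estimate_nuisance()` centres each endpoint by its arm mean, pools the
residuals across arms (SD denominator $n-2$: two arm means estimated), and
computes pairwise-complete Pearson correlations of those residuals.
Estimates are clamped to $[-0.99, 0.99]$ and the matrix repaired to the
nearest positive-semi-definite correlation matrix by eigenvalue clipping at
$10^{-6}$, so the variance formula stays positive and finite with noisy
estimates. A correlation with fewer than 3 complete pairs (or an SD with
fewer than 3 observations) falls back to the design-assumed value with a
warning. If, despite clamping, the variance bracket is non-positive, it is
floored at $10^{-8}\times 2\hat\sigma_K^2/N_K$ with a warning — reachable
only through clamping pathologies.

## Information, look scheduling, and two deliberate asymmetries

Information is inverse variance, $I = 1/\mathrm{var}(B)$; at the final
analysis $I_{\mathrm{final}} = N/(2\sigma_K^2)$. Looks are planned at
expected information levels computed from assumed nuisance values at
planned counts, and a look is taken the first time the *observed*
information reaches its planned level. The observed information is
re-evaluated at every outcome arrival; trigger crossings are checked when
new long-term outcomes arrive (`trigger_cadence = "final"`), the moments at
which information moves materially, with `"any"` available as an option.

Two deliberate asymmetries separate *scheduling* from *analysis*. They
exist because the trigger rule is a first-passage rule on an estimated
quantity: any noise or bias in the monitored information selects moments
where the variance is understated, which distorts stopping probabilities
even though the test statistic itself is perfectly calibrated at any fixed
look (both facts are verified by simulation in the test suite).

1. **Reciprocal-variance bias.** $E[1/\hat\sigma^2] =
   \mathrm{df}/((\mathrm{df}-2)\sigma^2)$, so plug-in information is biased
   upward and looks would trigger systematically before their planned
   counts. The monitored information carries the correction factor
   $(\mathrm{df}-2)/\mathrm{df}$.
2. **Scheduling SD pooling.** When the design assumes a common SD across
   the repeated measurements (as the motivating trial does), the efficient
   scheduling estimate pools arm-centred residuals of *all* endpoints —
   several times the degrees of freedom of the final-endpoint-only SD.
   `scheduling_sd = "auto"` enables pooling exactly when the assumed SDs
   are equal. The analysis statistic $S_w = B/\widehat{\mathrm{sd}}(B)$
   always uses the per-endpoint estimates.

Looks are also only contemplated once both arms have at least
`min_final_per_arm` (default 10) long-term outcomes: below that the
variance estimate has so few degrees of freedom that spurious information
crossings would schedule meaningless analyses. This mirrors the design's
stopping-window logic — no interim look before meaningful long-term data
exist — and the default is consistent with a first look at 10 completers
per arm in a small trial.

## Error-spending boundaries

The design spends one-sided type I error $\alpha$ (default 0.025) across
$W$ analyses through nondecreasing cumulative vectors: $\alpha^*_U(w)$ for
stopping-and-rejecting (efficacy), ending at $\alpha$, and $\alpha^*_L(w)$
for stopping-without-rejecting (futility), ending at $1-\alpha$. Sequential
z-statistics follow the canonical joint distribution
($\mathrm{Cov}(S_v,S_w)=\sqrt{I_v/I_w}$, drift $E[S_w]=\theta\sqrt{I_w}$
for a raw treatment difference $\theta$). Boundaries are found by the
standard stagewise recursion: the sub-density of the non-stopped score
statistic is propagated on a Simpson grid (501 nodes per stage spanning
±8 SD; doubling the grid moves no boundary by more than $10^{-4}$), and
each boundary solves its spending increment by root bracketing. Zero
increments give infinite boundaries; at the final analysis the two
boundaries coincide, with a diagnostic if the implied final futility
spending misses $1-\alpha$ by more than $10^{-4}$.

Futility boundaries are **binding** by default — error control relies on
stopping whenever they are crossed. `binding = FALSE` computes efficacy
boundaries ignoring futility stopping (error control survives overriding a
futility stop) and then spends the futility probabilities given those
efficacy boundaries. With the first analyses carrying (almost) no efficacy
spending the two modes differ negligibly; both reproduce the published
worked-example boundary 3.09 to 2 dp.

`crossing_probabilities()` is the verification twin: the same recursion run
with fixed boundaries and arbitrary drift. At $\theta=0$ it returns the
spending increments to $<10^{-6}$; its probabilities always sum to one.

## Decisions, ties and the overrunning analysis

At look $w$: stop for futility iff $S_w < l_w$; stop for efficacy iff
$S_w \ge u_w$; otherwise continue. The strict/inclusive split matches the
futility rule's "less than the lower boundary" phrasing and makes the
partition exhaustive. Boundaries are *pre-defined*: they are not recomputed
at the (slightly overshot) observed information. After an early stop,
follow-up continues and the definitive estimate uses all recruited
participants; with complete follow-up the corrections vanish and $B$ is
the plain difference of final means, with the two-sided normal p-value
$2\Phi(-|B|/\mathrm{sd}(B))$. A t reference would differ in the third
decimal at these sample sizes; the normal reference matches the design's
z-scale machinery.

## The simulator and what it emulates

`run_simulated_trial()` emulates the trial as it would unfold:

* **Recruitment** — monthly Poisson counts with mean rate × open centres,
  uniform entry times within month; default ramp 1, 2, 3, 6, 9, 12 then 15
  centres from month 7 of a 24-month window (303 centre-months) at 0.56
  participants/centre/month, the motivating trial's plan. Recruitment stops
  at the cap (170 = 2 × 85 by default); if the horizon ends short of the
  cap, recruitment continues at the plateau so the final analysis always
  has its planned N — roughly half of realisations need a few extra weeks
  under the default rate.
* **Allocation** — permuted blocks of 2, keeping arms balanced within one
  participant at every moment, matching the equal-arm formulas.
* **Outcomes** — one multivariate-normal draw per participant; endpoint
  $k$ becomes observable exactly `lags[k]` months after entry (follow-up
  mirrors recruitment). The default scenario puts the treatment difference
  on the final endpoint only; per-endpoint effects are configurable and,
  by the mean-centring argument, operating characteristics are insensitive
  to early effects.
* **Monitoring and decisions** — sequential nuisance re-estimation with
  design-assumed fallbacks while data are sparse, look triggering as
  above, decisions against the precomputed boundaries, and a final
  analysis at the cap when no early stop occurs. By default looks still
  happen if their information level is reached after recruitment completes
  (as in the published design simulations); `looks_after_recruitment =
  FALSE` abandons them, as a real trial would. The fraction of replicates
  with recruitment complete before the last early look is reported.

`operating_characteristics()` aggregates replicates into cumulative
futility stopping per look, early-efficacy and final rejection
probabilities, overall power, and expected sample size (reported both as
the mean randomised across traces and through the stopping-probability
decomposition, which agree within Monte-Carlo error). One master seed
spawns per-replicate substream seeds, recorded for exact replay.

What a green simulation test does **not** establish: the generator draws
exactly the multivariate-normal, lag-deterministic, dropout-free world of
the design assumptions. Real trials have missed visits, dropout,
non-normal scores bounded at 0–100, drifting recruitment rates and
possibly arm-specific correlation structures; none of these are emulated
by default (dropout exists only as a configuration hook, deliberately off
in the operating-characteristic simulations, which analyse the nominal
85 per arm).

## Numerical and design choices, in one place

* Spending vectors are user-supplied cumulative (or per-look) values; no
  spending *function* families are provided.
* Correlation clamping at ±0.99, PSD repair by eigenvalue clipping at
  $10^{-6}$; the vectorised monitoring path repairs whenever the 3×3
  determinant test signals non-PSD or near-singularity (det < $10^{-4}$),
  marginally more eager than the analysis path's eigenvalue rule.
* Boundary recursion: 501 Simpson nodes/stage, ±8 SD span, roots to
  $10^{-10}$; infinite boundaries serialised as `"inf"`/`"-inf"`.
* Ties: efficacy at $S_w = u_w$, continuation at $S_w = l_w$.
* Information may be supplied absolute or as fractions of the final level.
* Config files are JSON with unknown keys rejected; CSV datasets use
  empty cells for missing values.

## Known limitations

* The unequal-arm variance is a harmonic-mean approximation.
* The overrunning p-value uses a normal reference.
* Estimation noise in the interim statistic leaves small calibration
  residue in corners of the design space — most visibly, when the true
  correlations are zero the estimated-correlation corrections add noise
  that the plug-in variance books as a reduction, inflating the final
  rejection rate by about half a percentage point in a two-look design.
  The effect shrinks as looks move later (more pairs per correlation).
* Binary/survival endpoints, covariate adjustment, multiple imputation,
  post-stopping estimation bias adjustment and confidence intervals after
  sequential testing are out of scope.
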