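---
title: "Survival mediation analysis with multiple methylation exposures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival mediation analysis with multiple methylation exposures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iusmmt)
```

## The problem

Aberrant DNA methylation influences disease at least partly by regulating
gene expression. In a cancer cohort with methylation arrays, RNA-seq and
follow-up, a natural gene-centric question is whether the expression level
of a gene *mediates* the effect of its CpG methylation on patient survival:
does methylation act on survival *through* expression? For one gene this
involves a block of $K$ CpG M-values $\mathbf M$ ($n \times K$, $K$ often
10-30 and highly locally correlated), one expression level $G$, a censored
outcome $(t, d)$, and clinical covariates $\mathbf X$.

A mediation effect exists only when **both** paths are active: methylation
must move expression ($\boldsymbol\alpha \ne 0$) *and* expression must move
the hazard ($\beta \ne 0$). The null is therefore composite — a union of
three states: ($\alpha\ne0,\beta=0$), ($\alpha=0,\beta\ne0$),
($\alpha=0,\beta=0$) — and that structure is what makes naive genome-wide
testing badly conservative.

## The two stage models

**Methylation → expression.** A linear mixed model
$$G = \mathbf M\boldsymbol\alpha + \mathbf X\mathbf w_2 + \varepsilon,\qquad
  \alpha_k \sim N(0, \tau_2),\ \varepsilon \sim N(0, \sigma_\varepsilon^2),$$
tested as $H_0\colon \tau_2 = 0$ with the variance-component score
statistic $Q = \sum_k\big(\sum_i M_{ik} r_i\big)^2 = r^\top \mathbf M
\mathbf M^\top r$, $r$ the residuals of the covariate-only fit
(`test_methylation_expression()`). Under $H_0$,
$Q/\hat\sigma_\varepsilon^2$ follows a mixture of $\chi^2_1$ variables with
weights the nonzero eigenvalues of $\mathbf M^\top P_0 \mathbf M$ ($P_0$
the residual-maker of the intercept-augmented covariates). This pairing of
statistic and weights makes the p-value exactly invariant to rescaling of
$G$ and to affine recoding of $\mathbf X$. Tail probabilities use Davies'
characteristic-function inversion with a Liu-type moment-matching fallback
whenever the inversion fails or returns a value outside $[10^{-14}, 1]$
(`mixture_chisq_tail()`). An optional 1-D profile REML estimate of
$\tau_2$ is available; the boundary value 0 is allowed.

**Expression → survival.** A Cox model conditioning on the CpG block
through shrunken direct effects,
$$\log\frac{h(t)}{h_0(t)} = \mathbf M\boldsymbol\gamma^{DE} + G\beta +
  \mathbf X\mathbf w_3,\qquad \gamma^{DE}_k \sim N(0, \tau_3),$$
fitted by maximizing the ridge-penalized partial likelihood $\ell -
\boldsymbol\gamma^\top\boldsymbol\gamma/(2\tau_3)$ (Newton-Raphson with
step-halving, Efron ties, compiled in C++). $\tau_3$ is chosen by
maximizing the Laplace-approximate integrated likelihood
$\ell_{pen} - \tfrac12\log\det(I + \tau_3 H_{\gamma\gamma})$ over
$\log\tau_3$; `se(\hat\beta)` comes from the inverse penalized observed
information, and $P_\beta$ is the Wald p-value (`fit_coxlmm()`,
`wald_test_beta()`). The engine is cross-checked in the test suite against
`survival::coxph()` in both ridge limits ($\tau_3 \to 0$ drops the CpGs;
$\tau_3 \to \infty$ is the unpenalized joint fit).

A kernel-machine **total-effect** test of $\mathbf M$ on survival
(`total_effect_test()`) uses $Q_T = r^\top \mathbf M\mathbf M^\top r$ on
martingale residuals with weights from
$V = D - D\tilde{\mathbf X}(\tilde{\mathbf X}^\top D \tilde{\mathbf
X})^{-1}\tilde{\mathbf X}^\top D$, $D$ the diagonal of estimated cumulative
hazards. It is reported for context but never gates the mediation test: a
mediation effect can exist without a detectable total effect.

## The max-P statistic and its mixture null

Each stage yields a p-value; the intersection-union principle takes
$P_{\max} = \max(P_\alpha, P_\beta)$ and rejects when $P_{\max}$ is small.
Used with the uniform reference, this IUT is valid but very conservative:
genome-wide, most genes sit in the double-null component where
$P_{\max}$ is distributed as $u^2$, not $u$.

IUSMMT replaces the uniform reference with the estimated mixture null
$$\Pr(P_{\max}\le u \mid H_0) =
  \frac{\kappa_{10}\,p_{10}(u)\,u + \kappa_{01}\,p_{01}(u)\,u +
        \kappa_{00}\,u^2}{\kappa_{10} + \kappa_{01} + \kappa_{00}},$$
where $\kappa_{10}, \kappa_{01}, \kappa_{00}$ are the proportions of the
three null components and $p_{10}, p_{01}$ are the power curves of the
stage tests under their alternatives. Evaluating this CDF at each gene's
$P_{\max}$ gives the adjusted significance value (`iusmmt()`), to which
Bonferroni (FWER) or Benjamini-Hochberg (FDR) control is applied
(`significance_control()`). Because $p_{10}, p_{01} \le 1$ and $u^2 \le u$,
the adjusted value never exceeds $P_{\max}$, so every IUT discovery is also
an IUSMMT discovery at the same level.

**Estimating the ingredients.** The proportions use Storey's estimator
$\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda)S)$ with $\lambda = 0.5$ on each
stage series, combined under a working independence assumption
($\kappa_{00} = \hat\pi_{0\alpha}\hat\pi_{0\beta}$, etc.), clipped to
$[0,1]$ and renormalized. Independence across the two series is a working
assumption, not a truth: when the two alternatives concentrate in the same
genes (pure-mediation settings) the product splits that shared mass into
the single-path components and under-states $\kappa_{00}$ — visible in the
recovery tests and discussed under limitations. The power curves use the
Grenander estimator: the least concave majorant of the empirical p-value
CDF, deconvolved as $F_1(u) = (\hat F(u) - \pi_0 u)/(1 - \pi_0)$, clipped
monotone; the degenerate case $\pi_0 \ge 1 - 10^{-6}$ returns the identity.
Both curves are estimated from the full p-value series because component
membership is unobservable. The normalization of the mixture CDF by the
null mass $\kappa_{10}+\kappa_{01}+\kappa_{00}$ keeps it a proper CDF when
$\kappa_{11} > 0$; the unnormalized variant is available behind
`normalize = FALSE`.

## Passenger methylation screen

A significant mediation pattern can also arise when methylation is a
downstream *passenger* of expression changes. The reverse multivariate
score test (`reverse_score_test()`) regresses the CpG block on expression,
$\mathbf M = G\tilde\beta + \mathbf X\tilde W + \tilde\varepsilon$ with
$\tilde\beta_k \sim N(0, \tau)$, and tests $\tau = 0$ with
$Q_M = \|G^\top(\mathbf M - \hat\mu)\hat V^{-1}\|^2$, $\hat V$ the residual
covariance across CpGs (ridge-stabilized at condition number $> 10^8$).
Mediating genes with $p < \alpha / (\text{number of mediating genes})$ are
flagged (`flag_passengers()`).

## The synthetic-data generator

`simulate_study()` reproduces the simulation design the package is
validated on, one independent dataset per gene:

* **CpG block**: $K \sim$ uniform $\{10,\dots,30\}$ columns of an AR(1)
  Gaussian, $\mathrm{corr}(i,j) = 0.5^{|i-j|}$, column-standardized — a
  synthetic stand-in for real CpG blocks, which show comparably strong
  local correlation.
* **Covariates**: $x_1 \sim N(0,1)$ (age-like) and an ordinal 1-5
  stage-like $x_2$, both standardized, each with effect 0.5 in both stage
  models.
* **Mediator**: $G = \mathbf M\boldsymbol\alpha + 0.5x_1 + 0.5x_2 +
  \varepsilon$, $\alpha_k \sim N(0, \tau_2)$, $\varepsilon \sim N(0,1)$.
* **Survival**: inverse-probability Weibull, $\log t = \tfrac1\rho
  \log(-\log u / (\lambda e^\eta))$ with $\eta = \mathbf
  M\boldsymbol\gamma^{DE} + G\beta + 0.5x_1 + 0.5x_2$, $\gamma^{DE}_k \sim
  N(0, \tau_3)$; defaults $\lambda = 1$, $\rho = 0.01$, $\tau_3 = 0.02$.
* **Censoring**: exactly `round(rate * n)` subjects (default rate 0.5)
  drawn at random, each observed at a uniform$(0, t_i)$ time.
* **Components**: per-gene labels 00/01/10/11 drawn from the scenario
  proportions; 10/11 genes get $\tau_2 > 0$, 01/11 genes get $\beta \ne 0$.

Named scenarios carry the component frequencies used throughout the tests:
complete null $(1,0,0,0)$; dense null $(0.10,0.85,0.05,0)$; sparse null
$(0.99,0.01,0,0)$; dense alternative $(0.10,0.75,0.05,0.10)$; sparse
alternative $(0.90,0,0,0.10)$, ordered $(\kappa_{00}, \kappa_{01},
\kappa_{10}, \kappa_{11})$.

**Numerical note on time scales.** With $\rho = 0.01$ the Weibull times
span hundreds of orders of magnitude and overflow double precision. The
generator therefore works on the exact log-time scale (uniform$(0,t)$
censoring applied exactly as $\log t + \log U$) and stores observed times
through the global monotone map $e^{\rho \log t}$. The Cox partial
likelihood depends on times only through ranks and ties, which the map
preserves, so fits and tests are unaffected.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda` (Storey) | 0.5 | tail threshold for $\hat\pi_0$; larger values lower bias, raise variance |
| `promoter_bp` | 500 | upstream window (bases, strand-aware) when mapping CpGs to genes |
| `tau3_grid` | 21 log-spaced points in $[10^{-6}, 10]$ | outer search for the CpG random-effect variance; the genome-wide scan uses a 10-point grid without refinement, since the Wald p-value is insensitive to fine $\tau_3$ tuning |
| `acc` (Davies) | $10^{-7}$ | tail-probability accuracy; far below any downstream tolerance, at ~1 ms per evaluation |
| `ridge_delta` | $10^{-4}$ | relative ridge on $\hat V$ in the reverse test when ill-conditioned |
| convergence | rel. $\Delta\ell < 10^{-9}$, 50 iterations, 30 halvings | inner Newton for the penalized Cox fit |

Other numerical choices: eigenvalues below $10^{-10}$ of the largest are
dropped; survival ties are ordered by a stable sort on (time, status);
covariates are used as supplied (not standardized) since the stage tests
are invariant to affine recoding; clinical covariates are mean-imputed
while methylation/expression rows with missing values are dropped;
standardization uses the sample (n-1) convention so a standardized column
has `var() == 1` exactly.

## Design choices where the design was open

* **Proportion estimator.** Many estimators of multi-component null
  proportions exist; the product/independence construction over per-series
  Storey estimates was chosen because it is transparent, fast, requires no
  latent-component assignment, and reproduces the qualitative bias
  behaviour checked in the recovery tests.
* **Total-effect null covariance.** The weight matrix
  $V^{1/2}\mathbf M\mathbf M^\top V^{1/2}$ with the cumulative-hazard
  diagonal projected onto the null design is justified empirically: the
  resulting p-values agree with permutation references within Monte-Carlo
  error at $n = 250$ (test suite) rather than being derived from a closed
  form.
* **Direction of a vector effect.** $\boldsymbol\alpha$ has no single
  sign; `direction_of_effects()` summarizes it by the sign of the
  regression of $G$ on the equal-weight burden score $\sum_k M_k$ with
  covariates.
* **Ties.** Efron throughout; Breslow available in `fit_cox_ph()` for
  oracle cross-checks (exact subject-duplication invariance holds for
  Breslow, only approximately for Efron).
* **Significance rule for power summaries.** `run_power_experiment()`
  applies the same rule (default BH-FDR 0.05) to both the adjusted and the
  naive max-P values, so power differences reflect the calibration alone.

## What the tests do and do not show

The test suite and the reproduction script run entirely on the synthetic
generator. They verify: exact arithmetic on small fixtures; agreement of
every score test with permutation references (at $n = 250$, where the
asymptotic mixture and the exact permutation law coincide within
Monte-Carlo error; at toy $n \le 60$ the two differ by $O(1/n)$, and a
bounded-gap check is used); both ridge limits of the Cox engine against
`survival::coxph`; uniformity and correct size of $P_\alpha$, $P_\beta$
and the adjusted values under the complete null at $n = 400$; the
conservativeness of the naive IUT; elementwise dominance of the adjusted
values; recovery of $\beta = 0.3$ in mean over 200 genes at $n = 548$; and
recovery of the scenario proportions at reduced gene counts (2,000-4,000
genes per replicate rather than $10^4$; reproduction bands widen by the
Monte-Carlo sd of the scaled-down estimate).

Passing these tests does **not** show that real 450K/RNA-seq data behave
like the generator. Two gaps deserve emphasis. First, real CpG blocks have
heterogeneous, often small, per-CpG dispersion and non-Gaussian (bimodal)
M-value distributions; the standardized AR(1) stand-in fixes every column
variance at 1, which inflates the effective methylation-expression signal
at a given $\tau_2$. On unit-variance blocks the stage tests saturate
(power $\approx 1$) already at $\tau_2 \approx 0.04$ with $n \ge 250$, so
the advantage of the mixture calibration over the naive IUT — largest when
stage powers are intermediate — appears at much smaller $\tau_2$ (around
$10^{-3}$-$10^{-2}$) than it would on real methylation scales. Second,
saturation interacts with the independence construction: when both stage
tests detect nearly every active gene, the shared $\kappa_{11}$ mass is
split multiplicatively and $\hat\kappa_{00}$ is *under*-stated in
pure-mediation scenarios, the reverse of its behaviour at realistic power.
Conclusions about calibration transfer to real data; conclusions about
power magnitudes do not.

Known limitations: the ridge-penalized $\hat\beta$ is mildly attenuated at
small $n$ (non-collapsibility plus shrinkage of the CpG direct effects —
about 5% at $n = 400$ with 50% censoring, negligible at $n = 548$); the
mixture proportions need a few hundred genes to stabilize (the scan warns
below 100); and the reverse screen assumes an identity phenotype kernel
across CpGs.
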