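---
title: "Methods: latent-factor generalized SEM for intimate partner violence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-factor generalized SEM for intimate partner violence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipvgsem)
```

## The scientific problem

Intimate partner violence (IPV) among married women is usually measured in
population surveys such as the Demographic and Health Surveys (DHS) through
batteries of act-level items: for each act ("pushed or shook you", "forced
you to have sexual intercourse", ...) a woman reports whether it ever
happened and, if so, whether it happened often, sometimes or not at all in
the last 12 months. Three binary domain outcomes — physical, emotional and
sexual IPV over a 12-month recall window — are derived from these items,
and analysts want to know how socio-demographic covariates and the
husband's *controlling behaviour* relate to each domain.

Controlling behaviour is not directly observed. It is measured by a battery
of yes/no indicator items (jealousy when talking to other men, accusations
of unfaithfulness, limiting contact with friends and with family, insisting
on knowing the woman's whereabouts). Treating any single item, or their raw
sum, as a covariate conflates measurement error with effect. The package
instead treats controlling behaviour as a latent factor and fits the three
IPV domains jointly with the measurement model, in a generalized structural
equation model (GSEM) in which every equation is a Bernoulli--logit
regression.

## The model

Let $\eta_i \sim N(0,1)$ be the latent husband-controlling-behaviour score
of woman $i$, $y_{ij}$ her response to indicator item $j = 1,\dots,J$ and
$v_{id}$ her binary outcome in domain $d \in \{\text{phys}, \text{emo},
\text{sex}\}$, with covariate vector $x_i$ (dummy-coded, reference levels
dropped). The model is

$$
\Pr(y_{ij} = 1 \mid \eta_i) = \operatorname{logit}^{-1}(\tau_j +
\lambda_j \eta_i), \qquad
\Pr(v_{id} = 1 \mid x_i, \eta_i) = \operatorname{logit}^{-1}(\alpha_d +
x_i'\beta_d + \gamma_d \eta_i),
$$

with all responses conditionally independent given $\eta_i$. The marginal
likelihood contribution of a woman integrates $\eta$ out, and with design
weight $w_i$ the fitted objective is the pseudo-log-likelihood

$$
\ell = \sum_i w_i \log \int \prod_j \!\text{Bern}(y_{ij})
\prod_d \!\text{Bern}(v_{id}) \, \phi(\eta)\, d\eta .
$$

Exponentiated structural coefficients $e^{\beta}$ are adjusted odds
ratios; $e^{\gamma_d}$ is the odds ratio per standard deviation of the
latent factor.

### Identification

A one-factor binary measurement model needs a scale constraint. The
default here fixes the latent variance at 1 and leaves all loadings free,
so $\gamma_d$ is a per-SD effect and directly interpretable as an adjusted
odds ratio when exponentiated. The alternative convention — first loading
fixed at 1, factor variance free — is an exact reparameterization
($\sigma = \lambda_1$, $\lambda_j^{L} = \lambda_j/\lambda_1$,
$\gamma_d^{L} = \gamma_d/\lambda_1$) and is available as a reporting
option in `gsem_spec(ident = "loading")`. The reflection invariance
($\lambda, \gamma) \mapsto (-\lambda, -\gamma)$ is resolved by forcing the
first loading positive after optimization.

The per-outcome covariate sets in `default_gsem_spec()` follow the
adjusted model reported for pooled East-African DHS data: media exposure
appears only in the emotional and sexual equations, smoking only in the
emotional one, current pregnancy only in the sexual one; `full = TRUE`
puts every covariate everywhere. The latent construct is described in its
source with six indicators in one place and five named items in another;
the package defaults to the five named items, and `gsem_spec()` accepts
any indicator set of size two or more.

## Estimation and numerical choices

* **Quadrature.** The latent factor is integrated by non-adaptive
  Gauss--Hermite quadrature (`gh_quadrature()`), nodes rescaled to the
  N(0,1) convention, default order 15. Non-adaptive quadrature is exactly
  reproducible and, for a single latent dimension with bounded logistic
  integrands, order 15 agrees with a 10,001-point trapezoid reference to
  better than $10^{-7}$ relative error on test instances; the suite also
  checks that refitting at order 25 moves no estimate by more than
  $10^{-3}$.
* **Optimization.** BFGS on the per-observation average negative
  log-likelihood with analytic gradients (the likelihood, gradient and
  per-unit scores are implemented in compiled code). Starting values:
  marginal logits for all intercepts, loadings 1, structural coefficients
  from separate weighted logistic fits, latent effects 0.5. Convergence
  requires a scaled gradient max-norm below $10^{-5}$ *and* a relative
  log-likelihood change below $10^{-8}$ across a polishing restart;
  failure is reported, never silent. A fitted coefficient with absolute
  value above 15 triggers a separation warning. Indicators or outcomes
  with zero variance abort with an error naming the column.
* **Weights.** Design weights are normalized to mean 1 over the pooled
  sample before entering the pseudo-likelihood. No country-level
  re-scaling by population size is applied; cross-country weight handling
  is a genuine analytic choice and the mean-1 pooled convention keeps the
  effective sample size interpretable.
* **Variance.** The default covariance is the sandwich estimator with
  PSU-summed scores (bread: inverse observed information, computed by
  central differences of the analytic gradient; meat: outer product of
  cluster score totals with the $G/(G-1)$ factor). With one unit per
  cluster and unit weights it reduces to the heteroscedasticity-robust
  sandwich. Wald z-tests, significance at $p<0.05$, no multiplicity
  correction.

## Survey-weighted descriptives and pooling

`weighted_proportion()` estimates $p = \sum w_i x_i / \sum w_i$ with
Taylor-linearized variance, clustering on PSU within strata when ids are
supplied (the with-replacement first-stage approximation). Confidence
intervals are Wald intervals on the logit scale, which cannot leave
$[0,1]$; at the degenerate proportions 0 and 1 an exact-style one-sided
bound on the unweighted count is returned and flagged. Displayed percents
round half-up to two decimals, as printed survey tables do.

Country prevalences are pooled on the logit scale ($\theta = \log
p/(1-p)$, $\widehat{var} = 1/(np) + 1/(n(1-p))$, continuity correction
$0.5/(n+1)$ events at the boundary) with the DerSimonian--Laird moment
estimator; heterogeneity is reported as $Q$, $\tau^2$,
$I^2 = \max(0, 100(Q - df)/Q)$ and a $\chi^2_{k-1}$ p-value. Pooling on
the logit scale is a deliberate choice — the double-arcsine alternative is
common in prevalence meta-analysis but back-transforms less
transparently — and the identity-scale formulas are pinned by exact
worked-example tests.

## What the simulator emulates — and what it does not

`simulate_population()` generates woman-level records with the structure
the analysis assumes:

* stratified two-stage sampling: PSUs drawn with probability proportional
  to an *outdated* census size measure, a fixed take of women per PSU from
  the current size; weights are products of inverse selection
  probabilities, normalized to mean 1 per country (weight variation comes
  from the census/current size discrepancy, as in real frames);
* covariates drawn independently from the pooled East-African margins
  (56,657 married women); a `joint_sampler` hook accepts a user-supplied
  joint distribution, since independence is the one feature of real
  covariate structure the default deliberately ignores — only the margins
  are constrained by the source tables;
* a standard-normal latent factor driving the five indicator items
  (loadings 1, intercepts calibrated by root-finding to a 40% marginal
  item prevalence — the measurement scale is not printed anywhere, so
  these are documented defaults, not estimates);
* outcome equations whose structural coefficients are the natural logs of
  the published adjusted odds ratios, latent effects $\log 1.92$,
  $\log 2.32$, $\log 1.82$, and intercepts calibrated by root-finding so
  the marginal domain prevalences equal the published pooled values
  (physical 26.15%, emotional 26.06%, sexual 11.6%);
* act-level items thinned from the domain flag (a positive domain forces
  at least one recent act), plus lifetime-only reports that must *not*
  count toward the 12-month outcome — exercising the derivation rules end
  to end;
* optional country- and PSU-level intercept shifts (`country_sd`,
  `psu_sd`) to induce between-country heterogeneity and intra-cluster
  correlation for variance-estimator tests.

Passing tests on these data show that the derivation, weighting, pooling
and estimation machinery is correct under the stated generative model.
They do not show that real DHS data satisfy that model: real covariates
are dependent (wealth and residence strongly so), real item batteries have
country-specific skip patterns and missingness, real controlling-behaviour
items need not follow a one-factor logistic measurement model, and real
between-country heterogeneity ($I^2 \approx 99\%$ in the source analysis)
is far larger than any sampling noise the homogeneous default produces.

## Problem sizes used in the checks

The test suite's recovery study refits the full model on 20 independent
surveys of n = 20,000 women (4 countries x 40 PSUs x 125 women) simulated
at the reference parameters, and checks per-coefficient 95% CI coverage
(threshold: at least 90%) and the absolute Monte-Carlo bias
$|\overline{\hat\theta - \theta}|$ of each structural coefficient
(threshold 0.05). "Bias" here is the absolute value of the *mean* error
over replicates — the standard simulation-study bias metric — not the mean
of absolute errors, which would be dominated by the sampling standard
error of sparsely populated categories (smoking prevalence is 0.81%, so
its coefficient's sampling SD alone is about 0.17 at this n). The pooled
prevalence checks use a 12-country simulation of roughly 50,000 women,
matching the pooled sample of the source tables. With 60 structural
coefficients each tested on 20 replicates, a perfectly calibrated
estimator still fails a per-coefficient 90% threshold occasionally
(18-of-20 coverage has about 7.5% binomial probability at nominal 95%);
the suite reports which coefficients fall short so such events can be
distinguished from systematic failures.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_countries = 4, psus_per_country = 40,
                  women_per_psu = 125, seed = 1)
raw <- simulate_population(cfg)
d <- build_analysis_table(raw)

# survey-weighted prevalence, PSU-clustered CI
weighted_proportion(d$any_ipv, d$weight, psu = d$psu, strata = d$stratum)

# pooled prevalence across countries with heterogeneity statistics
pool_country_prevalence(country_prevalence(d))

# the joint latent-factor model
fit <- ipv_gsem(d)
summary(fit)
aor_table(fit)
```

## Known limitations

* One latent factor, logit links, no latent classes and no Bayesian
  estimation; the exploratory add-a-path model search of interactive SEM
  software is out of scope — `compare_models()` ranks user-specified fits
  by information criteria instead.
* Non-adaptive quadrature: adequate for one latent dimension at the
  fitted scales; models with very large loadings would need adaptive
  rescaling.
* The sandwich variance treats PSUs as sampled with replacement within
  strata (the standard survey approximation); finite-population
  corrections are not implemented.
* Complete-case analysis only, matching the source analysis; no
  imputation.
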