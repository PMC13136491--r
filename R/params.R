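## Canonical covariate factors, level orderings and dummy coding.
## The first level of every factor is the reference category used in the
## structural model (youngest age group, urban, no education, poorest
## quintile, and "no" for every binary factor).

#' Covariate factors used in the IPV structural model
#'
#' @return named list; each element is the character vector of levels of one
#'   categorical covariate, reference level first.
#' @export
ipv_factors <- function() {
  list(
    age_group         = c("15_24", "25_34", "35_49"),
    residence         = c("urban", "rural"),
    education         = c("none", "primary", "secondary_plus"),
    wealth            = c("poorest", "poorer", "middle", "richer", "richest"),
    media_exposure    = c("no", "yes"),
    working           = c("no", "yes"),
    pregnant          = c("no", "yes"),
    smoking           = c("no", "yes"),
    autonomy          = c("no", "yes"),
    beating_attitude  = c("no", "yes"),
    husband_education = c("none", "primary", "secondary_plus"),
    husband_working   = c("no", "yes"),
    husband_alcohol   = c("no", "yes")
  )
}

#' Default marginal category probabilities of the covariates
#'
#' Margins of the socio-demographic covariates in a pooled East-African
#' DHS sample of 56,657 married women; used as the simulator's default
#' covariate distribution.
#'
#' @return named list of probability vectors, one per factor in
#'   \code{\link{ipv_factors}}; each sums to 1.
#' @export
default_covariate_margins <- function() {
  list(
    age_group         = c(0.2399, 0.4353, 0.3248),
    residence         = c(0.2606, 0.7394),
    education         = c(0.2065, 0.4582, 0.3353),
    wealth            = c(0.1981, 0.1981, 0.1951, 0.2104, 0.1983),
    media_exposure    = c(0.4873, 0.5127),
    working           = c(0.2976, 0.7024),
    pregnant          = c(0.8885, 0.1115),
    smoking           = c(0.9919, 0.0081),
    autonomy          = c(0.7145, 0.2855),
    beating_attitude  = c(0.5464, 0.4536),
    husband_education = c(0.1754, 0.4297, 0.3949),
    husband_working   = c(0.0698, 0.9302),
    husband_alcohol   = c(0.6214, 0.3786)
  )
}

#' Default husband-controlling-behaviour indicator items
#' @return character vector of the five indicator names.
#' @export
hcb_indicators <- function() {
  c("jealous", "accuse_unfaithful", "limit_friends", "limit_family",
    "insist_whereabouts")
}

## dummy column names for one factor: "<factor>.<level>" for non-reference
## levels
dummy_names <- function(factor_name, levels) {
  paste(factor_name, levels[-1L], sep = ".")
}

#' Model structure of the IPV generalized SEM
#'
#' Defines which covariates enter each outcome equation and which indicator
#' items measure the latent husband-controlling-behaviour (HCB) factor. The
#' latent factor has mean 0; under the default \code{ident = "variance"}
#' convention its variance is fixed at 1 and all loadings are free, so each
#' structural latent effect is a per-standard-deviation log-odds ratio.
#' \code{ident = "loading"} reports the same fit rescaled so the first
#' loading equals 1 and the factor standard deviation is free.
#'
#' @param outcomes named list mapping each outcome (\code{physical},
#'   \code{emotional}, \code{sexual}) to the character vector of covariate
#'   factor names in its equation.
#' @param indicators character vector of binary indicator item names
#'   (at least 2, for identification).
#' @param factors factor/level definitions, see \code{\link{ipv_factors}}.
#' @param ident latent identification convention, \code{"variance"} or
#'   \code{"loading"}.
#' @return object of class \code{gsem_spec}.
#' @export
gsem_spec <- function(outcomes, indicators = hcb_indicators(),
                      factors = ipv_factors(),
                      ident = c("variance", "loading")) {
  ident <- match.arg(ident)
  if (length(indicators) < 2L) {
    stop("at least 2 indicator items are required to identify the loadings")
  }
  stopifnot(is.list(outcomes), length(outcomes) >= 1L,
            !is.null(names(outcomes)))
  for (d in names(outcomes)) {
    unknown <- setdiff(outcomes[[d]], names(factors))
    if (length(unknown)) {
      stop("unknown covariate factor(s) in outcome '", d, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(outcomes = outcomes, indicators = indicators,
                 factors = factors, ident = ident),
            class = "gsem_spec")
}

#' Default IPV model specification
#'
#' Covariate sets per domain follow the adjusted model reported for pooled
#' East-African DHS data: media exposure enters only the emotional and
#' sexual equations, smoking only the emotional equation, and current
#' pregnancy only the sexual equation; all other covariates enter all three.
#'
#' @inheritParams gsem_spec
#' @param full if \code{TRUE}, put every covariate in every equation.
#' @return object of class \code{gsem_spec}.
#' @export
default_gsem_spec <- function(indicators = hcb_indicators(), full = FALSE,
                              ident = "variance") {
  base <- c("age_group", "residence", "education", "wealth", "working",
            "autonomy", "beating_attitude", "husband_education",
            "husband_working", "husband_alcohol")
  if (full) {
    all_f <- names(ipv_factors())
    outcomes <- list(physical = all_f, emotional = all_f, sexual = all_f)
  } else {
    outcomes <- list(
      physical  = base,
      emotional = c(base, "media_exposure", "smoking"),
      sexual    = c(base, "media_exposure", "pregnant")
    )
  }
  gsem_spec(outcomes, indicators = indicators, ident = ident)
}

## expand a spec into per-outcome dummy-column names
spec_dummy_cols <- function(spec) {
  lapply(spec$outcomes, function(fs) {
    unlist(lapply(fs, function(f) dummy_names(f, spec$factors[[f]])),
           use.names = FALSE)
  })
}

#' Construct a GSEM parameter set
#'
#' @param tau indicator intercepts, named by indicator.
#' @param lambda factor loadings, named by indicator.
#' @param alpha outcome intercepts, named by outcome.
#' @param beta named list of structural coefficient vectors, one per
#'   outcome, named by dummy column (\code{"<factor>.<level>"}).
#' @param gamma latent-effect coefficients, named by outcome.
#' @return object of class \code{gsem_params}.
#' @export
gsem_params <- function(tau, lambda, alpha, beta, gamma) {
  stopifnot(length(tau) == length(lambda),
            length(alpha) == length(gamma),
            length(beta) == length(alpha),
            all(is.finite(c(tau, lambda, alpha, unlist(beta), gamma))))
  structure(list(tau = tau, lambda = lambda, alpha = alpha,
                 beta = beta, gamma = gamma),
            class = "gsem_params")
}

#' Flatten a parameter set to a named vector (and back)
#'
#' Packing order: indicator intercepts, loadings, then intercept plus
#' structural coefficients outcome by outcome, latent effects last.
#' \code{unpack_params} inverts \code{pack_params} exactly.
#'
#' @param params a \code{gsem_params} object.
#' @return named numeric vector.
#' @export
pack_params <- function(params) {
  c(setNames(params$tau, paste0("tau.", names(params$tau))),
    setNames(params$lambda, paste0("lambda.", names(params$lambda))),
    unlist(lapply(names(params$beta), function(d) {
      c(setNames(params$alpha[d], paste0("alpha.", d)),
        setNames(params$beta[[d]],
                 paste0("beta.", d, ".", names(params$beta[[d]]))))
    })),
    setNames(params$gamma, paste0("gamma.", names(params$gamma))))
}

#' @rdname pack_params
#' @param theta packed numeric vector.
#' @param skeleton a \code{gsem_params} object supplying names and shapes.
#' @export
unpack_params <- function(theta, skeleton) {
  J <- length(skeleton$tau)
  D <- length(skeleton$alpha)
  pos <- 0L
  take <- function(k) {
    out <- theta[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  tau <- setNames(take(J), names(skeleton$tau))
  lambda <- setNames(take(J), names(skeleton$lambda))
  alpha <- numeric(D)
  names(alpha) <- names(skeleton$alpha)
  beta <- lapply(skeleton$beta, function(b) NULL)
  for (d in names(skeleton$beta)) {
    alpha[d] <- take(1L)
    beta[[d]] <- setNames(take(length(skeleton$beta[[d]])),
                          names(skeleton$beta[[d]]))
  }
  gamma <- setNames(take(D), names(skeleton$gamma))
  stopifnot(pos == length(theta))
  gsem_params(tau, lambda, alpha, beta, gamma)
}

## Exact marginal prevalence of one outcome under the generative model:
## covariates independent with the given margins, latent N(0,1) integrated
## by quadrature. Enumerates the joint distribution of x'beta over the
## factors present in the equation (a few 10^4 cells at most).
marginal_outcome_prevalence <- function(alpha, beta, gamma, spec, margins,
                                        quad = gh_quadrature(40)) {
  all_f <- names(spec$factors)
  fs <- all_f[vapply(all_f, function(f) {
    any(startsWith(names(beta), paste0(f, ".")))
  }, logical(1))]
  dist <- data.frame(s = 0, p = 1)
  for (f in fs) {
    lv <- spec$factors[[f]]
    contrib <- c(0, beta[dummy_names(f, lv)])
    dist <- data.frame(
      s = as.vector(outer(dist$s, contrib, `+`)),
      p = as.vector(outer(dist$p, margins[[f]], `*`))
    )
  }
  lin <- outer(dist$s + alpha, gamma * quad$nodes, `+`)
  sum(dist$p * (invlogit(lin) %*% quad$weights))
}

## solve for the intercept giving a target marginal prevalence
calibrate_intercept <- function(target, beta, gamma, spec, margins,
                                quad = gh_quadrature(40)) {
  uniroot(function(a) {
    marginal_outcome_prevalence(a, beta, gamma, spec, margins, quad) - target
  }, interval = c(-15, 15), tol = 1e-10)$root
}

## solve for the indicator intercept giving a target marginal item prevalence
calibrate_indicator_intercept <- function(target, lambda,
                                          quad = gh_quadrature(40)) {
  uniroot(function(tau) {
    sum(quad$weights * invlogit(tau + lambda * quad$nodes)) - target
  }, interval = c(-15, 15), tol = 1e-10)$root
}

#' Reference parameter values for the simulator
#'
#' Structural coefficients are the natural logs of the adjusted odds ratios
#' reported for pooled East-African DHS data (e.g. husband drinks alcohol on
#' the physical domain: \code{log(3.06)}); the latent HCB effects are
#' \code{log(1.92)}, \code{log(2.32)} and \code{log(1.82)} on the physical,
#' emotional and sexual domains. Loadings default to 1 with indicator
#' intercepts calibrated to a 40\% marginal item prevalence; outcome
#' intercepts are calibrated by root-finding so the marginal domain
#' prevalences under the generative model equal the reported pooled values
#' (physical 26.15\%, emotional 26.06\%, sexual 11.6\%).
#'
#' @param spec model structure, see \code{\link{default_gsem_spec}}.
#' @param margins covariate margins used for intercept calibration.
#' @param indicator_prev target marginal prevalence of each indicator item.
#' @param domain_prev target marginal prevalence of each outcome domain,
#'   named by outcome.
#' @return object of class \code{gsem_params}.
#' @export
default_true_params <- function(spec = default_gsem_spec(),
                                margins = default_covariate_margins(),
                                indicator_prev = 0.40,
                                domain_prev = c(physical = 0.2615,
                                                emotional = 0.2606,
                                                sexual = 0.116)) {
  aor <- list(
    physical = c(
      "age_group.25_34" = 1.24, "age_group.35_49" = 1.33,
      "residence.rural" = 1.02,
      "education.primary" = 1.04, "education.secondary_plus" = 0.76,
      "wealth.poorer" = 0.98, "wealth.middle" = 0.90,
      "wealth.richer" = 0.90, "wealth.richest" = 0.72,
      "working.yes" = 1.20,
      "autonomy.yes" = 1.02, "beating_attitude.yes" = 1.58,
      "husband_education.primary" = 1.17,
      "husband_education.secondary_plus" = 0.99,
      "husband_working.yes" = 0.91, "husband_alcohol.yes" = 3.06),
    emotional = c(
      "age_group.25_34" = 1.29, "age_group.35_49" = 1.49,
      "residence.rural" = 1.09,
      "education.primary" = 1.08, "education.secondary_plus" = 0.94,
      "wealth.poorer" = 0.97, "wealth.middle" = 1.01,
      "wealth.richer" = 0.96, "wealth.richest" = 0.84,
      "media_exposure.yes" = 1.10, "working.yes" = 1.35,
      "smoking.yes" = 0.74,
      "autonomy.yes" = 1.17, "beating_attitude.yes" = 1.25,
      "husband_education.primary" = 1.17,
      "husband_education.secondary_plus" = 0.97,
      "husband_working.yes" = 0.93, "husband_alcohol.yes" = 2.55),
    sexual = c(
      "age_group.25_34" = 1.04, "age_group.35_49" = 1.01,
      "residence.rural" = 1.32,
      "education.primary" = 1.04, "education.secondary_plus" = 0.77,
      "wealth.poorer" = 1.24, "wealth.middle" = 1.22,
      "wealth.richer" = 1.32, "wealth.richest" = 1.20,
      "media_exposure.yes" = 0.95, "working.yes" = 1.63,
      "pregnant.yes" = 1.06,
      "autonomy.yes" = 0.76, "beating_attitude.yes" = 1.55,
      "husband_education.primary" = 1.06,
      "husband_education.secondary_plus" = 0.84,
      "husband_working.yes" = 1.12, "husband_alcohol.yes" = 2.24)
  )
  latent_or <- c(physical = 1.92, emotional = 2.32, sexual = 1.82)
  dummy_cols <- spec_dummy_cols(spec)
  beta <- lapply(names(spec$outcomes), function(d) {
    b <- setNames(rep(0, length(dummy_cols[[d]])), dummy_cols[[d]])
    known <- intersect(names(b), names(aor[[d]]))
    b[known] <- log(aor[[d]][known])
    b
  })
  names(beta) <- names(spec$outcomes)
  gamma <- setNames(log(latent_or[names(spec$outcomes)]),
                    names(spec$outcomes))

  J <- length(spec$indicators)
  lambda <- setNames(rep(1, J), spec$indicators)
  quad <- gh_quadrature(40)
  tau <- setNames(
    vapply(seq_len(J), function(j) {
      calibrate_indicator_intercept(indicator_prev, lambda[j], quad)
    }, numeric(1)),
    spec$indicators)
  alpha <- setNames(
    vapply(names(spec$outcomes), function(d) {
      calibrate_intercept(domain_prev[[d]], beta[[d]], gamma[[d]],
                          spec, margins, quad)
    }, numeric(1)),
    names(spec$outcomes))
  gsem_params(tau, lambda, alpha, beta, gamma)
}
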