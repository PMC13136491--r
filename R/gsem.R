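## Latent-factor generalized SEM for the three IPV domains.
##
## One standard-normal latent factor (husband controlling behaviour) is
## measured by J binary indicator items through logit links and enters the
## three binary outcome equations alongside observed covariates, also
## through logit links. The latent factor is integrated out of the
## likelihood by Gauss-Hermite quadrature and the weighted (pseudo-)
## log-likelihood is maximized by BFGS with analytic gradients. Identified
## with latent variance 1 and free loadings; the sign convention
## (first loading positive) resolves the reflection invariance.

outcome_columns <- c(physical = "phys_ipv", emotional = "emo_ipv",
                     sexual = "sex_ipv")

## assemble the numeric model matrices the likelihood core needs
gsem_matrices <- function(data, spec) {
  J <- length(spec$indicators)
  miss <- setdiff(spec$indicators, names(data))
  if (length(miss)) {
    stop("indicator column(s) missing from data: ",
         paste(miss, collapse = ", "))
  }
  Y <- as.matrix(data[spec$indicators])
  storage.mode(Y) <- "double"

  ocols <- vapply(names(spec$outcomes), function(d) {
    if (d %in% names(data)) d
    else if (!is.na(outcome_columns[d]) && outcome_columns[d] %in% names(data)) {
      outcome_columns[[d]]
    } else stop("outcome column for '", d, "' not found in data")
  }, character(1))
  V <- as.matrix(data[ocols])
  storage.mode(V) <- "double"
  colnames(V) <- names(spec$outcomes)

  for (j in seq_len(ncol(Y))) {
    if (sd(Y[, j]) == 0) {
      stop("indicator '", spec$indicators[j], "' has zero variance")
    }
  }
  for (d in seq_len(ncol(V))) {
    if (sd(V[, d]) == 0) {
      stop("outcome '", colnames(V)[d], "' has zero variance")
    }
  }

  used <- unique(unlist(spec$outcomes))
  X <- dummy_matrix(data[used], spec$factors[used])
  dummy_cols <- spec_dummy_cols(spec)
  xcols <- lapply(dummy_cols, function(cc) {
    match(cc, colnames(X)) - 1L  # 0-based for the C++ core
  })
  list(Y = Y, V = V, X = X, xcols = xcols, dummy_cols = dummy_cols,
       w = data$weight %||% rep(1, nrow(Y)),
       psu = data$psu %||% seq_len(nrow(Y)))
}

ll_call <- function(theta, skeleton, mats, quad, want_grad = FALSE,
                    want_scores = FALSE) {
  p <- unpack_params(theta, skeleton)
  gsem_ll_cpp(p$tau, p$lambda, p$alpha,
              lapply(p$beta, unname), p$gamma,
              mats$Y, mats$V, mats$X, lapply(mats$xcols, as.integer),
              mats$w, quad$nodes, quad$weights,
              want_grad, want_scores)
}

#' Weighted marginal log-likelihood of the IPV generalized SEM
#'
#' Each woman contributes \eqn{w_i \log \int \prod_j Bern(y_{ij};
#' logit^{-1}(\tau_j + \lambda_j\eta)) \prod_d Bern(v_{id};
#' logit^{-1}(\alpha_d + x_i'\beta_d + \gamma_d\eta)) \phi(\eta) d\eta},
#' the integral evaluated by the supplied quadrature rule. Weights are used
#' exactly as given (the fitting routine normalizes them to mean 1 first;
#' this function does not).
#'
#' @param params a \code{gsem_params} object.
#' @param data an \code{ipv_data} analysis table.
#' @param spec model structure.
#' @param quad quadrature rule from \code{\link{gh_quadrature}}.
#' @return the weighted log-likelihood (a single number).
#' @export
joint_loglik <- function(params, data, spec = default_gsem_spec(),
                         quad = gh_quadrature(15)) {
  mats <- gsem_matrices(data, spec)
  if (any(!is.finite(mats$w)) || any(is.na(mats$Y)) || any(is.na(mats$V))) {
    stop("data contain missing or non-finite values")
  }
  ll_call(pack_params(params), params, mats, quad)$loglik
}

## starting values: marginal logits for intercepts, separate weighted
## logistic fits for the structural coefficients, unit loadings, 0.5 latent
## effects
gsem_start <- function(mats, spec) {
  w <- mats$w
  marg_logit <- function(y) {
    p <- min(max(sum(w * y) / sum(w), 1e-4), 1 - 1e-4)
    logit(p)
  }
  tau <- setNames(apply(mats$Y, 2, marg_logit), spec$indicators)
  lambda <- setNames(rep(1, ncol(mats$Y)), spec$indicators)
  alpha <- numeric(ncol(mats$V))
  names(alpha) <- colnames(mats$V)
  beta <- list()
  for (d in colnames(mats$V)) {
    Xd <- mats$X[, mats$xcols[[d]] + 1L, drop = FALSE]
    fit <- suppressWarnings(
      glm.fit(cbind(1, Xd), mats$V[, d], weights = w,
              family = quasibinomial()))
    cf <- fit$coefficients
    cf[!is.finite(cf)] <- 0
    alpha[d] <- cf[1]
    beta[[d]] <- setNames(cf[-1], mats$dummy_cols[[d]])
  }
  gamma <- setNames(rep(0.5, ncol(mats$V)), colnames(mats$V))
  gsem_params(tau, lambda, alpha, beta, gamma)
}

#' Fit the latent-factor generalized SEM for IPV
#'
#' Maximizes the design-weighted marginal likelihood (weights normalized to
#' mean 1, i.e. pseudo-maximum likelihood) by BFGS with analytic gradients,
#' integrating the latent factor with non-adaptive Gauss-Hermite
#' quadrature. The fit is declared converged when the gradient of the
#' per-observation average log-likelihood has max-norm below \code{1e-5}
#' and a polishing restart improves the log-likelihood by less than
#' \code{1e-8} in relative terms. The reported variance-covariance matrix
#' is the PSU-clustered sandwich estimator when \code{cluster = TRUE}
#' (inverse observed information otherwise).
#'
#' @param data an \code{ipv_data} analysis table from
#'   \code{\link{build_analysis_table}} (any data.frame with the indicator,
#'   outcome, weight and psu columns works).
#' @param spec model structure, see \code{\link{default_gsem_spec}}.
#' @param quad_order number of Gauss-Hermite nodes (default 15).
#' @param start optional \code{gsem_params} starting values.
#' @param fixed optional named vector of packed parameter values to hold
#'   fixed (e.g. all loadings and latent effects at 0 to reduce the model
#'   to independent logistic regressions).
#' @param cluster compute the PSU-clustered sandwich vcov (default TRUE).
#' @param max_iter BFGS iteration cap per run (default 500).
#' @param compute_vcov set \code{FALSE} to skip variance estimation.
#' @return object of class \code{ipv_gsem}.
#' @export
ipv_gsem <- function(data, spec = default_gsem_spec(), quad_order = 15,
                     start = NULL, fixed = NULL, cluster = TRUE,
                     max_iter = 500, compute_vcov = TRUE) {
  cl <- match.call()
  mats <- gsem_matrices(data, spec)
  n <- nrow(mats$Y)
  if (n == 0L) stop("no data rows")
  if (any(is.na(mats$Y)) || any(is.na(mats$V)) || any(is.na(mats$X))) {
    stop("data contain missing values; build a complete-case table first")
  }
  if (any(mats$w <= 0)) stop("weights must be positive")
  mats$w <- mats$w / mean(mats$w)
  quad <- gh_quadrature(quad_order)

  skeleton <- start %||% gsem_start(mats, spec)
  theta <- pack_params(skeleton)
  free <- rep(TRUE, length(theta))
  names(free) <- names(theta)
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), names(theta))
    if (length(unknown)) {
      stop("unknown fixed parameter(s): ", paste(unknown, collapse = ", "))
    }
    theta[names(fixed)] <- fixed
    free[names(fixed)] <- FALSE
  }

  ## memoized objective on the free subset, per-observation scale
  last <- new.env(parent = emptyenv())
  evaluate <- function(th_free) {
    if (!is.null(last$th) && identical(last$th, th_free)) return(last$res)
    th <- theta
    th[free] <- th_free
    res <- ll_call(th, skeleton, mats, quad, want_grad = TRUE)
    last$th <- th_free
    last$res <- res
    res
  }
  fn <- function(th_free) -evaluate(th_free)$loglik / n
  gr <- function(th_free) -evaluate(th_free)$grad[free] / n

  opt <- optim(theta[free], fn, gr, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  ll1 <- -opt$value * n
  ## polishing restart: also operationalizes the relative-change criterion
  opt2 <- optim(opt$par, fn, gr, method = "BFGS",
                control = list(maxit = max_iter, reltol = 1e-12))
  ll2 <- -opt2$value * n
  theta[free] <- opt2$par

  g <- ll_call(theta, skeleton, mats, quad, want_grad = TRUE)$grad
  grad_max <- max(abs(g[free])) / n
  rel_change <- abs(ll2 - ll1) / max(1, abs(ll2))
  converged <- grad_max < 1e-5 && rel_change < 1e-8
  if (!converged) {
    warning("GSEM fit did not meet convergence criteria (scaled gradient ",
            format(grad_max, digits = 3), ", relative change ",
            format(rel_change, digits = 3), ")")
  }

  ## reflection: flip the factor so the first free loading is positive
  J <- length(spec$indicators)
  lam_idx <- J + seq_len(J)
  gam_idx <- length(theta) - length(spec$outcomes) +
    seq_along(spec$outcomes)
  first_free_lam <- lam_idx[free[lam_idx]][1]
  if (!is.na(first_free_lam) && theta[first_free_lam] < 0) {
    flip <- c(lam_idx, gam_idx)
    flip <- flip[free[flip]]
    theta[flip] <- -theta[flip]
  }
  if (any(abs(theta[free]) > 15)) {
    warning("possible separation: fitted |coefficient| > 15 for ",
            paste(names(theta[free])[abs(theta[free]) > 15], collapse = ", "))
  }

  params <- unpack_params(theta, skeleton)
  loglik <- ll_call(theta, skeleton, mats, quad)$loglik
  p_free <- sum(free)
  fit <- structure(list(
    params = params, theta = theta, free = free, spec = spec,
    loglik = loglik, n = n, n_params = p_free,
    aic = -2 * loglik + 2 * p_free,
    bic = -2 * loglik + p_free * log(n),
    quad_order = quad_order, converged = converged,
    grad_max = grad_max, iterations = opt$counts[["function"]] +
      opt2$counts[["function"]],
    cluster = cluster, n_clusters = length(unique(mats$psu)),
    model = mats, call = cl), class = "ipv_gsem")

  if (compute_vcov) {
    info <- observed_information(theta, free, skeleton, mats, quad)
    fit$info <- info
    fit$vcov_independence <- solve_psd(info)
    fit$vcov <- if (cluster) robust_vcov(fit) else fit$vcov_independence
  }
  fit
}

## observed information (negative Hessian of the summed log-likelihood)
## over the free parameters, by central differences of the analytic gradient
observed_information <- function(theta, free, skeleton, mats, quad,
                                 h_rel = 1e-5) {
  idx <- which(free)
  p <- length(idx)
  H <- matrix(0, p, p)
  for (m in seq_len(p)) {
    h <- h_rel * max(1, abs(theta[idx[m]]))
    tp <- theta; tp[idx[m]] <- tp[idx[m]] + h
    tm <- theta; tm[idx[m]] <- tm[idx[m]] - h
    gp <- ll_call(tp, skeleton, mats, quad, want_grad = TRUE)$grad[idx]
    gm <- ll_call(tm, skeleton, mats, quad, want_grad = TRUE)$grad[idx]
    H[, m] <- -(gp - gm) / (2 * h)
  }
  H <- (H + t(H)) / 2
  dimnames(H) <- list(names(theta)[idx], names(theta)[idx])
  H
}

## inverse of a (near-)PSD information matrix, with a pseudo-inverse
## fallback and a report of the offending block when singular
solve_psd <- function(H) {
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(out)) {
    ev <- eigen(H, symmetric = TRUE)
    if (all(ev$values < sqrt(.Machine$double.eps) * max(abs(ev$values)))) {
      stop("information matrix is singular")
    }
    bad <- colnames(H)[abs(ev$vectors[, which.min(ev$values)]) > 0.3]
    warning("information matrix nearly singular; affected parameter(s): ",
            paste(bad, collapse = ", "), "; using pseudo-inverse")
    keep <- ev$values > sqrt(.Machine$double.eps) * max(ev$values)
    out <- ev$vectors[, keep, drop = FALSE] %*%
      diag(1 / ev$values[keep], sum(keep)) %*%
      t(ev$vectors[, keep, drop = FALSE])
    dimnames(out) <- dimnames(H)
  }
  (out + t(out)) / 2
}

#' Cluster-robust (sandwich) covariance of a GSEM fit
#'
#' Bread is the inverse observed information; meat is the outer product of
#' PSU-summed weighted score vectors with the usual \eqn{G/(G-1)}
#' small-sample factor. With one unit per cluster and unit weights this is
#' the heteroscedasticity-robust sandwich.
#'
#' @param fit a converged \code{ipv_gsem} fit.
#' @param cluster optional replacement cluster ids (defaults to the PSU ids
#'   the model was fitted with).
#' @return covariance matrix over the free parameters.
#' @export
robust_vcov <- function(fit, cluster = NULL) {
  stopifnot(inherits(fit, "ipv_gsem"))
  if (is.null(fit$info)) {
    stop("fit carries no information matrix (compute_vcov = FALSE)")
  }
  cluster <- cluster %||% fit$model$psu
  quad <- gh_quadrature(fit$quad_order)
  sc <- ll_call(fit$theta, fit$params, fit$model, quad,
                want_scores = TRUE)$scores[, fit$free, drop = FALSE]
  cl <- as.factor(cluster)
  G <- nlevels(cl)
  S <- rowsum(sc, cl)
  meat <- crossprod(S) * if (G > 1) G / (G - 1) else 1
  bread <- solve_psd(fit$info)
  v <- bread %*% meat %*% bread
  v <- (v + t(v)) / 2
  dimnames(v) <- dimnames(fit$info)
  v
}

#' Adjusted odds ratio table of a GSEM fit
#'
#' Structural coefficients (covariates and the latent HCB effect per
#' outcome) exponentiated to adjusted odds ratios with Wald confidence
#' intervals and p-values; significance declared at p < 0.05.
#'
#' @param fit an \code{ipv_gsem} fit with a covariance matrix.
#' @param conf_level confidence level.
#' @return data.frame with columns \code{outcome}, \code{term}, \code{aor},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{significant}.
#' @export
aor_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "ipv_gsem"))
  if (is.null(fit$vcov)) stop("fit carries no covariance matrix")
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_of <- function(nm) {
    if (nm %in% rownames(fit$vcov)) sqrt(fit$vcov[nm, nm]) else NA_real_
  }
  rows <- list()
  for (d in names(fit$spec$outcomes)) {
    terms <- c(setNames(paste0("beta.", d, ".", names(fit$params$beta[[d]])),
                        names(fit$params$beta[[d]])),
               hcb = paste0("gamma.", d))
    for (i in seq_along(terms)) {
      est <- fit$theta[[terms[i]]]
      se <- se_of(terms[i])
      pv <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(est / se))
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = d, term = names(terms)[i], estimate = est,
        aor = exp(est),
        ci_low = exp(est - z * se), ci_high = exp(est + z * se),
        p_value = pv,
        significant = !is.na(pv) & pv < 0.05)
    }
  }
  do.call(rbind, rows)
}

#' Rank fitted models by information criteria
#'
#' @param ... two or more \code{ipv_gsem} fits on the same data.
#' @param by criterion used for the ordering, \code{"aic"} or \code{"bic"};
#'   ties are broken by fewer parameters.
#' @return data.frame ranked best-first with log-likelihood, parameter
#'   count, AIC and BIC.
#' @export
compare_models <- function(..., by = c("aic", "bic")) {
  by <- match.arg(by)
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "ipv_gsem")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "ipv_gsem")))
  if (length(unique(vapply(fits, `[[`, numeric(1), "n"))) != 1L) {
    stop("models were fitted to differing numbers of observations")
  }
  nm <- names(fits) %||% paste0("model_", seq_along(fits))
  nm[nm == ""] <- paste0("model_", which(nm == ""))
  tab <- data.frame(
    model = nm,
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  tab <- tab[order(tab[[by]], tab$n_params), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
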