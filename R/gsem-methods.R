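#' @export
print.ipv_gsem <- function(x, ...) {
  cat("Latent-factor generalized SEM for IPV (logit links)\n")
  cat(sprintf("  n = %d women, %d PSUs; %d free parameters; GH order %d\n",
              x$n, x$n_clusters, x$n_params, x$quad_order))
  cat(sprintf("  log-likelihood %.2f, AIC %.2f, BIC %.2f%s\n",
              x$loglik, x$aic, x$bic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  Latent effects (odds ratio per SD of the factor):\n")
  or <- exp(x$params$gamma)
  for (d in names(or)) cat(sprintf("    %-10s %.3f\n", d, or[d]))
  invisible(x)
}

#' @export
coef.ipv_gsem <- function(object, ...) object$theta

#' @export
vcov.ipv_gsem <- function(object, ...) object$vcov

#' @export
logLik.ipv_gsem <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
confint.ipv_gsem <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$vcov)) stop("fit carries no covariance matrix")
  est <- object$theta[rownames(object$vcov)]
  se <- sqrt(diag(object$vcov))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.ipv_gsem <- function(object, conf_level = 0.95, ...) {
  meas <- data.frame(
    indicator = object$spec$indicators,
    intercept = unname(object$params$tau),
    loading = unname(object$params$lambda))
  structure(list(fit = object, measurement = meas,
                 aor = aor_table(object, conf_level)),
            class = "summary.ipv_gsem")
}

#' @export
print.summary.ipv_gsem <- function(x, digits = 3, ...) {
  print(x$fit)
  cat("\nMeasurement model (latent variance fixed at 1):\n")
  print(format(x$measurement, digits = digits), row.names = FALSE)
  cat("\nAdjusted odds ratios (* significant at p < 0.05):\n")
  tab <- x$aor
  tab$aor <- sprintf("%.2f (%.2f-%.2f)%s", tab$aor, tab$ci_low,
                     tab$ci_high, ifelse(tab$significant, "*", ""))
  print(tab[, c("outcome", "term", "aor")], row.names = FALSE)
  invisible(x)
}

#' Marginal outcome probabilities from a GSEM fit
#'
#' Population-averaged probability of each IPV domain given covariates,
#' integrating the latent factor over its N(0,1) distribution with the
#' fit's quadrature rule.
#'
#' @param object an \code{ipv_gsem} fit.
#' @param newdata optional data.frame with the covariate factor columns;
#'   defaults to the fitting data.
#' @param type \code{"response"} for probabilities, \code{"link"} for the
#'   linear predictor at latent value 0.
#' @param ... unused.
#' @return numeric matrix, one column per outcome.
#' @export
predict.ipv_gsem <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  spec <- object$spec
  if (is.null(newdata)) {
    X <- object$model$X
    xcols <- object$model$xcols
  } else {
    used <- unique(unlist(spec$outcomes))
    X <- dummy_matrix(newdata[used], spec$factors[used])
    xcols <- lapply(spec_dummy_cols(spec), function(cc) {
      match(cc, colnames(X)) - 1L
    })
  }
  quad <- gh_quadrature(object$quad_order)
  out <- sapply(names(spec$outcomes), function(d) {
    eta <- object$params$alpha[[d]] +
      as.vector(X[, xcols[[d]] + 1L, drop = FALSE] %*%
                  object$params$beta[[d]])
    if (type == "link") return(eta)
    lin <- outer(eta, object$params$gamma[[d]] * quad$nodes, `+`)
    as.vector(invlogit(lin) %*% quad$weights)
  })
  matrix(out, ncol = length(spec$outcomes),
         dimnames = list(NULL, names(spec$outcomes)))
}

#' @export
residuals.ipv_gsem <- function(object, type = c("pearson", "response"),
                               ...) {
  type <- match.arg(type)
  phat <- predict(object)
  res <- object$model$V - phat
  if (type == "pearson") res <- res / sqrt(phat * (1 - phat))
  res
}

#' Simulate indicator and outcome data from a fitted GSEM
#'
#' Draws a fresh latent factor for every woman and regenerates the binary
#' indicators and domain outcomes at the fitted parameters, holding the
#' covariates at their observed values (a parametric-bootstrap draw).
#'
#' @param object an \code{ipv_gsem} fit.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of \code{nsim} data.frames.
#' @export
simulate.ipv_gsem <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    p <- object$params
    n <- object$n
    eta <- rnorm(n)
    Y <- sapply(seq_along(p$tau), function(j) {
      rbinom(n, 1, invlogit(p$tau[j] + p$lambda[j] * eta))
    })
    colnames(Y) <- names(p$tau)
    V <- sapply(names(object$spec$outcomes), function(d) {
      lin <- p$alpha[[d]] +
        as.vector(object$model$X[, object$model$xcols[[d]] + 1L,
                                 drop = FALSE] %*% p$beta[[d]]) +
        p$gamma[[d]] * eta
      rbinom(n, 1, invlogit(lin))
    })
    data.frame(Y, V)
  }
  run <- function() replicate(nsim, draw(), simplify = FALSE)
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Forest-style plot of adjusted odds ratios
#'
#' @param x an \code{ipv_gsem} fit.
#' @param outcome which outcome equation to display.
#' @param ... passed to \code{plot}.
#' @return invisibly, the AOR table plotted.
#' @export
plot.ipv_gsem <- function(x, outcome = names(x$spec$outcomes)[1], ...) {
  tab <- aor_table(x)
  tab <- tab[tab$outcome == outcome, , drop = FALSE]
  k <- nrow(tab)
  yy <- rev(seq_len(k))
  rng <- range(c(tab$ci_low, tab$ci_high, 1), na.rm = TRUE)
  graphics::plot(NA, xlim = rng, ylim = c(0.5, k + 0.5), log = "x",
                 yaxt = "n", xlab = "Adjusted odds ratio",
                 ylab = "", main = paste("Outcome:", outcome), ...)
  graphics::axis(2, at = yy, labels = tab$term, las = 1, cex.axis = 0.7)
  graphics::segments(tab$ci_low, yy, tab$ci_high, yy)
  graphics::points(tab$aor, yy, pch = 15)
  graphics::abline(v = 1, lty = 3)
  invisible(tab)
}
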