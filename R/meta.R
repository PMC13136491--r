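## Random-effects meta-analysis of prevalences (DerSimonian-Laird).
##
## Study proportions are pooled on the logit scale. Heterogeneity is
## summarized by Cochran's Q, the moment estimator of the between-study
## variance tau^2, and I2 = max(0, 100 * (Q - df) / Q).

#' Logit transform of a prevalence with its sampling variance
#'
#' \eqn{\theta = \log(p/(1-p))}, \eqn{var(\theta) = 1/(np) + 1/(n(1-p))}.
#' Degenerate proportions (0 or 1) receive the continuity correction
#' \code{0.5/(n+1)} events before transforming.
#'
#' @param p proportion(s) in [0, 1].
#' @param n sample size(s).
#' @return data.frame with columns \code{theta} and \code{var}.
#' @export
logit_transform <- function(p, n) {
  stopifnot(length(p) == length(n), all(n > 0),
            all(p >= 0), all(p <= 1))
  adj <- p == 0 | p == 1
  p[adj & p == 0] <- 0.5 / (n[adj & p == 0] + 1)
  p[adj & p == 1] <- 1 - 0.5 / (n[adj & p == 1] + 1)
  data.frame(theta = logit(p), var = 1 / (n * p) + 1 / (n * (1 - p)))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator on any effect scale: fixed-effect weights \eqn{w_i =
#' 1/v_i} give \eqn{Q = \sum w_i(\theta_i - \bar\theta)^2};
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i))};
#' random-effects weights \eqn{1/(v_i + \tau^2)} give the pooled estimate
#' and its Wald confidence interval. For a single study the pooled estimate
#' is that study's, with Q = 0 and I2 defined as 0.
#'
#' @param thetas study effect estimates.
#' @param vars their sampling variances (all positive).
#' @param conf_level confidence level.
#' @return list with \code{pooled}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{tau2}, \code{Q}, \code{df}, \code{I2},
#'   \code{p_het}, \code{weights_re} (normalized to percent).
#' @export
dersimonian_laird <- function(thetas, vars, conf_level = 0.95) {
  k <- length(thetas)
  if (k == 0L) stop("no studies to pool")
  stopifnot(length(vars) == k, all(vars > 0))
  w <- 1 / vars
  theta_fe <- sum(w * thetas) / sum(w)
  Q <- sum(w * (thetas - theta_fe)^2)
  df <- k - 1L
  tau2 <- if (k > 1) {
    max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  } else 0
  I2 <- if (Q > 0) max(0, 100 * (Q - df) / Q) else 0
  p_het <- if (df > 0) pchisq(Q, df, lower.tail = FALSE) else NA_real_
  wr <- 1 / (vars + tau2)
  pooled <- sum(wr * thetas) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(pooled = pooled, se = se,
       ci_low = pooled - z * se, ci_high = pooled + z * se,
       tau2 = tau2, Q = Q, df = df, I2 = I2, p_het = p_het,
       weights_re = 100 * wr / sum(wr))
}

#' Pool country prevalences into an overall estimate
#'
#' Applies the logit transform, DerSimonian-Laird random-effects pooling and
#' the back-transform to the proportion scale, and returns per-country rows
#' ready for a forest plot.
#'
#' @param per_country data.frame with columns \code{p} and \code{n} (and
#'   optionally \code{country} or \code{label}); output of
#'   \code{\link{country_prevalence}} works directly.
#' @param conf_level confidence level.
#' @return object of class \code{ipv_meta}: pooled prevalence with CI,
#'   heterogeneity statistics (\code{tau2} on the logit scale, \code{Q},
#'   \code{I2}, \code{p_het}) and a \code{per_study} data.frame.
#' @export
pool_country_prevalence <- function(per_country, conf_level = 0.95) {
  stopifnot(is.data.frame(per_country), nrow(per_country) >= 1,
            all(c("p", "n") %in% names(per_country)))
  labels <- per_country$label %||% per_country$country %||%
    paste0("study_", seq_len(nrow(per_country)))
  tr <- logit_transform(per_country$p, per_country$n)
  dl <- dersimonian_laird(tr$theta, tr$var, conf_level)
  z <- qnorm(1 - (1 - conf_level) / 2)
  per_study <- data.frame(
    label = as.character(labels),
    p = per_country$p, n = per_country$n,
    ci_low = invlogit(tr$theta - z * sqrt(tr$var)),
    ci_high = invlogit(tr$theta + z * sqrt(tr$var)),
    weight_percent = dl$weights_re)
  structure(list(pooled_p = invlogit(dl$pooled),
                 ci_low = invlogit(dl$ci_low),
                 ci_high = invlogit(dl$ci_high),
                 tau2 = dl$tau2, Q = dl$Q, df = dl$df, I2 = dl$I2,
                 p_het = dl$p_het, conf_level = conf_level,
                 per_study = per_study),
            class = "ipv_meta")
}

#' @export
print.ipv_meta <- function(x, digits = 2, ...) {
  cat("Random-effects (DerSimonian-Laird) pooled prevalence\n")
  cat(sprintf("  Pooled: %.*f%% (%g%% CI %.*f, %.*f), k = %d countries\n",
              digits, 100 * x$pooled_p, 100 * x$conf_level,
              digits, 100 * x$ci_low, digits, 100 * x$ci_high,
              nrow(x$per_study)))
  cat(sprintf("  Heterogeneity: Q = %.2f (df = %d, p %s), tau^2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df,
              if (is.na(x$p_het)) "= NA" else sprintf("= %.3g", x$p_het),
              x$tau2, x$I2))
  invisible(x)
}

#' Forest plot of a pooled prevalence
#'
#' @param x an \code{ipv_meta} object.
#' @param xlab x-axis label.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{x}.
#' @export
plot.ipv_meta <- function(x, xlab = "Prevalence (%)", ...) {
  ps <- x$per_study
  k <- nrow(ps)
  yy <- rev(seq_len(k + 1))
  graphics::plot(NA, xlim = c(0, 100), ylim = c(0.5, k + 1.5), yaxt = "n",
                 xlab = xlab, ylab = "", ...)
  graphics::axis(2, at = yy, labels = c(ps$label, "Pooled"), las = 1,
                 cex.axis = 0.8)
  graphics::segments(100 * ps$ci_low, yy[seq_len(k)],
                     100 * ps$ci_high, yy[seq_len(k)])
  graphics::points(100 * ps$p, yy[seq_len(k)], pch = 15,
                   cex = 0.5 + ps$weight_percent / max(ps$weight_percent))
  graphics::segments(100 * x$ci_low, yy[k + 1], 100 * x$ci_high, yy[k + 1],
                     lwd = 2)
  graphics::points(100 * x$pooled_p, yy[k + 1], pch = 18, cex = 1.5)
  graphics::abline(v = 100 * x$pooled_p, lty = 3)
  invisible(x)
}
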