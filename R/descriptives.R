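## Design-weighted descriptive statistics.
##
## Variance of a weighted proportion uses Taylor linearization of the ratio
## estimator p = sum(w*x)/sum(w). With PSU cluster ids the score totals are
## aggregated within PSU before the between-cluster variance is formed
## (with-replacement first-stage approximation, the standard treatment of
## two-stage survey designs); without cluster ids, units are treated as
## independent. Confidence intervals are Wald intervals on the logit scale,
## which respects the [0,1] bounds.

#' Design-weighted proportion with confidence interval
#'
#' @param x binary (0/1) vector.
#' @param w positive sampling weights.
#' @param psu optional cluster ids for Taylor-linearized cluster variance.
#' @param strata optional stratum ids (clusters are nested in strata).
#' @param conf_level confidence level (default 0.95).
#' @return object of class \code{prevalence_estimate}: list with \code{p},
#'   \code{ci_low}, \code{ci_high}, \code{se}, \code{n_unweighted},
#'   \code{n_weighted}, \code{method}, \code{degenerate}.
#' @details At the degenerate proportions 0 and 1 the logit interval is
#'   undefined; the estimate is then returned with an exact-style one-sided
#'   Clopper-Pearson bound on the unweighted count and flagged
#'   \code{degenerate = TRUE}.
#' @examples
#' weighted_proportion(c(1, 0), c(3, 1))$p  # 0.75
#' @export
weighted_proportion <- function(x, w, psu = NULL, strata = NULL,
                                conf_level = 0.95) {
  if (length(x) == 0L) stop("empty input")
  stopifnot(length(x) == length(w), all(x %in% c(0, 1)))
  if (all(w == 0)) stop("all weights are zero")
  if (any(w < 0) || any(is.na(w))) stop("weights must be positive")
  n <- length(x)
  W <- sum(w)
  p <- sum(w * x) / W
  z <- qnorm(1 - (1 - conf_level) / 2)

  method <- if (is.null(psu)) "independence" else "cluster-robust"
  if (p <= 0 || p >= 1) {
    ## exact-style one-sided bound on the unweighted count
    if (p <= 0) {
      ci <- c(0, 1 - ((1 - conf_level) / 2)^(1 / n))
    } else {
      ci <- c(((1 - conf_level) / 2)^(1 / n), 1)
    }
    return(structure(list(p = p, ci_low = ci[1], ci_high = ci[2], se = NA_real_,
                          n_unweighted = n, n_weighted = W, method = method,
                          degenerate = TRUE),
                     class = "prevalence_estimate"))
  }

  u <- w * (x - p) / W  # linearized score of the ratio estimator
  if (is.null(psu)) {
    v <- n / (n - 1) * sum(u^2)
  } else {
    stopifnot(length(psu) == n)
    if (is.null(strata)) strata <- rep(1L, n)
    v <- 0
    for (h in unique(strata)) {
      sel <- strata == h
      tot <- tapply(u[sel], psu[sel], sum)
      g <- length(tot)
      v <- v + if (g > 1) g / (g - 1) * sum((tot - mean(tot))^2) else 0
    }
  }
  se <- sqrt(v)
  se_logit <- se / (p * (1 - p))
  ci <- invlogit(logit(p) + c(-1, 1) * z * se_logit)
  structure(list(p = p, ci_low = ci[1], ci_high = ci[2], se = se,
                 n_unweighted = n, n_weighted = W, method = method,
                 degenerate = FALSE),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted proportion: %.*f (%d%% CI %.*f-%.*f), n = %d [%s]\n",
              digits, x$p, 95, digits, x$ci_low, digits, x$ci_high,
              x$n_unweighted, x$method))
  invisible(x)
}

#' Weighted frequency table
#'
#' @param var categorical vector (factor or character).
#' @param w weights (default all 1, i.e. unweighted counts).
#' @param digits decimals for the percent column (half-up rounding, as in
#'   printed survey tables).
#' @return data.frame with columns \code{level}, \code{freq_weighted},
#'   \code{percent}; percents sum to 100 up to rounding.
#' @export
frequency_table <- function(var, w = rep(1, length(var)), digits = 2) {
  if (length(var) == 0L) stop("empty column")
  stopifnot(length(var) == length(w))
  keep <- !is.na(var)
  var <- var[keep]
  w <- w[keep]
  if (!is.factor(var)) var <- factor(var, levels = unique(var))
  freq <- tapply(w, var, sum, default = 0)
  total <- sum(freq)
  data.frame(level = names(freq),
             freq_weighted = as.numeric(freq),
             percent = round_half_up(100 * as.numeric(freq) / total, digits),
             row.names = NULL)
}

#' Per-country weighted prevalence of an outcome
#'
#' @param data an \code{ipv_data} analysis table (or any data.frame with
#'   \code{country}, \code{psu}, \code{weight} and the outcome column).
#' @param outcome outcome column name (default overall IPV).
#' @param cluster use PSU-clustered variance (default TRUE).
#' @return data.frame with one row per country: \code{country}, \code{p},
#'   \code{ci_low}, \code{ci_high}, \code{n}, \code{n_weighted}.
#' @export
country_prevalence <- function(data, outcome = "any_ipv", cluster = TRUE) {
  stopifnot(outcome %in% names(data))
  countries <- unique(data$country)
  rows <- lapply(countries, function(cc) {
    sel <- data$country == cc
    if (!any(sel)) stop("country with zero rows: ", cc)
    est <- weighted_proportion(
      data[[outcome]][sel], data$weight[sel],
      psu = if (cluster) data$psu[sel] else NULL,
      strata = if (cluster && "stratum" %in% names(data)) {
        data$stratum[sel]
      } else NULL)
    data.frame(country = cc, p = est$p, ci_low = est$ci_low,
               ci_high = est$ci_high, n = est$n_unweighted,
               n_weighted = est$n_weighted)
  })
  do.call(rbind, rows)
}
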