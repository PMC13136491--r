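## Synthetic DHS-style survey generator.
##
## Emulates stratified two-stage cluster sampling: PSUs (enumeration areas)
## selected with probability proportional to a census size measure, then a
## fixed number of women per PSU with equal probability from the PSU's
## current listing. Design weights are products of inverse stage-selection
## probabilities; weight variation arises because the census size used for
## stage-1 selection is an outdated measure of the current PSU size.

#' Violence act items per IPV domain
#'
#' Seven act groups for physical violence (pushing/shaking, slapping or arm
#' twisting, punching, kicking or beating, choking, burning, weapon threat),
#' three for sexual and three for emotional violence, mirroring the standard
#' DHS domestic-violence module.
#'
#' @return named list of character vectors of act item names.
#' @export
ipv_act_items <- function() {
  list(
    physical = c("push_shake_throw", "slap_twist_pull", "punch",
                 "kick_drag_beat", "choke", "burn", "weapon_threat"),
    emotional = c("humiliate", "threaten_harm", "insult"),
    sexual = c("forced_intercourse", "forced_acts", "forced_other")
  )
}

## raw-item code sets
media_codes <- c("not_at_all", "less_than_once_week", "at_least_once_week")
freq_codes <- c("not_at_all", "sometimes", "often")
decision_codes <- c("self", "joint", "other")
decision_items <- c("decide_health", "decide_purchases", "decide_visits")
attitude_items <- c("beat_goes_out", "beat_neglects_children",
                    "beat_argues", "beat_refuses_sex", "beat_burns_food")

#' Configuration for the survey simulator
#'
#' @param n_countries,psus_per_country,women_per_psu positive integers
#'   giving the design dimensions; the simulated sample has
#'   \code{n_countries * psus_per_country * women_per_psu} women.
#' @param margins covariate category probabilities
#'   (\code{\link{default_covariate_margins}}); each vector must sum to 1.
#' @param true_params generative \code{gsem_params}
#'   (\code{\link{default_true_params}}).
#' @param spec model structure matching \code{true_params}.
#' @param seed integer seed; the same config and seed reproduce the table
#'   exactly.
#' @param country_sd standard deviation of a country-level shift added to
#'   every outcome linear predictor (0 = homogeneous countries).
#' @param psu_sd standard deviation of a PSU-level shift added to every
#'   outcome linear predictor, inducing intra-cluster correlation.
#' @param lifetime_only_rate probability that an act not experienced in the
#'   last 12 months is still reported as ever experienced (with 12-month
#'   frequency "not_at_all").
#' @param act_rate probability that each act in a positive domain is
#'   reported for the last 12 months (at least one act is always forced).
#' @param missing_rate per-cell probability of a missing covariate value.
#' @param joint_sampler optional function \code{function(n)} returning a
#'   data.frame of covariate columns (factor levels as character), replacing
#'   the independent-margins sampler when covariate dependence is wanted.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_countries = 12, psus_per_country = 25,
                       women_per_psu = 20,
                       margins = default_covariate_margins(),
                       true_params = default_true_params(),
                       spec = default_gsem_spec(),
                       seed = 1L,
                       country_sd = 0, psu_sd = 0,
                       lifetime_only_rate = 0.10, act_rate = 0.45,
                       missing_rate = 0, joint_sampler = NULL) {
  counts <- c(n_countries, psus_per_country, women_per_psu)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("design counts must be positive integers")
  }
  for (f in names(margins)) {
    if (abs(sum(margins[[f]]) - 1) > 1e-12) {
      stop("margin for '", f, "' does not sum to 1")
    }
    if (length(margins[[f]]) != length(ipv_factors()[[f]])) {
      stop("margin for '", f, "' has the wrong number of categories")
    }
  }
  stopifnot(inherits(true_params, "gsem_params"),
            inherits(spec, "gsem_spec"),
            country_sd >= 0, psu_sd >= 0,
            lifetime_only_rate >= 0, lifetime_only_rate <= 1,
            act_rate > 0, act_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_countries = n_countries,
                 psus_per_country = psus_per_country,
                 women_per_psu = women_per_psu,
                 margins = margins, true_params = true_params, spec = spec,
                 seed = as.integer(seed),
                 country_sd = country_sd, psu_sd = psu_sd,
                 lifetime_only_rate = lifetime_only_rate,
                 act_rate = act_rate, missing_rate = missing_rate,
                 joint_sampler = joint_sampler),
            class = "sim_config")
}

## sample one categorical column from a margin
sample_factor <- function(n, levels, probs) {
  levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
}

## act-level responses consistent with a domain flag: a positive domain has
## at least one act in the last 12 months; negative-domain (or unused) acts
## may still be lifetime-only reports
simulate_acts <- function(domain_flag, acts, act_rate, lifetime_only_rate) {
  n <- length(domain_flag)
  k <- length(acts)
  recent <- matrix(rbinom(n * k, 1, act_rate), n, k) * domain_flag
  none <- domain_flag == 1 & rowSums(recent) == 0
  if (any(none)) {
    forced <- sample.int(k, sum(none), replace = TRUE)
    recent[cbind(which(none), forced)] <- 1L
  }
  lifetime_only <- matrix(rbinom(n * k, 1, lifetime_only_rate), n, k) *
    (1 - recent)
  out <- list()
  for (j in seq_len(k)) {
    ever <- ifelse(recent[, j] == 1 | lifetime_only[, j] == 1, "yes", "no")
    freq <- ifelse(recent[, j] == 1,
                   ifelse(runif(n) < 0.4, "often", "sometimes"),
                   "not_at_all")
    out[[paste0(acts[j], "_ever")]] <- ever
    out[[paste0(acts[j], "_freq")]] <- freq
  }
  out
}

#' Simulate a woman-level DHS-style survey table
#'
#' Generates the full raw table the derivation stage expects: design columns
#' (country, stratum, PSU, design weight), a standard-normal latent
#' husband-controlling-behaviour score with its binary indicator items,
#' act-level violence items with 12-month frequency codes, raw media,
#' decision-making and wife-beating-attitude items, and categorical
#' covariates. Truth columns (\code{latent_hcb}, \code{true_physical},
#' \code{true_emotional}, \code{true_sexual}) are included for
#' parameter-recovery and round-trip testing; they exist only in simulated
#' data.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with one row per woman and attribute \code{"config"}.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  p <- config$true_params
  spec <- config$spec
  nc <- config$n_countries
  np <- config$psus_per_country
  nw <- config$women_per_psu
  n <- nc * np * nw

  country_id <- rep(seq_len(nc), each = np * nw)
  psu_within <- rep(rep(seq_len(np), each = nw), times = nc)
  psu_id <- (country_id - 1L) * np + psu_within
  ## two strata per country, PSUs split evenly (proxy for region strata)
  stratum_id <- (country_id - 1L) * 2L + ifelse(psu_within <= ceiling(np / 2), 1L, 2L)

  ## two-stage design weights: stage 1 PPS on an outdated census size,
  ## stage 2 equal-probability take of women_per_psu from the current size
  g <- nc * np
  size_census <- pmax(round(exp(rnorm(g, log(200), 0.25))), nw + 5)
  size_current <- pmax(round(size_census * exp(rnorm(g, 0, 0.15))), nw)
  p1 <- numeric(g)
  for (cc in seq_len(nc)) {
    idx <- (cc - 1L) * np + seq_len(np)
    p1[idx] <- pmin(np * size_census[idx] / sum(size_census[idx]), 0.999)
  }
  p2 <- pmin(nw / size_current, 1)
  w_psu <- 1 / (p1 * p2)
  weight <- w_psu[psu_id]
  for (cc in seq_len(nc)) {
    sel <- country_id == cc
    weight[sel] <- weight[sel] / mean(weight[sel])
  }

  ## covariates
  if (is.null(config$joint_sampler)) {
    covs <- as.data.frame(lapply(names(config$margins), function(f) {
      sample_factor(n, spec$factors[[f]], config$margins[[f]])
    }), col.names = names(config$margins), stringsAsFactors = FALSE)
  } else {
    covs <- config$joint_sampler(n)
    stopifnot(is.data.frame(covs), nrow(covs) == n)
  }

  ## latent factor and indicator items
  eta <- rnorm(n)
  Y <- sapply(seq_along(spec$indicators), function(j) {
    rbinom(n, 1, invlogit(p$tau[j] + p$lambda[j] * eta))
  })
  colnames(Y) <- paste0("hcb_", spec$indicators)

  ## outcome domains
  country_re <- if (config$country_sd > 0) {
    rnorm(nc, 0, config$country_sd)[country_id]
  } else 0
  psu_re <- if (config$psu_sd > 0) {
    rnorm(g, 0, config$psu_sd)[psu_id]
  } else 0
  X <- dummy_matrix(covs, spec$factors)
  domains <- sapply(names(spec$outcomes), function(d) {
    lin <- p$alpha[[d]] + as.vector(X[, names(p$beta[[d]]), drop = FALSE] %*%
                                      p$beta[[d]]) +
      p$gamma[[d]] * eta + country_re + psu_re
    rbinom(n, 1, invlogit(lin))
  })

  ## raw item blocks consistent with the derived composites
  acts <- ipv_act_items()
  prefix <- c(physical = "phys", emotional = "emo", sexual = "sex")
  act_cols <- list()
  for (d in names(acts)) {
    act_cols <- c(act_cols,
                  simulate_acts(domains[, d],
                                paste0(prefix[[d]], "_", acts[[d]]),
                                config$act_rate, config$lifetime_only_rate))
  }

  media_yes <- covs$media_exposure == "yes"
  media <- list()
  for (m in c("newspaper", "radio", "tv")) {
    code <- ifelse(media_yes,
                   media_codes[1 + (runif(n) < 0.6) + (runif(n) < 0.5)],
                   media_codes[1 + (runif(n) < 0.25)])
    media[[paste0("media_", m)]] <- code
  }
  ## guarantee consistency with the composite
  any_weekly <- Reduce(`|`, lapply(media, function(x) {
    x == "at_least_once_week"
  }))
  fix <- media_yes & !any_weekly
  media$media_radio[fix] <- "at_least_once_week"

  aut_yes <- covs$autonomy == "yes"
  dec <- list()
  for (it in decision_items) {
    dec[[it]] <- ifelse(aut_yes,
                        ifelse(runif(n) < 0.5, "self", "joint"),
                        ifelse(runif(n) < 0.5, "other",
                               ifelse(runif(n) < 0.5, "self", "joint")))
  }
  all_part <- Reduce(`&`, lapply(dec, function(x) x != "other"))
  fix <- !aut_yes & all_part
  dec[[decision_items[1]]][fix] <- "other"

  att_yes <- covs$beating_attitude == "yes"
  att <- list()
  for (it in attitude_items) {
    att[[it]] <- ifelse(att_yes & runif(n) < 0.4, "yes", "no")
  }
  any_just <- Reduce(`|`, lapply(att, function(x) x == "yes"))
  fix <- att_yes & !any_just
  att[[attitude_items[1]]][fix] <- "yes"

  df <- data.frame(
    woman_id = seq_len(n), country_id = country_id,
    stratum_id = stratum_id, psu_id = psu_id, weight = weight,
    latent_hcb = eta,
    true_physical = domains[, "physical"],
    true_emotional = domains[, "emotional"],
    true_sexual = domains[, "sexual"],
    Y, act_cols, media, dec, att, covs,
    stringsAsFactors = FALSE, check.names = FALSE
  )

  if (config$missing_rate > 0) {
    for (f in names(config$margins)) {
      miss <- runif(n) < config$missing_rate
      df[[f]][miss] <- NA_character_
    }
  }
  attr(df, "config") <- config
  df
}

#' Simulate country-level prevalence summaries
#'
#' Draws country logit-prevalences from \eqn{N(\mu, \tau^2)} and observed
#' event counts from a binomial; a fixture generator for the meta-analysis
#' stage.
#'
#' @param k number of countries (>= 1).
#' @param mu mean logit prevalence.
#' @param tau between-country standard deviation on the logit scale (>= 0).
#' @param n_per_country sample size per country (recycled to length k).
#' @param seed integer seed.
#' @return data.frame with columns \code{label}, \code{events}, \code{n},
#'   \code{p} and the latent \code{true_p}.
#' @export
simulate_country_prevalences <- function(k, mu, tau, n_per_country,
                                         seed = 1L) {
  stopifnot(k >= 1, tau >= 0, all(n_per_country >= 1))
  with_seed(seed, {
    theta <- rnorm(k, mu, tau)
    n <- rep_len(n_per_country, k)
    events <- rbinom(k, n, invlogit(theta))
    data.frame(label = paste0("country_", seq_len(k)),
               events = events, n = n, p = events / n,
               true_p = invlogit(theta))
  })
}

#' Write a simulated table and its metadata sidecar
#'
#' @param df table from \code{\link{simulate_population}}.
#' @param dir output directory (created if absent).
#' @return paths of the two files written, invisibly.
#' @export
write_simulation <- function(df, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "women.csv")
  meta_path <- file.path(dir, "women_meta.yaml")
  write.csv(df, data_path, row.names = FALSE)
  cfg <- attr(df, "config")
  meta <- list(
    n = nrow(df),
    seed = cfg$seed,
    design = list(n_countries = cfg$n_countries,
                  psus_per_country = cfg$psus_per_country,
                  women_per_psu = cfg$women_per_psu),
    margins = lapply(cfg$margins, as.numeric),
    true_params = lapply(unclass(cfg$true_params), function(x) {
      if (is.list(x)) lapply(x, as.list) else as.list(x)
    })
  )
  yaml::write_yaml(meta, meta_path)
  invisible(c(data = data_path, meta = meta_path))
}
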