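# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small complete survey + derived table (n = 500)
small_raw <- function() {
  fixture("small_raw", simulate_population(
    sim_config(n_countries = 2, psus_per_country = 10, women_per_psu = 25,
               seed = 7)))
}
small_derived <- function() {
  fixture("small_derived", build_analysis_table(small_raw()))
}

# medium table for fitting tests (n = 2,000)
medium_derived <- function() {
  fixture("medium_derived", build_analysis_table(simulate_population(
    sim_config(n_countries = 2, psus_per_country = 20, women_per_psu = 50,
               seed = 21))))
}

# data generated under lambda = gamma = 0 (no latent structure), n = 2,000
nolatent_derived <- function() {
  fixture("nolatent_derived", {
    tp <- default_true_params()
    tp$lambda[] <- 0
    tp$gamma[] <- 0
    build_analysis_table(simulate_population(
      sim_config(n_countries = 2, psus_per_country = 20, women_per_psu = 50,
                 true_params = tp, seed = 33)))
  })
}

# fits shared across test files (computed once per run)
medium_fit <- function() {
  fixture("medium_fit", ipv_gsem(medium_derived()))
}
nolatent_fit_constrained <- function() {
  fixture("nolatent_fit_constrained", {
    spec <- default_gsem_spec()
    start <- default_true_params()
    start$tau[] <- 0; start$lambda[] <- 1; start$alpha[] <- 0
    for (d in names(start$beta)) start$beta[[d]][] <- 0
    start$gamma[] <- 0.5
    fixed <- c(setNames(rep(0, 5), paste0("lambda.", spec$indicators)),
               setNames(rep(0, 3), paste0("gamma.", names(spec$outcomes))))
    ipv_gsem(nolatent_derived(), spec, start = start, fixed = fixed)
  })
}

# survey with strong induced intra-PSU outcome correlation
clustered_derived <- function() {
  fixture("clustered_derived", build_analysis_table(simulate_population(
    sim_config(n_countries = 1, psus_per_country = 100, women_per_psu = 30,
               psu_sd = 1.5, seed = 55))))
}

# brute-force trapezoid integration of the marginal log-likelihood over a
# fine grid on [-8, 8]; independent of the quadrature code path
trapezoid_loglik <- function(params, data, spec, n_grid = 10001) {
  mats <- ipvgsem:::gsem_matrices(data, spec)
  eta <- seq(-8, 8, length.out = n_grid)
  h <- eta[2] - eta[1]
  wts <- dnorm(eta) * h
  wts[c(1, n_grid)] <- wts[c(1, n_grid)] / 2
  ll <- 0
  for (i in seq_len(nrow(mats$Y))) {
    f <- rep(1, n_grid)
    for (j in seq_len(ncol(mats$Y))) {
      pj <- plogis(params$tau[j] + params$lambda[j] * eta)
      f <- f * (if (mats$Y[i, j] == 1) pj else 1 - pj)
    }
    for (d in colnames(mats$V)) {
      lin <- params$alpha[[d]] +
        sum(mats$X[i, mats$xcols[[d]] + 1] * params$beta[[d]]) +
        params$gamma[[d]] * eta
      pd <- plogis(lin)
      f <- f * (if (mats$V[i, d] == 1) pd else 1 - pd)
    }
    ll <- ll + mats$w[i] * log(sum(f * wts))
  }
  ll
}

# random parameter draw of the default model shape
random_params <- function(spec = default_gsem_spec()) {
  skel <- fixture("skel", default_true_params())
  gsem_params(
    tau = setNames(runif(length(spec$indicators), -1.5, 1.5),
                   spec$indicators),
    lambda = setNames(runif(length(spec$indicators), -1, 1),
                      spec$indicators),
    alpha = setNames(runif(3, -1.5, 1.5), names(spec$outcomes)),
    beta = lapply(skel$beta, function(b) {
      setNames(runif(length(b), -0.5, 0.5), names(b))
    }),
    gamma = setNames(runif(3, -1, 1), names(spec$outcomes)))
}

# independent per-equation weighted logistic log-likelihood (for the
# factorization identity)
separate_bernoulli_loglik <- function(params, data, spec) {
  mats <- ipvgsem:::gsem_matrices(data, spec)
  ll <- 0
  for (j in seq_len(ncol(mats$Y))) {
    ll <- ll + sum(mats$w * dbinom(mats$Y[, j], 1,
                                   plogis(params$tau[j]), log = TRUE))
  }
  for (d in colnames(mats$V)) {
    lin <- params$alpha[[d]] +
      as.vector(mats$X[, mats$xcols[[d]] + 1, drop = FALSE] %*%
                  params$beta[[d]])
    ll <- ll + sum(mats$w * dbinom(mats$V[, d], 1, plogis(lin), log = TRUE))
  }
  ll
}
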