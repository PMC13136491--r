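test_that("same config and seed give identical tables", {
  cfg <- sim_config(n_countries = 2, psus_per_country = 5,
                    women_per_psu = 10, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  attr(a, "config") <- attr(b, "config") <- NULL
  expect_identical(a, b)
})

test_that("design dimensions and weights behave as configured", {
  df <- small_raw()
  expect_equal(nrow(df), 2 * 10 * 25)
  expect_true(all(df$weight > 0))
  # weights normalized to mean 1 within country
  for (cc in unique(df$country_id)) {
    expect_equal(mean(df$weight[df$country_id == cc]), 1, tolerance = 1e-12)
  }
  # PSU ids nest in countries, women nest in PSUs
  expect_equal(length(unique(df$psu_id)), 2 * 10)
  expect_true(all(table(df$psu_id) == 25))
})

test_that("with no latent or covariate effects, prevalence matches the intercept", {
  tp <- default_true_params()
  tp$lambda[] <- 0
  tp$gamma[] <- 0
  for (d in names(tp$beta)) tp$beta[[d]][] <- 0
  cfg <- sim_config(n_countries = 1, psus_per_country = 20,
                    women_per_psu = 500, true_params = tp, seed = 17)
  df <- simulate_population(cfg)
  n <- nrow(df)
  for (d in c("physical", "emotional", "sexual")) {
    target <- plogis(tp$alpha[[d]])
    got <- mean(df[[paste0("true_", d)]])
    mc_se <- sqrt(target * (1 - target) / n)
    expect_lt(abs(got - target), 3 * mc_se)
  }
})

test_that("covariate margins are recovered in large samples", {
  cfg <- sim_config(n_countries = 1, psus_per_country = 50,
                    women_per_psu = 1000, seed = 23)
  df <- simulate_population(cfg)
  n <- nrow(df)
  margins <- default_covariate_margins()
  for (f in c("age_group", "wealth", "husband_alcohol")) {
    lv <- ipv_factors()[[f]]
    for (i in seq_along(lv)) {
      target <- margins[[f]][i]
      # weighted prevalence of the category
      got <- sum(df$weight * (df[[f]] == lv[i])) / sum(df$weight)
      mc_se <- sqrt(target * (1 - target) / n)
      expect_lt(abs(got - target), 3 * sqrt(2) * mc_se)  # weights inflate
    }
  }
})

test_that("indicator items are positively associated under same-sign loadings", {
  df <- small_raw()
  Y <- as.matrix(df[paste0("hcb_", hcb_indicators())])
  co <- cor(Y)
  expect_true(all(co[upper.tri(co)] >= 0))
})

test_that("simulated domain prevalence matches the calibrated pooled targets", {
  cfg <- sim_config(n_countries = 12, psus_per_country = 25,
                    women_per_psu = 167, seed = 41)  # n ~ 50,100
  df <- simulate_population(cfg)
  expect_equal(100 * mean(df$true_physical), 26.15, tolerance = 1.5 / 26.15)
  expect_equal(100 * mean(df$true_emotional), 26.06, tolerance = 1.5 / 26.06)
  expect_equal(100 * mean(df$true_sexual), 11.6, tolerance = 1.5 / 11.6)
})

test_that("country prevalence fixtures behave at their degenerate settings", {
  # tau = 0: all true prevalences identical
  a <- simulate_country_prevalences(5, qlogis(0.3), 0, 1000, seed = 2)
  expect_equal(a$true_p, rep(0.3, 5), tolerance = 1e-12)
  # k = 1: a single row
  b <- simulate_country_prevalences(1, 0, 0.5, 500, seed = 3)
  expect_equal(nrow(b), 1)
  # mu = 0, tau = 0, large n: close to one half
  c3 <- simulate_country_prevalences(4, 0, 0, 2e5, seed = 4)
  expect_equal(c3$p, rep(0.5, 4), tolerance = 0.01)
  expect_error(simulate_country_prevalences(3, 0, -1, 100), "tau")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_countries = 0), "positive")
  bad <- default_covariate_margins()
  bad$wealth <- c(0.5, 0.2, 0.1, 0.1, 0.2)  # sums to 1.1
  expect_error(sim_config(margins = bad), "sum to 1")
})

test_that("writing a simulation produces the table and a metadata sidecar", {
  dir <- withr::local_tempdir()
  paths <- write_simulation(small_raw(), dir)
  expect_true(all(file.exists(paths)))
  meta <- yaml::read_yaml(paths[["meta"]])
  expect_equal(meta$n, nrow(small_raw()))
  back <- read.csv(paths[["data"]])
  expect_equal(nrow(back), nrow(small_raw()))
})
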