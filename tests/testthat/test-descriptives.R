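test_that("weighted proportion matches hand arithmetic", {
  expect_equal(weighted_proportion(c(1, 0), c(3, 1))$p, 0.75)
  est <- weighted_proportion(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(est$p, 0.5)
  expect_equal(est$n_unweighted, 4)
  expect_equal(est$n_weighted, 4)
})

test_that("logit-scale interval matches an independent closed form", {
  x <- rep(c(1, 0), each = 50)
  est <- weighted_proportion(x, rep(1, 100))
  # textbook computation: p = 0.5, linearized SE with the n/(n-1) factor,
  # delta-method SE on the logit scale, Wald back-transformed
  p <- 0.5
  se <- sqrt(100 / 99 * sum((rep(1, 100) * (x - p) / 100)^2))
  half <- qnorm(0.975) * se / (p * (1 - p))
  expect_equal(est$p, p)
  expect_equal(est$ci_low, plogis(qlogis(p) - half), tolerance = 1e-12)
  expect_equal(est$ci_high, plogis(qlogis(p) + half), tolerance = 1e-12)
  expect_true(est$ci_low >= 0 && est$ci_low <= est$p &&
                est$p <= est$ci_high && est$ci_high <= 1)
})

test_that("degenerate proportions return flagged one-sided bounds", {
  up <- weighted_proportion(rep(1, 20), runif(20, 0.5, 2))
  expect_equal(up$p, 1)
  expect_true(up$degenerate)
  expect_lt(up$ci_low, 1)
  expect_equal(up$ci_high, 1)
  down <- weighted_proportion(rep(0, 20), rep(1, 20))
  expect_equal(down$p, 0)
  expect_equal(down$ci_low, 0)
  expect_gt(down$ci_high, 0)
})

test_that("frequency table reproduces printed survey percentages", {
  age <- frequency_table(factor(c("15_24", "25_34", "35_49"),
                                levels = c("15_24", "25_34", "35_49")),
                         c(13593, 24663, 18401))
  expect_equal(sum(age$freq_weighted), 56657)
  expect_equal(age$percent, c(23.99, 43.53, 32.48))

  alc <- frequency_table(c("no", "yes"), c(35207, 21450))
  expect_equal(alc$percent, c(62.14, 37.86))

  single <- frequency_table(rep("only", 7), runif(7, 0.1, 3))
  expect_equal(single$percent, 100.00)
})

test_that("frequency table percents always sum to 100 up to rounding", {
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    tab <- frequency_table(sample(letters[1:k], 200, replace = TRUE),
                           runif(200, 0.2, 3))
    expect_lt(abs(sum(tab$percent) - 100), 0.05)
  }
})

test_that("estimates are invariant to rescaling all weights", {
  d <- small_derived()
  a <- weighted_proportion(d$any_ipv, d$weight, psu = d$psu)
  b <- weighted_proportion(d$any_ipv, d$weight * 7.3, psu = d$psu)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$ci_low, b$ci_low, tolerance = 1e-12)
  expect_equal(a$ci_high, b$ci_high, tolerance = 1e-12)
})

test_that("cluster-robust variance exceeds the independence variance under intra-PSU correlation", {
  d <- clustered_derived()
  ind <- weighted_proportion(d$any_ipv, d$weight)
  clu <- weighted_proportion(d$any_ipv, d$weight, psu = d$psu)
  expect_equal(ind$p, clu$p)
  expect_gt(clu$se, ind$se)
  expect_identical(clu$method, "cluster-robust")
})

test_that("per-country prevalence estimates behave", {
  d <- small_derived()
  prev <- country_prevalence(d)
  expect_equal(nrow(prev), 2)
  expect_true(all(prev$ci_low <= prev$p & prev$p <= prev$ci_high))

  # identical data in two countries give identical estimates
  dd <- as.data.frame(d)
  d2 <- rbind(dd, transform(dd, country = country + 100,
                            psu = psu + 1000))
  prev2 <- country_prevalence(d2)
  expect_equal(prev2$p[prev2$country <= 100],
               prev2$p[prev2$country > 100])

  # an all-zero country falls back to the degenerate-CI rule
  d3 <- dd
  d3$any_ipv[d3$country == 1] <- 0
  prev3 <- country_prevalence(d3)
  expect_equal(prev3$p[prev3$country == 1], 0)
})

test_that("invalid inputs are rejected", {
  expect_error(weighted_proportion(numeric(0), numeric(0)), "empty")
  expect_error(weighted_proportion(c(1, 0), c(0, 0)), "zero")
  expect_error(frequency_table(character(0)), "empty")
})
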