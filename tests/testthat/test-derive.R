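test_that("domain derivation follows the 12-month recall rule", {
  ever <- rbind(c("no", "no", "no"))
  freq <- rbind(c("not_at_all", "not_at_all", "not_at_all"))
  expect_equal(derive_domain(ever, freq), 0L)

  # one act occurred often in the last 12 months
  ever2 <- rbind(c("yes", "no", "no"))
  freq2 <- rbind(c("often", "not_at_all", "not_at_all"))
  expect_equal(derive_domain(ever2, freq2), 1L)

  # lifetime-only experience does not count in the 12-month window
  freq3 <- rbind(c("not_at_all", "not_at_all", "not_at_all"))
  expect_equal(derive_domain(ever2, freq3), 0L)

  # "sometimes" counts
  freq4 <- rbind(c("sometimes", "not_at_all", "not_at_all"))
  expect_equal(derive_domain(ever2, freq4), 1L)

  # fully missing rows are flagged for complete-case removal
  expect_true(is.na(derive_domain(rbind(rep(NA_character_, 3)),
                                  rbind(rep(NA_character_, 3)))))
  expect_error(derive_domain(matrix(character(0), 1, 0),
                             matrix(character(0), 1, 0)), "empty")
  expect_error(derive_domain(ever, rbind(c("weekly", "no", "no"))),
               "unknown frequency")
})

test_that("overall IPV is the logical OR of the domains", {
  cases <- expand.grid(p = 0:1, e = 0:1, s = 0:1)
  got <- derive_any_ipv(cases$p, cases$e, cases$s)
  expect_equal(got, as.integer(cases$p | cases$e | cases$s))
})

test_that("media exposure composite requires at least one weekly medium", {
  expect_equal(derive_media_exposure("not_at_all", "not_at_all",
                                     "not_at_all"), 0L)
  expect_equal(derive_media_exposure("not_at_all", "at_least_once_week",
                                     "not_at_all"), 1L)
  expect_equal(derive_media_exposure("at_least_once_week",
                                     "at_least_once_week",
                                     "at_least_once_week"), 1L)
  # less than once a week is not exposure in the reference week
  expect_equal(derive_media_exposure("less_than_once_week",
                                     "less_than_once_week",
                                     "not_at_all"), 0L)
  expect_true(is.na(derive_media_exposure(NA_character_, NA_character_,
                                          NA_character_)))
})

test_that("attitude composite is positive iff any scenario is justified", {
  expect_equal(derive_attitude_wife_beating(rbind(rep("no", 5))), 0L)
  one <- rep("no", 5); one[3] <- "yes"
  expect_equal(derive_attitude_wife_beating(rbind(one)), 1L)
  expect_equal(derive_attitude_wife_beating(rbind(rep("yes", 5))), 1L)
})

test_that("autonomy composite requires participation in all decisions", {
  expect_equal(derive_decision_autonomy(rbind(c("self", "self", "self"))), 1L)
  expect_equal(derive_decision_autonomy(rbind(c("joint", "joint", "joint"))),
               1L)
  expect_equal(derive_decision_autonomy(rbind(c("other", "self", "self"))),
               0L)
  expect_equal(derive_decision_autonomy(rbind(c("self", "joint", "other"))),
               0L)
})

test_that("analysis table applies strict complete-case filtering", {
  raw <- simulate_population(
    sim_config(n_countries = 1, psus_per_country = 2, women_per_psu = 3,
               seed = 12))
  raw$education[2] <- NA
  d <- build_analysis_table(raw)
  expect_equal(nrow(d), 5)
  log <- attr(d, "removal_log")
  expect_equal(unname(log["removed_missing"]), 1)
  expect_equal(unname(log["retained"]), 5)
})

test_that("dummy coding is one-hot with the reference level dropped", {
  covs <- data.frame(age_group = c("25_34", "15_24", "35_49"))
  X <- dummy_matrix(covs, ipv_factors()["age_group"])
  expect_equal(colnames(X), c("age_group.25_34", "age_group.35_49"))
  expect_equal(rowSums(X), c(1, 0, 1))
  expect_error(dummy_matrix(data.frame(age_group = "60_plus"),
                            ipv_factors()["age_group"]),
               "unknown category")
})

test_that("derived outcomes and composites round-trip the simulator truth", {
  raw <- small_raw()
  d <- build_analysis_table(raw)
  expect_equal(nrow(d), nrow(raw))
  expect_equal(d$phys_ipv, raw$true_physical)
  expect_equal(d$emo_ipv, raw$true_emotional)
  expect_equal(d$sex_ipv, raw$true_sexual)
  expect_equal(as.character(d$media_exposure), raw$media_exposure)
  expect_equal(as.character(d$autonomy), raw$autonomy)
  expect_equal(as.character(d$beating_attitude), raw$beating_attitude)
})

test_that("occurrence is monotone: adding an act never clears an outcome", {
  set.seed(61)
  for (rep in 1:50) {
    k <- sample(2:7, 1)
    ever <- matrix(sample(c("yes", "no"), k, replace = TRUE), 1)
    freq <- ifelse(ever == "yes",
                   sample(c("often", "sometimes", "not_at_all"), k,
                          replace = TRUE),
                   "not_at_all")
    freq <- matrix(freq, 1)
    before <- derive_domain(ever, freq)
    idx <- which(freq == "not_at_all")
    if (!length(idx)) next
    j <- idx[sample.int(length(idx), 1)]
    ever2 <- ever; freq2 <- freq
    ever2[j] <- "yes"; freq2[j] <- "sometimes"
    after <- derive_domain(ever2, freq2)
    expect_gte(after, max(before, 0, na.rm = TRUE))
  }
})

test_that("overall IPV prevalence dominates every domain prevalence", {
  d <- small_derived()
  expect_gte(mean(d$any_ipv),
             max(mean(d$phys_ipv), mean(d$emo_ipv), mean(d$sex_ipv)))
})

test_that("dummy matrix has full column rank when all categories occur", {
  d <- small_derived()
  X <- dummy_matrix(as.data.frame(d), attr(d, "factors"))
  expect_equal(qr(cbind(1, X))$rank, ncol(X) + 1)
})

test_that("unmapped columns produce a named error", {
  raw <- small_raw()
  raw$media_radio <- NULL
  expect_error(build_analysis_table(raw), "media_radio")
})
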