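test_that("marginal likelihood matches brute-force grid integration", {
  d <- small_derived()[1:20, ]
  spec <- default_gsem_spec()
  set.seed(77)
  for (rep in 1:5) {
    p <- random_params(spec)
    a <- joint_loglik(p, d, spec)
    b <- trapezoid_loglik(p, d, spec)
    expect_lt(abs(a - b) / abs(b), 1e-6)
  }
})

test_that("likelihood factorizes when the latent paths vanish", {
  d <- small_derived()
  spec <- default_gsem_spec()
  set.seed(78)
  p <- random_params(spec)
  p$lambda[] <- 0
  p$gamma[] <- 0
  expect_equal(joint_loglik(p, d, spec),
               separate_bernoulli_loglik(p, d, spec), tolerance = 1e-12)
})

test_that("log-likelihood is exactly linear in the weights", {
  d <- small_derived()
  spec <- default_gsem_spec()
  set.seed(79)
  p <- random_params(spec)
  d2 <- d
  d2$weight <- 2 * d2$weight
  expect_identical(joint_loglik(p, d2, spec), 2 * joint_loglik(p, d, spec))
})

test_that("analytic gradient matches central finite differences", {
  d <- small_derived()[1:60, ]
  spec <- default_gsem_spec()
  mats <- ipvgsem:::gsem_matrices(d, spec)
  set.seed(80)
  p <- random_params(spec)
  theta <- pack_params(p)
  quad <- gh_quadrature(15)
  res <- ipvgsem:::ll_call(theta, p, mats, quad, want_grad = TRUE,
                           want_scores = TRUE)
  coords <- sample(length(theta), 10)
  for (k in coords) {
    h <- 1e-6
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    num <- (ipvgsem:::ll_call(tp, p, mats, quad)$loglik -
              ipvgsem:::ll_call(tm, p, mats, quad)$loglik) / (2 * h)
    expect_equal(res$grad[k], num, tolerance = 1e-5)
  }
  # per-unit scores sum to the gradient
  expect_equal(colSums(res$scores), as.numeric(res$grad), tolerance = 1e-8)
})

test_that("likelihood is invariant to reflecting the latent factor", {
  d <- small_derived()
  spec <- default_gsem_spec()
  set.seed(81)
  p <- random_params(spec)
  pf <- p
  pf$lambda <- -pf$lambda
  pf$gamma <- -pf$gamma
  expect_equal(joint_loglik(p, d, spec), joint_loglik(pf, d, spec),
               tolerance = 1e-12)
  # the fitted model resolves the reflection with a positive first loading
  expect_gt(medium_fit()$params$lambda[[1]], 0)
})

test_that("constrained fit reproduces separate weighted logistic regressions", {
  fit <- nolatent_fit_constrained()
  expect_true(fit$converged)
  d <- nolatent_derived()
  mats <- ipvgsem:::gsem_matrices(as.data.frame(d), fit$spec)
  w <- mats$w / mean(mats$w)
  for (dd in names(fit$spec$outcomes)) {
    Xd <- mats$X[, mats$xcols[[dd]] + 1, drop = FALSE]
    ref <- suppressWarnings(
      glm.fit(cbind(1, Xd), mats$V[, dd], weights = w,
              family = quasibinomial()))$coefficients
    expect_equal(fit$params$alpha[[dd]], unname(ref[1]), tolerance = 1e-3)
    expect_equal(unname(fit$params$beta[[dd]]), unname(ref[-1]),
                 tolerance = 1e-3)
  }
})

test_that("estimates are invariant to row permutation and PSU relabeling", {
  d <- medium_derived()
  fit <- medium_fit()
  set.seed(90)
  dd <- as.data.frame(d)[sample(nrow(d)), ]
  dd$psu <- dd$psu + 5000  # relabel clusters
  class(dd) <- class(d)
  attr(dd, "factors") <- attr(d, "factors")
  fit2 <- ipv_gsem(dd, compute_vcov = FALSE)
  expect_equal(fit2$theta, fit$theta, tolerance = 1e-3)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("duplicating every PSU leaves point estimates unchanged", {
  d <- as.data.frame(medium_derived())
  d2 <- rbind(d, transform(d, psu = psu + 10000))
  fit2 <- ipv_gsem(d2, compute_vcov = FALSE)
  expect_equal(fit2$theta, medium_fit()$theta, tolerance = 1e-3)
})

test_that("sandwich vcov reduces to the unit-cluster form and inflates under clustering", {
  fit <- medium_fit()
  n <- fit$n
  # one unit per cluster: meat is the outer product of unit scores
  v1 <- robust_vcov(fit, cluster = seq_len(n))
  sc <- ipvgsem:::ll_call(fit$theta, fit$params, fit$model,
                          gh_quadrature(fit$quad_order),
                          want_scores = TRUE)$scores[, fit$free]
  bread <- solve(fit$info)
  vref <- bread %*% (crossprod(sc) * n / (n - 1)) %*% bread
  expect_equal(unname(v1), unname(vref), tolerance = 1e-8)

  # induced intra-PSU correlation: clustered SEs exceed independence SEs
  fcl <- fixture("clustered_fit", ipv_gsem(clustered_derived()))
  se_cl <- sqrt(diag(fcl$vcov))
  se_in <- sqrt(diag(fcl$vcov_independence))
  for (d in names(fcl$spec$outcomes)) {
    a <- paste0("alpha.", d)
    expect_gt(se_cl[[a]], se_in[[a]])
  }
})

test_that("odds-ratio table satisfies the Wald identities", {
  tab <- aor_table(medium_fit())
  expect_true(all(c("outcome", "term", "aor", "ci_low", "ci_high",
                    "p_value", "significant") %in% names(tab)))
  # log-scale symmetric interval: ci_low * ci_high = aor^2
  expect_equal(tab$ci_low * tab$ci_high, tab$aor^2, tolerance = 1e-8)
  expect_true(all(tab$term[tab$term == "hcb"] == "hcb"))
  expect_equal(sum(tab$term == "hcb"), 3)
  expect_identical(tab$significant, !is.na(tab$p_value) & tab$p_value < 0.05)
})

test_that("information criteria follow their definitions and rank models sensibly", {
  fit <- medium_fit()
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n))
  expect_equal(AIC(fit), fit$aic)

  # on data without latent structure the constrained model wins by BIC
  con <- nolatent_fit_constrained()
  full <- fixture("nolatent_fit_full", ipv_gsem(nolatent_derived(),
                                                compute_vcov = FALSE))
  cmp <- compare_models(constrained = con, full = full, by = "bic")
  expect_identical(cmp$model[1], "constrained")

  # with the latent paths truly present, the full model wins by AIC
  con2 <- fixture("medium_fit_constrained", {
    spec <- default_gsem_spec()
    fixed <- c(setNames(rep(0, 5), paste0("lambda.", spec$indicators)),
               setNames(rep(0, 3), paste0("gamma.", names(spec$outcomes))))
    ipv_gsem(medium_derived(), fixed = fixed, compute_vcov = FALSE)
  })
  cmp2 <- compare_models(full = fit, constrained = con2, by = "aic")
  expect_identical(cmp2$model[1], "full")

  # exact ties break toward the smaller model
  cmp3 <- compare_models(a = con, b = con)
  expect_equal(nrow(cmp3), 2)
  con_other_n <- con
  con_other_n$n <- con$n - 1
  expect_error(compare_models(con, con_other_n), "differing")
})

test_that("predicted marginal probabilities track observed prevalences", {
  fit <- medium_fit()
  phat <- predict(fit)
  d <- medium_derived()
  obs <- c(physical = mean(d$phys_ipv), emotional = mean(d$emo_ipv),
           sexual = mean(d$sex_ipv))
  for (dd in names(obs)) {
    expect_equal(mean(phat[, dd]), unname(obs[dd]), tolerance = 0.02)
  }
  r <- residuals(fit)
  expect_equal(dim(r), c(fit$n, 3))
})

test_that("degenerate inputs abort with a named error", {
  d <- as.data.frame(small_derived())
  d$jealous <- 1L
  expect_error(ipv_gsem(d, compute_vcov = FALSE), "jealous")
  d2 <- as.data.frame(small_derived())
  d2$phys_ipv <- 0L
  expect_error(ipv_gsem(d2, compute_vcov = FALSE), "phys")
})
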