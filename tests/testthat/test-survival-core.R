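# Cox engine: contract checks against hand computations and the
# brute-force partial-likelihood oracle.

test_that("fitted coefficients match the brute-force partial-likelihood oracle", {
  fixtures <- list(
    make_fixture(30, seed = 101, binary_x = TRUE),
    make_fixture(40, seed = 102, binary_x = FALSE, delayed = TRUE),
    make_fixture(50, seed = 103, binary_x = TRUE, strata_k = 2)
  )
  for (fx in fixtures) {
    ds <- survival_design(fx$entry, fx$exit, fx$event,
                          data.frame(x = fx$x), strata = fx$strata)
    fit <- fit_cox(ds)
    b_oracle <- oracle_maximize_1d(fx$entry, fx$exit, fx$event, fx$x,
                                   fx$strata)
    expect_lt(abs(coef(fit)[["x"]] - b_oracle), 1e-3)
  }
  # two covariates
  fx <- make_fixture(40, seed = 104, binary_x = TRUE, delayed = TRUE)
  set.seed(105)
  x2 <- round(rnorm(40), 1)
  ds <- survival_design(fx$entry, fx$exit, fx$event,
                        data.frame(x1 = fx$x, x2 = x2))
  fit <- fit_cox(ds)
  b_oracle <- oracle_maximize_2d(fx$entry, fx$exit, fx$event,
                                 cbind(fx$x, x2))
  expect_lt(max(abs(coef(fit) - b_oracle)), 1e-3)
})

test_that("null model has loglik_full equal to loglik_null", {
  fx <- make_fixture(25, seed = 110)
  ds <- survival_design(fx$entry, fx$exit, fx$event)
  fit <- fit_cox(ds)
  expect_identical(fit$loglik, fit$loglik_null)
})

test_that("duplicating every subject leaves beta unchanged and scales SE by 1/sqrt(2)", {
  # exact under Breslow ties, where the duplicated partial likelihood is
  # the square of the original
  fx <- make_fixture(30, seed = 111)
  ds1 <- survival_design(fx$entry, fx$exit, fx$event, data.frame(x = fx$x))
  ds2 <- survival_design(rep(fx$entry, 2), rep(fx$exit, 2),
                         rep(fx$event, 2), data.frame(x = rep(fx$x, 2)))
  f1 <- fit_cox(ds1, ties = "breslow")
  f2 <- fit_cox(ds2, ties = "breslow")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(unname(f2$se / f1$se), 1 / sqrt(2), tolerance = 1e-6)
})

test_that("stratified fit with a single stratum equals the pooled fit", {
  fx <- make_fixture(40, seed = 112, binary_x = FALSE)
  ds_plain <- survival_design(fx$entry, fx$exit, fx$event,
                              data.frame(x = fx$x))
  ds_strat <- survival_design(fx$entry, fx$exit, fx$event,
                              data.frame(x = fx$x),
                              strata = rep("only", 40))
  expect_lt(abs(coef(fit_cox(ds_plain)) - coef(fit_cox(ds_strat))), 1e-10)
})

test_that("aliased covariates are rejected by name and divergence is flagged", {
  fx <- make_fixture(30, seed = 113)
  ds <- survival_design(fx$entry, fx$exit, fx$event,
                        data.frame(a = fx$x, b = fx$x))
  expect_error(fit_cox(ds), "aliased.*b")
  # monotone likelihood: a covariate that perfectly orders events
  n <- 20
  exit <- seq_len(n)
  x <- as.numeric(exit <= 10)
  ds2 <- survival_design(rep(0, n), exit, rep(1, n), data.frame(x = x))
  fit <- suppressWarnings(fit_cox(ds2))
  expect_false(fit$converged)
})

test_that("Nelson-Aalen matches hand-computed risk sets, with delayed entry", {
  # censor 1, deaths at 2 and 3, censor 4: H(2)=1/3, H(3)=1/3+1/2
  na <- nelson_aalen(rep(0, 4), c(1, 2, 3, 4), c(0, 1, 1, 0))
  expect_equal(na$H(2), 1 / 3, tolerance = 1e-12)
  expect_equal(na$H(3), 1 / 3 + 1 / 2, tolerance = 1e-12)
  expect_equal(round(na$H(3), 4), 0.8333)
  # single subject with an event jumps to 1
  na1 <- nelson_aalen(0, 5, 1)
  expect_equal(na1$H(5), 1)
  expect_equal(na1$H(4.9), 0)
  # late entrant excluded from the first risk set: subjects (0,2] death,
  # (0,5] censored, entrant at 3 with death at 6
  na2 <- nelson_aalen(c(0, 0, 3), c(2, 5, 6), c(1, 0, 1))
  expect_equal(na2$H(2), 1 / 2)   # risk set {1,2}, entrant not yet in
  expect_equal(na2$H(6), 1 / 2 + 1)
  # per-subject evaluation at exit
  expect_equal(na$at_exit, c(0, 1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2))
  expect_warning(nelson_aalen(0, c(1, 2), c(0, 0)), "no events")
})

test_that("explained randomness follows the closed form and is scale invariant", {
  fake <- list(loglik = -100 + 69.3 / 2, loglik_null = -100, n_events = 100)
  expect_equal(explained_randomness_r2(fake), 1 - exp(-0.693), tolerance = 1e-12)
  expect_lt(abs(explained_randomness_r2(fake) - 0.5), 1e-4)
  expect_equal(explained_randomness_r2(list(loglik = -50, loglik_null = -50,
                                            n_events = 10)), 0)
  expect_error(explained_randomness_r2(list(loglik = 0, loglik_null = 0,
                                            n_events = 0)), "zero events")
  # rescaling a covariate cannot change the likelihood ratio
  fx <- make_fixture(60, seed = 120, binary_x = FALSE)
  ds1 <- survival_design(fx$entry, fx$exit, fx$event, data.frame(x = fx$x))
  ds2 <- survival_design(fx$entry, fx$exit, fx$event,
                         data.frame(x = fx$x * 37.5))
  expect_equal(explained_randomness_r2(fit_cox(ds1)),
               explained_randomness_r2(fit_cox(ds2)), tolerance = 1e-10)
  # nested models: R2 non-decreasing
  set.seed(121)
  x2 <- rnorm(60)
  ds3 <- survival_design(fx$entry, fx$exit, fx$event,
                         data.frame(x = fx$x, x2 = x2))
  expect_gte(explained_randomness_r2(fit_cox(ds3)),
             explained_randomness_r2(fit_cox(ds1)) - 1e-12)
})

test_that("concordance index honours its tie and ordering conventions", {
  ds <- survival_design(rep(0, 5), 1:5, rep(1, 5),
                        data.frame(x = 1:5))
  expect_equal(concordance_index(-(1:5), ds), 1)   # predicts risk order exactly
  expect_equal(concordance_index(rep(0, 5), ds), 0.5)
  set.seed(130)
  n <- 4000
  dsr <- survival_design(rep(0, n), rexp(n) + 0.01, rbinom(n, 1, 0.7))
  expect_lt(abs(concordance_index(rnorm(n), dsr) - 0.5), 0.02)
  expect_error(concordance_index(rnorm(5), dsr), "misaligned")
})

test_that("Wald group chi-squared proportions behave as hand-computed", {
  fake <- list(coefficients = c(a = 2), vcov = matrix(1, 1, 1,
                                                      dimnames = list("a", "a")))
  w <- wald_group_chi2(fake, c(a = "g1"))
  expect_equal(w$chi2, 4)
  expect_equal(w$proportion, 1)
  # two independent coefficients with equal z -> proportions (0.5, 0.5)
  fake2 <- list(coefficients = c(a = 1, b = -1),
                vcov = diag(c(1, 1)))
  dimnames(fake2$vcov) <- list(c("a", "b"), c("a", "b"))
  w2 <- wald_group_chi2(fake2, c(a = "g1", b = "g2"))
  expect_equal(w2$proportion, c(0.5, 0.5))
  expect_equal(sum(w2$proportion), 1, tolerance = 1e-12)
})

test_that("GVIF matches the two-variable closed form and ignores reference level", {
  # exact r = 0.6 by construction
  set.seed(140)
  a <- scale(rnorm(300))[, 1]
  b <- scale(resid(lm(rnorm(300) ~ a)))[, 1]
  y <- 0.6 * a + sqrt(1 - 0.36) * b
  g <- gvif(cbind(x1 = a, x2 = y))
  expect_equal(g$gvif, rep(1 / (1 - 0.36), 2), tolerance = 1e-10)
  expect_equal(g$gvif_adj, rep(1.25, 2), tolerance = 1e-10)
  # orthogonal pair -> 1
  g0 <- gvif(cbind(x1 = a, x2 = b))
  expect_equal(g0$gvif_adj, c(1, 1), tolerance = 1e-10)
  # multi-level nominal term: invariant to the reference level chosen
  set.seed(141)
  f <- factor(sample(c("a", "b", "c"), 400, TRUE))
  z <- rnorm(400) + (f == "b")
  d1 <- data.frame(f = f, z = z)
  d2 <- data.frame(f = relevel(f, "c"), z = z)
  expect_equal(gvif(d1)$gvif_adj, gvif(d2)$gvif_adj, tolerance = 1e-10)
})

test_that("Schoenfeld test is calibrated under PH and powered against violations", {
  # null calibration: flag rate close to alpha across seeds
  flags <- vapply(1:120, function(s) {
    set.seed(200 + s)
    n <- 150
    x <- rnorm(n)
    t <- rexp(n, exp(0.5 * x))
    ds <- survival_design(rep(0, n), t + 1e-9, rep(1, n),
                          data.frame(x = x))
    schoenfeld_ph_test(fit_cox(ds))$flagged
  }, logical(1))
  expect_gt(mean(flags), 0.05 - 3 * sqrt(0.05 * 0.95 / 120))
  expect_lt(mean(flags), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
  # sign-flipping effect is caught decisively
  set.seed(333)
  n <- 20000
  x <- rnorm(n)
  t1 <- rexp(n, 0.4 * exp(0.8 * x))        # early: strong positive effect
  flip <- t1 > 1
  t <- ifelse(flip, 1 + rexp(n, 0.4 * exp(-0.8 * x[])), t1)
  ds <- survival_design(rep(0, n), t, rep(1, n), data.frame(x = x))
  tab <- schoenfeld_ph_test(fit_cox(ds))
  expect_lt(tab$p[tab$covariate == "x"], 0.01)
})

test_that("episode splitting preserves the partial likelihood and total follow-up", {
  sp1 <- split_survival_time(data.frame(entry = 0, exit = 5, event = 1,
                                        x = 1), 2)
  expect_equal(sp1$entry, c(0, 2, 4))
  expect_equal(sp1$exit, c(2, 4, 5))
  expect_equal(sp1$event, c(0, 0, 1))
  set.seed(150)
  n <- 400
  d <- data.frame(entry = 0, exit = rexp(n, 0.3) + 0.05,
                  event = rbinom(n, 1, 0.6), x = rnorm(n))
  ds <- survival_design(d$entry, d$exit, d$event, d["x"])
  f0 <- fit_cox(ds)
  sp <- split_survival_time(d, 2)
  dsp <- survival_design(sp$entry, sp$exit, sp$event, sp["x"])
  f1 <- fit_cox(dsp)
  expect_lt(abs(f0$loglik - f1$loglik), 1e-6)
  expect_equal(sum(sp$exit - sp$entry), sum(d$exit - d$entry),
               tolerance = 1e-10)
  expect_error(split_survival_time(d, 0), "positive")
})

test_that("confidence interval coverage of a planted log-HR is nominal", {
  hits <- vapply(1:300, function(s) {
    set.seed(400 + s)
    n <- 800
    x <- rnorm(n)
    u <- runif(n)
    t <- -log(u) / (0.1 * exp(0.4 * x))
    cens <- runif(n, 2, 8)
    ds <- survival_design(rep(0, n), pmin(t, cens) + 1e-12,
                          as.integer(t <= cens), data.frame(x = x))
    fit <- fit_cox(ds)
    abs(coef(fit) - 0.4) <= 1.96 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.93 - 0.02)  # binomial noise at 300 replicates
  expect_lte(mean(hits), 0.97 + 0.02)
})
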