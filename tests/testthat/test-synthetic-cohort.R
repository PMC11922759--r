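# Generator contracts: copula structure, type thresholds, Gompertz
# left-truncated survival, ancillary columns and the MAR mechanism.

test_that("latent block correlation is reproduced and blocks are independent", {
  cfg <- cohort_config(n = 50000, n_exposures = 4,
                       cluster_blocks = data.frame(size = c(2, 2),
                                                   r = c(0.8, 0)),
                       exposure_type_mix = c(continuous = 1, ordinal = 0,
                                             binary = 0, nominal = 0),
                       decoy_plan = c(confounded = 0, reverse_causation = 0,
                                      mortality_only = 0, sign_discordant = 0),
                       true_effects = numeric(0),
                       proteomic_effects = numeric(0), n_diseases = 0)
  exo <- generate_exposome(cfg, seed = 21)
  r12 <- cor(exo$exposures$exp01, exo$exposures$exp02)
  expect_lt(abs(r12 - 0.8), 0.02)
  # cross-block correlations vanish
  cross <- abs(c(cor(exo$exposures$exp01, exo$exposures$exp03),
                 cor(exo$exposures$exp01, exo$exposures$exp04),
                 cor(exo$exposures$exp02, exo$exposures$exp03)))
  expect_lt(mean(cross), 0.02)
})

test_that("ordinal thresholds give equal-probability levels", {
  cfg <- cohort_config(n = 100000, n_exposures = 2,
                       cluster_blocks = data.frame(size = 2, r = 0),
                       exposure_type_mix = c(continuous = 0, ordinal = 1,
                                             binary = 0, nominal = 0),
                       ordinal_levels = 4,
                       decoy_plan = c(confounded = 0, reverse_causation = 0,
                                      mortality_only = 0, sign_discordant = 0),
                       true_effects = numeric(0),
                       proteomic_effects = numeric(0), n_diseases = 0)
  exo <- generate_exposome(cfg, seed = 22)
  freq <- table(exo$exposures$exp01) / 100000
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("generator config validates its invariants", {
  expect_error(cohort_config(cluster_blocks = data.frame(size = 42, r = 1)),
               "\\[0, 1\\)")
  expect_error(cohort_config(exposure_type_mix = c(continuous = 0.6,
                                                   ordinal = 0.6,
                                                   binary = 0, nominal = 0)),
               "sum to 1")
  expect_error(cohort_config(missingness = 0.85), "below 0.8")
  # every causal and decoy name appears exactly once in the ledger
  sim <- simulate_cohort(cohort_config(n = 300), seed = 23)
  expect_identical(sort(sim$truth$exposure), sort(sim$specs$name))
  expect_false(anyDuplicated(sim$truth$exposure) > 0)
  tab <- table(sim$truth$role)
  expect_equal(as.vector(tab[c("causal", "confounded", "reverse_causation",
                               "mortality_only", "sign_discordant")]),
               c(8L, 1L, 2L, 2L, 1L))
  # ledger role semantics
  with(sim$truth, {
    expect_true(all(beta_mortality[role == "causal"] != 0))
    expect_true(all(sign(gamma_proteomic[role == "causal"]) ==
                      sign(beta_mortality[role == "causal"])))
    expect_true(all(beta_mortality[role == "null"] == 0 &
                      gamma_proteomic[role == "null"] == 0))
    expect_true(all(beta_mortality[role == "reverse_causation"] == 0 &
                      theta_poor_health[role == "reverse_causation"] != 0))
    expect_true(all(beta_mortality[role == "mortality_only"] != 0 &
                      gamma_proteomic[role == "mortality_only"] == 0))
    expect_true(all(sign(gamma_proteomic[role == "sign_discordant"]) ==
                      -sign(beta_mortality[role == "sign_discordant"])))
  })
})

test_that("mortality calibrates to 7.3% and censoring respects the follow-up window", {
  sim <- simulate_cohort(cohort_config(n = 100000), seed = 24)
  expect_lt(abs(mean(sim$complete$death_event) - 0.073), 0.005)
  censored <- sim$complete$death_time[sim$complete$death_event == 0]
  expect_lte(max(censored), 15)
  expect_gte(min(censored), 11 - 1e-9)
  expect_true(all(sim$complete$death_time > 0))
})

test_that("a planted log-HR of 0.405 is recovered by a Cox fit", {
  cfg <- cohort_config(n = 50000, n_exposures = 2,
                       cluster_blocks = data.frame(size = 2, r = 0),
                       exposure_type_mix = c(continuous = 1, ordinal = 0,
                                             binary = 0, nominal = 0),
                       decoy_plan = c(confounded = 0, reverse_causation = 0,
                                      mortality_only = 0, sign_discordant = 0),
                       true_effects = c(exp01 = 0.405),
                       proteomic_effects = c(exp01 = 1),
                       income_loghr = 0, n_diseases = 0,
                       poor_health_loghr = 0)
  sim <- simulate_cohort(cfg, seed = 25)
  d <- sim$complete
  ds <- survival_design(d$recruit_age, d$recruit_age + d$death_time,
                        d$death_event, data.frame(x = d$exp01),
                        strata = d$birth_cohort)
  expect_lt(abs(coef(fit_cox(ds))[["x"]] - 0.405), 0.03)
})

test_that("event ages follow the analytic conditional Gompertz survivor function", {
  # inverse-transform correctness: pushing the drawn event times back
  # through the conditional cumulative hazard must recover exact uniforms,
  # for a heterogeneous mix of entry ages and linear predictors and with
  # the early-acting poor-health block switched on
  set.seed(26)
  n <- 100000
  a0 <- runif(n, 40, 70)
  eta <- rnorm(n, 0, 0.5)
  eta_ph <- rep(c(0, 0.8), length.out = n)
  A <- 2e-5
  b <- 0.09
  t <- expowas:::gomp_draw(runif(n), A, b, a0, eta, eta_ph, 4)
  u <- 1 - exp(-expowas:::gomp_cumhaz(t, A, b, a0, eta, eta_ph, 4))
  qq <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(stats::quantile(u, qq) - qq)), 0.02)
  expect_gt(suppressWarnings(stats::ks.test(u, "punif"))$p.value, 0.01)
})

test_that("attained age bookkeeping and proteomic subsampling are exact", {
  sim <- simulate_cohort(cohort_config(n = 5000), seed = 27)
  d <- sim$complete
  expect_equal(d$recruit_age + d$death_time,
               d$recruit_age + d$death_time)  # columns, not recomputed copies
  n_gap <- sum(!is.na(d$proteo_age_gap))
  n_train <- sum(d$region == "train")
  expect_equal(n_gap, round(0.104 * n_train))
  expect_true(all(is.na(d$proteo_age_gap[d$region == "holdout"])))
  expect_true(all(d$bm1 > 0))
})

test_that("ancillary effects behave as planted", {
  sim <- simulate_cohort(cohort_config(n = 100000), seed = 28)
  d <- sim$complete
  # PRS-dominant disease: top-vs-bottom quintile HR close to
  # exp(loghr * 2.80), the expected extreme-quintile mean gap of a
  # standard normal
  q <- cut(d$prs_d2, quantile(d$prs_d2, seq(0, 1, 0.2)), labels = FALSE,
           include.lowest = TRUE)
  sub <- d[q %in% c(1, 5), ]
  ds <- survival_design(sub$recruit_age, sub$recruit_age + sub$d2_time,
                        sub$d2_event,
                        data.frame(top = as.numeric(q[q %in% c(1, 5)] == 5)))
  hr <- exp(coef(fit_cox(ds))[["top"]])
  expect_lt(abs(log(hr) - 0.5 * 2.7979), 3 * fit_cox(ds)$se)
  # sign-discordant decoy carries opposite signs in the two screens
  sdx <- sim$truth$exposure[sim$truth$role == "sign_discordant"]
  dsx <- survival_design(d$recruit_age, d$recruit_age + d$death_time,
                         d$death_event, data.frame(x = d[[sdx]]))
  bm <- coef(fit_cox(dsx))[["x"]]
  gm <- coef(lm(d$proteo_age_gap ~ d[[sdx]]))[2]
  expect_gt(bm, 0)
  expect_lt(gm, 0)
})

test_that("MAR injection hits configured rates and never masks outcomes", {
  cfg <- cohort_config(n = 50000, missingness = c(0.11, rep(0, 41)))
  sim <- simulate_cohort(cfg, seed = 29)
  expect_lt(abs(mean(is.na(sim$cohort$exp01)) - 0.11), 0.01)
  expect_false(anyNA(sim$cohort$death_time))
  expect_false(anyNA(sim$cohort$death_event))
  expect_false(anyNA(sim$cohort$exp02))
  # MAR gradient: positive income coefficient raises missingness on top band
  m_by_band <- tapply(is.na(sim$cohort$exp01), sim$cohort$income_band, mean)
  expect_gt(m_by_band[["5"]], m_by_band[["1"]])
  # rate 0 -> nothing masked
  cfg0 <- cohort_config(n = 2000, missingness = 0)
  sim0 <- simulate_cohort(cfg0, seed = 30)
  expect_false(any(attr(sim0$cohort, "miss_mask")))
  cfg_bad <- cfg0
  cfg_bad$missingness <- rep(0.9, 42)
  expect_error(inject_missingness(sim0$complete, cfg_bad), "below 0.8")
})

test_that("copula marginals are invariant to block correlation", {
  mk <- function(r, seed) {
    cfg <- cohort_config(n = 20000, n_exposures = 2,
                         cluster_blocks = data.frame(size = 2, r = r),
                         exposure_type_mix = c(continuous = 1, ordinal = 0,
                                               binary = 0, nominal = 0),
                         decoy_plan = c(confounded = 0, reverse_causation = 0,
                                        mortality_only = 0,
                                        sign_discordant = 0),
                         true_effects = numeric(0),
                         proteomic_effects = numeric(0), n_diseases = 0)
    generate_exposome(cfg, seed = seed)$exposures$exp01
  }
  ks <- suppressWarnings(stats::ks.test(mk(0, 31), mk(0.7, 32)))
  expect_gt(ks$p.value, 0.01)
})
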