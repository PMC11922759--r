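# Robustness filters: rule fixtures on the pure functions and recovery
# behaviour on generated cohorts with planted decoys.

sim_f <- simulate_cohort(cohort_config(n = 15000), seed = 90)
tr_f <- sim_f$cohort[sim_f$cohort$region == "train", ]
roles_f <- stats::setNames(sim_f$truth$role, sim_f$truth$exposure)

test_that("early-death exclusion attenuates reverse-causation decoys only", {
  rc <- names(roles_f)[roles_f == "reverse_causation"]
  ca <- names(roles_f)[roles_f == "causal"][3]  # block-pure causal exposure
  sp <- sim_f$specs[sim_f$specs$name %in% c(rc, ca), ]
  base <- run_xwas(tr_f, sp, stage = "pooled")
  early <- early_death_sensitivity(tr_f, sp, window = 4)
  for (e in rc) {
    b0 <- base$beta[base$exposure == e]
    b1 <- early$beta[early$exposure == e]
    expect_lt(abs(b1), 0.5 * abs(b0))
  }
  b0 <- base$beta[base$exposure == ca]
  b1 <- early$beta[early$exposure == ca]
  se <- base$se[base$exposure == ca]
  expect_lt(abs(b1 - b0), 2 * se)
  # window 0 excludes nobody
  same <- early_death_sensitivity(tr_f, sp, window = 0)
  expect_equal(same$beta, base$beta, tolerance = 1e-12)
  expect_error(early_death_sensitivity(tr_f, sp, window = 99), "follow-up")
})

test_that("the interaction rule removes reverse-causation decoys and keeps causal exposures", {
  tested <- names(roles_f)[roles_f %in% c("reverse_causation", "causal")]
  sp <- sim_f$specs[sim_f$specs$name %in% tested, ]
  verdicts <- poor_health_interaction_filter(tr_f, sp)
  v <- stats::setNames(verdicts$decision, verdicts$exposure)
  expect_true(all(v[names(roles_f)[roles_f == "reverse_causation"]] ==
                    "remove"))
  expect_gte(mean(v[names(roles_f)[roles_f == "causal"]] == "retain"), 7 / 8)
  # constant indicator rejected
  tr_bad <- tr_f
  tr_bad$poor_health <- 0L
  expect_error(poor_health_interaction_filter(tr_bad, sp), "constant")
})

test_that("PheWAS screen families, guards and the confounded decoy behave", {
  conf <- names(roles_f)[roles_f == "confounded"]
  panel <- data.frame(phenotype = c("income_band", "education_years",
                                    "poor_health", "bm1"),
                      category = c("exposure", "exposure",
                                   "disease_frailty_disability", "other"))
  recs <- phewas_screen(tr_f, conf, panel, sim_f$specs)
  expect_equal(recs$family, rep("linear", 4))
  top <- recs$phenotype[which.max(abs(recs$beta))]
  expect_equal(top, "income_band")
  # binary exposure outcome -> logistic family
  bin <- sim_f$specs$name[sim_f$specs$type == "binary"][1]
  recs_b <- phewas_screen(tr_f, bin, panel[1, , drop = FALSE], sim_f$specs)
  expect_equal(recs_b$family, "logistic")
  # self-regression and constant phenotypes are guarded
  expect_error(phewas_screen(tr_f, "income_band",
                             data.frame(phenotype = "income_band",
                                        category = "exposure"),
                             sim_f$specs), "own phenotype")
  tr_c <- tr_f
  tr_c$bm1 <- 1
  expect_warning(phewas_screen(tr_c, conf, panel, sim_f$specs), "constant")
})

test_that("the two-threshold flag rule is exact on fixtures", {
  mk <- function(beta, p, cat = "exposure") {
    data.frame(exposure = "e", phenotype = paste0("ph", seq_along(beta)),
               category = cat, family = "linear", beta = beta, se = 0.1,
               p = p)
  }
  expect_equal(phewas_flag_rule(mk(1.1, 8.1e-12))$decision, "remove")
  expect_equal(phewas_flag_rule(mk(0.1, 1e-30))$decision, "retain")
  expect_equal(phewas_flag_rule(mk(0.9, 0.2))$decision, "retain")
  # untagged other-category effects never trigger removal
  expect_equal(phewas_flag_rule(mk(2, 1e-40, cat = "other"))$decision,
               "retain")
  # degenerate thresholds remove nothing
  expect_equal(phewas_flag_rule(mk(5, 1e-200), p_thresh = 0,
                                e_thresh = Inf)$decision, "retain")
  expect_error(phewas_flag_rule(mk(1, 0.01, cat = "junk")), "untagged")
  # removals carry a review report
  rv <- attr(phewas_flag_rule(mk(1.1, 8.1e-12)), "review")
  expect_equal(nrow(rv), 1)
})

test_that("proteomic concordance retains causal, drops mortality-only and discordant", {
  tested <- names(roles_f)[roles_f %in% c("causal", "mortality_only",
                                          "sign_discordant")]
  sp <- sim_f$specs[sim_f$specs$name %in% tested, ]
  beta_mort <- stats::setNames(sim_f$truth$beta_mortality[
    match(tested, sim_f$truth$exposure)], tested)
  verdicts <- proteomic_concordance_filter(tr_f, sp, beta_mort)
  v <- stats::setNames(verdicts$decision, verdicts$exposure)
  reason <- stats::setNames(verdicts$reason, verdicts$exposure)
  mo <- names(roles_f)[roles_f == "mortality_only"]
  sd_ <- names(roles_f)[roles_f == "sign_discordant"]
  expect_true(all(v[mo] == "remove"))
  expect_true(all(reason[mo] == "not_associated"))
  expect_equal(unname(v[sd_]), "remove")
  expect_equal(unname(reason[sd_]), "discordant")
  expect_gte(mean(v[names(roles_f)[roles_f == "causal"]] == "retain"), 7 / 8)
  expect_error(proteomic_concordance_filter(tr_f, sp, beta_mort,
                                            min_subsample = 1e7),
               "subsample")
})

test_that("filters are idempotent and read only original inputs", {
  tested <- names(roles_f)[roles_f == "causal"][1:3]
  sp <- sim_f$specs[sim_f$specs$name %in% tested, ]
  v1 <- poor_health_interaction_filter(tr_f, sp)
  survivors <- v1$exposure[v1$decision == "retain"]
  v2 <- poor_health_interaction_filter(tr_f, sp[sp$name %in% survivors, ])
  expect_equal(v2$decision, v1$decision[v1$exposure %in% survivors])
  expect_equal(v2$p_direct, v1$p_direct[v1$exposure %in% survivors],
               tolerance = 1e-12)
})
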