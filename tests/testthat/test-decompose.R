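# PRS handling and the sequential variance-decomposition models.

test_that("PRS scores, quintiles and guards follow their definitions", {
  p <- compute_prs(matrix(c(0, 1, 2), ncol = 1), 0.5)
  expect_equal(p$score, c(0, 0.5, 1.0))
  expect_error(compute_prs(matrix(3, 1, 1), 1), "\\[0, 2\\]")
  expect_error(compute_prs(matrix(c(0, 1), 1), 1), "misaligned")
  expect_warning(p2 <- compute_prs(matrix(c(NA, 1, 2), ncol = 1), 1),
                 "variant mean")
  expect_equal(p2$score[1], 1.5)
  # degenerate: all weights zero -> quintiles rejected
  z <- compute_prs(matrix(runif(30, 0, 2), ncol = 3), c(0, 0, 0))
  expect_error(prs_quintiles(z$score), "degenerate")
  # quintile balance at scale
  set.seed(310)
  q <- prs_quintiles(rnorm(100000))
  expect_true(all(abs(table(q) / 100000 - 0.2) < 0.01))
  # boundaries frozen on the training part
  x <- c(rnorm(1000), rnorm(500, 5))
  train <- rep(c(TRUE, FALSE), c(1000, 500))
  q2 <- prs_quintiles(x, train)
  expect_true(all(q2[!train][x[!train] > 2] == 5))
})

sim_d <- simulate_cohort(cohort_config(n = 30000), seed = 311)
tr_d <- sim_d$complete[sim_d$complete$region == "train", ]
ho_d <- sim_d$complete[sim_d$complete$region == "holdout", ]
specs_d <- sim_d$specs[sim_d$specs$name %in%
                         sim_d$truth$exposure[sim_d$truth$role == "causal"], ]

test_that("nested models are monotone and the exposome dominates mortality", {
  res <- fit_sequential_models(tr_d, specs_d, outcome = "mortality")
  r2 <- res$r2
  expect_gte(r2[["M4"]], max(r2[["M2"]], r2[["M3"]]) - 1e-6)
  expect_gte(min(r2[["M2"]], r2[["M3"]]), r2[["M1"]] - 1e-6)
  # exposome gain dwarfs the PRS gain; PRS on top of the exposome adds
  # less than one percentage point
  expect_gt(r2[["M3"]] - r2[["M1"]], r2[["M2"]] - r2[["M1"]])
  expect_lt(r2[["M4"]] - r2[["M3"]], 0.01)
  imp <- importance_report(res)
  expect_equal(sum(imp$proportion), 1, tolerance = 1e-12)
  expect_gt(imp$proportion[imp$group == "exposome"],
            imp$proportion[imp$group == "prs"])
})

test_that("a PRS-dominant disease reverses the importance ordering", {
  res <- fit_sequential_models(tr_d, specs_d, outcome = "d2")
  imp <- importance_report(res)
  expect_gt(imp$proportion[imp$group == "prs"],
            imp$proportion[imp$group == "exposome"])
  expect_gt(res$r2[["M2"]] - res$r2[["M1"]], res$r2[["M3"]] - res$r2[["M1"]])
})

test_that("missing PRS drops models 2 and 4 but keeps 1 and 3", {
  res <- fit_sequential_models(tr_d, specs_d, outcome = "mortality",
                               prs_cols = character(0))
  expect_equal(res$models, c("M1", "M3"))
  expect_gt(res$r2[["M3"]], res$r2[["M1"]])
})

test_that("sparse categorical levels are excluded from the exposome", {
  d <- tr_d
  d$rare_nom <- factor(rep(c("a", "b", "z"), c(nrow(d) - 30, 15, 15)))
  # level z carries almost no deaths
  d$rare_nom[d$death_event == 1] <- "a"
  sp <- rbind(specs_d[, c("name", "type", "sex_specific")],
              data.frame(name = "rare_nom", type = "nominal",
                         sex_specific = FALSE))
  res <- fit_sequential_models(d, sp, outcome = "mortality",
                               prs_cols = character(0))
  expect_false("rare_nom" %in% res$specs$name)
})

test_that("holdout validation with frozen coefficients is exchangeable and calibrated", {
  res <- fit_sequential_models(tr_d, specs_d, outcome = "mortality")
  hv <- validate_holdout(res, ho_d, tr_d)
  expect_false(any(hv$low_power))
  expect_lt(abs(hv$c_index[hv$model == "M4"] - res$c_index[["M4"]]), 0.03)
  expect_lt(abs(hv$slope[hv$model == "M4"] - 1),
            3 * 0.08)  # calibration slope near 1
  # constant predictor degenerates to C = 0.5, R2 = 0
  res0 <- res
  res0$fits$M1$coefficients[] <- 0
  hv0 <- validate_holdout(res0, ho_d, tr_d)
  expect_equal(hv0$c_index[hv0$model == "M1"], 0.5)
  expect_equal(hv0$r2[hv0$model == "M1"], 0)
})

test_that("importance proportions are invariant to covariate scaling", {
  fake <- list(coefficients = c(a = 0.5, b = 0.25),
               vcov = diag(c(0.01, 0.0025)))
  dimnames(fake$vcov) <- list(c("a", "b"), c("a", "b"))
  w1 <- wald_group_chi2(fake, c(a = "g1", b = "g2"))
  # rescale covariate b by 2: beta and se halve, chi2 unchanged
  fake2 <- list(coefficients = c(a = 0.5, b = 0.125),
                vcov = diag(c(0.01, 0.000625)))
  dimnames(fake2$vcov) <- list(c("a", "b"), c("a", "b"))
  w2 <- wald_group_chi2(fake2, c(a = "g1", b = "g2"))
  expect_equal(w1$proportion, w2$proportion, tolerance = 1e-12)
})

test_that("pooled R2 across identical copies equals the single-copy value", {
  small <- tr_d[1:4000, ]
  r1 <- fit_sequential_models(small, specs_d, outcome = "mortality",
                              prs_cols = character(0), ph_check = FALSE)
  r3 <- fit_sequential_models(list(small, small, small), specs_d,
                              outcome = "mortality",
                              prs_cols = character(0), ph_check = FALSE)
  expect_equal(r1$r2[["M3"]], r3$r2[["M3"]], tolerance = 1e-12)
  expect_equal(r1$c_index[["M3"]], r3$c_index[["M3"]], tolerance = 1e-12)
})
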