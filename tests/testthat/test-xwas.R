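# Exposure coding, the stratified split, BH-FDR, serial screening,
# replication and sex concordance.

test_that("exposure coding follows the type rules", {
  d <- data.frame(cont = c(8, 10, 12, 10),
                  ord = factor(c("never", "previous", "current", "never"),
                               levels = c("never", "previous", "current")),
                  nom = factor(c("A", "A", "B", "C")))
  d$ord <- as.integer(d$ord) - 1L  # linear scores 0,1,2
  specs <- data.frame(name = c("cont", "ord", "nom"),
                      type = c("continuous", "ordinal", "nominal"),
                      sex_specific = FALSE)
  prep <- prepare_exposures(d, specs)
  # mean 10, SD sd(c(8,10,12,10)); value 12 standardized
  expect_equal(prep$mat$cont[3], (12 - 10) / sd(d$cont))
  expect_equal(prep$mat$ord, c(0, 1, 2, 0))
  # modal reference A -> dummies B-vs-A and C-vs-A
  expect_setequal(prep$map$nom, c("nom.B", "nom.C"))
  expect_equal(prep$mat[["nom.B"]], c(0, 0, 1, 0))
  expect_error(prepare_exposures(d, data.frame(name = "cont", type = "wild",
                                               sex_specific = FALSE)),
               "unknown")
  # affine rescaling leaves the standardized column unchanged
  d2 <- d
  d2$cont <- d$cont * 3 + 7
  expect_equal(prepare_exposures(d2, specs)$mat$cont, prep$mat$cont)
})

test_that("the discovery/replication split is stratified, exact and deterministic", {
  d <- data.frame(death_event = rep(c(1, 0), c(100, 900)))
  s <- split_discovery_replication(d, seed = 80)
  expect_equal(as.vector(table(s)), c(500, 500))
  expect_equal(sum(d$death_event[s == "discovery"]), 50)
  expect_identical(s, split_discovery_replication(d, seed = 80))
  expect_false(identical(s, split_discovery_replication(d, seed = 81)))
  # odd totals at cohort scale: halves within one row, case proportions
  # within 0.1pp
  d2 <- data.frame(death_event = rep(c(1, 0), c(1459, 18542)))
  s2 <- split_discovery_replication(d2, seed = 82)
  expect_lte(abs(diff(as.vector(table(s2)))), 1)
  props <- tapply(d2$death_event, s2, mean)
  expect_lt(abs(diff(props)), 0.001)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
      adj[o[i]] <- min(1, min(m * p[o[i:m]] / seq(i, m)))
    }
    adj
  }
  set.seed(83)
  for (i in 1:40) {
    p <- runif(25)
    expect_equal(bh_fdr(p), brute(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, NaN)), "NaN")
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")
})

test_that("the serial screen recovers planted effects and honours its contracts", {
  sim <- simulate_cohort(cohort_config(n = 12000), seed = 84)
  tr <- sim$cohort[sim$cohort$region == "train", ]
  specs <- sim$specs
  recs <- run_xwas(tr, specs, stage = "pooled")
  # HR = exp(beta) to machine precision; FDR-P >= P
  expect_equal(recs$hr, exp(recs$beta), tolerance = 1e-12)
  expect_true(all(recs$fdr_p >= recs$p - 1e-15, na.rm = TRUE))
  # planted effect recovered: exp07 is its block's only causal member, so
  # its marginal screening coefficient is unconfounded
  truth <- sim$truth
  b07 <- truth$beta_mortality[truth$exposure == "exp07"]
  r7 <- recs[recs$exposure == "exp07", ]
  expect_lt(abs(r7$beta - b07) / r7$se, 3)
  # exposure-order invariance of the record set
  recs_perm <- run_xwas(tr, specs[rev(seq_len(nrow(specs))), ],
                        stage = "pooled")
  ord <- order(recs$term)
  ord_p <- order(recs_perm$term)
  expect_equal(recs[ord, c("term", "beta", "se", "p", "fdr_p")],
               recs_perm[ord_p, c("term", "beta", "se", "p", "fdr_p")],
               tolerance = 1e-12, ignore_attr = TRUE)
  # sex-specific exposures are absent from the pooled screen but present
  # in the sex-specific one
  specs2 <- specs
  specs2$sex_specific[specs2$name == "exp03"] <- TRUE
  pooled2 <- run_xwas(tr, specs2, stage = "pooled")
  expect_false("exp03" %in% pooled2$exposure)
  fem <- run_xwas(tr, specs2[specs2$name == "exp03", ], sex = "female",
                  stage = "female")
  expect_true("exp03" %in% fem$exposure)
  # the special-covariate hook shows up in the model descriptor
  hooked <- run_xwas(tr, specs[specs$name == "exp04", ],
                     extra_covariates = list(exp04 = "poor_health"))
  expect_match(hooked$model, "poor_health")
})

test_that("replication demands FDR significance in both stages plus direction", {
  mk <- function(beta, fdr) {
    data.frame(exposure = c("a", "b", "c"), level = NA, term = c("a", "b", "c"),
               beta = beta, se = 0.1, hr = exp(beta), p = fdr / 2,
               fdr_p = fdr, stage = "x", n = 10, n_events = 5, model = "m")
  }
  disc <- mk(c(0.5, 0.4, 0.3), c(0.01, 0.01, 0.2))
  repl <- mk(c(0.4, -0.4, 0.3), c(0.04, 0.04, 0.01))
  rr <- replicate_exposures(disc, repl)
  expect_equal(rr$replicated, c(TRUE, FALSE, FALSE))  # b flips sign, c fails disc
  rr2 <- replicate_exposures(disc, repl, require_direction = FALSE)
  expect_equal(rr2$replicated, c(TRUE, TRUE, FALSE))
  expect_error(replicate_exposures(disc, repl[1:2, ]), "differ")
})

test_that("sex concordance is exact on constructed coefficient vectors", {
  mk <- function(beta) {
    data.frame(exposure = paste0("e", seq_along(beta)), level = NA,
               term = paste0("e", seq_along(beta)), beta = beta)
  }
  b <- c(0.2, -0.1, 0.4, 0.05, -0.3)
  expect_equal(sex_concordance(mk(b), mk(b))$r, 1)
  expect_equal(sex_concordance(mk(b), mk(-b))$r, -1)
  expect_error(sex_concordance(mk(b[1:2]), mk(b[1:2])), "fewer than 3")
})
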