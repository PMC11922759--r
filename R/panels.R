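# Outcome panels for the final exposure set: age-adjusted biomarkers
# (linear models), incident diseases (stratified Cox with prevalent-case
# exclusion) and metabolic risk factors (logistic models), with BH-FDR
# applied within each outcome separately.

panel_pool <- function(est, var_) {
  m <- nrow(est)
  if (m >= 2) {
    pooled <- pool_rubin(est, var_)
    list(beta = pooled$estimate, se = pooled$se, p = pooled$p)
  } else {
    se <- sqrt(var_[1, ])
    list(beta = est[1, ], se = se,
         p = 2 * stats::pnorm(-abs(est[1, ] / se)))
  }
}

finish_panel <- function(recs, effect_name = "beta") {
  if (!length(recs)) {
    return(structure(list(grid = NULL, top = NULL,
                          outcome_counts = table(character(0)),
                          exposure_counts = table(character(0))),
                     class = "panel_result"))
  }
  grid <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  grid$fdr_p <- NA_real_
  for (oc in unique(grid$outcome)) {
    i <- which(grid$outcome == oc & !is.na(grid$p))
    grid$fdr_p[i] <- bh_fdr(grid$p[i])
  }
  # summary counts: for multi-level exposures, the level with the
  # strongest p represents the exposure in the grid counts
  key <- paste(grid$exposure, grid$outcome)
  best <- tapply(seq_len(nrow(grid)), key, function(i) i[which.min(grid$p[i])])
  top <- grid[unlist(best), , drop = FALSE]
  sig <- top[!is.na(top$fdr_p) & top$fdr_p < 0.05, , drop = FALSE]
  structure(list(grid = grid, top = top,
                 outcome_counts = table(factor(sig$outcome,
                                               levels = unique(grid$outcome))),
                 exposure_counts = table(factor(sig$exposure,
                                                levels = unique(grid$exposure)))),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("Panel:", length(unique(x$grid$exposure)), "exposures x",
      length(unique(x$grid$outcome)), "outcomes;",
      sum(x$outcome_counts), "FDR-significant cells\n")
  invisible(x)
}

#' Aging-biomarker panel
#'
#' Biomarkers are log-transformed and age-adjusted by regressing each onto
#' recruitment age separately in women and men; the residuals are the
#' outcomes of per-exposure linear models with the configured covariate
#' roles.
#'
#' @param copies imputed set / data.frame(s).
#' @param specs exposure specs for the final exposure set.
#' @param biomarkers biomarker column names (strictly positive).
#' @param covariates covariate columns for the exposure models.
#' @param extra_covariates named list: biomarker -> additional covariate
#'   columns (e.g. height for IGF-1, leukocyte count, assessment month).
#' @return a `panel_result` (record grid + per-outcome FDR and counts).
#' @export
biomarker_panel <- function(copies, specs, biomarkers,
                            covariates = c("sex", "birth_cohort", "center",
                                           "education_years", "ethnicity",
                                           "n_medications"),
                            extra_covariates = list()) {
  copies <- as_copies(copies)
  m <- length(copies)
  for (bm in biomarkers) {
    x <- copies[[1]][[bm]]
    if (any(x <= 0, na.rm = TRUE)) {
      stop_("nonpositive biomarker value in ", bm, " (row ",
            which(x <= 0)[1], ")")
    }
  }
  per_copy <- lapply(copies, function(d) {
    prep <- prepare_exposures(d, specs)
    adj <- lapply(biomarkers, function(bm) {
      y <- log(d[[bm]])
      res <- numeric(length(y))
      for (s in levels(factor(d$sex))) {
        i <- d$sex == s
        res[i] <- stats::residuals(stats::lm(y[i] ~ d$recruit_age[i]))
      }
      res
    })
    names(adj) <- biomarkers
    list(d = d, prep = prep, adj = adj)
  })
  prep1 <- per_copy[[1]]$prep
  recs <- list()
  for (bm in biomarkers) {
    covs <- unique(c(covariates, extra_covariates[[bm]]))
    for (v in names(prep1$map)) {
      for (col in prep1$map[[v]]) {
        est <- numeric(m)
        var_ <- numeric(m)
        for (ci in seq_len(m)) {
          pc <- per_copy[[ci]]
          df <- cbind(data.frame(.y = pc$adj[[bm]],
                                 .x = pc$prep$mat[[col]]),
                      pc$d[covs])
          cf <- summary(stats::lm(.y ~ ., data = df))$coefficients
          est[ci] <- cf[".x", 1]
          var_[ci] <- cf[".x", 2]^2
        }
        pl <- panel_pool(matrix(est, m), matrix(var_, m))
        recs[[paste(bm, col)]] <- data.frame(
          exposure = v, level = prep1$level[col], term = col, outcome = bm,
          beta = pl$beta, se = pl$se, p = pl$p, family = "linear",
          stringsAsFactors = FALSE)
      }
    }
  }
  finish_panel(recs)
}

#' Incident-disease panel
#'
#' One stratified, left-truncated Cox model per exposure and disease on
#' the age timescale, excluding that disease's prevalent cases from its
#' risk set; BH-FDR within each disease.
#'
#' @param copies imputed set / data.frame(s).
#' @param specs exposure specs.
#' @param diseases disease stems; each needs `<stem>_time`,
#'   `<stem>_event`, and optionally `<stem>_prevalent` columns.
#' @param covariates covariate columns (the screening covariates plus
#'   income, per the disease-model specification).
#' @param strata stratum columns.
#' @return a `panel_result`.
#' @export
disease_panel <- function(copies, specs, diseases,
                          covariates = c("center", "education_years",
                                         "ethnicity", "income_band"),
                          strata = c("birth_cohort", "sex")) {
  copies <- as_copies(copies)
  m <- length(copies)
  recs <- list()
  for (dz in diseases) {
    ev_col <- paste0(dz, "_event")
    tm_col <- paste0(dz, "_time")
    pv_col <- paste0(dz, "_prevalent")
    if (sum(copies[[1]][[ev_col]], na.rm = TRUE) == 0) {
      warn_("disease ", dz, " has no incident events; skipped")
      next
    }
    per_copy <- lapply(copies, function(d) {
      if (pv_col %in% names(d)) d <- d[d[[pv_col]] == 0, , drop = FALSE]
      prep <- prepare_exposures(d, specs)
      base <- data.frame(.entry = d$recruit_age,
                         .exit = d$recruit_age + d[[tm_col]],
                         .event = d[[ev_col]])
      base$.st <- interaction(d[strata], drop = TRUE)
      list(df = cbind(base, d[covariates], prep$mat), prep = prep)
    })
    prep1 <- per_copy[[1]]$prep
    for (v in names(prep1$map)) {
      cols <- prep1$map[[v]]
      rhs <- paste(c(sprintf("`%s`", cols), covariates, "strata(.st)"),
                   collapse = " + ")
      fml <- stats::as.formula(paste("Surv(.entry, .exit, .event) ~", rhs))
      est <- matrix(NA_real_, m, length(cols))
      var_ <- matrix(NA_real_, m, length(cols))
      for (ci in seq_len(m)) {
        fit <- quiet_coxph(fml, data = per_copy[[ci]]$df, ties = "efron")
        b <- stats::coef(fit)
        idx <- match(sprintf("`%s`", cols), names(b))
        if (anyNA(idx)) idx <- match(cols, names(b))
        est[ci, ] <- b[idx]
        var_[ci, ] <- diag(as.matrix(stats::vcov(fit)))[idx]
      }
      pl <- panel_pool(est, var_)
      recs[[paste(dz, v)]] <- data.frame(
        exposure = v, level = prep1$level[cols], term = cols, outcome = dz,
        beta = pl$beta, se = pl$se, p = pl$p, family = "cox",
        stringsAsFactors = FALSE)
    }
  }
  finish_panel(recs)
}

#' Prevalent risk-factor panel
#'
#' Cross-sectional logistic models of each binary risk factor (obesity,
#' hypertension, dyslipidemia analogues) on each exposure; BH-FDR within
#' each factor. Odds ratios satisfy `OR = exp(beta)`.
#'
#' @param copies imputed set / data.frame(s).
#' @param specs exposure specs.
#' @param factors binary risk-factor column names.
#' @param covariates covariate columns.
#' @return a `panel_result` (records carry `or = exp(beta)`).
#' @export
risk_factor_panel <- function(copies, specs, factors,
                              covariates = c("recruit_age", "sex", "center",
                                             "income_band", "education_years",
                                             "ethnicity")) {
  copies <- as_copies(copies)
  m <- length(copies)
  for (rf in factors) {
    pr <- mean(copies[[1]][[rf]], na.rm = TRUE)
    if (pr %in% c(0, 1)) stop_("risk factor ", rf, " has prevalence ", pr)
  }
  per_copy <- lapply(copies, function(d) {
    list(d = d, prep = prepare_exposures(d, specs))
  })
  prep1 <- per_copy[[1]]$prep
  recs <- list()
  for (rf in factors) {
    for (v in names(prep1$map)) {
      for (col in prep1$map[[v]]) {
        est <- numeric(m)
        var_ <- numeric(m)
        for (ci in seq_len(m)) {
          pc <- per_copy[[ci]]
          df <- cbind(data.frame(.y = pc$d[[rf]], .x = pc$prep$mat[[col]]),
                      pc$d[covariates])
          cf <- summary(stats::glm(.y ~ ., data = df,
                                   family = stats::binomial()))$coefficients
          est[ci] <- cf[".x", 1]
          var_[ci] <- cf[".x", 2]^2
        }
        pl <- panel_pool(matrix(est, m), matrix(var_, m))
        recs[[paste(rf, col)]] <- data.frame(
          exposure = v, level = prep1$level[col], term = col, outcome = rf,
          beta = pl$beta, or = exp(pl$beta), se = pl$se, p = pl$p,
          family = "logistic", stringsAsFactors = FALSE)
      }
    }
  }
  # align columns with other panels (keep `or` as extra)
  finish_panel(recs)
}
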