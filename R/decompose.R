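# Sequential multivariable models quantifying age/sex, polygenic risk and
# exposome contributions to mortality and each disease: model 1 (age +
# sex), model 2 (+ PRS quintiles, genotype batch, genetic PCs), model 3
# (+ exposome), model 4 (everything); explained-randomness R-squared and
# C-index per model (Fisher-z pooled across imputed copies), Wald
# chi-squared importance by category, proportional-hazards checks with
# 2-year time-splitting for violators, and frozen-coefficient holdout
# validation.

#' Polygenic risk score from dosages and weights
#'
#' `PRS_i = sum_v dosage_iv * weight_v`; missing dosages fall back to the
#' variant's mean dosage (with a warning). The score is returned both raw
#' and standardized.
#'
#' @param dosages numeric matrix (subjects x variants) with entries in
#'   `[0, 2]`.
#' @param weights per-variant effect sizes.
#' @return list with `score` (raw weighted sum) and `z` (standardized).
#' @export
compute_prs <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(weights)) stop_("weights misaligned with variants")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop_("dosages must lie in [0, 2]")
  }
  if (anyNA(dosages)) {
    warn_("missing dosages replaced by the variant mean")
    for (j in seq_len(ncol(dosages))) {
      mj <- mean(dosages[, j], na.rm = TRUE)
      dosages[is.na(dosages[, j]), j] <- mj
    }
  }
  score <- as.numeric(dosages %*% weights)
  s <- stats::sd(score)
  list(score = score, z = if (s > 0) (score - mean(score)) / s else score * 0)
}

#' Quintile coding of a PRS with training-frozen boundaries
#'
#' Boundaries are the training-region quintiles and are frozen for the
#' holdout rows.
#'
#' @param x PRS values for all subjects.
#' @param train logical (or index) vector marking the training rows.
#' @return integer vector of quintiles 1-5.
#' @export
prs_quintiles <- function(x, train = rep(TRUE, length(x))) {
  qs <- stats::quantile(x[train], probs = seq(0.2, 0.8, 0.2), names = FALSE)
  if (anyDuplicated(qs) || stats::sd(x[train]) == 0) {
    stop_("degenerate PRS distribution: quintile boundaries are not unique")
  }
  as.integer(cut(x, c(-Inf, qs, Inf), labels = FALSE))
}

# Build one model data.frame (+ group tags) for a copy.
build_decomp_frame <- function(d, outcome, exposome_prep, prs_cols, n_pcs,
                               include_prs, include_expo, drop_sex,
                               age_scale) {
  tm <- if (outcome == "mortality") d$death_time else d[[paste0(outcome, "_time")]]
  ev <- if (outcome == "mortality") d$death_event else d[[paste0(outcome, "_event")]]
  df <- data.frame(.time = tm, .event = ev)
  groups <- character(0)
  df$.age <- (d$recruit_age - age_scale[1]) / age_scale[2]
  groups[".age"] <- "age"
  if (!drop_sex) {
    df$.sex <- as.integer(d$sex == "male")
    groups[".sex"] <- "sex"
  }
  if (include_prs && length(prs_cols)) {
    for (pc in prs_cols) {
      q <- d[[paste0(".q_", pc)]]
      for (lv in 2:5) {
        cn <- paste0(pc, ".q", lv)
        df[[cn]] <- as.integer(q == lv)
        groups[cn] <- "prs"
      }
    }
    df$.batch <- d$geno_batch
    groups[".batch"] <- "prs"
    for (p in seq_len(n_pcs)) {
      cn <- paste0(".pc", p)
      df[[cn]] <- d[[paste0("pc", p)]]
      groups[cn] <- "prs"
    }
  }
  if (include_expo && length(exposome_prep$cols)) {
    for (cn in exposome_prep$cols) {
      df[[cn]] <- exposome_prep$mat[[cn]]
      groups[cn] <- "exposome"
    }
  }
  list(df = df, groups = groups)
}

#' Sequential exposome / polygenic-risk decomposition models
#'
#' Fits the four nested Cox models on the time-on-study scale in the
#' training region — model 1: standardized recruitment age + sex; model 2:
#' + outcome PRS quintiles, genotype batch and genetic principal
#' components; model 3: + exposome; model 4: all — and reports
#' explained-randomness R-squared and Harrell's C per model (pooled across
#' imputed copies via the square-root / Fisher-z path), Wald group
#' importance for model 4, and the proportional-hazards violation roster
#' (violators are refit with 2-year time-split interactions).
#'
#' Categorical exposures with fewer than `min_level_cases` outcome cases
#' in any level are excluded from that outcome's exposome. For mortality,
#' all disease PRS enter model 2 jointly.
#'
#' @param copies imputed set / data.frame(s) (training region only).
#' @param specs exposure specs of the outcome's exposome.
#' @param outcome `"mortality"` or a disease stem (`"d1"`, ...).
#' @param prs_cols PRS column names to use (default: all `prs_d*` for
#'   mortality, the matching column for a disease; `character(0)` skips
#'   models 2 and 4).
#' @param n_pcs number of genetic principal components.
#' @param drop_sex drop the sex covariate (sex-specific outcomes).
#' @param min_level_cases exclusion threshold for sparse categorical
#'   exposure levels.
#' @param ph_check test proportional hazards (Schoenfeld, identity time)
#'   and add 2-year time-split interactions for violators.
#' @param ph_alpha flagging level for the PH check.
#' @return object of class `decomposition_result`: per-model `r2`, `c`
#'   (pooled), coefficient tables, `importance` (model 4), `ph_violations`,
#'   and the frozen training metadata needed by [validate_holdout()].
#' @export
fit_sequential_models <- function(copies, specs, outcome = "mortality",
                                  prs_cols = NULL, n_pcs = 4,
                                  drop_sex = FALSE, min_level_cases = 10,
                                  ph_check = TRUE, ph_alpha = 0.05) {
  copies <- as_copies(copies)
  m <- length(copies)
  d1 <- copies[[1]]
  if (is.null(prs_cols)) {
    prs_cols <- if (outcome == "mortality") {
      grep("^prs_d[0-9]+$", names(d1), value = TRUE)
    } else {
      intersect(paste0("prs_", outcome), names(d1))
    }
  }
  has_prs <- length(prs_cols) > 0
  ev <- if (outcome == "mortality") d1$death_event else d1[[paste0(outcome, "_event")]]

  # sparse-level exclusion rule for categorical exposures
  keep_specs <- specs
  for (v in specs$name[specs$type %in% c("nominal", "binary", "ordinal")]) {
    lv_cases <- tapply(ev, d1[[v]], sum)
    if (any(lv_cases < min_level_cases, na.rm = TRUE)) {
      keep_specs <- keep_specs[keep_specs$name != v, , drop = FALSE]
    }
  }

  age_scale <- c(mean(d1$recruit_age), stats::sd(d1$recruit_age))
  # training-frozen PRS quintiles per copy (identical across copies since
  # PRS columns are never imputed)
  copies <- lapply(copies, function(d) {
    for (pc in prs_cols) d[[paste0(".q_", pc)]] <- prs_quintiles(d[[pc]])
    d
  })

  model_defs <- list(M1 = c(prs = FALSE, expo = FALSE),
                     M2 = c(prs = TRUE, expo = FALSE),
                     M3 = c(prs = FALSE, expo = TRUE),
                     M4 = c(prs = TRUE, expo = TRUE))
  if (!has_prs) model_defs <- model_defs[c("M1", "M3")]

  scalings <- vector("list", m)
  fits <- list()
  r2 <- list()
  cind <- list()
  ph_violations <- character(0)
  importance <- NULL
  for (mod in names(model_defs)) {
    def <- model_defs[[mod]]
    r2_copies <- numeric(m)
    c_copies <- numeric(m)
    fit1 <- NULL
    groups <- NULL
    imp_mat <- NULL
    for (ci in seq_len(m)) {
      d <- copies[[ci]]
      prep <- prepare_exposures(d, keep_specs)
      scalings[[ci]] <- attr(prep$mat, "scaling")
      expo <- list(cols = unlist(prep$map), mat = prep$mat)
      bf <- build_decomp_frame(d, outcome, expo, prs_cols, n_pcs,
                               def[["prs"]], def[["expo"]], drop_sex,
                               age_scale)
      df <- bf$df
      covs <- setdiff(names(df), c(".time", ".event"))
      fml <- stats::as.formula(paste("Surv(.time, .event) ~",
                                     paste(sprintf("`%s`", covs),
                                           collapse = " + ")))
      fit <- quiet_coxph(fml, data = df, ties = "efron")
      flagged <- character(0)
      if (ph_check && mod == "M4") {
        zp <- tryCatch(survival::cox.zph(fit, transform = "identity",
                                         terms = FALSE, global = FALSE),
                       error = function(e) NULL)
        if (!is.null(zp)) {
          tab <- as.data.frame(zp$table)
          flagged <- gsub("`", "", rownames(tab)[tab$p < ph_alpha])
        }
        if (length(flagged)) {
          ph_violations <- union(ph_violations, flagged)
          sp <- df
          names(sp)[names(sp) == ".time"] <- "exit"
          sp$entry <- 0
          names(sp)[names(sp) == ".event"] <- "event"
          sp <- split_survival_time(sp, 2, time_varying = flagged)
          tv_cols <- paste0(flagged, "_x_time")
          fml2 <- stats::as.formula(
            paste("Surv(entry, exit, event) ~",
                  paste(sprintf("`%s`", c(covs, tv_cols)), collapse = " + ")))
          fit <- quiet_coxph(fml2, data = sp, ties = "efron")
        }
      }
      ll <- fit$loglik
      nev <- sum(df$.event)
      r2_copies[ci] <- 1 - exp(-2 * (ll[2] - ll[1]) / nev)
      cc <- survival::concordance(fit)
      c_copies[ci] <- unname(cc$concordance)
      if (ci == 1) {
        fit1 <- fit
        groups <- bf$groups
      }
      if (mod == "M4" || (!has_prs && mod == "M3")) {
        cfit <- list(coefficients = stats::coef(fit),
                     vcov = as.matrix(stats::vcov(fit)))
        nm <- names(cfit$coefficients) <- gsub("`", "",
                                               names(cfit$coefficients))
        dimnames(cfit$vcov) <- list(nm, nm)
        gr <- bf$groups
        extra <- setdiff(nm, names(gr))
        if (length(extra)) {
          gr[extra] <- gr[gsub("_x_time$", "", extra)]
        }
        w <- wald_group_chi2(cfit, gr)
        if (is.null(imp_mat)) {
          imp_mat <- matrix(0, m, nrow(w), dimnames = list(NULL, w$group))
        }
        imp_mat[ci, w$group] <- w$proportion
      }
    }
    r2[[mod]] <- if (m >= 2) pool_fisher_z(r2_copies, "r2") else r2_copies[1]
    cind[[mod]] <- if (m >= 2) pool_fisher_z(c_copies, "cindex") else c_copies[1]
    fits[[mod]] <- fit1
    if (!is.null(imp_mat)) {
      importance <- data.frame(group = colnames(imp_mat),
                               proportion = colMeans(imp_mat),
                               row.names = NULL)
    }
  }
  structure(list(outcome = outcome, models = names(model_defs),
                 r2 = unlist(r2), c_index = unlist(cind),
                 fits = fits, importance = importance,
                 ph_violations = ph_violations,
                 specs = keep_specs, prs_cols = prs_cols, n_pcs = n_pcs,
                 drop_sex = drop_sex, age_scale = age_scale,
                 m = m),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("Sequential decomposition for", x$outcome, "\n")
  print(data.frame(model = x$models, r2 = x$r2[x$models],
                   c_index = x$c_index[x$models], row.names = NULL))
  if (!is.null(x$importance)) {
    cat("model-4 importance:\n")
    print(x$importance)
  }
  if (length(x$ph_violations)) {
    cat("PH violations (time interactions added):",
        paste(x$ph_violations, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Frozen-coefficient holdout validation
#'
#' For each fitted model, the training coefficients are applied to the
#' holdout rows to form a linear predictor (continuous exposures are
#' standardized with training statistics; PRS quintile boundaries are the
#' frozen training ones); a one-covariate Cox of the holdout outcome on
#' that predictor yields the holdout explained-randomness R-squared and
#' C-index.
#'
#' @param result a `decomposition_result`.
#' @param holdout_copies holdout-region imputed set / data.frame(s).
#' @param train_copies the training copies (for the frozen quintile
#'   boundaries and exposure scaling).
#' @return data.frame per model with holdout r2, c-index, calibration
#'   slope and the low-power flag (fewer than 10 holdout events).
#' @export
validate_holdout <- function(result, holdout_copies, train_copies) {
  holdout_copies <- as_copies(holdout_copies)
  train_copies <- as_copies(train_copies)
  out <- list()
  d_tr <- train_copies[[1]]
  d_ho <- holdout_copies[[1]]
  for (pc in result$prs_cols) {
    d_ho[[paste0(".q_", pc)]] <-
      prs_quintiles(c(d_tr[[pc]], d_ho[[pc]]),
                    train = c(rep(TRUE, nrow(d_tr)),
                              rep(FALSE, nrow(d_ho))))[-seq_len(nrow(d_tr))]
  }
  # training-scaled exposure coding for the holdout
  prep_tr <- prepare_exposures(d_tr, result$specs)
  prep_ho <- prepare_exposures_scaled(d_ho, result$specs, prep_tr)
  expo <- list(cols = unlist(prep_ho$map), mat = prep_ho$mat)
  for (mod in result$models) {
    def <- c(prs = grepl("2|4", mod), expo = grepl("3|4", mod))
    bf <- build_decomp_frame(d_ho, result$outcome, expo, result$prs_cols,
                             result$n_pcs, def[["prs"]], def[["expo"]],
                             result$drop_sex, result$age_scale)
    df <- bf$df
    beta <- stats::coef(result$fits[[mod]])
    names(beta) <- gsub("`", "", names(beta))
    beta <- beta[!grepl("_x_time$", names(beta))]
    X <- as.matrix(df[names(beta)])
    lp <- as.numeric(X %*% beta)
    nev <- sum(df$.event)
    if (stats::sd(lp) == 0) {
      out[[mod]] <- data.frame(model = mod, r2 = 0, c_index = 0.5,
                               slope = NA_real_, n_events = nev,
                               low_power = nev < 10)
      next
    }
    vd <- data.frame(.time = df$.time, .event = df$.event, lp = lp)
    fit <- quiet_coxph(Surv(.time, .event) ~ lp, data = vd, ties = "efron")
    r2 <- 1 - exp(-2 * (fit$loglik[2] - fit$loglik[1]) / nev)
    cc <- unname(survival::concordance(fit)$concordance)
    out[[mod]] <- data.frame(model = mod, r2 = r2, c_index = cc,
                             slope = unname(stats::coef(fit)),
                             n_events = nev, low_power = nev < 10)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Exposure coding with frozen scaling from a training prepare_exposures().
prepare_exposures_scaled <- function(data, specs, train_prep) {
  sc <- attr(train_prep$mat, "scaling")
  prep <- prepare_exposures(data, specs, scaling = sc,
                            references = attr(train_prep$mat, "references"))
  prep
}

#' Wald-importance report for a fitted decomposition model
#'
#' @param result a `decomposition_result`.
#' @return the model-4 per-category importance proportions (summing to 1).
#' @export
importance_report <- function(result) {
  if (is.null(result$importance)) stop_("no grouped model available")
  result$importance
}
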