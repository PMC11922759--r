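# Post-replication robustness screens: early-death sensitivity,
# the poor-health interaction rule (reverse causation), the per-exposure
# PheWAS with its two-threshold flag rule (residual confounding /
# redundancy), and the proteomic-age concordance rule (non-aging
# exposures). Each filter reads only the original cohort and the
# replicated exposure list, so retain/remove decisions are
# order-independent and idempotent.


#' Early-death sensitivity re-screen
#'
#' Re-runs the mortality screen excluding participants who died within the
#' first `window` years of follow-up; associations driven by prevalent
#' illness at baseline attenuate. The comparison is advisory: removal is
#' driven by the interaction rule, not by this table.
#'
#' @param copies imputed set / data.frame(s).
#' @param specs exposure specs restricted to the exposures under test.
#' @param window exclusion window in years (deaths before `window` are
#'   dropped).
#' @param ... passed to [run_xwas()].
#' @return association records with stage `"early_death"`.
#' @export
early_death_sensitivity <- function(copies, specs, window = 4, ...) {
  copies <- as_copies(copies)
  maxfu <- max(copies[[1]]$death_time)
  if (window >= maxfu) stop_("window exceeds the maximum follow-up")
  trimmed <- lapply(copies, function(d) {
    d[!(d$death_event == 1 & d$death_time < window), , drop = FALSE]
  })
  run_xwas(trimmed, specs, stage = "early_death", ...)
}

#' Poor-health interaction filter for reverse causation
#'
#' Augments each exposure's screening model with the baseline poor-health
#' indicator and its interaction with the exposure. An exposure is removed
#' iff its direct effect is no longer significant (p >= alpha) while the
#' interaction is significant (p < alpha) — the signature of an
#' association carried entirely by prevalent disease.
#'
#' @param copies imputed set / data.frame(s).
#' @param specs exposure specs for the exposures under test.
#' @param alpha significance level for both clauses of the rule.
#' @param covariates,strata as in [run_xwas()].
#' @param rows optional row subset.
#' @return data.frame of verdicts with the supporting direct/interaction
#'   statistics.
#' @export
poor_health_interaction_filter <- function(copies, specs, alpha = 0.05,
                                           covariates = c("center",
                                                          "education_years",
                                                          "ethnicity"),
                                           strata = c("birth_cohort", "sex"),
                                           rows = NULL) {
  copies <- as_copies(copies)
  m <- length(copies)
  if (length(unique(copies[[1]]$poor_health)) < 2) {
    stop_("poor_health indicator is constant")
  }
  per_copy <- lapply(copies, function(d) {
    if (!is.null(rows)) d <- d[rows, , drop = FALSE]
    prep <- prepare_exposures(d, specs)
    base <- data.frame(.entry = d$recruit_age,
                       .exit = d$recruit_age + d$death_time,
                       .event = d$death_event,
                       .ph = d$poor_health)
    base$.st <- interaction(d[strata], drop = TRUE)
    list(df = cbind(base, d[covariates], prep$mat), prep = prep)
  })
  prep1 <- per_copy[[1]]$prep
  out <- list()
  for (v in names(prep1$map)) {
    cols <- prep1$map[[v]]
    # one direct + one interaction term per level column
    terms_dir <- sprintf("`%s`", cols)
    terms_int <- sprintf("`%s`:.ph", cols)
    rhs <- paste(c(terms_dir, ".ph", terms_int, covariates, "strata(.st)"),
                 collapse = " + ")
    fml <- stats::as.formula(paste("Surv(.entry, .exit, .event) ~", rhs))
    nm_all <- NULL
    est <- NULL
    var_ <- NULL
    for (ci in seq_len(m)) {
      fit <- quiet_coxph(fml, data = per_copy[[ci]]$df, ties = "efron")
      b <- stats::coef(fit)
      if (is.null(nm_all)) {
        nm_all <- names(b)
        est <- matrix(NA_real_, m, length(b))
        var_ <- matrix(NA_real_, m, length(b))
      }
      est[ci, ] <- b
      var_[ci, ] <- diag(as.matrix(stats::vcov(fit)))
    }
    if (m >= 2) {
      pooled <- pool_rubin(est, var_)
      p <- pooled$p
    } else {
      p <- 2 * stats::pnorm(-abs(est[1, ] / sqrt(var_[1, ])))
    }
    names(p) <- nm_all
    plain <- gsub("`", "", nm_all)
    i_dir <- match(cols, plain)
    i_int <- match(paste0(cols, ":.ph"), plain)
    if (anyNA(i_int)) i_int <- match(paste0(".ph:", cols), plain)
    p_dir <- min(p[i_dir], na.rm = TRUE)
    p_int <- min(p[i_int], na.rm = TRUE)
    remove <- p_dir >= alpha && p_int < alpha
    out[[v]] <- data.frame(exposure = v, filter = "poor_health_interaction",
                           decision = if (remove) "remove" else "retain",
                           reason = if (remove) {
                             sprintf("direct p=%.3g >= %.2f and interaction p=%.3g < %.2f",
                                     p_dir, alpha, p_int, alpha)
                           } else "direct effect persists",
                           p_direct = p_dir, p_interaction = p_int,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Phenome-wide screen of one exposure
#'
#' Regresses the exposure (as outcome) on each phenotype of the panel,
#' adjusting for recruitment age and sex: linear regression for
#' continuous/ordinal exposure outcomes, logistic for binary, and
#' per-level-vs-reference logistic for nominal ones. Continuous phenotypes
#' are standardized before the regression. Results are pooled across
#' imputed copies by Rubin's rules.
#'
#' @param copies imputed set / data.frame(s).
#' @param exposure name of the exposure used as outcome.
#' @param panel data.frame with columns `phenotype` (column name) and
#'   `category` (one of `disease_frailty_disability`, `exposure`, `other`).
#' @param specs exposure specs (for the outcome's type).
#' @return association records: one per phenotype (x level for nominal
#'   outcomes) with standardized effect, p, family and category tag.
#' @export
phewas_screen <- function(copies, exposure, panel, specs) {
  copies <- as_copies(copies)
  m <- length(copies)
  if (exposure %in% panel$phenotype) {
    stop_("the exposure cannot appear in its own phenotype panel")
  }
  ty <- specs$type[match(exposure, specs$name)]
  # age/sex adjustment by residual projection, computed once per copy:
  # the adjusted slope of y on x equals the slope of the residualized
  # y on the residualized x (Frisch-Waugh), so the serial panel needs
  # only O(n) work per phenotype
  proj <- lapply(copies, function(d) {
    C <- cbind(1, d$recruit_age, as.integer(d$sex == "male"))
    CtCi <- solve(crossprod(C))
    y <- d[[exposure]]
    y <- as.numeric(y)
    ystar <- y - C %*% (CtCi %*% crossprod(C, y))
    list(C = C, CtCi = CtCi, ystar = as.numeric(ystar))
  })
  recs <- list()
  for (i in seq_len(nrow(panel))) {
    ph <- panel$phenotype[i]
    fam <- NULL
    est <- c()
    var_ <- c()
    skipped <- FALSE
    for (ci in seq_len(m)) {
      d <- copies[[ci]]
      x <- d[[ph]]
      if (length(unique(x[!is.na(x)])) < 2) {
        warn_("phenotype ", ph, " is constant; skipped")
        skipped <- TRUE
        break
      }
      # every phenotype enters in SD units so the flag rule's single
      # standardized-effect threshold is comparable across types
      x <- standardize(as.numeric(if (is.factor(x)) as.integer(x) else x))
      if (ty %in% c("continuous", "ordinal")) {
        fam <- "linear"
        pr <- proj[[ci]]
        xstar <- x - pr$C %*% (pr$CtCi %*% crossprod(pr$C, x))
        sxx <- sum(xstar^2)
        beta <- sum(xstar * pr$ystar) / sxx
        dfree <- nrow(pr$C) - ncol(pr$C) - 1
        sigma2 <- (sum(pr$ystar^2) - beta^2 * sxx) / dfree
        est[ci] <- beta
        var_[ci] <- sigma2 / sxx
      } else {
        y <- d[[exposure]]
        df <- data.frame(.x = x, .age = d$recruit_age, .sex = d$sex)
        df$.y <- if (is.factor(y)) {
          as.integer(y != names(which.max(table(y))))
        } else as.integer(y)
        fit <- stats::glm(.y ~ .x + .age + .sex, data = df,
                          family = stats::binomial())
        fam <- "logistic"
        cf <- summary(fit)$coefficients
        est[ci] <- cf[".x", 1]
        var_[ci] <- cf[".x", 2]^2
      }
    }
    if (skipped) next
    if (m >= 2) {
      pooled <- pool_rubin(est, var_)
      beta <- pooled$estimate
      se <- pooled$se
      p <- pooled$p
    } else {
      beta <- est[1]
      se <- sqrt(var_[1])
      p <- 2 * stats::pnorm(-abs(beta / se))
    }
    recs[[ph]] <- data.frame(exposure = exposure, phenotype = ph,
                             category = panel$category[i], family = fam,
                             beta = beta, se = se, p = p,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(recs, list(make.row.names = FALSE)))
}

#' Two-threshold PheWAS flag rule
#'
#' Codifies "associated extremely strongly with a disease/frailty/
#' disability phenotype or with another exposure": remove iff any tagged
#' phenotype reaches `p < p_thresh` with `|standardized effect| >=
#' e_thresh`. Every removal is also emitted to a human-review report
#' attached as attribute `review`.
#'
#' @param records output of [phewas_screen()].
#' @param p_thresh p-value threshold (default 1e-10).
#' @param e_thresh standardized-effect threshold (default 0.5).
#' @return one verdict row; offending phenotypes in `reason`.
#' @export
phewas_flag_rule <- function(records, p_thresh = 1e-10, e_thresh = 0.5) {
  if (any(!records$category %in%
          c("disease_frailty_disability", "exposure", "other"))) {
    stop_("untagged phenotype categories present")
  }
  tagged <- records[records$category %in%
                      c("disease_frailty_disability", "exposure"), ,
                    drop = FALSE]
  hits <- tagged[tagged$p < p_thresh & abs(tagged$beta) >= e_thresh, ,
                 drop = FALSE]
  remove <- nrow(hits) > 0
  out <- data.frame(exposure = records$exposure[1], filter = "phewas",
                    decision = if (remove) "remove" else "retain",
                    reason = if (remove) {
                      paste0("strong association with ",
                             paste(hits$phenotype, collapse = ", "))
                    } else "no extreme tagged association",
                    n_hits = nrow(hits), stringsAsFactors = FALSE)
  attr(out, "review") <- hits
  out
}

#' Proteomic-age concordance filter
#'
#' Within the proteomic subsample, regresses the proteomic age gap on each
#' exposure with covariates sex, recruitment age, assessment center, years
#' of education and ethnicity; BH-FDR across the tested exposures. An
#' exposure is retained iff FDR-p < alpha AND the sign of its age-gap
#' slope agrees with the sign of its mortality coefficient; otherwise it
#' is removed as `not_associated` or `discordant`.
#'
#' @param copies imputed set / data.frame(s) carrying `proteo_age_gap`.
#' @param specs exposure specs for the exposures under test.
#' @param mortality_beta named vector of mortality coefficients (per
#'   exposure; for nominal exposures, of the reported level).
#' @param alpha FDR threshold.
#' @param covariates adjustment columns.
#' @param min_subsample smallest admissible proteomic subsample.
#' @return verdict data.frame with gamma, fdr-p and the removal reason.
#' @export
proteomic_concordance_filter <- function(copies, specs, mortality_beta,
                                         alpha = 0.05,
                                         covariates = c("sex", "recruit_age",
                                                        "center",
                                                        "education_years",
                                                        "ethnicity"),
                                         min_subsample = 100) {
  copies <- as_copies(copies)
  m <- length(copies)
  nsub <- sum(!is.na(copies[[1]]$proteo_age_gap))
  if (nsub < min_subsample) {
    stop_("proteomic subsample smaller than the configured minimum (",
          nsub, " < ", min_subsample, ")")
  }
  est <- matrix(NA_real_, m, nrow(specs), dimnames = list(NULL, specs$name))
  var_ <- est
  for (ci in seq_len(m)) {
    d <- copies[[ci]]
    d <- d[!is.na(d$proteo_age_gap), , drop = FALSE]
    prep <- prepare_exposures(d, specs)
    base <- cbind(data.frame(.y = d$proteo_age_gap), d[covariates], prep$mat)
    for (v in specs$name) {
      cols <- prep$map[[v]]
      # for nominal exposures test the level reported in the mortality screen
      col <- cols[1]
      if (length(cols) > 1 && !is.null(names(mortality_beta))) {
        hit <- cols[cols %in% names(mortality_beta)]
        if (length(hit)) col <- hit[1]
      }
      fml <- stats::as.formula(paste0(".y ~ `", col, "` + ",
                                      paste(covariates, collapse = " + ")))
      cf <- summary(stats::lm(fml, data = base))$coefficients
      est[ci, v] <- cf[2, 1]
      var_[ci, v] <- cf[2, 2]^2
    }
  }
  if (m >= 2) {
    pooled <- pool_rubin(est, var_)
    gamma <- pooled$estimate
    p <- pooled$p
  } else {
    gamma <- est[1, ]
    p <- 2 * stats::pnorm(-abs(gamma / sqrt(var_[1, ])))
  }
  fdr <- bh_fdr(p)
  beta <- mortality_beta[specs$name]
  concordant <- sign(gamma) == sign(beta)
  retain <- fdr < alpha & concordant
  reason <- ifelse(retain, "associated with proteomic aging, concordant",
            ifelse(fdr >= alpha, "not_associated", "discordant"))
  data.frame(exposure = specs$name, filter = "proteomic_concordance",
             decision = ifelse(retain, "retain", "remove"),
             reason = reason, gamma = unname(gamma), fdr_p = unname(fdr),
             beta_mortality = unname(beta),
             stringsAsFactors = FALSE, row.names = NULL)
}
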