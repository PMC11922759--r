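# Exposome-wide association screening: exposure coding, the stratified
# discovery/replication split, serial Cox screening with Rubin pooling and
# Benjamini-Hochberg FDR, the replication rule, and the sex-concordance
# check.

#' Infer exposure metadata from cohort columns
#'
#' @param data cohort data.frame.
#' @param exposures character vector of exposure column names.
#' @return data.frame of per-exposure specs (name, type, sex_specific).
#' @export
infer_exposure_specs <- function(data, exposures) {
  type <- vapply(exposures, function(v) {
    x <- data[[v]]
    if (is.factor(x) || is.character(x)) return("nominal")
    u <- unique(x[!is.na(x)])
    if (length(u) <= 2) return("binary")
    if (is.integer(x) || all(u == round(u))) return("ordinal")
    "continuous"
  }, character(1))
  data.frame(name = exposures, type = unname(type), sex_specific = FALSE,
             stringsAsFactors = FALSE)
}

#' Code exposures for modeling
#'
#' Continuous exposures are centered and standardized in the analysis
#' sample; ordinal exposures enter as unstandardized integer scores
#' (linear contrasts only); binary exposures as 0/1; nominal exposures are
#' expanded to dummies against the modal reference level. Columns with
#' 80% or more missing are dropped (the exposure inclusion rule).
#'
#' @param data cohort data.frame.
#' @param specs exposure spec data.frame (see [infer_exposure_specs()]).
#' @param scaling optional named list `column -> c(mean, sd)` freezing the
#'   standardization of continuous exposures (e.g. training statistics
#'   applied to a holdout).
#' @param references optional named list `exposure -> list(ref, levels)`
#'   freezing nominal reference levels.
#' @return list with `mat` (data.frame of model-ready columns, carrying
#'   the applied `scaling`/`references` as attributes), `map` (exposure
#'   name to column names), `level` (column name to nominal level label or
#'   `NA`), and `dropped` (exposures dropped by the inclusion rule).
#' @export
prepare_exposures <- function(data, specs, scaling = NULL,
                              references = NULL) {
  mat <- list()
  map <- list()
  level <- character(0)
  dropped <- character(0)
  scl <- list()
  refs <- list()
  for (i in seq_len(nrow(specs))) {
    v <- specs$name[i]
    ty <- specs$type[i]
    x <- data[[v]]
    if (is.null(x)) stop_("exposure column missing from data: ", v)
    if (mean(is.na(x)) >= 0.8) {
      dropped <- c(dropped, v)
      next
    }
    if (ty == "continuous") {
      ms <- scaling[[v]] %||% c(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
      if (!is.finite(ms[2]) || ms[2] == 0) stop_("constant exposure: ", v)
      mat[[v]] <- (x - ms[1]) / ms[2]
      scl[[v]] <- ms
      map[[v]] <- v
      level[v] <- NA_character_
    } else if (ty %in% c("ordinal", "binary")) {
      mat[[v]] <- as.numeric(x)
      map[[v]] <- v
      level[v] <- NA_character_
    } else if (ty == "nominal") {
      rf <- references[[v]]
      f <- if (is.null(rf)) factor(x) else factor(x, levels = rf$levels)
      ref <- if (is.null(rf)) names(which.max(table(f))) else rf$ref
      refs[[v]] <- list(ref = ref, levels = levels(f))
      other <- setdiff(levels(f), ref)
      cols <- character(0)
      for (lv in other) {
        cn <- paste0(v, ".", lv)
        mat[[cn]] <- as.numeric(f == lv)
        level[cn] <- lv
        cols <- c(cols, cn)
      }
      map[[v]] <- cols
    } else {
      stop_("unknown exposure type tag: ", ty)
    }
  }
  mat <- as.data.frame(mat, optional = TRUE)
  attr(mat, "scaling") <- scl
  attr(mat, "references") <- refs
  list(mat = mat, map = map, level = level, dropped = dropped)
}

#' Stratified discovery/replication split
#'
#' 50/50 random partition of rows stratified on the mortality indicator so
#' both halves carry the same case proportion.
#'
#' @param data cohort data.frame with `death_event`.
#' @param seed integer seed.
#' @return factor of `"discovery"`/`"replication"` per row.
#' @export
split_discovery_replication <- function(data, seed = 1) {
  set.seed(seed)
  n <- nrow(data)
  stage <- character(n)
  ev <- data$death_event == 1
  for (grp in list(which(ev), which(!ev))) {
    k <- length(grp)
    shuffled <- grp[sample.int(k)]
    # events: extra one to discovery; non-events: extra one to replication,
    # keeping the overall halves within one row of each other
    nd <- if (identical(grp, which(ev))) ceiling(k / 2) else floor(k / 2)
    stage[shuffled[seq_len(nd)]] <- "discovery"
    stage[shuffled[setdiff(seq_len(k), seq_len(nd))]] <- "replication"
  }
  factor(stage, levels = c("discovery", "replication"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p vector of p-values in `[0, 1]` (no `NaN`).
#' @return step-up adjusted p-values, monotone and capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(is.nan(p))) stop_("NaN p-values")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

as_copies <- function(x) {
  if (inherits(x, "imputed_set")) return(x$copies)
  if (is.data.frame(x)) return(list(x))
  if (is.list(x)) return(x)
  stop_("expected an imputed_set, a data.frame or a list of data.frames")
}

#' Serial exposome-wide Cox screen
#'
#' Fits one stratified, left-truncated Cox model per exposure per imputed
#' copy — age as the timescale (entry at recruitment age), strata =
#' 5-year birth cohort crossed with sex, covariates assessment center,
#' years of education and ethnicity — and pools coefficients across copies
#' by Rubin's rules. One association record is emitted per exposure level,
#' with BH-FDR across the records of the stage.
#'
#' @param copies an `imputed_set`, a single data.frame, or a list of
#'   data.frames (complete-data analysis is the m = 1 case).
#' @param specs exposure spec data.frame.
#' @param covariates covariate column names.
#' @param strata stratum column names (crossed).
#' @param sex `NULL` for the pooled screen (which omits sex-specific
#'   exposures and keeps sex in the strata) or `"female"`/`"male"` for a
#'   sex-specific screen on that subset.
#' @param extra_covariates named list: exposure name -> additional
#'   covariate columns for that exposure's model only (e.g. adding overall
#'   health status for a self-reported alcohol exposure).
#' @param stage stage label stored on the records.
#' @param rows optional row subset (applied to every copy).
#' @return data.frame of association records: exposure, level, term, beta,
#'   se, hr, p, fdr_p, stage, n, n_events, model.
#' @export
run_xwas <- function(copies, specs,
                     covariates = c("center", "education_years", "ethnicity"),
                     strata = c("birth_cohort", "sex"),
                     sex = NULL, extra_covariates = list(),
                     stage = "pooled", rows = NULL) {
  copies <- as_copies(copies)
  m <- length(copies)
  if (!is.null(sex)) {
    strata <- setdiff(strata, "sex")
  } else if (any(specs$sex_specific)) {
    specs <- specs[!specs$sex_specific, , drop = FALSE]
  }
  per_copy <- lapply(copies, function(d) {
    if (!is.null(rows)) d <- d[rows, , drop = FALSE]
    if (!is.null(sex)) d <- d[d$sex == sex, , drop = FALSE]
    prep <- prepare_exposures(d, specs)
    base <- data.frame(.entry = d$recruit_age,
                       .exit = d$recruit_age + d$death_time,
                       .event = d$death_event)
    base$.st <- interaction(d[strata], drop = TRUE)
    cov_df <- d[intersect(unique(c(covariates,
                                   unlist(extra_covariates))), names(d))]
    list(df = cbind(base, cov_df, prep$mat), prep = prep,
         n = nrow(base), n_events = sum(base$.event))
  })
  prep1 <- per_copy[[1]]$prep
  recs <- list()
  for (v in names(prep1$map)) {
    cols <- prep1$map[[v]]
    covs <- covariates
    extra <- extra_covariates[[v]]
    if (!is.null(extra)) covs <- unique(c(covs, extra))
    rhs <- paste(c(sprintf("`%s`", cols), covs, "strata(.st)"),
                 collapse = " + ")
    fml <- stats::as.formula(paste("Surv(.entry, .exit, .event) ~", rhs))
    est <- matrix(NA_real_, m, length(cols))
    var_ <- matrix(NA_real_, m, length(cols))
    aliased <- FALSE
    for (ci in seq_len(m)) {
      fit <- quiet_coxph(fml, data = per_copy[[ci]]$df, ties = "efron")
      b <- stats::coef(fit)[sprintf("`%s`", cols)]
      if (anyNA(b)) b <- stats::coef(fit)[cols]
      if (anyNA(b)) {
        aliased <- TRUE
        break
      }
      est[ci, ] <- b
      var_[ci, ] <- diag(as.matrix(stats::vcov(fit)))[seq_along(cols)]
    }
    model_desc <- paste0("cox[age timescale|strata ",
                         paste(strata, collapse = "*"), "|covs ",
                         paste(covs, collapse = ","), "]")
    if (aliased) {
      recs[[v]] <- data.frame(exposure = v, level = prep1$level[cols],
                              term = cols, beta = NA_real_, se = NA_real_,
                              hr = NA_real_, p = NA_real_,
                              stage = stage, n = per_copy[[1]]$n,
                              n_events = per_copy[[1]]$n_events,
                              model = paste0(model_desc, "|ALIASED"),
                              stringsAsFactors = FALSE)
      next
    }
    if (m >= 2) {
      pooled <- pool_rubin(est, var_)
      beta <- pooled$estimate
      se <- pooled$se
      p <- pooled$p
    } else {
      beta <- est[1, ]
      se <- sqrt(var_[1, ])
      p <- 2 * stats::pnorm(-abs(beta / se))
    }
    recs[[v]] <- data.frame(exposure = v, level = prep1$level[cols],
                            term = cols, beta = beta, se = se,
                            hr = exp(beta), p = p, stage = stage,
                            n = per_copy[[1]]$n,
                            n_events = per_copy[[1]]$n_events,
                            model = model_desc, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  ok <- !is.na(out$p)
  out$fdr_p <- NA_real_
  out$fdr_p[ok] <- bh_fdr(out$p[ok])
  out
}

#' Replication rule across discovery and replication records
#'
#' An exposure level replicates iff its FDR-adjusted p-value is below
#' `alpha` in both stages and (by default) the effect directions agree.
#'
#' @param discovery,replication aligned record data.frames from
#'   [run_xwas()].
#' @param alpha FDR significance threshold.
#' @param require_direction demand directional consistency.
#' @return data.frame with exposure, level, per-stage statistics and
#'   `replicated`.
#' @export
replicate_exposures <- function(discovery, replication, alpha = 0.05,
                                require_direction = TRUE) {
  key_d <- paste(discovery$exposure, discovery$term)
  key_r <- paste(replication$exposure, replication$term)
  if (!setequal(key_d, key_r)) {
    stop_("exposure(-level) sets differ between stages: ",
          paste(c(setdiff(key_d, key_r), setdiff(key_r, key_d)),
                collapse = ", "))
  }
  r <- replication[match(key_d, key_r), ]
  rep_ok <- discovery$fdr_p < alpha & r$fdr_p < alpha
  if (require_direction) {
    rep_ok <- rep_ok & sign(discovery$beta) == sign(r$beta)
  }
  rep_ok[is.na(rep_ok)] <- FALSE
  data.frame(exposure = discovery$exposure, level = discovery$level,
             term = discovery$term,
             beta_discovery = discovery$beta, fdr_p_discovery = discovery$fdr_p,
             beta_replication = r$beta, fdr_p_replication = r$fdr_p,
             replicated = rep_ok, stringsAsFactors = FALSE)
}

#' Sex concordance of screening coefficients
#'
#' Pearson correlation (with its two-sided p-value) between the aligned
#' coefficient vectors of the female-only and male-only screens.
#'
#' @param female,male record data.frames from sex-specific [run_xwas()]
#'   runs.
#' @return list with `r`, `p` and `n` (number of common exposure levels).
#' @export
sex_concordance <- function(female, male) {
  key_f <- paste(female$exposure, female$term)
  key_m <- paste(male$exposure, male$term)
  common <- intersect(key_f, key_m)
  if (length(common) < 3) stop_("fewer than 3 common exposures")
  bf <- female$beta[match(common, key_f)]
  bm <- male$beta[match(common, key_m)]
  ok <- stats::complete.cases(bf, bm)
  ct <- stats::cor.test(bf[ok], bm[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
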