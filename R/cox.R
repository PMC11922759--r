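# Survival engine: stratified, left-truncated Cox fitting and the
# model-level statistics used throughout the pipeline. Partial-likelihood
# maximization itself is delegated to survival::coxph (Efron ties,
# counting-process Surv, strata); this module owns the design contract,
# the convergence/aliasing diagnostics and the derived statistics
# (explained-randomness R-squared, Wald group importance, GVIF,
# proportional-hazards flags, episode splitting).

#' Survival design for a stratified, left-truncated Cox model
#'
#' @param entry per-subject entry time (recruitment age when age is the
#'   timescale, 0 on the time-on-study scale).
#' @param exit per-subject exit time; must exceed `entry`.
#' @param event binary event indicator.
#' @param covariates data.frame of covariates (numeric or factor).
#' @param strata optional nominal stratum label per subject (e.g. the
#'   5-year birth cohort crossed with sex).
#' @param groups optional named character vector mapping covariate names to
#'   importance groups (used by [wald_group_chi2()]).
#' @return an object of class `survival_design`.
#' @export
survival_design <- function(entry, exit, event, covariates = NULL,
                            strata = NULL, groups = NULL) {
  n <- length(exit)
  if (length(entry) == 1) entry <- rep(entry, n)
  if (any(exit <= entry)) {
    stop_("exit must exceed entry for every subject (",
          sum(exit <= entry), " violations)")
  }
  if (!all(event %in% c(0, 1))) stop_("event must be binary")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop_("covariates misaligned with times")
  }
  structure(list(entry = as.numeric(entry), exit = as.numeric(exit),
                 event = as.integer(event), covariates = covariates,
                 strata = if (!is.null(strata)) as.factor(strata),
                 groups = groups, n = n),
            class = "survival_design")
}

#' Fit a stratified left-truncated Cox model
#'
#' Newton-Raphson maximization of the stratified partial likelihood over
#' per-subject `(entry, exit]` risk intervals with the Efron tie
#' correction. Monotone-likelihood divergence (any |coefficient| beyond
#' `beta_bound`) is flagged as non-converged rather than silently
#' reported; aliased (rank-deficient) covariates are a hard error naming
#' the offending columns.
#'
#' @param design a [survival_design()].
#' @param ties tie handling, `"efron"` (default) or `"breslow"`.
#' @param beta_bound divergence bound on |coefficient|.
#' @param iter_max maximum Newton iterations.
#' @param eps convergence tolerance passed to the maximizer.
#' @return an object of class `cox_fit` with elements `coefficients`, `se`,
#'   `z`, `p`, `hr`, `vcov`, `loglik_null`, `loglik`, `n`, `n_events`,
#'   `converged`, plus the underlying `survival::coxph` fit in `$model`.
#' @examples
#' ds <- survival_design(entry = rep(0, 6), exit = c(2, 3, 5, 6, 8, 9),
#'                       event = c(1, 1, 0, 1, 0, 1),
#'                       covariates = data.frame(x = c(1, 0, 1, 0, 1, 0)))
#' fit_cox(ds)
#' @export
fit_cox <- function(design, ties = c("efron", "breslow"), beta_bound = 20,
                    iter_max = 50, eps = 1e-10) {
  ties <- match.arg(ties)
  if (sum(design$event) < 1) stop_("at least one event is required")
  df <- data.frame(.entry = design$entry, .exit = design$exit,
                   .event = design$event)
  rhs <- "1"
  if (!is.null(design$covariates) && ncol(design$covariates) > 0) {
    df <- cbind(df, design$covariates)
    rhs <- paste(sprintf("`%s`", names(design$covariates)), collapse = " + ")
  }
  if (!is.null(design$strata)) {
    df$.strata <- design$strata
    rhs <- paste(rhs, "+ strata(.strata)")
  }
  fml <- stats::as.formula(paste("Surv(.entry, .exit, .event) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(eps = eps,
                                                           iter.max = iter_max))
  beta <- stats::coef(fit)
  if (is.null(beta)) beta <- numeric(0)
  if (length(beta) && anyNA(beta)) {
    stop_("rank-deficient covariate matrix; aliased columns: ",
          paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  converged <- TRUE
  if (length(beta) && any(abs(beta) > beta_bound)) converged <- FALSE
  if (!is.null(fit$info) && isTRUE(fit$info > 0)) converged <- FALSE
  V <- if (length(beta)) stats::vcov(fit) else matrix(0, 0, 0)
  se <- if (length(beta)) sqrt(diag(V)) else numeric(0)
  z <- if (length(beta)) beta / se else numeric(0)
  ll <- fit$loglik
  structure(list(coefficients = beta, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)), hr = exp(beta),
                 vcov = V,
                 loglik_null = ll[1], loglik = ll[length(ll)],
                 n = design$n, n_events = sum(design$event),
                 converged = converged, ties = ties,
                 groups = design$groups, model = fit, data = df),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Stratified left-truncated Cox fit:", x$n, "subjects,",
      x$n_events, "events", if (!x$converged) "(NOT converged)", "\n")
  if (length(x$coefficients)) {
    print(data.frame(beta = x$coefficients, HR = x$hr, se = x$se,
                     z = x$z, p = x$p))
  } else {
    cat("  (null model)\n")
  }
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  out <- list(table = data.frame(beta = object$coefficients, HR = object$hr,
                                 se = object$se, z = object$z, p = object$p),
              loglik_null = object$loglik_null, loglik = object$loglik,
              lr = 2 * (object$loglik - object$loglik_null),
              n = object$n, n_events = object$n_events,
              converged = object$converged)
  class(out) <- "summary.cox_fit"
  out
}

#' @export
print.summary.cox_fit <- function(x, ...) {
  print(x$table)
  cat(sprintf("LR = %.3f on %d events; loglik %0.3f (null %0.3f)\n",
              x$lr, x$n_events, x$loglik, x$loglik_null))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$vcov

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' Linear predictor for new data
#' @param object a `cox_fit`.
#' @param newdata data.frame carrying the model covariates.
#' @param ... unused.
#' @export
predict.cox_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(object$model$linear.predictors))
  unname(stats::predict(object$model, newdata = newdata, type = "lp",
                        reference = "sample"))
}

#' Serialize a Cox fit to JSON
#' @param fit a `cox_fit`.
#' @return a JSON string with coefficients, covariance, log-likelihoods and
#'   event counts.
#' @export
cox_fit_json <- function(fit) {
  jsonlite::toJSON(list(coefficients = as.list(fit$coefficients),
                        se = as.list(fit$se),
                        vcov = fit$vcov,
                        loglik_null = fit$loglik_null,
                        loglik = fit$loglik,
                        n = fit$n, n_events = fit$n_events,
                        converged = fit$converged),
                   auto_unbox = TRUE, digits = NA)
}

#' Nelson-Aalen cumulative hazard with delayed entry
#'
#' `H(t) = sum_{event times <= t} d_i / n_i` with left-truncation-aware
#' risk sets (a subject is at risk in `(entry, exit]` only).
#'
#' @param entry,exit,event per-subject times and event indicator.
#' @return list with `time` (event times), `cumhaz`, a step function
#'   `H(t)`, and `at_exit`, the estimate evaluated at each subject's exit
#'   (the imputation predictor).
#' @export
nelson_aalen <- function(entry, exit, event) {
  n <- length(exit)
  if (length(entry) == 1) entry <- rep(entry, n)
  if (any(exit <= entry)) stop_("exit must exceed entry")
  if (sum(event) == 0) {
    warn_("no events: cumulative hazard is identically 0")
    H <- stats::stepfun(max(exit), c(0, 0))
    return(list(time = numeric(0), cumhaz = numeric(0), H = H,
                at_exit = rep(0, n)))
  }
  sf <- survival::survfit(survival::Surv(entry, exit, event) ~ 1)
  keep <- sf$n.event > 0
  tt <- sf$time[keep]
  Ht <- cumsum(sf$n.event[keep] / sf$n.risk[keep])
  H <- stats::stepfun(tt, c(0, Ht))
  list(time = tt, cumhaz = Ht, H = H, at_exit = H(exit))
}

#' Explained-randomness R-squared of a Cox model
#'
#' `R2 = 1 - exp(-LR / d)` where `LR = 2 (loglik_full - loglik_null)` is
#' the partial likelihood ratio statistic and `d` the number of events
#' (the denominator is configurable).
#'
#' @param fit a `cox_fit` (or any list with `loglik`, `loglik_null`,
#'   `n_events`, `n`).
#' @param denominator `"events"` (default) or `"subjects"`.
#' @return R-squared in `[0, 1)`.
#' @export
explained_randomness_r2 <- function(fit, denominator = c("events", "subjects")) {
  denominator <- match.arg(denominator)
  d <- if (denominator == "events") fit$n_events else fit$n
  if (is.null(d) || d == 0) stop_("undefined with zero events")
  lr <- 2 * (fit$loglik - fit$loglik_null)
  1 - exp(-lr / d)
}

#' Harrell's concordance index respecting delayed entry
#'
#' @param lp linear predictor (higher = higher risk).
#' @param design a [survival_design()] aligned with `lp`.
#' @return C-index in `[0, 1]`; tied predictions count 0.5.
#' @export
concordance_index <- function(lp, design) {
  if (length(lp) != design$n) stop_("predictor misaligned with design rows")
  df <- data.frame(entry = design$entry, exit = design$exit,
                   event = design$event, lp = lp)
  cf <- survival::concordance(
    survival::Surv(entry, exit, event) ~ lp, data = df, reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0) {
    stop_("no comparable pairs")
  }
  unname(cf$concordance)
}

#' Per-group Wald chi-squared importance
#'
#' For each covariate group g, `X2_g = b_g' V_gg^-1 b_g` on that group's
#' coefficient block; importances are the proportions `X2_g / sum X2`.
#'
#' @param fit a `cox_fit`.
#' @param groups named character vector mapping every coefficient name to a
#'   group label; defaults to the design's `groups`.
#' @return data.frame with group, df, chi2 and proportion (summing to 1).
#' @export
wald_group_chi2 <- function(fit, groups = NULL) {
  groups <- groups %||% fit$groups
  beta <- fit$coefficients
  if (is.null(groups)) stop_("no group tags supplied")
  miss <- setdiff(names(beta), names(groups))
  if (length(miss)) stop_("covariates without a group tag: ",
                          paste(miss, collapse = ", "))
  glab <- unique(unname(groups[names(beta)]))
  chi2 <- vapply(glab, function(g) {
    idx <- names(beta)[groups[names(beta)] == g]
    Vgg <- fit$vcov[idx, idx, drop = FALSE]
    qr_ <- qr(Vgg)
    if (qr_$rank < length(idx)) stop_("singular covariance block for group ", g)
    as.numeric(t(beta[idx]) %*% solve(Vgg, beta[idx]))
  }, numeric(1))
  df_ <- vapply(glab, function(g) sum(groups[names(beta)] == g), integer(1))
  data.frame(group = glab, df = df_, chi2 = chi2,
             proportion = chi2 / sum(chi2), row.names = NULL)
}

#' Generalized variance inflation factors
#'
#' Fox-Monette GVIF per model term from determinant ratios of the
#' covariate correlation matrix, reported on the degrees-of-freedom
#' adjusted scale `GVIF^(1/(2 df))`.
#'
#' @param x a model matrix (no intercept), a data.frame of covariates, or a
#'   `cox_fit`.
#' @param terms optional integer/character vector assigning each column to
#'   a term (multi-column factors share one term); defaults to one term per
#'   column, or to the model's term assignment for a `cox_fit`.
#' @return data.frame with term, df, gvif and `gvif_adj` = GVIF^(1/(2 df)).
#' @export
gvif <- function(x, terms = NULL) {
  if (inherits(x, "cox_fit")) {
    mm <- stats::model.matrix(x$model)
    assign <- attr(mm, "assign") %||% seq_len(ncol(mm))
    tl <- attr(stats::terms(x$model), "term.labels")
    tl <- tl[tl != "strata(.strata)"]
    keep <- assign > 0
    mm <- mm[, keep, drop = FALSE]
    terms <- tl[assign[keep]]
    x <- mm
  } else if (is.data.frame(x)) {
    mm <- stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
    assign <- attr(stats::model.matrix(~ ., data = x), "assign")[-1]
    terms <- terms %||% names(x)[assign]
    x <- mm
  }
  x <- as.matrix(x)
  if (is.null(terms)) terms <- colnames(x) %||% as.character(seq_len(ncol(x)))
  if (length(unique(terms)) < 2) stop_("GVIF needs at least 2 model terms")
  R <- stats::cor(x)
  detR <- det(R)
  if (detR < .Machine$double.eps) stop_("singular correlation matrix")
  ut <- unique(terms)
  out <- lapply(ut, function(tm) {
    i <- which(terms == tm)
    g <- det(R[i, i, drop = FALSE]) * det(R[-i, -i, drop = FALSE]) / detR
    data.frame(term = tm, df = length(i), gvif = g,
               gvif_adj = g^(1 / (2 * length(i))))
  })
  do.call(rbind, out)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Scaled Schoenfeld residuals per event; per-covariate score test of zero
#' slope against event time (identity transform by default).
#'
#' @param fit a `cox_fit`.
#' @param alpha flagging level.
#' @param transform time transform passed to the score test.
#' @return data.frame with covariate, chi2, df, p and `flagged` (p < alpha);
#'   the global test is attached as attribute `global`.
#' @export
schoenfeld_ph_test <- function(fit, alpha = 0.05, transform = "identity") {
  if (!fit$converged) stop_("fit did not converge")
  if (fit$n_events < 2) stop_("needs at least 2 events")
  if (fit$n_events < length(fit$coefficients)) {
    stop_("fewer events than covariates")
  }
  zp <- survival::cox.zph(fit$model, transform = transform, terms = FALSE,
                          global = TRUE)
  tab <- as.data.frame(zp$table)
  glob <- tab["GLOBAL", , drop = FALSE]
  tab <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  out <- data.frame(covariate = rownames(tab), chi2 = tab$chisq, df = tab$df,
                    p = tab$p, flagged = tab$p < alpha, row.names = NULL)
  attr(out, "global") <- glob
  out
}

#' Split survival records into fixed-length episodes
#'
#' Each subject's `(entry, exit]` interval is split into consecutive
#' episodes of at most `interval` length (on the time scale of the data);
#' the event is carried only by the final episode. For each name in
#' `time_varying`, a covariate-by-time interaction column
#' `<name>_x_time` (covariate times episode start) is appended.
#'
#' @param data data.frame with columns `entry`, `exit`, `event` plus
#'   covariates.
#' @param interval episode length (> 0), e.g. 2 years.
#' @param time_varying character vector of covariate names needing
#'   time interactions.
#' @return the expanded data.frame (episode bounds in `entry`/`exit`).
#' @export
split_survival_time <- function(data, interval, time_varying = character()) {
  if (interval <= 0) stop_("interval must be positive")
  cuts <- seq(interval, max(data$exit), by = interval)
  sp <- survival::survSplit(Surv(entry, exit, event) ~ .,
                            data = data, cut = cuts,
                            start = "entry", end = "exit", event = "event")
  for (v in time_varying) {
    sp[[paste0(v, "_x_time")]] <- sp[[v]] * sp$entry
  }
  sp
}
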