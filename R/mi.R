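# Multiple imputation of missing exposures by chained random forests with
# predictive mean matching, and Rubin's-rule pooling of downstream
# estimates across the imputed copies.

#' Impute missing values by chained random forests with PMM
#'
#' Each of `m` copies is initialized by random draws from the observed
#' marginals and then refined by chained iterations: every column with
#' missing values (visited in order of increasing missingness) is
#' predicted by a random forest on the currently-completed predictors, and
#' numeric imputations are replaced by the observed value of one of the
#' `pmm_k` nearest donors by predicted value (predictive mean matching),
#' so imputed values always lie on the observed support. Categorical
#' columns take the forest's majority-vote class. Iteration stops after
#' `max_iter` sweeps or when the mean absolute change of imputed numeric
#' cells drops below `tol`.
#'
#' The survival outcome enters the predictor set through the Nelson-Aalen
#' cumulative hazard at exit and the event indicator; outcome columns
#' themselves are never imputed.
#'
#' @param data cohort data.frame containing `recruit_age`, `death_time`,
#'   `death_event` and the columns to impute.
#' @param m number of imputed copies.
#' @param max_iter maximum chained sweeps per copy.
#' @param num_trees random-forest size.
#' @param pmm_k donor-pool size for predictive mean matching.
#' @param tol numeric-cell convergence tolerance.
#' @param predictors character vector of predictor columns; defaults to
#'   all baseline columns (demographics + exposures) present in `data`.
#' @param timescale `"age"` (default) evaluates the Nelson-Aalen predictor
#'   on the attained-age scale with delayed entry at recruitment.
#' @param seed master seed; each copy gets an independent child seed.
#' @return an object of class `imputed_set`: list with `copies` (list of m
#'   completed data.frames) and `config` (the echoed settings).
#' @export
impute_cohort <- function(data, m = 5, max_iter = 10, num_trees = 200,
                          pmm_k = 5, tol = 1e-4, predictors = NULL,
                          timescale = c("age", "time_on_study"), seed = 1) {
  timescale <- match.arg(timescale)
  if (anyNA(data$death_time) || anyNA(data$death_event)) {
    stop_("outcome columns must be complete")
  }
  miss_frac <- vapply(data, function(x) mean(is.na(x)), numeric(1))
  too_missing <- names(miss_frac)[miss_frac >= 0.8]
  if (length(too_missing)) {
    stop_("columns with >=80% missing are excluded by the inclusion rule: ",
          paste(too_missing, collapse = ", "))
  }
  targets <- names(miss_frac)[miss_frac > 0]
  if (!length(targets)) {
    warn_("no missing values; returning m identical copies")
  }
  targets <- targets[order(miss_frac[targets])]

  if (is.null(predictors)) {
    drop_cols <- c("participant_id", "death_time", "death_event",
                   grep("^d[0-9]+_(time|event|prevalent)$", names(data),
                        value = TRUE),
                   "proteo_age_gap", "censor_time")
    predictors <- setdiff(names(data), drop_cols)
  }
  all_na <- predictors[vapply(data[predictors],
                              function(x) all(is.na(x)), logical(1))]
  if (length(all_na)) {
    warn_("dropping all-missing predictors: ", paste(all_na, collapse = ", "))
    predictors <- setdiff(predictors, all_na)
  }
  # survival information for the imputation model
  if (timescale == "age") {
    na_haz <- nelson_aalen(data$recruit_age,
                           data$recruit_age + data$death_time,
                           data$death_event)$at_exit
  } else {
    na_haz <- nelson_aalen(0, data$death_time, data$death_event)$at_exit
  }

  seeds <- child_seeds(seed, m)
  copies <- lapply(seq_len(m), function(ci) {
    impute_one(data, targets, predictors, na_haz, max_iter, num_trees,
               pmm_k, tol, seeds[ci])
  })
  structure(list(copies = copies,
                 config = list(m = m, max_iter = max_iter,
                               num_trees = num_trees, pmm_k = pmm_k,
                               tol = tol, seed = seed,
                               targets = targets, predictors = predictors)),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("Imputed set: m =", x$config$m, "copies,",
      length(x$config$targets), "imputed columns",
      sprintf("(trees=%d, max_iter=%d, pmm_k=%d)\n",
              x$config$num_trees, x$config$max_iter, x$config$pmm_k))
  invisible(x)
}

impute_one <- function(data, targets, predictors, na_haz, max_iter,
                       num_trees, pmm_k, tol, seed) {
  set.seed(seed)
  work <- data
  work$.na_cumhaz <- na_haz
  work$.event <- data$death_event
  pred_all <- c(setdiff(predictors, targets), ".na_cumhaz", ".event")
  miss_idx <- lapply(targets, function(v) which(is.na(data[[v]])))
  names(miss_idx) <- targets
  # initialize from observed marginals
  for (v in targets) {
    obs <- data[[v]][!is.na(data[[v]])]
    work[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                       replace = TRUE)
  }
  for (it in seq_len(max_iter)) {
    delta <- 0
    ncell <- 0
    for (v in targets) {
      idx <- miss_idx[[v]]
      rhs <- c(pred_all, setdiff(targets, v))
      y <- data[[v]]
      obs <- which(!is.na(y))
      df <- work[c(v, rhs)]
      categ <- is.factor(y) || is.character(y)
      if (categ) df[[v]] <- factor(df[[v]])
      rf <- ranger::ranger(
        stats::as.formula(paste0("`", v, "` ~ .")),
        data = df[obs, , drop = FALSE],
        num.trees = num_trees, respect.unordered.factors = "order",
        num.threads = 1, verbose = FALSE,
        seed = seed + it)
      pred <- stats::predict(rf, data = df[idx, , drop = FALSE],
                             num.threads = 1)$predictions
      if (categ) {
        new_vals <- as.character(pred)
        if (is.factor(y)) {
          new_vals <- factor(new_vals, levels = levels(y))
        }
      } else {
        pred_obs <- stats::predict(rf, data = df[obs, , drop = FALSE],
                                   num.threads = 1)$predictions
        new_vals <- pmm_match(pred, pred_obs, y[obs], pmm_k)
        delta <- delta + sum(abs(new_vals - work[[v]][idx]))
        ncell <- ncell + length(idx)
      }
      work[[v]][idx] <- new_vals
    }
    if (ncell > 0 && delta / ncell < tol) break
  }
  work$.na_cumhaz <- NULL
  work$.event <- NULL
  work
}

# Predictive mean matching: for each target prediction pick one of the k
# observed donors whose predictions are nearest.
pmm_match <- function(pred_target, pred_donor, donor_values, k) {
  ord <- order(pred_donor)
  pd <- pred_donor[ord]
  dv <- donor_values[ord]
  nd <- length(pd)
  k <- min(k, nd)
  pos <- findInterval(pred_target, pd)
  out <- numeric(length(pred_target))
  for (i in seq_along(pred_target)) {
    lo <- max(1L, pos[i] - k)
    hi <- min(nd, pos[i] + k)
    cand <- lo:hi
    d <- abs(pd[cand] - pred_target[i])
    sel <- cand[order(d)[seq_len(k)]]
    out[i] <- dv[sel[sample.int(length(sel), 1L)]]
  }
  out
}

#' Pool estimates across imputed copies by Rubin's rules
#'
#' `Qbar` = mean estimate, `W` = mean within-imputation variance, `B` =
#' between-imputation variance of the estimates, total variance
#' `T = W + (1 + 1/m) B`; the p-value uses a normal reference on
#' `Qbar / sqrt(T)`.
#'
#' @param estimates numeric vector (one estimate per copy) or matrix
#'   (copies in rows, parameters in columns).
#' @param variances squared standard errors, same shape as `estimates`.
#' @return data.frame with estimate, W, B, T, se, z, p and m per parameter.
#' @examples
#' pool_rubin(c(1.0, 1.2, 0.8, 1.1, 0.9), rep(0.04, 5))
#' @export
pool_rubin <- function(estimates, variances) {
  if (is.null(dim(estimates))) estimates <- matrix(estimates, ncol = 1)
  if (is.null(dim(variances))) variances <- matrix(variances, ncol = 1)
  if (!all(dim(estimates) == dim(variances))) {
    stop_("estimates and variances have mismatched shapes")
  }
  m <- nrow(estimates)
  if (m < 2) stop_("Rubin pooling needs m >= 2 copies")
  qbar <- colMeans(estimates)
  w <- colMeans(variances)
  b <- apply(estimates, 2, stats::var)
  tt <- w + (1 + 1 / m) * b
  se <- sqrt(tt)
  z <- qbar / se
  data.frame(estimate = qbar, W = w, B = b, T = tt, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), m = m,
             row.names = colnames(estimates))
}

#' Pool correlation-scale quantities via Fisher's z
#'
#' Values are mapped to the correlation scale (`r` as-is; `r = sqrt(R2)`
#' for R-squared; `2C - 1` for a C-index), transformed by `atanh`,
#' averaged across copies, and back-transformed (then squared / remapped).
#'
#' @param values per-copy values.
#' @param kind one of `"r"`, `"r2"`, `"cindex"`.
#' @return the pooled value on the original scale.
#' @export
pool_fisher_z <- function(values, kind = c("r", "r2", "cindex")) {
  kind <- match.arg(kind)
  r <- switch(kind, r = values, r2 = sqrt(pmax(values, 0)),
              cindex = 2 * values - 1)
  if (any(abs(r) >= 1)) stop_("correlation-scale values must lie in (-1, 1)")
  z <- mean(atanh(r))
  out <- tanh(z)
  switch(kind, r = out, r2 = out^2, cindex = (out + 1) / 2)
}
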