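# Internal helpers shared across modules.

#' @importFrom survival Surv strata coxph
NULL

# Deterministic fan-out of one master seed into per-stage child seeds.
# Children stay below 2^31 so they are valid R integer seeds.
child_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)

is_binaryish <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2
}

# Standardize to mean 0 / SD 1; constant columns are rejected by callers.
standardize <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop_("cannot standardize a constant column")
  (x - mean(x, na.rm = TRUE)) / s
}

# coxph, muffling the small-cell "beta may be infinite" note that rare
# nuisance-covariate levels trigger; the exposure coefficients of interest
# are unaffected.
quiet_coxph <- function(...) {
  withCallingHandlers(
    coxph(...),
    warning = function(w) {
      if (grepl("Loglik converged before variable", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# 5-year birth-cohort stratum label from recruitment age and calendar year.
birth_cohort <- function(recruit_age, recruit_year = 2008) {
  floor((recruit_year - recruit_age) / 5)
}
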