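# Synthetic cohort generator: biobank-scale prospective cohorts with a planted causal
# structure (a truth ledger) so every downstream stage of the screening
# pipeline can be scored against known ground truth.
#
# The latent exposome is a blocked Gaussian copula; survival is an
# age-timescale Gompertz hazard with left truncation at recruitment age;
# decoy exposures encode the failure modes the pipeline's filters target
# (confounding by income, reverse causation through baseline poor health,
# mortality-only and sign-discordant proteomic behaviour).

#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates all generator parameters. Defaults describe a
#' desk-scale cohort: n = 20,000 participants aged ~57 (SD 8.1), 54% female,
#' 11-15 years of administrative follow-up with the Gompertz baseline hazard
#' auto-calibrated to 7.3% all-cause mortality, a 42-exposure exposome in 7
#' correlation blocks, 8 planted causal exposures and 6 decoys
#' (1 income-confounded, 2 reverse-causation, 2 mortality-only,
#' 1 sign-discordant), an 11.3% holdout region and a 10.4% proteomic
#' subsample.
#'
#' @param n number of participants.
#' @param n_exposures number of exposure columns.
#' @param cluster_blocks data.frame with columns `size` and `r` giving block
#'   sizes and within-block latent correlations in `[0, 1)`; sizes must sum
#'   to `n_exposures`. Default: 7 equal blocks with r = 0.45.
#' @param exposure_type_mix named proportions over
#'   `continuous/ordinal/binary/nominal`; must sum to 1.
#' @param ordinal_levels,nominal_levels,binary_prevalence shapes of the
#'   discretized exposure margins (equal-probability ordinal cuts; nominal
#'   argmax over latent dimensions with a dominant reference level).
#' @param true_effects named vector of mortality log hazard ratios per SD;
#'   `NULL` plants the default 8 causal effects.
#' @param proteomic_effects named vector of proteomic age-gap slopes
#'   (years per SD); `NULL` derives them as `2.5 *` the mortality effect.
#' @param decoy_plan named counts of
#'   `confounded/reverse_causation/mortality_only/sign_discordant` decoys.
#' @param gompertz_a baseline Gompertz scale (per year); `NULL` means
#'   calibrate by bisection so that the expected death fraction over the
#'   realized age/follow-up mix equals `target_mortality`.
#' @param gompertz_b Gompertz log-hazard slope per year of attained age.
#' @param target_mortality expected death fraction within follow-up used
#'   when `gompertz_a` is auto-calibrated.
#' @param followup_range_years administrative censoring window (min, max).
#' @param missingness per-exposure MAR rates in `[0, 0.8)`; a single number
#'   recycles over all exposures; `NULL` means fully observed.
#' @param n_diseases number of incident diseases.
#' @param disease_incidence target incident fractions per disease.
#' @param prs_effects per-disease log-HR per PRS standard deviation.
#' @param disease_exposure_effects optional list of named log-HR vectors,
#'   one per disease, over exposure names.
#' @param region_split fraction of participants assigned to the holdout
#'   region (England vs Scotland/Wales analogue).
#' @param proteomic_subsample fraction of training-region rows carrying the
#'   proteomic age gap.
#' @param proteomic_sd residual SD (years) of the age gap.
#' @param n_biomarkers number of positive (lognormal) biomarkers.
#' @param poor_health_prevalence baseline prevalence of the poor-health
#'   indicator before exposure loadings.
#' @param poor_health_loghr direct log-HR of poor health on mortality.
#' @param poor_health_early_years years of follow-up during which the
#'   poor-health hazard block (main effect and reverse-causation terms)
#'   acts; prevalent illness kills early, which is what the early-death and
#'   interaction sensitivity analyses target. 0 makes it time-constant.
#' @param reverse_theta within-poor-health log-HR per SD of each
#'   reverse-causation decoy (its marginal effect outside the stratum is 0).
#' @param reverse_ph_loading logit slope of poor health on each
#'   reverse-causation decoy.
#' @param income_loghr mortality log-HR per SD of the latent income scale.
#' @param confound_loading latent correlation of the confounded decoy with
#'   the income scale.
#' @param recruit_year fixed recruitment calendar year used for the 5-year
#'   birth-cohort strata.
#' @param age_mean,age_sd,age_range recruitment-age distribution (truncated
#'   normal).
#' @param female_fraction fraction of female participants.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n = 20000,
                          n_exposures = 42,
                          cluster_blocks = NULL,
                          exposure_type_mix = c(continuous = 0.45, ordinal = 0.25,
                                                binary = 0.20, nominal = 0.10),
                          ordinal_levels = 4,
                          nominal_levels = 3,
                          binary_prevalence = 0.3,
                          true_effects = NULL,
                          proteomic_effects = NULL,
                          decoy_plan = c(confounded = 1, reverse_causation = 2,
                                         mortality_only = 2, sign_discordant = 1),
                          gompertz_a = NULL,
                          gompertz_b = 0.09,
                          target_mortality = 0.073,
                          followup_range_years = c(11, 15),
                          missingness = NULL,
                          n_diseases = 5,
                          disease_incidence = NULL,
                          prs_effects = NULL,
                          disease_exposure_effects = NULL,
                          region_split = 0.113,
                          proteomic_subsample = 0.104,
                          proteomic_sd = 4,
                          n_biomarkers = 5,
                          poor_health_prevalence = 0.18,
                          poor_health_loghr = 0.8,
                          poor_health_early_years = 4,
                          reverse_theta = 0.8,
                          reverse_ph_loading = 1.0,
                          income_loghr = -0.35,
                          confound_loading = 0.8,
                          recruit_year = 2008,
                          age_mean = 57, age_sd = 8.1, age_range = c(40, 70),
                          female_fraction = 0.54) {
  if (n < 1) stop_("n must be positive")
  if (is.null(cluster_blocks)) {
    sz <- rep(n_exposures %/% 7, 7)
    sz[seq_len(n_exposures %% 7)] <- sz[seq_len(n_exposures %% 7)] + 1L
    cluster_blocks <- data.frame(size = sz, r = 0.45)
  }
  cluster_blocks <- as.data.frame(cluster_blocks)
  if (any(cluster_blocks$r < 0 | cluster_blocks$r >= 1)) {
    bad <- which(cluster_blocks$r < 0 | cluster_blocks$r >= 1)
    stop_("within-block correlation outside [0, 1) in block ",
          paste(bad, collapse = ", "))
  }
  if (sum(cluster_blocks$size) != n_exposures) {
    stop_("cluster block sizes must sum to n_exposures")
  }
  if (abs(sum(exposure_type_mix) - 1) > 1e-8) {
    stop_("exposure_type_mix must sum to 1")
  }
  if (!is.null(missingness)) {
    if (length(missingness) == 1) missingness <- rep(missingness, n_exposures)
    if (any(missingness >= 0.8)) {
      stop_("missingness rates must be strictly below 0.8 (exposure inclusion rule)")
    }
    if (any(missingness < 0)) stop_("missingness rates must be nonnegative")
  }
  if (region_split < 0 || region_split >= 1) stop_("region_split must be in [0, 1)")
  if (proteomic_subsample <= 0 || proteomic_subsample > 1) {
    stop_("proteomic_subsample must be in (0, 1]")
  }

  nm <- sprintf("exp%02d", seq_len(n_exposures))
  roles <- assign_roles(nm, cluster_blocks, decoy_plan,
                        causal_names = if (!is.null(true_effects))
                          names(true_effects) %||% character(0))
  if (is.null(true_effects)) {
    beta <- c(0.405, 0.30, -0.30, 0.25, -0.25, 0.20, -0.20, 0.15)
    causal <- names(roles)[roles == "causal"]
    true_effects <- stats::setNames(beta[seq_along(causal)], causal)
  }
  if (is.null(proteomic_effects)) {
    proteomic_effects <- 2.5 * true_effects
  }
  if (is.null(disease_incidence)) {
    disease_incidence <- rep(c(0.05, 0.05, 0.04, 0.03, 0.002),
                             length.out = n_diseases)
  }
  if (is.null(prs_effects) && n_diseases > 0) {
    prs_effects <- rep(c(0.10, 0.50, 0.20, 0.15, 0.00), length.out = n_diseases)
  }
  if (is.null(disease_exposure_effects) && n_diseases > 0) {
    causal <- names(true_effects)
    disease_exposure_effects <- vector("list", n_diseases)
    # disease 1 is exposome-driven, disease 2 PRS-driven, last one null/rare
    if (length(causal) >= 2) {
      disease_exposure_effects[[1]] <- stats::setNames(c(0.3, 0.25), causal[1:2])
    }
    if (n_diseases >= 3 && length(causal) >= 3) {
      disease_exposure_effects[[3]] <- stats::setNames(0.2, causal[3])
    }
  }

  cfg <- list(n = as.integer(n), n_exposures = as.integer(n_exposures),
              cluster_blocks = cluster_blocks,
              exposure_type_mix = exposure_type_mix,
              ordinal_levels = ordinal_levels, nominal_levels = nominal_levels,
              binary_prevalence = binary_prevalence,
              exposure_names = nm, roles = roles,
              true_effects = true_effects, proteomic_effects = proteomic_effects,
              decoy_plan = decoy_plan,
              gompertz_a = gompertz_a, gompertz_b = gompertz_b,
              target_mortality = target_mortality,
              followup_range_years = followup_range_years,
              missingness = missingness,
              n_diseases = as.integer(n_diseases),
              disease_incidence = disease_incidence,
              prs_effects = prs_effects,
              disease_exposure_effects = disease_exposure_effects,
              region_split = region_split,
              proteomic_subsample = proteomic_subsample,
              proteomic_sd = proteomic_sd,
              n_biomarkers = as.integer(n_biomarkers),
              poor_health_prevalence = poor_health_prevalence,
              poor_health_loghr = poor_health_loghr,
              poor_health_early_years = poor_health_early_years,
              reverse_theta = reverse_theta,
              reverse_ph_loading = reverse_ph_loading,
              income_loghr = income_loghr,
              confound_loading = confound_loading,
              recruit_year = recruit_year,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              female_fraction = female_fraction)
  class(cfg) <- "cohort_config"
  cfg
}

# Spread causal exposures across blocks, one slot at a time (slot j of
# block b is filled before slot j+1 of any block); decoys take the slots
# that follow but live on their own independent latents, so their planted
# failure modes are not contaminated by correlation with causal
# block-mates.
assign_roles <- function(names, blocks, decoy_plan, causal_names = NULL) {
  n <- length(names)
  block_of <- rep(seq_len(nrow(blocks)), blocks$size)
  slot_of <- unlist(lapply(blocks$size, seq_len))
  ord <- order(slot_of, block_of)
  roles <- stats::setNames(rep("null", n), names)
  n_decoys <- sum(unlist(decoy_plan))
  if (is.null(causal_names)) {
    n_causal <- min(8L, max(0L, n - n_decoys))
    want <- rep("causal", n_causal)
  } else {
    if (!all(causal_names %in% names)) {
      stop_("true_effects names outside the exposure set")
    }
    roles[causal_names] <- "causal"
    ord <- ord[!names[ord] %in% causal_names]
    want <- character(0)
  }
  want <- c(want,
            rep("confounded", decoy_plan[["confounded"]]),
            rep("reverse_causation", decoy_plan[["reverse_causation"]]),
            rep("mortality_only", decoy_plan[["mortality_only"]]),
            rep("sign_discordant", decoy_plan[["sign_discordant"]]))
  if (length(want) > length(ord)) {
    stop_("decoy plan and causal set exceed n_exposures")
  }
  roles[ord[seq_along(want)]] <- want
  roles
}

# Demographic columns; the income latent is kept because the confounded
# decoy and the MAR mechanism are built on it.
gen_demographics <- function(config, seed) {
  set.seed(seed)
  n <- config$n
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])
  sex <- factor(ifelse(stats::runif(n) < config$female_fraction,
                       "female", "male"), levels = c("female", "male"))
  region <- factor(ifelse(stats::runif(n) < config$region_split,
                          "holdout", "train"), levels = c("train", "holdout"))
  center <- factor(sample(paste0("c", 1:5), n, TRUE,
                          prob = c(0.3, 0.25, 0.2, 0.15, 0.1)))
  edu_levels <- c(7, 10, 13, 15, 19, 20)
  education_years <- sample(edu_levels, n, TRUE,
                            prob = c(0.168, 0.171, 0.055, 0.120, 0.157, 0.320))
  income_z <- stats::rnorm(n)
  income_band <- as.integer(cut(income_z,
                                c(-Inf, stats::qnorm(cumsum(c(0.207, 0.239, 0.230, 0.176)))),
                                labels = FALSE, right = TRUE))
  income_band[is.na(income_band)] <- 5L
  ethnicity <- factor(sample(c("white", "asian", "black", "mixed", "other"),
                             n, TRUE, prob = c(0.94, 0.024, 0.018, 0.006, 0.012)),
                      levels = c("white", "asian", "black", "mixed", "other"))
  n_medications <- stats::rpois(n, 2)
  out <- data.frame(participant_id = sprintf("p%06d", seq_len(n)),
                    recruit_age = age, sex = sex, region = region,
                    center = center, education_years = education_years,
                    income_band = income_band, ethnicity = ethnicity,
                    n_medications = n_medications,
                    stringsAsFactors = FALSE)
  attr(out, "income_z") <- income_z
  out
}

#' Generate the latent-copula exposome
#'
#' Samples a blocked Gaussian copula (between-block correlation 0) and
#' thresholds each column to its declared type: continuous columns keep the
#' standard-normal latent, ordinal columns are cut at equal-probability
#' normal quantiles, binary columns at the configured prevalence, and
#' nominal columns take the argmax over latent dimensions with a dominant
#' reference level. The confounded decoy replaces its block latent with a
#' loading on the income scale.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param income optional income latent (standard normal, length n); drawn
#'   internally when `NULL`.
#' @return list with `exposures` (data.frame), `latent` (numeric matrix of
#'   the underlying latents), `truth` (the truth ledger, one row per
#'   exposure: role, true mortality/proteomic effects, confounder parent)
#'   and `specs` (per-exposure type metadata).
#' @export
generate_exposome <- function(config, seed = 1, income = NULL) {
  set.seed(seed)
  n <- config$n
  blocks <- config$cluster_blocks
  if (is.null(income)) income <- stats::rnorm(n)
  block_of <- rep(seq_len(nrow(blocks)), blocks$size)
  lat <- matrix(0, n, config$n_exposures,
                dimnames = list(NULL, config$exposure_names))
  for (b in seq_len(nrow(blocks))) {
    f <- stats::rnorm(n)
    r <- blocks$r[b]
    for (j in which(block_of == b)) {
      lat[, j] <- sqrt(r) * f + sqrt(1 - r) * stats::rnorm(n)
    }
  }
  roles <- config$roles
  decoy <- which(roles %in% c("confounded", "reverse_causation",
                              "mortality_only", "sign_discordant"))
  for (j in decoy) lat[, j] <- stats::rnorm(n)
  for (j in which(roles == "confounded")) {
    lam <- config$confound_loading
    lat[, j] <- lam * income + sqrt(1 - lam^2) * stats::rnorm(n)
  }
  block_of[decoy] <- NA_integer_

  types <- assign_types(config)
  ex <- as.data.frame(lat)
  for (j in seq_len(config$n_exposures)) {
    ex[[j]] <- threshold_column(lat[, j], types[j], config)
  }
  specs <- data.frame(name = config$exposure_names, type = types,
                      n_levels = ifelse(types == "ordinal", config$ordinal_levels,
                                 ifelse(types == "nominal", config$nominal_levels,
                                 ifelse(types == "binary", 2L, NA_integer_))),
                      sex_specific = FALSE, modifiable = TRUE,
                      stringsAsFactors = FALSE)
  truth <- data.frame(exposure = config$exposure_names,
                      role = unname(roles),
                      block = block_of,
                      beta_mortality = 0, gamma_proteomic = 0,
                      theta_poor_health = 0,
                      confounder_parent = NA_character_,
                      stringsAsFactors = FALSE)
  truth$block[truth$role == "confounded"] <- NA_integer_
  ce <- config$true_effects
  truth$beta_mortality[match(names(ce), truth$exposure)] <- ce
  ge <- config$proteomic_effects
  truth$gamma_proteomic[match(names(ge), truth$exposure)] <- ge
  mo <- which(truth$role == "mortality_only")
  truth$beta_mortality[mo] <- rep(c(0.3, -0.3), length.out = length(mo))
  sd_ <- which(truth$role == "sign_discordant")
  truth$beta_mortality[sd_] <- 0.2
  truth$gamma_proteomic[sd_] <- -0.5
  rc <- which(truth$role == "reverse_causation")
  truth$theta_poor_health[rc] <- config$reverse_theta
  truth$confounder_parent[truth$role == "confounded"] <- "income_band"

  list(exposures = ex, latent = lat, truth = truth, specs = specs)
}

assign_types <- function(config) {
  mix <- config$exposure_type_mix
  n <- config$n_exposures
  cnt <- round(mix * n)
  while (sum(cnt) > n) {
    over <- which.max(cnt - mix * n)
    cnt[over] <- cnt[over] - 1
  }
  while (sum(cnt) < n) {
    under <- which.min(cnt - mix * n)
    cnt[under] <- cnt[under] + 1
  }
  types <- rep(NA_character_, n)
  # role-carrying exposures are continuous so that planted per-SD effects
  # act on the modeled scale directly
  special <- which(config$roles != "null")
  types[special] <- "continuous"
  cnt["continuous"] <- max(0, cnt["continuous"] - length(special))
  pool <- rep(names(mix), times = pmax(cnt, 0))
  rest <- which(is.na(types))
  pool <- rep(pool, length.out = length(rest))
  types[rest] <- pool
  types
}

threshold_column <- function(z, type, config) {
  switch(type,
    continuous = z,
    ordinal = {
      L <- config$ordinal_levels
      as.integer(cut(stats::pnorm(z), seq(0, 1, length.out = L + 1),
                     labels = FALSE, include.lowest = TRUE))
    },
    binary = as.integer(z > stats::qnorm(1 - config$binary_prevalence)),
    nominal = {
      L <- config$nominal_levels
      offs <- seq(0.7, -0.3, length.out = L)
      zm <- cbind(z + offs[1],
                  matrix(stats::rnorm(length(z) * (L - 1)), ncol = L - 1) +
                    rep(offs[-1], each = length(z)))
      factor(paste0("l", max.col(zm)), levels = paste0("l", seq_len(L)))
    },
    stop_("unknown exposure type: ", type))
}

# Numeric, per-SD-scaled version of an exposure column for hazard building.
numeric_std <- function(x) {
  if (is.factor(x)) x <- as.integer(x)
  standardize(as.numeric(x))
}

#' Generate survival columns under a left-truncated Gompertz hazard
#'
#' Event ages are drawn from the age-timescale Gompertz hazard
#' `h(a) = a0 * exp(b * a) * exp(eta)` conditional on survival to the
#' recruitment age (inverse transform on the conditional survivor
#' function), with administrative censoring at recruitment plus a uniform
#' draw from the follow-up window. The linear predictor contains the
#' planted exposure effects, the poor-health indicator, the within-poor-
#' health reverse-causation terms and the income effect.
#'
#' @param exposome result of [generate_exposome()].
#' @param config a [cohort_config()].
#' @param demographics data.frame from the generator's demographics stage
#'   (carries the income latent as an attribute).
#' @param seed integer seed.
#' @return data.frame with `poor_health`, `death_time` (years since
#'   recruitment), `death_event`, plus the calibrated `gompertz_a` as an
#'   attribute.
#' @export
generate_survival <- function(exposome, config, demographics, seed = 1) {
  set.seed(seed)
  n <- config$n
  truth <- exposome$truth
  lat <- exposome$latent
  income <- attr(demographics, "income_z")

  rc <- truth$exposure[truth$role == "reverse_causation"]
  ph_logit <- stats::qlogis(config$poor_health_prevalence)
  if (length(rc)) {
    ph_logit <- ph_logit + config$reverse_ph_loading * rowSums(lat[, rc, drop = FALSE])
  }
  poor_health <- as.integer(stats::runif(n) < stats::plogis(ph_logit))

  # Time-constant part of the linear predictor: planted exposure effects
  # and the income effect.
  eta <- rep(0, n)
  carriers <- truth$exposure[truth$beta_mortality != 0]
  for (e in carriers) {
    eta <- eta + truth$beta_mortality[truth$exposure == e] * lat[, e]
  }
  eta <- eta + config$income_loghr * income
  # Poor-health block (baseline illness and its reverse-causation terms)
  # acts only during the first `poor_health_early_years` of follow-up:
  # prevalent disease kills early, which is exactly what the early-death
  # and interaction sensitivity analyses are designed to catch.
  eta_ph <- config$poor_health_loghr * poor_health
  for (e in rc) {
    eta_ph <- eta_ph +
      truth$theta_poor_health[truth$exposure == e] * poor_health * lat[, e]
  }
  tp <- config$poor_health_early_years

  a0 <- demographics$recruit_age
  b <- config$gompertz_b
  cens <- stats::runif(n, config$followup_range_years[1],
                       config$followup_range_years[2])
  A <- config$gompertz_a %||%
    calibrate_gompertz(a0, cens, eta, eta_ph, tp, b, config$target_mortality)

  # P(death within follow-up | alive at a0)
  pdeath <- 1 - exp(-gomp_cumhaz(cens, A, b, a0, eta, eta_ph, tp))
  if (mean(pdeath) > 0.5) {
    warn_("hazard parameters imply >50% event rate within follow-up")
  }
  t_event <- gomp_draw(stats::runif(n), A, b, a0, eta, eta_ph, tp)
  death_event <- as.integer(t_event <= cens)
  death_time <- pmin(t_event, cens)

  out <- data.frame(poor_health = poor_health,
                    death_time = death_time, death_event = death_event,
                    censor_time = cens)
  attr(out, "gompertz_a") <- A
  attr(out, "eta") <- eta
  out
}

# Cumulative hazard of the conditional (left-truncated) Gompertz model at
# time-since-recruitment t, with an extra hazard block eta_ph active only
# for t < tp.
gomp_cumhaz <- function(t, A, b, a0, eta, eta_ph, tp) {
  base <- (A / b) * exp(b * a0 + eta)
  early <- exp(b * pmin(t, tp)) - 1
  late <- pmax(0, exp(b * t) - exp(b * tp))
  base * (exp(eta_ph) * early + late)
}

# Inverse-transform draw of the event time since recruitment.
gomp_draw <- function(u, A, b, a0, eta, eta_ph, tp) {
  e <- -log(u)
  base <- (A / b) * exp(b * a0 + eta)
  h_tp <- base * exp(eta_ph) * (exp(b * tp) - 1)
  early <- e <= h_tp
  t <- numeric(length(u))
  t[early] <- log1p(e[early] / (base[early] * exp(eta_ph[early]))) / b
  rem <- (e[!early] - h_tp[!early]) / base[!early]
  t[!early] <- log(exp(b * tp) + rem) / b
  t
}

# Bisection on the Gompertz scale so the expected death fraction over the
# realized (age, censoring, eta) mix hits the target.
calibrate_gompertz <- function(a0, cens, eta, eta_ph = NULL, tp = 0, b,
                               target) {
  if (is.null(eta_ph)) eta_ph <- rep(0, length(a0))
  f <- function(logA) {
    A <- exp(logA)
    mean(1 - exp(-gomp_cumhaz(cens, A, b, a0, eta, eta_ph, tp))) - target
  }
  exp(stats::uniroot(f, c(-40, 0), tol = 1e-12)$root)
}

#' Generate ancillary columns: proteomic age gap, biomarkers, diseases,
#' PRS, genetic covariates and risk factors
#'
#' @param exposome result of [generate_exposome()].
#' @param survival result of [generate_survival()].
#' @param config a [cohort_config()].
#' @param demographics demographics data.frame.
#' @param seed integer seed.
#' @return data.frame of ancillary columns aligned with the cohort rows.
#' @export
generate_ancillary <- function(exposome, survival, config, demographics,
                               seed = 1) {
  set.seed(seed)
  n <- config$n
  lat <- exposome$latent
  truth <- exposome$truth
  out <- data.frame(row.names = seq_len(n))

  # proteomic age gap on a training-region subsample
  gamma <- truth$gamma_proteomic
  gap <- as.numeric(lat %*% gamma) + stats::rnorm(n, 0, config$proteomic_sd)
  train_rows <- which(demographics$region == "train")
  keep <- sample(train_rows, round(config$proteomic_subsample * length(train_rows)))
  out$proteo_age_gap <- NA_real_
  out$proteo_age_gap[keep] <- gap[keep]

  # lognormal biomarkers with linear age and planted exposure terms
  causal <- names(config$true_effects)
  for (k in seq_len(config$n_biomarkers)) {
    lp <- 0.02 * demographics$recruit_age
    if (k <= length(causal)) lp <- lp + 0.10 * lat[, causal[k]]
    out[[paste0("bm", k)]] <- exp(lp + stats::rnorm(n, 0, 0.3))
  }

  # PRS, genetic covariates, per-disease incident times
  a0 <- demographics$recruit_age
  b <- config$gompertz_b
  cens <- survival$censor_time
  for (d in seq_len(config$n_diseases)) {
    prs <- stats::rnorm(n)
    out[[paste0("prs_d", d)]] <- prs
    eta <- config$prs_effects[d] * prs
    de <- config$disease_exposure_effects[[d]]
    if (!is.null(de)) eta <- eta + as.numeric(lat[, names(de), drop = FALSE] %*% de)
    zero <- rep(0, n)
    A <- calibrate_gompertz(a0, cens, eta, zero, 0, b, config$disease_incidence[d])
    t_event <- gomp_draw(stats::runif(n), A, b, a0, eta, zero, 0)
    out[[paste0("d", d, "_event")]] <- as.integer(t_event <= cens)
    out[[paste0("d", d, "_time")]] <- pmin(t_event, cens)
    out[[paste0("d", d, "_prevalent")]] <- as.integer(stats::runif(n) < 0.025)
  }
  for (p in 1:4) out[[paste0("pc", p)]] <- stats::rnorm(n)
  out$geno_batch <- as.integer(stats::runif(n) < 0.1)

  # cross-sectional metabolic risk factors
  rf_names <- c("rf_obesity", "rf_hypertension", "rf_dyslipidemia")
  rf_prev <- c(0.25, 0.30, 0.20)
  age_std <- standardize(a0)
  for (i in seq_along(rf_names)) {
    lp <- stats::qlogis(rf_prev[i]) + 0.3 * age_std
    if (i <= length(causal)) lp <- lp + 0.3 * lat[, causal[i]]
    out[[rf_names[i]]] <- as.integer(stats::runif(n) < stats::plogis(lp))
  }
  out
}

#' Inject missing-at-random missingness into exposure columns
#'
#' Missingness probabilities are logit-linear in always-observed columns
#' (recruitment age, sex, income band), with the intercept calibrated per
#' column so the realized rate matches the configured rate. Outcome columns
#' are never masked.
#'
#' @param cohort complete cohort data.frame.
#' @param config a [cohort_config()] with non-`NULL` `missingness`.
#' @param seed integer seed.
#' @return the cohort with `NA`s injected; the logical missingness mask for
#'   the exposure columns is attached as attribute `miss_mask`.
#' @export
inject_missingness <- function(cohort, config, seed = 1) {
  rates <- config$missingness
  if (is.null(rates)) rates <- rep(0, config$n_exposures)
  if (any(rates >= 0.8)) stop_("missingness rates must be strictly below 0.8")
  set.seed(seed)
  age_std <- standardize(cohort$recruit_age)
  male <- as.integer(cohort$sex == "male")
  inc_std <- standardize(cohort$income_band)
  lp0 <- 0.3 * age_std + 0.2 * male + 0.25 * inc_std
  mask <- matrix(FALSE, nrow(cohort), config$n_exposures,
                 dimnames = list(NULL, config$exposure_names))
  for (j in seq_len(config$n_exposures)) {
    r <- rates[j]
    if (r <= 0) next
    alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lp0)) - r,
                            c(-20, 20), tol = 1e-10)$root
    mask[, j] <- stats::runif(nrow(cohort)) < stats::plogis(alpha + lp0)
    cohort[[config$exposure_names[j]]][mask[, j]] <- NA
  }
  attr(cohort, "miss_mask") <- mask
  cohort
}

#' Simulate a full synthetic cohort
#'
#' Runs the generator stages in order (demographics, exposome, survival,
#' ancillary columns, missingness), fanning one master seed out into
#' per-stage child seeds.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @return an object of class `synthetic_cohort`: a list with `cohort`
#'   (analysis table, with `NA`s if missingness is configured), `complete`
#'   (the pre-missingness table), `truth` (truth ledger), `specs`
#'   (exposure metadata), `config` and `seed`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n = 500), seed = 7)
#' table(sim$truth$role)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  seeds <- child_seeds(seed, 5)
  demo <- gen_demographics(config, seeds[1])
  exo <- generate_exposome(config, seeds[2], income = attr(demo, "income_z"))
  surv <- generate_survival(exo, config, demo, seeds[3])
  anc <- generate_ancillary(exo, surv, config, demo, seeds[4])
  complete <- cbind(demo, exo$exposures, surv[c("poor_health", "death_time",
                                                "death_event")], anc)
  complete$birth_cohort <- birth_cohort(complete$recruit_age, config$recruit_year)
  attr(complete, "income_z") <- attr(demo, "income_z")
  cohort <- complete
  if (!is.null(config$missingness)) {
    cohort <- inject_missingness(complete, config, seeds[5])
  }
  structure(list(cohort = cohort, complete = complete, truth = exo$truth,
                 specs = exo$specs, config = config, seed = seed,
                 gompertz_a = attr(surv, "gompertz_a")),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "participants,",
      x$config$n_exposures, "exposures\n")
  cat("  deaths:", sum(x$cohort$death_event),
      sprintf("(%.1f%%)", 100 * mean(x$cohort$death_event)), "\n")
  cat("  roles:", paste(names(table(x$truth$role)), table(x$truth$role),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}
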