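# Configuration-driven orchestration of the full screening pipeline
# (simulate -> impute -> XWAS -> robustness filters -> correlation
# clusters -> outcome panels -> variance decomposition) plus plot-ready
# summary exports.

#' Pipeline configuration
#'
#' Collects every threshold of the pipeline in one validated object. The
#' defaults are the analysis constants used throughout: FDR 0.05,
#' interaction alpha 0.05, adjusted-GVIF cutoff 1.6, cluster scan k =
#' 1..25, 2-year time splitting, 4-year early-death window, m = 5 imputed
#' copies, PheWAS flag thresholds (1e-10, 0.5).
#'
#' @param cohort a [cohort_config()] (used when no cohort is supplied to
#'   [run_pipeline()]).
#' @param seed master seed for the run.
#' @param m imputed copies (only relevant when the cohort has missing
#'   values).
#' @param impute_trees,impute_iter random-forest imputation settings.
#' @param fdr_alpha FDR significance threshold for discovery/replication.
#' @param interaction_alpha alpha of the poor-health interaction rule.
#' @param phewas_p_thresh,phewas_e_thresh two-threshold PheWAS flag rule.
#' @param gvif_threshold adjusted-GVIF collinearity cutoff.
#' @param k_range cluster-count scan range.
#' @param cluster_k manual cluster count (`NULL` = automatic elbow).
#' @param early_death_window years for the early-death sensitivity
#'   re-screen.
#' @param time_split_years episode length for PH-violation interactions.
#' @param n_pcs genetic principal components in PRS models.
#' @param stages named logical vector switching stages on/off.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), seed = 1, m = 5,
                            impute_trees = 200, impute_iter = 10,
                            fdr_alpha = 0.05, interaction_alpha = 0.05,
                            phewas_p_thresh = 1e-10, phewas_e_thresh = 0.5,
                            gvif_threshold = 1.6, k_range = 1:25,
                            cluster_k = NULL, early_death_window = 4,
                            time_split_years = 2, n_pcs = 4,
                            stages = c(impute = TRUE, xwas = TRUE,
                                       filters = TRUE, cluster = TRUE,
                                       panels = TRUE, decompose = TRUE)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may carry any [pipeline_config()] argument at the top level
#' plus a `cohort:` block of [cohort_config()] arguments.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_("the yaml package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort %||% list()
  # YAML 1.1 parses a bare `n:` key as a boolean; map it back
  names(cohort_args)[names(cohort_args) == "FALSE"] <- "n"
  raw$cohort <- NULL
  if (!is.null(cohort_args$cluster_blocks)) {
    cohort_args$cluster_blocks <-
      as.data.frame(do.call(rbind, lapply(cohort_args$cluster_blocks,
                                          as.data.frame)))
  }
  args <- raw
  args$cohort <- do.call(cohort_config, cohort_args)
  if (!is.null(args$stages)) args$stages <- unlist(args$stages)
  do.call(pipeline_config, args)
}

#' Run the full screening pipeline
#'
#' Executes the stages in order on a synthetic (or supplied) cohort:
#' imputation (when missingness is present), sex-specific and pooled
#' discovery/replication mortality screens, the three robustness filters,
#' correlation clustering with within-cluster multivariable pruning,
#' the outcome panels, and the exposome/PRS variance decomposition with
#' holdout validation. Stages toggled off are skipped, and stages whose
#' inputs are missing refuse to run.
#'
#' @param config a [pipeline_config()].
#' @param sim optional pre-generated [simulate_cohort()] result (otherwise
#'   one is generated from `config$cohort` and `config$seed`).
#' @param resume_from optional stage name; stages before it are copied
#'   from `previous` instead of recomputed.
#' @param previous a prior `xwas_run` used with `resume_from`.
#' @return an object of class `xwas_run`: a list of per-stage results plus
#'   a `manifest` echoing configuration and seeds.
#' @export
run_pipeline <- function(config = pipeline_config(), sim = NULL,
                         resume_from = NULL, previous = NULL) {
  stage_order <- c("simulate", "impute", "xwas", "filters", "cluster",
                   "panels", "decompose")
  resume_at <- if (is.null(resume_from)) 1L else match(resume_from, stage_order)
  if (is.na(resume_at)) stop_("unknown stage: ", resume_from)
  if (resume_at > 1 && is.null(previous) && is.null(sim)) {
    stop_("resuming requires the previous run")
  }
  reuse <- function(stage) {
    !is.null(previous) && match(stage, stage_order) < resume_at &&
      !is.null(previous[[stage]])
  }
  run <- list()
  seeds <- child_seeds(config$seed, 10)

  # -- simulate ---------------------------------------------------------
  if (reuse("simulate")) {
    sim <- previous$simulate
  } else if (is.null(sim)) {
    sim <- simulate_cohort(config$cohort, seed = seeds[1])
  }
  run$simulate <- sim
  cohort <- sim$cohort
  specs <- sim$specs
  train <- cohort[cohort$region == "train", , drop = FALSE]
  holdout_rows <- cohort$region == "holdout"

  # -- impute -----------------------------------------------------------
  if (reuse("impute")) {
    run$impute <- previous$impute
  } else if (isTRUE(config$stages[["impute"]]) && anyNA(train[specs$name])) {
    # imputation is region-separate: training and holdout copies never mix
    imp_tr <- impute_cohort(train, m = config$m,
                            max_iter = config$impute_iter,
                            num_trees = config$impute_trees,
                            seed = seeds[2])
    imp_ho <- impute_cohort(cohort[holdout_rows, , drop = FALSE],
                            m = config$m, max_iter = config$impute_iter,
                            num_trees = config$impute_trees,
                            seed = seeds[3])
    run$impute <- list(train = imp_tr, holdout = imp_ho)
  } else {
    run$impute <- list(train = list(train),
                       holdout = list(cohort[holdout_rows, , drop = FALSE]))
  }
  tr_copies <- as_copies(run$impute$train)
  ho_copies <- as_copies(run$impute$holdout)

  # -- xwas -------------------------------------------------------------
  if (reuse("xwas")) {
    run$xwas <- previous$xwas
  } else if (isTRUE(config$stages[["xwas"]])) {
    stage <- split_discovery_replication(tr_copies[[1]], seed = seeds[4])
    disc <- run_xwas(tr_copies, specs, stage = "discovery",
                     rows = which(stage == "discovery"))
    repl <- run_xwas(tr_copies, specs, stage = "replication",
                     rows = which(stage == "replication"))
    fem <- run_xwas(tr_copies, specs, sex = "female", stage = "female")
    mal <- run_xwas(tr_copies, specs, sex = "male", stage = "male")
    pooled <- run_xwas(tr_copies, specs, stage = "pooled")
    rep_tab <- replicate_exposures(disc, repl, alpha = config$fdr_alpha)
    run$xwas <- list(split = stage, discovery = disc, replication = repl,
                     female = fem, male = mal, pooled = pooled,
                     replication_table = rep_tab,
                     replicated = unique(rep_tab$exposure[rep_tab$replicated]),
                     sex_concordance = sex_concordance(fem, mal))
  }

  # -- filters ----------------------------------------------------------
  if (reuse("filters")) {
    run$filters <- previous$filters
  } else if (isTRUE(config$stages[["filters"]])) {
    if (is.null(run$xwas)) stop_("filters require the xwas stage")
    run$filters <- run_filter_stage(tr_copies, specs, run$xwas, config)
  }

  # -- cluster ----------------------------------------------------------
  if (reuse("cluster")) {
    run$cluster <- previous$cluster
  } else if (isTRUE(config$stages[["cluster"]])) {
    if (is.null(run$filters)) stop_("cluster stage requires the filters stage")
    run$cluster <- run_cluster_stage(tr_copies, specs,
                                     run$filters$survivors, config)
  }

  # -- panels -----------------------------------------------------------
  if (reuse("panels")) {
    run$panels <- previous$panels
  } else if (isTRUE(config$stages[["panels"]])) {
    if (is.null(run$cluster)) stop_("panels require the cluster stage")
    final <- run$cluster$final
    if (length(final)) {
      sp <- specs[specs$name %in% final, , drop = FALSE]
      d1 <- tr_copies[[1]]
      bms <- grep("^bm[0-9]+$", names(d1), value = TRUE)
      dzs <- sub("_event$", "", grep("^d[0-9]+_event$", names(d1), value = TRUE))
      rfs <- grep("^rf_", names(d1), value = TRUE)
      run$panels <- list(
        biomarkers = biomarker_panel(tr_copies, sp, bms),
        diseases = disease_panel(tr_copies, sp, dzs),
        risk_factors = risk_factor_panel(tr_copies, sp, rfs))
    }
  }

  # -- decompose --------------------------------------------------------
  if (reuse("decompose")) {
    run$decompose <- previous$decompose
  } else if (isTRUE(config$stages[["decompose"]])) {
    if (is.null(run$cluster)) stop_("decomposition requires the cluster stage")
    final <- run$cluster$final
    sp <- specs[specs$name %in% final, , drop = FALSE]
    d1 <- tr_copies[[1]]
    dzs <- sub("_event$", "", grep("^d[0-9]+_event$", names(d1), value = TRUE))
    res <- list()
    for (oc in c("mortality", dzs)) {
      fit <- fit_sequential_models(tr_copies, sp, outcome = oc,
                                   n_pcs = config$n_pcs)
      hv <- validate_holdout(fit, ho_copies, tr_copies)
      res[[oc]] <- list(fit = fit, holdout = hv)
    }
    run$decompose <- res
  }

  run$manifest <- list(seed = config$seed, child_seeds = seeds,
                       m = length(tr_copies),
                       n = nrow(cohort), n_train = nrow(train),
                       thresholds = config[c("fdr_alpha", "interaction_alpha",
                                             "phewas_p_thresh",
                                             "phewas_e_thresh",
                                             "gvif_threshold",
                                             "early_death_window",
                                             "time_split_years")],
                       stages_run = names(run))
  class(run) <- "xwas_run"
  run
}

# Robustness-filter stage over the replicated exposures: every filter
# reads the original copies + replication table only (order-independent).
run_filter_stage <- function(tr_copies, specs, xwas, config) {
  replicated <- xwas$replicated
  sp <- specs[specs$name %in% replicated, , drop = FALSE]
  if (!nrow(sp)) {
    return(list(survivors = character(0), verdicts = NULL))
  }
  early <- early_death_sensitivity(tr_copies, sp,
                                   window = config$early_death_window)
  inter <- poor_health_interaction_filter(tr_copies, sp,
                                          alpha = config$interaction_alpha)
  phe <- list()
  d1 <- tr_copies[[1]]
  bms <- grep("^bm[0-9]+$", names(d1), value = TRUE)
  for (v in sp$name) {
    panel <- data.frame(
      phenotype = c("income_band", "education_years", "poor_health",
                    "n_medications", bms, setdiff(specs$name, v)),
      category = c("exposure", "exposure", "disease_frailty_disability",
                   "disease_frailty_disability", rep("other", length(bms)),
                   rep("exposure", length(setdiff(specs$name, v)))),
      stringsAsFactors = FALSE)
    recs <- phewas_screen(tr_copies, v, panel, specs)
    phe[[v]] <- phewas_flag_rule(recs, config$phewas_p_thresh,
                                 config$phewas_e_thresh)
    attr(phe[[v]], "records") <- recs
  }
  phe_tab <- do.call(rbind, c(phe, list(make.row.names = FALSE)))
  # mortality coefficient per exposure: strongest pooled-screen level
  pooled <- xwas$pooled
  beta_mort <- vapply(sp$name, function(v) {
    rows <- pooled[pooled$exposure == v, , drop = FALSE]
    rows$beta[which.min(rows$p)]
  }, numeric(1))
  names(beta_mort) <- sp$name
  prote <- proteomic_concordance_filter(tr_copies, sp, beta_mort,
                                        alpha = config$fdr_alpha)
  verdicts <- rbind(inter[c("exposure", "filter", "decision", "reason")],
                    phe_tab[c("exposure", "filter", "decision", "reason")],
                    prote[c("exposure", "filter", "decision", "reason")])
  keep <- tapply(verdicts$decision, verdicts$exposure,
                 function(d) all(d == "retain"))
  survivors <- names(keep)[keep]
  list(survivors = survivors, verdicts = verdicts, early_death = early,
       interaction = inter, phewas = phe_tab, proteomic = prote)
}

# Correlation-cluster stage over the filter survivors.
run_cluster_stage <- function(tr_copies, specs, survivors, config) {
  sp <- specs[specs$name %in% survivors, , drop = FALSE]
  if (nrow(sp) < 2) {
    return(list(final = survivors, solution = NULL, models = NULL))
  }
  # nominal exposures enter the correlation as their dummy binaries
  expanded <- sp
  if (any(sp$type == "nominal")) {
    prep <- prepare_exposures(tr_copies[[1]], sp)
    expanded <- data.frame(name = unlist(prep$map),
                           type = ifelse(rep(sp$type, vapply(prep$map[sp$name],
                                                             length,
                                                             integer(1))) ==
                                           "nominal", "binary",
                                         rep(sp$type,
                                             vapply(prep$map[sp$name], length,
                                                    integer(1)))),
                           sex_specific = FALSE, stringsAsFactors = FALSE)
    tr_copies <- lapply(tr_copies, function(d) {
      cbind(d[setdiff(names(d), names(prep$mat))], prep$mat)
    })
  }
  hc <- heterogeneous_correlation(tr_copies, expanded)
  k_range <- config$k_range[config$k_range <= nrow(expanded)]
  sol <- cluster_exposures(hc, k_range = k_range, k = config$cluster_k)
  models <- list()
  final <- character(0)
  for (cl in sort(unique(sol$labels))) {
    members_cols <- names(sol$labels)[sol$labels == cl]
    members <- unique(ifelse(members_cols %in% specs$name, members_cols,
                             sub("\\.[^.]+$", "", members_cols)))
    wm <- within_cluster_model(tr_copies, members,
                               rbind_spec(specs, expanded, members),
                               gvif_threshold = config$gvif_threshold)
    models[[as.character(cl)]] <- wm
    final <- c(final, wm$survivors)
  }
  list(final = sort(unique(final)), solution = sol, correlation = hc,
       models = models)
}

rbind_spec <- function(specs, expanded, members) {
  out <- specs[match(members, specs$name), , drop = FALSE]
  miss <- members[is.na(out$name)]
  if (length(miss)) {
    out <- rbind(out[!is.na(out$name), c("name", "type", "sex_specific")],
                 expanded[match(miss, expanded$name),
                          c("name", "type", "sex_specific")])
  }
  out[c("name", "type", "sex_specific")]
}

#' @export
print.xwas_run <- function(x, ...) {
  cat("XWAS pipeline run (seed", x$manifest$seed, "): n =", x$manifest$n,
      "\n")
  if (!is.null(x$xwas)) {
    cat("  replicated exposures:", length(x$xwas$replicated), "\n")
  }
  if (!is.null(x$filters)) {
    cat("  filter survivors:", length(x$filters$survivors), "\n")
  }
  if (!is.null(x$cluster)) {
    cat("  clusters:", if (!is.null(x$cluster$solution)) x$cluster$solution$k
        else 0, "| final exposures:", length(x$cluster$final), "\n")
  }
  invisible(x)
}

#' Export plot-ready summary tables from a pipeline run
#'
#' Writes TSV/JSON artifacts: the volcano table (log2 HR, -log10 p,
#' replication class), the per-stage summary statistics, the forest table
#' of within-cluster models, heat-map matrices of the outcome panels, the
#' decomposition stack, the verdict audit trail and a JSON manifest.
#' Numeric columns are formatted at 6 significant digits so repeated runs
#' diff byte-identically.
#'
#' @param run an `xwas_run`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_summaries <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  fmt <- function(d) {
    for (j in seq_along(d)) {
      if (is.numeric(d[[j]])) d[[j]] <- signif(d[[j]], 6)
    }
    d
  }
  wr <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(fmt(d), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(run$xwas)) {
    for (stg in c("discovery", "replication", "pooled", "female", "male")) {
      wr(run$xwas[[stg]][c("exposure", "level", "beta", "se", "hr", "p",
                           "fdr_p", "n", "n_events")],
         paste0("xwas_", stg, ".tsv"))
    }
    disc <- run$xwas$discovery
    rep_tab <- run$xwas$replication_table
    cls <- ifelse(rep_tab$replicated[match(paste(disc$exposure, disc$term),
                                           paste(rep_tab$exposure,
                                                 rep_tab$term))],
                  "replicated", "nonreplicated")
    volcano <- data.frame(exposure = disc$exposure, level = disc$level,
                          log2_hr = log2(disc$hr),
                          neg_log10_p = -log10(pmax(disc$p, 1e-300)),
                          class = cls)
    wr(volcano, "volcano.tsv")
  }
  if (!is.null(run$filters)) {
    wr(run$filters$verdicts, "filter_verdicts.tsv")
  }
  if (!is.null(run$cluster) && !is.null(run$cluster$solution)) {
    sol <- run$cluster$solution
    wr(data.frame(exposure = names(sol$labels), cluster = sol$labels),
       "clusters.tsv")
    forest <- do.call(rbind, lapply(run$cluster$models, function(mn) {
      if (is.null(mn$records)) return(NULL)
      data.frame(mn$records,
                 ci_lo = exp(mn$records$beta - 1.96 * mn$records$se),
                 ci_hi = exp(mn$records$beta + 1.96 * mn$records$se))
    }))
    if (!is.null(forest)) wr(forest, "forest.tsv")
    writeLines(dendrogram_newick(sol), file.path(dir, "dendrogram.nwk"))
    paths <- c(paths, file.path(dir, "dendrogram.nwk"))
  }
  if (!is.null(run$panels)) {
    for (pn in names(run$panels)) {
      wr(run$panels[[pn]]$grid, paste0("panel_", pn, ".tsv"))
    }
  }
  if (!is.null(run$decompose)) {
    stack <- do.call(rbind, lapply(names(run$decompose), function(oc) {
      r <- run$decompose[[oc]]
      data.frame(outcome = oc, model = r$fit$models,
                 r2_train = unname(r$fit$r2[r$fit$models]),
                 c_train = unname(r$fit$c_index[r$fit$models]),
                 r2_holdout = r$holdout$r2, c_holdout = r$holdout$c_index)
    }))
    wr(stack, "decomposition.tsv")
    imp <- do.call(rbind, lapply(names(run$decompose), function(oc) {
      im <- run$decompose[[oc]]$fit$importance
      if (is.null(im)) return(NULL)
      data.frame(outcome = oc, im)
    }))
    if (!is.null(imp)) wr(imp, "importance.tsv")
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, manifest_path)
  invisible(paths)
}
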