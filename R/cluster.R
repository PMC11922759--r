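# Correlation-cluster decomposition: heterogeneous correlation matrix
# (Pearson / polyserial / polychoric by pair type, Fisher-z pooled across
# imputed copies), Ward hierarchical clustering on correlation profiles
# with a WSS elbow scan, and within-cluster multivariable Cox models with
# iterative GVIF pruning.

#' Heterogeneous correlation matrix of mixed-type exposures
#'
#' Pearson for continuous-continuous pairs, polyserial for
#' continuous-ordinal, polychoric (tetrachoric) for ordinal/binary pairs.
#' Nominal exposures must be pre-expanded to binaries. Per-copy matrices
#' are pooled entry-wise via Fisher's z.
#'
#' @param copies imputed set / data.frame(s).
#' @param specs exposure specs (types continuous/ordinal/binary).
#' @return list of class `hetcor_matrix`: `r` (pooled correlation matrix),
#'   `method` (per-pair estimator tags), `per_copy` (list of per-copy
#'   matrices).
#' @export
heterogeneous_correlation <- function(copies, specs) {
  copies <- as_copies(copies)
  if (any(specs$type == "nominal")) {
    stop_("expand nominal exposures to binaries before correlation")
  }
  vars <- specs$name
  k <- length(vars)
  type <- stats::setNames(specs$type, vars)
  for (ci in seq_along(copies)) {
    for (v in vars) {
      x <- copies[[ci]][[v]]
      if (length(unique(x[!is.na(x)])) < 2) {
        stop_("column with a single observed level: ", v)
      }
    }
  }
  method <- matrix("", k, k, dimnames = list(vars, vars))
  mats <- lapply(copies, function(d) {
    r <- diag(1, k)
    dimnames(r) <- list(vars, vars)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        ti <- type[vars[i]]
        tj <- type[vars[j]]
        xi <- as.numeric(d[[vars[i]]])
        xj <- as.numeric(d[[vars[j]]])
        if (ti == "continuous" && tj == "continuous") {
          rij <- stats::cor(xi, xj, use = "pairwise.complete.obs")
          method[i, j] <<- method[j, i] <<- "pearson"
        } else if (ti == "continuous" || tj == "continuous") {
          if (ti == "continuous") {
            rij <- polyserial(xi, xj)
          } else {
            rij <- polyserial(xj, xi)
          }
          method[i, j] <<- method[j, i] <<- "polyserial"
        } else {
          rij <- polychoric(xi, xj)
          method[i, j] <<- method[j, i] <<- "polychoric"
        }
        r[i, j] <- r[j, i] <- rij
      }
    }
    r
  })
  pooled <- diag(1, k)
  dimnames(pooled) <- list(vars, vars)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      vals <- vapply(mats, function(mm) mm[i, j], numeric(1))
      pooled[i, j] <- pooled[j, i] <- pool_fisher_z(vals, "r")
    }
  }
  structure(list(r = pooled, method = method, per_copy = mats),
            class = "hetcor_matrix")
}

#' Hierarchical clustering of exposures with a WSS elbow scan
#'
#' Each exposure is represented by its row of the (pooled) correlation
#' matrix; rows are clustered by Ward linkage on Euclidean distance. The
#' tree is cut at each k in `k_range`, the within-cluster sum of squares
#' (in the row-vector space) is recorded, and the automatic elbow picks
#' the k maximizing the second difference of the WSS curve; a manual k
#' overrides.
#'
#' @param r correlation matrix (or a `hetcor_matrix`).
#' @param k_range candidate numbers of clusters (default 1 to 25).
#' @param k manual override for the chosen k.
#' @param use_abs cluster on |r| profiles instead of signed ones.
#' @return object of class `cluster_solution`: `labels` (chosen-k cluster
#'   id per exposure), `k`, `wss` (per scanned k), `selection`
#'   (`auto_elbow` or `manual`), and the `hclust` tree.
#' @export
cluster_exposures <- function(r, k_range = 1:25, k = NULL, use_abs = FALSE) {
  if (inherits(r, "hetcor_matrix")) r <- r$r
  x <- if (use_abs) abs(r) else r
  p <- nrow(x)
  if (max(k_range) > p) {
    warn_("k range truncated to the number of exposures (", p, ")")
    k_range <- k_range[k_range <= p]
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  wss_of <- function(labels) {
    sum(vapply(unique(labels), function(cl) {
      rows <- x[labels == cl, , drop = FALSE]
      ctr <- colMeans(rows)
      sum(sweep(rows, 2, ctr)^2)
    }, numeric(1)))
  }
  cuts <- lapply(k_range, function(kk) stats::cutree(hc, k = kk))
  wss <- vapply(cuts, wss_of, numeric(1))
  names(wss) <- k_range
  if (is.null(k)) {
    selection <- "auto_elbow"
    if (length(k_range) < 3) {
      k <- k_range[which.min(wss)]
    } else {
      d2 <- wss[-c(1, length(wss))]
      d2 <- wss[seq_len(length(wss) - 2)] - 2 * wss[seq(2, length(wss) - 1)] +
        wss[seq(3, length(wss))]
      k <- k_range[which.max(d2) + 1L]
    }
  } else {
    selection <- "manual"
    if (!k %in% k_range) stop_("manual k outside the scanned range")
  }
  labels <- cuts[[match(k, k_range)]]
  names(labels) <- rownames(x)
  structure(list(labels = labels, k = k, wss = wss, selection = selection,
                 hclust = hc), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Cluster solution: k =", x$k, paste0("(", x$selection, ")"), "\n")
  print(table(x$labels))
  invisible(x)
}

#' Export a cluster dendrogram as Newick text
#' @param solution a `cluster_solution`.
#' @return a Newick string of the Ward tree.
#' @export
dendrogram_newick <- function(solution) {
  hc <- solution$hclust
  lab <- hc$labels %||% as.character(seq_along(hc$order))
  rec <- function(i) {
    if (i < 0) return(lab[-i])
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    paste0("(", rec(kids[1]), ":", format(h, digits = 6), ",",
           rec(kids[2]), ":", format(h, digits = 6), ")")
  }
  paste0(rec(nrow(hc$merge)), ";")
}

#' Within-cluster multivariable mortality model
#'
#' Step 1: iterative collinearity pruning — GVIF^(1/(2 df)) is computed
#' over the cluster members (plus covariates), the worst offender above
#' the threshold is removed, and the factors are recomputed until all
#' members pass. Step 2: all surviving members enter one multivariable
#' stratified Cox model (age timescale, birth-cohort x sex strata,
#' covariates center, household income, years of education and ethnicity
#' unless already members); survivors are the members with pooled p <
#' 0.05.
#'
#' @param copies imputed set / data.frame(s).
#' @param members exposure names in the cluster.
#' @param specs exposure specs covering the members.
#' @param covariates default adjustment set; any name also appearing in
#'   `members` is skipped.
#' @param strata stratum columns.
#' @param gvif_threshold pruning threshold on the adjusted GVIF scale.
#' @param alpha survivor significance level.
#' @param rows optional row subset.
#' @return list with `collinearity` (per-exposure adjusted GVIF and the
#'   removed set), `records` (association records from the multivariable
#'   model), `survivors` (exposures with pooled p < alpha).
#' @export
within_cluster_model <- function(copies, members, specs,
                                 covariates = c("center", "income_band",
                                                "education_years",
                                                "ethnicity"),
                                 strata = c("birth_cohort", "sex"),
                                 gvif_threshold = 1.6, alpha = 0.05,
                                 rows = NULL) {
  copies <- as_copies(copies)
  if (!length(members)) stop_("cluster is empty")
  specs <- specs[match(members, specs$name), , drop = FALSE]
  covariates <- setdiff(covariates, members)
  d1 <- copies[[1]]
  if (!is.null(rows)) d1 <- d1[rows, , drop = FALSE]
  prep <- prepare_exposures(d1, specs)

  # step 1: iterative GVIF pruning among the cluster members
  keep <- members
  removed <- character(0)
  gvif_tab <- NULL
  repeat {
    cols <- unlist(prep$map[keep])
    cov_mm <- stats::model.matrix(~ ., data = d1[covariates])[, -1, drop = FALSE]
    X <- cbind(as.matrix(prep$mat[cols]), cov_mm)
    terms <- c(rep(keep, vapply(prep$map[keep], length, integer(1))),
               rep("(covariates)", ncol(cov_mm)))
    if (length(keep) == 1 && ncol(cov_mm) == 0) break
    # perfect collinearity: drop duplicates before the determinant work
    qrX <- qr(scale(X))
    if (qrX$rank < ncol(X)) {
      drop_col <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      offender <- unique(terms[match(drop_col, colnames(X))])
      offender <- setdiff(offender, "(covariates)")
      if (!length(offender)) stop_("covariates are collinear")
      removed <- c(removed, offender[1])
      keep <- setdiff(keep, offender[1])
      if (!length(keep)) break
      next
    }
    g <- gvif(X, terms)
    gvif_tab <- g[g$term != "(covariates)", , drop = FALSE]
    worst <- gvif_tab[which.max(gvif_tab$gvif_adj), ]
    if (nrow(gvif_tab) && worst$gvif_adj > gvif_threshold && length(keep) > 1) {
      removed <- c(removed, worst$term)
      keep <- setdiff(keep, worst$term)
    } else {
      break
    }
  }
  if (!length(keep)) {
    warn_("all cluster members pruned for collinearity")
    return(list(collinearity = list(gvif = gvif_tab, removed = removed,
                                    threshold = gvif_threshold),
                records = NULL, survivors = character(0)))
  }

  # step 2: one multivariable Cox over the surviving members
  m <- length(copies)
  spec_keep <- specs[match(keep, specs$name), , drop = FALSE]
  per_copy <- lapply(copies, function(d) {
    if (!is.null(rows)) d <- d[rows, , drop = FALSE]
    pr <- prepare_exposures(d, spec_keep)
    base <- data.frame(.entry = d$recruit_age,
                       .exit = d$recruit_age + d$death_time,
                       .event = d$death_event)
    base$.st <- interaction(d[strata], drop = TRUE)
    cbind(base, d[covariates], pr$mat)
  })
  cols <- unlist(prep$map[keep])
  rhs <- paste(c(sprintf("`%s`", cols), covariates, "strata(.st)"),
               collapse = " + ")
  fml <- stats::as.formula(paste("Surv(.entry, .exit, .event) ~", rhs))
  est <- matrix(NA_real_, m, length(cols), dimnames = list(NULL, cols))
  var_ <- est
  for (ci in seq_len(m)) {
    fit <- quiet_coxph(fml, data = per_copy[[ci]], ties = "efron")
    b <- stats::coef(fit)
    idx <- match(sprintf("`%s`", cols), names(b))
    if (anyNA(idx)) idx <- match(cols, names(b))
    est[ci, ] <- b[idx]
    var_[ci, ] <- diag(as.matrix(stats::vcov(fit)))[idx]
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
  expo_of <- rep(keep, vapply(prep$map[keep], length, integer(1)))
  records <- data.frame(exposure = expo_of, term = cols,
                        level = prep$level[cols],
                        beta = beta, se = se, hr = exp(beta), p = p,
                        stage = "within_cluster",
                        stringsAsFactors = FALSE, row.names = NULL)
  surv_p <- tapply(records$p, records$exposure, min)
  survivors <- names(surv_p)[surv_p < alpha]
  list(collinearity = list(gvif = gvif_tab, removed = removed,
                           threshold = gvif_threshold),
       records = records, survivors = survivors)
}
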