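# Coerce case/control labels to 0/1 (case = 1); "excluded" -> NA.
as_binary_outcome <- function(x) {
  if (is.numeric(x) || is.logical(x)) return(as.integer(x))
  out <- rep(NA_integer_, length(x))
  out[x == "case"] <- 1L
  out[x == "control"] <- 0L
  out
}

#' Principal components of the genotype matrix
#'
#' Computes the top-k left singular directions of the column-standardised
#' dosage matrix, restricted to an LD-pruned variant subset. Each variant
#' column is mean-centred and scaled to unit variance (zero-variance columns
#' are skipped); missing dosages are mean-imputed first. PC scores are
#' `U %*% diag(d)`. Sign convention: the loading with the largest magnitude
#' on each component is positive.
#'
#' @param ds a [dosage_set()]
#' @param prune_idx optional integer index of the variant subset (e.g. from
#'   [ld_prune()]); default all variants
#' @param k number of components (default 10)
#' @return numeric matrix n x k with columns `PC1..PCk`
#' @export
compute_pcs <- function(ds, prune_idx = NULL, k = 10) {
  stopifnot(inherits(ds, "dosage_set"))
  X <- impute_mean_cols(ds$dosages[, prune_idx %||% seq_len(ncol(ds$dosages)),
                                   drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  X <- scale(X)
  if (k > min(dim(X))) stop_input("k exceeds the rank of the pruned matrix")
  sv <- svd(X, nu = k, nv = k)
  if (k > sum(sv$d > 1e-8 * sv$d[1]))
    stop_input("k exceeds the rank of the pruned matrix")
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2,
                  sv$d[seq_len(k)] * flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(ds$dosages)
  scores
}

nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  num <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  den <- 1 - exp(-fit$null.deviance / n)
  if (den <= 0) return(0)
  num / den
}

#' Logistic association of a score with a binary outcome
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`): `outcome ~ score + covariates`. Reports the score
#' coefficient, Wald standard error, odds ratio with 95% Wald CI
#' (`exp(beta +/- 1.96 se)`), two-sided Wald p-value, and the incremental
#' Nagelkerke pseudo-R-squared of the score (full model minus
#' covariates-only model). Non-convergence and separation are flagged in the
#' `status` field, never silently returned as estimates.
#'
#' @param outcome binary vector (1/TRUE or `"case"` = case)
#' @param score numeric score vector (typically a standardized PRS)
#' @param covariates optional data.frame of covariates
#' @return list: `beta`, `se`, `or`, `ci_lo`, `ci_hi`, `pvalue`, `r2_obs`,
#'   `n_case`, `n_control`, `status` (`"ok"`, `"separation"`, or
#'   `"no_convergence"`)
#' @export
fit_logistic <- function(outcome, score, covariates = NULL) {
  y <- as_binary_outcome(outcome)
  ok <- !is.na(y) & !is.na(score)
  dat <- data.frame(.y = y, .score = score)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    ok <- ok & stats::complete.cases(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[ok, , drop = FALSE]
  if (length(unique(dat$.y)) < 2)
    stop_input("outcome must contain both cases and controls")
  res <- list(beta = NA_real_, se = NA_real_, or = NA_real_,
              ci_lo = NA_real_, ci_hi = NA_real_, pvalue = NA_real_,
              r2_obs = NA_real_, n_case = sum(dat$.y == 1L),
              n_control = sum(dat$.y == 0L), status = "ok")
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  separated <- warned && (all(mu > 1 - 1e-8 | mu < 1e-8))
  if (separated) {
    res$status <- "separation"
    return(res)
  }
  if (!fit$converged) {
    res$status <- "no_convergence"
    return(res)
  }
  co <- summary(fit)$coefficients
  if (!".score" %in% rownames(co) || !is.finite(co[".score", 2]) ||
      co[".score", 2] > 100) {
    res$status <- "separation"
    return(res)
  }
  b <- co[".score", 1]
  se <- co[".score", 2]
  res$beta <- b
  res$se <- se
  res$or <- exp(b)
  res$ci_lo <- exp(b - 1.96 * se)
  res$ci_hi <- exp(b + 1.96 * se)
  res$pvalue <- 2 * stats::pnorm(-abs(b / se))
  r2_full <- nagelkerke_r2(fit)
  r2_cov <- if (is.null(covariates)) 0 else {
    null_fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat[, names(dat) != ".score", drop = FALSE],
                 family = stats::binomial()))
    nagelkerke_r2(null_fit)
  }
  res$r2_obs <- max(r2_full - r2_cov, 0)
  res
}

#' Liability-scale conversion of observed-scale R-squared
#'
#' Converts an observed-scale (Nagelkerke) case-control R-squared to the
#' liability scale, correcting for case-control ascertainment:
#' `R2_liab = R2_obs * C` with
#' `C = [K(1-K)/phi(z_K)^2] * [K(1-K)/(P(1-P))]`, where `K` is the population
#' prevalence, `P` the sample case fraction, `z_K` the standard-normal
#' quantile at `1-K`, and `phi` the standard-normal density.
#'
#' @param r2_observed observed-scale R-squared (>= 0)
#' @param K population prevalence, in (0, 1)
#' @param P sample case fraction, in (0, 1)
#' @return liability-scale R-squared
#' @export
liability_r2 <- function(r2_observed, K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop_input("K and P must lie strictly in (0, 1)")
  if (r2_observed < 0) stop_input("r2_observed must be >= 0")
  z <- stats::qnorm(1 - K)
  C <- (K * (1 - K) / stats::dnorm(z)^2) * (K * (1 - K) / (P * (1 - P)))
  r2_observed * C
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param m number of tests (>= 1)
#' @return `alpha / m` (exact; round to 2 significant figures for reporting)
#' @export
bonferroni <- function(alpha = 0.05, m) {
  if (m < 1) stop_input("m must be >= 1")
  alpha / m
}

#' The nine age/sex strata and their covariate sets
#'
#' Full sample; males; females; the two age bands split at 60 years; and the
#' four age-by-sex cells. Stratified-on variables never reappear as
#' covariates: the full sample adjusts for age, sex and the PCs; sex strata
#' for age and the PCs; age strata for sex and the PCs; age-by-sex cells for
#' the PCs only.
#'
#' @param age_cut age split in years (default 60)
#' @param n_pcs number of principal components used as covariates
#' @return data.frame: `label`, `age_filter` (`"all"/"lt"/"ge"`),
#'   `sex_filter` (`"all"/"male"/"female"`), `covariates`
#'   (comma-separated covariate names)
#' @export
strata_grid <- function(age_cut = 60, n_pcs = 10) {
  pcs <- paste0("PC", seq_len(n_pcs))
  pc_lab <- paste(pcs, collapse = ",")
  df <- data.frame(
    label = c("all", "males", "females",
              sprintf(">=%d years", age_cut), sprintf("<%d years", age_cut),
              sprintf(">=%d years, males", age_cut),
              sprintf(">=%d years, females", age_cut),
              sprintf("<%d years, males", age_cut),
              sprintf("<%d years, females", age_cut)),
    age_filter = c("all", "all", "all", "ge", "lt", "ge", "ge", "lt", "lt"),
    sex_filter = c("all", "male", "female", "all", "all",
                   "male", "female", "male", "female"),
    stringsAsFactors = FALSE)
  df$covariates <- vapply(seq_len(nrow(df)), function(i) {
    covs <- pcs
    if (df$sex_filter[i] == "all") covs <- c("sex", covs)
    if (df$age_filter[i] == "all") covs <- c("age", covs)
    paste(covs, collapse = ",")
  }, character(1))
  df
}

stratum_index <- function(cohort, stratum, age_cut = 60) {
  sel <- rep(TRUE, nrow(cohort))
  if (stratum$age_filter == "lt") sel <- sel & cohort$age < age_cut
  if (stratum$age_filter == "ge") sel <- sel & cohort$age >= age_cut
  if (stratum$sex_filter != "all") sel <- sel & cohort$sex == stratum$sex_filter
  sel
}

stratum_covariates <- function(cohort, stratum) {
  covs <- strsplit(stratum$covariates, ",", fixed = TRUE)[[1]]
  out <- cohort[, covs, drop = FALSE]
  if ("sex" %in% covs) out$sex <- as.integer(out$sex == "male")
  out
}

#' Stratified PRS association grid
#'
#' Runs the full discovery grid: for each outcome and each of the nine
#' age/sex strata, scans the threshold grid within the stratum (scores
#' standardised on the outcome's full analysis sample so strata share a
#' common scale), fits the stratum's logistic model with its covariate set,
#' and reports the best-fit model's association. Significance is flagged at
#' the Bonferroni threshold for the number of grid rows (27 by default).
#'
#' @param cohort phenotype/covariate data.frame (must contain the outcome
#'   flag columns, `age`, `sex`, and `PC1..PCk`)
#' @param panel clumped harmonized panel
#' @param ds a [dosage_set()] aligned with `cohort` rows
#' @param outcomes outcome flag columns to test
#' @param grid p-value threshold grid
#' @param prevalences named population prevalences per outcome, for the
#'   liability-scale R-squared conversion
#' @param alpha family-wise error rate for the Bonferroni flag
#' @param age_cut age split in years
#' @param n_pcs number of PC covariates
#' @return data.frame with one row per stratum x outcome: stratum `label`,
#'   `outcome`, `covariates`, `cases`, `controls`, `threshold`, `n_snp`,
#'   `or`, `ci_lo`, `ci_hi`, `pvalue`, `r2_obs`, `r2_liability`,
#'   `significant`, `status`; attribute `models` holds the per-row best
#'   `prs_model`s, attribute `bonferroni` the threshold used
#' @export
run_stratified <- function(cohort, panel, ds,
                           outcomes = c("hospitalised", "severe", "critical"),
                           grid = default_threshold_grid(),
                           prevalences = c(hospitalised = 0.005,
                                           severe = 0.00295,
                                           critical = 0.00095),
                           alpha = 0.05, age_cut = 60, n_pcs = 10) {
  stopifnot(nrow(cohort) == nrow(ds$dosages))
  strata <- strata_grid(age_cut = age_cut, n_pcs = n_pcs)
  m_tests <- nrow(strata) * length(outcomes)
  thr <- bonferroni(alpha, m_tests)
  rows <- list()
  models <- list()
  for (oc in outcomes) {
    y <- as_binary_outcome(cohort[[oc]])
    analysis <- which(!is.na(y))
    for (si in seq_len(nrow(strata))) {
      stratum <- strata[si, ]
      idx <- intersect(which(stratum_index(cohort, stratum, age_cut)),
                       analysis)
      label <- stratum$label
      row_id <- paste(oc, label, sep = " | ")
      base_row <- data.frame(
        label = label, outcome = oc, covariates = stratum$covariates,
        cases = sum(y[idx] == 1L, na.rm = TRUE),
        controls = sum(y[idx] == 0L, na.rm = TRUE),
        threshold = NA_real_, n_snp = NA_integer_, or = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, pvalue = NA_real_,
        r2_obs = NA_real_, r2_liability = NA_real_, significant = FALSE,
        status = "ok", stringsAsFactors = FALSE)
      if (base_row$cases == 0 || base_row$controls == 0) {
        base_row$status <- "empty_stratum"
        rows[[row_id]] <- base_row
        models[[row_id]] <- NULL
        next
      }
      covs <- stratum_covariates(cohort, stratum)
      sc <- tryCatch(
        threshold_scan(panel, ds, y, covariates = covs, grid = grid,
                       fit_idx = idx, standardize_idx = analysis),
        prsct_error = function(e) e)
      if (inherits(sc, "error")) {
        base_row$status <- conditionMessage(sc)
        rows[[row_id]] <- base_row
        next
      }
      b <- sc$best
      base_row$threshold <- b$threshold
      base_row$n_snp <- b$n_snp
      base_row$or <- b$or
      base_row$ci_lo <- b$ci_lo
      base_row$ci_hi <- b$ci_hi
      base_row$pvalue <- b$pvalue
      P <- base_row$cases / (base_row$cases + base_row$controls)
      r2o <- refit_r2(sc, panel, ds, y, covs, idx, analysis)
      base_row$r2_obs <- r2o
      if (!is.na(r2o) && oc %in% names(prevalences))
        base_row$r2_liability <- liability_r2(r2o, prevalences[[oc]], P)
      base_row$significant <- !is.na(base_row$pvalue) & base_row$pvalue <= thr
      rows[[row_id]] <- base_row
      models[[row_id]] <- sc$best_model
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  attr(out, "bonferroni") <- thr
  out
}

# incremental Nagelkerke R2 of the best model in a finished scan
refit_r2 <- function(sc, panel, ds, y, covs, idx, analysis) {
  f <- tryCatch({
    raw <- compute_prs(ds, sc$best_model)
    sv <- standardize(raw[analysis])
    z <- (raw - sv$mean) / sv$sd
    fit_logistic(y[idx], z[idx], covariates = covs[idx, , drop = FALSE])
  }, prsct_error = function(e) NULL)
  if (is.null(f) || !identical(f$status, "ok")) NA_real_ else f$r2_obs
}

#' Per-quartile odds ratios against the lowest quartile
#'
#' Logistic fit with indicator terms for quartiles Q2-Q4 (Q1 reference),
#' using the same covariates as the continuous model.
#'
#' @param bins factor from [quartile_bins()]
#' @param outcome binary outcome vector
#' @param covariates optional covariate data.frame
#' @return data.frame with one row per non-reference quartile: `quartile`,
#'   `or`, `ci_lo`, `ci_hi`, `pvalue`
#' @export
quartile_or <- function(bins, outcome, covariates = NULL) {
  y <- as_binary_outcome(outcome)
  ok <- !is.na(y) & !is.na(bins)
  if (any(table(bins[ok]) == 0)) stop_input("every quartile must be non-empty")
  dat <- data.frame(.y = y, .q = bins)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- dat[ok & stats::complete.cases(dat), , drop = FALSE]
  fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  qs <- paste0(".qQ", 2:4)
  data.frame(quartile = paste0("Q", 2:4),
             or = exp(co[qs, 1]),
             ci_lo = exp(co[qs, 1] - 1.96 * co[qs, 2]),
             ci_hi = exp(co[qs, 1] + 1.96 * co[qs, 2]),
             pvalue = 2 * stats::pnorm(-abs(co[qs, 1] / co[qs, 2])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sensitivity re-analyses
#'
#' Re-runs the stratified association grid under three modified designs:
#' excluding samples with a history of chronic respiratory disease; using
#' only at-risk controls (non-hospitalised phenotyped patients, i.e. no
#' population controls); and the 90-day mortality outcome, whose
#' significance is flagged at the Bonferroni threshold for the nine strata.
#'
#' @param cohort phenotype/covariate data.frame (with PCs attached)
#' @param panel clumped harmonized panel
#' @param ds a [dosage_set()] aligned with `cohort`
#' @param grid threshold grid
#' @param outcomes outcomes for the first two re-analyses
#' @param prevalences population prevalences for liability conversion
#' @param alpha family-wise error rate
#' @param ... passed to [run_stratified()]
#' @return list of association grids: `no_chronic`, `at_risk_controls`,
#'   `mortality`
#' @export
sensitivity_suite <- function(cohort, panel, ds, grid = default_threshold_grid(),
                              outcomes = c("hospitalised", "severe", "critical"),
                              prevalences = c(hospitalised = 0.005,
                                              severe = 0.00295,
                                              critical = 0.00095),
                              alpha = 0.05, ...) {
  keep_nc <- !cohort$chronic_resp_disease
  no_chronic <- run_stratified(cohort[keep_nc, , drop = FALSE],
                               panel, subset_samples(ds, keep_nc),
                               outcomes = outcomes, grid = grid,
                               prevalences = prevalences, alpha = alpha, ...)
  at_risk <- cohort
  for (oc in outcomes)
    at_risk[[oc]][at_risk$population_control] <- "excluded"
  at_risk_res <- run_stratified(at_risk, panel, ds, outcomes = outcomes,
                                grid = grid, prevalences = prevalences,
                                alpha = alpha, ...)
  mortality <- run_stratified(cohort, panel, ds, outcomes = "mortality",
                              grid = grid, prevalences = prevalences,
                              alpha = alpha, ...)
  # mortality: 9 strata for one outcome -> alpha/9 flag
  thr9 <- bonferroni(alpha, nrow(mortality))
  mortality$significant <- !is.na(mortality$pvalue) & mortality$pvalue <= thr9
  attr(mortality, "bonferroni") <- thr9
  list(no_chronic = no_chronic, at_risk_controls = at_risk_res,
       mortality = mortality)
}

#' Subset a dosage set by sample
#'
#' @param ds a [dosage_set()]
#' @param idx logical or integer sample index
#' @return the restricted `dosage_set`
#' @export
subset_samples <- function(ds, idx) {
  out <- ds
  out$dosages <- ds$dosages[idx, , drop = FALSE]
  out
}
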