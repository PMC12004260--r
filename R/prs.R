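#' Build a PRS model at a p-value threshold
#'
#' Selects exactly the clumped panel variants whose base p-value is at or
#' below the threshold; weights are the harmonised effect sizes.
#'
#' @param panel a harmonized panel, already restricted to clumped variants
#' @param p_threshold inclusion p-value cutoff `P_T`
#' @return a `prs_model`: list with `threshold`, `variants` (data.frame
#'   `key`, `chrom`, `pos`, `effect_allele`, `other_allele`, `weight`,
#'   `pvalue`), and `n_snp`
#' @export
build_model <- function(panel, p_threshold) {
  stopifnot(inherits(panel, "harmonized_panel"))
  keep <- panel$stats$pvalue <= p_threshold
  if (!any(keep))
    prsct_stop(sprintf("no variants at threshold %g", p_threshold),
               class = "prsct_empty_model")
  st <- panel$stats[keep, , drop = FALSE]
  variants <- data.frame(key = panel$dosages$map$key[keep],
                         chrom = st$chrom, pos = st$pos,
                         effect_allele = st$effect_allele,
                         other_allele = st$other_allele,
                         weight = st$beta, pvalue = st$pvalue,
                         stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  structure(list(threshold = p_threshold, variants = variants,
                 n_snp = nrow(variants)), class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> P_T = %g, %d variant(s)\n", x$threshold, x$n_snp))
  invisible(x)
}

#' Compute raw polygenic risk scores
#'
#' `score_j = sum_i weight_i * G_ij`, where `G` is the dosage of the model's
#' effect allele. Missing dosages are replaced by the variant's sample mean
#' dosage before summation. If a model variant is stored with the opposite
#' counted allele in the dosage set, its dosage enters as `2 - G`.
#'
#' @param ds a [dosage_set()]
#' @param model a `prs_model`
#' @return numeric vector of raw scores, named by sample id
#' @export
compute_prs <- function(ds, model) {
  stopifnot(inherits(ds, "dosage_set"), inherits(model, "prs_model"))
  idx <- match(model$variants$key, ds$map$key)
  if (anyNA(idx))
    prsct_stop(paste0("model variant(s) absent from dosage matrix: ",
                      paste(model$variants$key[is.na(idx)], collapse = ", ")),
               class = "prsct_missing_variant")
  G <- impute_mean_cols(ds$dosages[, idx, drop = FALSE])
  flip <- model$variants$effect_allele != ds$map$counted[idx]
  if (any(flip)) G[, flip] <- 2 - G[, flip]
  drop(G %*% model$variants$weight)
}

#' Standardise raw scores to z-scores
#'
#' `z = (raw - mean) / sd` with the sample (n-1) standard deviation, so the
#' standardized score has mean 0 and unit variance in the standardisation
#' sample.
#'
#' @param raw numeric vector of raw scores (>= 2 values, nonzero variance)
#' @return a `score_vector`: list with `raw`, `z`, `mean`, `sd`
#' @export
standardize <- function(raw) {
  if (length(raw) < 2) stop_input("standardisation needs at least 2 samples")
  m <- mean(raw)
  s <- stats::sd(raw)
  if (!is.finite(s) || s <= 0)
    prsct_stop("zero-variance score: degenerate model",
               class = "prsct_degenerate_score")
  structure(list(raw = raw, z = (raw - m) / s, mean = m, sd = s),
            class = "score_vector")
}

#' Default p-value threshold grid
#'
#' Genome-wide and suggestive anchors plus a fine arithmetic grid with 5e-5
#' spacing up to 0.5, and 1 (all clumped variants).
#'
#' @param fine spacing of the arithmetic part
#' @param upper upper end of the arithmetic part
#' @return increasing numeric vector of thresholds
#' @export
default_threshold_grid <- function(fine = 5e-5, upper = 0.5) {
  sort(unique(c(5e-8, 1e-6, 1e-4, seq(fine, upper, by = fine), 1)))
}

#' Scan p-value thresholds for the best-fit PRS model
#'
#' For each grid threshold with a non-empty model, computes the standardized
#' PRS and fits the stratum's logistic model, recording the Wald p-value of
#' the score term. Thresholds that select the same variant subset share one
#' fit. The best model minimises the association p-value; ties are broken by
#' smaller `n_snp`, then smaller threshold. Scores can be standardised on a
#' different (larger) sample than the association fit, so strata share a
#' common scale.
#'
#' @param panel clumped harmonized panel
#' @param ds a [dosage_set()] with all samples
#' @param outcome binary vector over all samples (1/TRUE = case; `NA` allowed
#'   outside the analysis subset)
#' @param covariates data.frame of covariates over all samples (or NULL)
#' @param grid numeric vector of thresholds
#' @param fit_idx integer indices of samples entering the logistic fit
#'   (default: all samples with non-missing outcome)
#' @param standardize_idx indices of the standardisation sample (default:
#'   `fit_idx`)
#' @return list with `best_model` (a `prs_model`), `best` (its scan row), and
#'   `scan` (data.frame: `threshold`, `n_snp`, `beta`, `se`, `or`, `ci_lo`,
#'   `ci_hi`, `pvalue`, `status`)
#' @export
threshold_scan <- function(panel, ds, outcome, covariates = NULL,
                           grid = default_threshold_grid(),
                           fit_idx = NULL, standardize_idx = NULL) {
  stopifnot(inherits(panel, "harmonized_panel"))
  if (length(grid) == 0) stop_input("threshold grid is empty")
  outcome <- as_binary_outcome(outcome)
  fit_idx <- fit_idx %||% which(!is.na(outcome))
  standardize_idx <- standardize_idx %||% fit_idx
  if (length(unique(outcome[fit_idx])) < 2)
    stop_input("outcome must have both cases and controls")
  st <- panel$stats
  ord <- order(st$pvalue, st$pos, st$effect_allele)
  p_sorted <- st$pvalue[ord]
  grid <- sort(grid)
  n_at <- findInterval(grid, p_sorted) # variants included per threshold
  ok <- n_at > 0
  if (!any(ok)) prsct_stop("no threshold yields a non-empty model",
                           class = "prsct_empty_model")
  X <- impute_mean_cols(panel$dosages$dosages[, ord, drop = FALSE])
  w <- st$beta[ord]
  cuts <- sort(unique(n_at[ok]))
  raw <- numeric(nrow(X))
  fits <- vector("list", length(cuts))
  prev <- 0L
  for (ci in seq_along(cuts)) {
    k <- cuts[ci]
    add <- (prev + 1L):k
    raw <- raw + drop(X[, add, drop = FALSE] %*% w[add])
    prev <- k
    fits[[ci]] <- tryCatch({
      sv <- standardize(raw[standardize_idx])
      z_all <- (raw - sv$mean) / sv$sd
      fit_logistic(outcome[fit_idx], z_all[fit_idx],
                   covariates = if (is.null(covariates)) NULL else
                     covariates[fit_idx, , drop = FALSE])
    }, prsct_error = function(e) list(status = conditionMessage(e)))
  }
  rows <- lapply(seq_along(grid), function(gi) {
    if (!ok[gi])
      return(data.frame(threshold = grid[gi], n_snp = 0L, beta = NA_real_,
                        se = NA_real_, or = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, pvalue = NA_real_,
                        status = "empty_model", stringsAsFactors = FALSE))
    f <- fits[[match(n_at[gi], cuts)]]
    if (!identical(f$status, "ok"))
      return(data.frame(threshold = grid[gi], n_snp = n_at[gi],
                        beta = NA_real_, se = NA_real_, or = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, pvalue = NA_real_,
                        status = f$status, stringsAsFactors = FALSE))
    data.frame(threshold = grid[gi], n_snp = n_at[gi], beta = f$beta,
               se = f$se, or = f$or, ci_lo = f$ci_lo, ci_hi = f$ci_hi,
               pvalue = f$pvalue, status = "ok", stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, rows)
  usable <- scan$status == "ok"
  if (!any(usable))
    prsct_stop("no threshold yielded a successful fit",
               class = "prsct_scan_failed")
  su <- scan[usable, , drop = FALSE]
  best_row <- su[order(su$pvalue, su$n_snp, su$threshold)[1], , drop = FALSE]
  best_model <- build_model(panel, best_row$threshold)
  list(best_model = best_model, best = best_row, scan = scan)
}

#' Exclude a locus and its flanking region from a model or panel
#'
#' Removes every variant on the locus chromosome whose position is within
#' `flank_bp` (inclusive) of the locus position, including the locus variant
#' itself. Used to drop a sentinel locus (e.g. a MUC5B-promoter-like variant)
#' and its LD proxies. If the locus key is not present, a warning is issued
#' and the input is returned unchanged.
#'
#' @param x a `prs_model` or harmonized panel
#' @param locus variant key string (`"chrom:pos:a:b"`) identifying the locus
#' @param flank_bp flank half-width in bp (default 1 Mb)
#' @return the reduced model/panel
#' @export
subset_exclude_locus <- function(x, locus, flank_bp = 1e6) {
  parts <- strsplit(locus, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop_input("locus must be a variant key 'chrom:pos:a:b'")
  lchrom <- parts[1]
  lpos <- as.integer(parts[2])
  if (inherits(x, "prs_model")) {
    if (!locus %in% x$variants$key) {
      warning("locus ", locus, " not found in model; model unchanged",
              call. = FALSE)
      return(x)
    }
    keep <- !(x$variants$chrom == lchrom &
                abs(x$variants$pos - lpos) <= flank_bp)
    if (!any(keep)) prsct_stop("locus exclusion empties the model",
                               class = "prsct_empty_model")
    v <- x$variants[keep, , drop = FALSE]
    rownames(v) <- NULL
    return(structure(list(threshold = x$threshold, variants = v,
                          n_snp = nrow(v)), class = "prs_model"))
  }
  if (inherits(x, "harmonized_panel")) {
    if (!locus %in% x$dosages$map$key) {
      warning("locus ", locus, " not found in panel; panel unchanged",
              call. = FALSE)
      return(x)
    }
    keep <- !(x$stats$chrom == lchrom & abs(x$stats$pos - lpos) <= flank_bp)
    return(subset_panel(x, keep))
  }
  stop_input("x must be a prs_model or harmonized_panel")
}

#' Sentinels-only PRS model
#'
#' Builds a model containing exactly the supplied (harmonised) sentinel
#' variants — the previously published genome-wide significant risk variants
#' — optionally excluding a designated promoter sentinel.
#'
#' @param sentinels harmonized panel (or `prs_model` variants data.frame)
#'   holding only the sentinel variants
#' @param exclude_locus drop the designated sentinel?
#' @param locus_key variant key of the sentinel to drop (required when
#'   `exclude_locus = TRUE`)
#' @return a `prs_model` with `threshold = 1`
#' @export
sentinels_model <- function(sentinels, exclude_locus = FALSE,
                            locus_key = NULL) {
  if (inherits(sentinels, "harmonized_panel")) {
    if (nrow(sentinels$stats) == 0)
      prsct_stop("no sentinel matches the target genotypes",
                 class = "prsct_empty_model")
    model <- build_model(sentinels, 1)
  } else stop_input("sentinels must be a harmonized panel")
  if (exclude_locus) {
    if (is.null(locus_key)) stop_input("locus_key required to exclude a sentinel")
    keep <- model$variants$key != locus_key
    if (!any(keep)) prsct_stop("exclusion empties the sentinel model",
                               class = "prsct_empty_model")
    model$variants <- model$variants[keep, , drop = FALSE]
    rownames(model$variants) <- NULL
    model$n_snp <- nrow(model$variants)
  }
  model
}

#' Quartile bins of a standardized score
#'
#' Boundaries at the empirical 25/50/75 percentiles of the full analysis
#' sample; Q1 (lowest scores) is the reference group.
#'
#' @param z numeric score vector (n >= 4)
#' @return factor with levels `Q1`-`Q4`
#' @export
quartile_bins <- function(z) {
  if (length(z) < 4) stop_input("quartile binning needs at least 4 samples")
  br <- unique(c(-Inf, stats::quantile(z, c(0.25, 0.5, 0.75), names = FALSE),
                 Inf))
  if (length(br) < 5)
    prsct_stop("ties prevent four non-empty quartile bins",
               class = "prsct_degenerate_bins")
  q <- cut(z, breaks = br, labels = paste0("Q", 1:4), include.lowest = TRUE)
  if (any(table(q) == 0))
    prsct_stop("ties prevent four non-empty quartile bins",
               class = "prsct_degenerate_bins")
  q
}
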