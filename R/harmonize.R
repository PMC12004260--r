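#' Clumping parameters
#'
#' Defaults follow the standard clumping setting for PRS construction:
#' r-squared threshold 0.1 within a 250-kb window.
#'
#' @param r2_threshold squared-correlation threshold in `(0, 1)`; a candidate
#'   is removed when its r-squared with the index variant is `>=` this value
#' @param window_kb window half-width in kilobases (inclusive:
#'   `|pos - pos_index| <= window_kb * 1000`)
#' @return a `clump_params` list
#' @export
clump_params <- function(r2_threshold = 0.1, window_kb = 250) {
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop_input("r2_threshold must lie in (0, 1)")
  if (window_kb <= 0) stop_input("window_kb must be positive")
  structure(list(r2_threshold = r2_threshold, window_kb = window_kb),
            class = "clump_params")
}

new_harmonized_panel <- function(stats, ds, flipped, exclusions) {
  stopifnot(nrow(stats) == ncol(ds$dosages), nrow(stats) == length(flipped))
  structure(list(stats = stats, dosages = ds, flipped = flipped,
                 exclusions = exclusions),
            class = "harmonized_panel")
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat(sprintf("<harmonized_panel> %d variants x %d samples (%d excluded during harmonisation/QC)\n",
              nrow(x$stats), nrow(x$dosages$dosages), nrow(x$exclusions)))
  invisible(x)
}

#' Subset a harmonized panel by variant index
#'
#' @param panel a harmonized panel
#' @param idx integer or logical variant index
#' @return the restricted panel (exclusion log untouched)
#' @export
subset_panel <- function(panel, idx) {
  stopifnot(inherits(panel, "harmonized_panel"))
  st <- panel$stats[idx, , drop = FALSE]
  rownames(st) <- NULL
  new_harmonized_panel(st, subset_variants(panel$dosages, idx),
                       panel$flipped[idx], panel$exclusions)
}

#' Harmonise base summary statistics against target genotypes
#'
#' Matches base variants to target dosage columns on (chromosome, position,
#' unordered allele pair), trying the reported alleles first and their strand
#' complement second. Matches where the base effect allele is the target's
#' counted allele are kept as-is; swapped matches (effect allele = target's
#' other allele) have their effect size negated and the effect/other labels
#' exchanged, which is equivalent to complementing the dosage to `2 - G`.
#' Strand-ambiguous variants (A/T, C/G) are dropped, as are unmatched and
#' duplicated base records; every drop is logged with a reason code.
#'
#' @param base summary-statistics data.frame (see [read_sumstats()])
#' @param target a [dosage_set()]
#' @return a `harmonized_panel`: aligned `stats` and `dosages` (identical
#'   variant order), per-variant `flipped` flags (TRUE where the effect size
#'   sign was changed), and an `exclusions` log (`key`, `reason`)
#' @export
harmonize_alleles <- function(base, target) {
  stopifnot(inherits(target, "dosage_set"))
  excl <- list()
  drop <- function(rows, reason) {
    if (nrow(rows) > 0)
      excl[[length(excl) + 1L]] <<- data.frame(
        key = variant_key(rows$chrom, rows$pos, rows$effect_allele,
                          rows$other_allele),
        reason = reason, stringsAsFactors = FALSE)
  }
  amb <- is_strand_ambiguous(base$effect_allele, base$other_allele)
  drop(base[amb, , drop = FALSE], "strand_ambiguous")
  base <- base[!amb, , drop = FALSE]
  key_as_is <- variant_key(base$chrom, base$pos, base$effect_allele,
                           base$other_allele)
  key_comp <- variant_key(base$chrom, base$pos,
                          complement_allele(base$effect_allele),
                          complement_allele(base$other_allele))
  tkey <- target$map$key
  hit_direct <- match(key_as_is, tkey)
  hit_comp <- match(key_comp, tkey)
  use_comp <- is.na(hit_direct) & !is.na(hit_comp)
  hit <- ifelse(use_comp, hit_comp, hit_direct)
  unmatched <- is.na(hit)
  drop(base[unmatched, , drop = FALSE], "unmatched")
  dupe <- !unmatched & duplicated(hit, incomparables = NA)
  drop(base[dupe, , drop = FALSE], "duplicate")
  keep <- !unmatched & !dupe
  if (!any(keep)) prsct_stop("no base variants overlap the target genotypes",
                             class = "prsct_no_overlap")
  base <- base[keep, , drop = FALSE]
  hit <- hit[keep]
  use_comp <- use_comp[keep]
  eff <- ifelse(use_comp, complement_allele(base$effect_allele),
                base$effect_allele)
  counted <- target$map$counted[hit]
  other <- target$map$other[hit]
  flip <- eff != counted
  stats <- data.frame(
    chrom = target$map$chrom[hit], pos = target$map$pos[hit],
    id = target$map$id[hit],
    effect_allele = counted, other_allele = other,
    beta = ifelse(flip, -base$beta, base$beta),
    pvalue = base$pvalue,
    maf = base$maf %||% NA_real_,
    info = base$info %||% NA_real_, stringsAsFactors = FALSE)
  ds <- subset_variants(target, hit)
  ord <- order(stats$chrom, stats$pos, stats$effect_allele)
  stats <- stats[ord, , drop = FALSE]
  rownames(stats) <- NULL
  exclusions <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(key = character(0), reason = character(0))
  new_harmonized_panel(stats, subset_variants(ds, ord), flip[ord], exclusions)
}

#' Apply variant QC filters
#'
#' Removes variants with minor allele frequency below `maf_min` or imputation
#' quality below `info_min`; both comparisons are strict (`<`), so values at
#' exactly the boundary are retained. Missing `maf` is computed empirically
#' from the dosages; missing `info` passes the filter. Dropped variants are
#' appended to the exclusion log.
#'
#' @param panel a harmonized panel
#' @param maf_min minor-allele-frequency floor (default 1%)
#' @param info_min imputation-quality floor (default 0.3)
#' @return the filtered panel (possibly empty)
#' @export
qc_filter <- function(panel, maf_min = 0.01, info_min = 0.3) {
  stopifnot(inherits(panel, "harmonized_panel"))
  if (nrow(panel$stats) == 0) return(panel)
  maf <- panel$stats$maf
  emp <- allele_freq(panel$dosages, folded = TRUE)
  maf[is.na(maf)] <- emp[is.na(maf)]
  info <- panel$stats$info
  low_maf <- maf < maf_min
  low_info <- !is.na(info) & info < info_min
  dropped <- low_maf | low_info
  out <- subset_panel(panel, !dropped)
  if (any(dropped)) {
    out$exclusions <- rbind(panel$exclusions, data.frame(
      key = panel$dosages$map$key[dropped],
      reason = ifelse(low_maf[dropped], "low_maf", "low_info"),
      stringsAsFactors = FALSE))
  }
  out
}

#' Pairwise dosage r-squared
#'
#' Squared Pearson correlation of two dosage vectors; sample pairs with a
#' missing value in either variant are excluded listwise. When either
#' variant has zero variance (or fewer than two complete pairs remain), the
#' r-squared is defined as 0.
#'
#' @param x,y numeric dosage vectors of equal length
#' @return r-squared in `[0, 1]`
#' @export
pairwise_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

# r2 of one column against a set of columns, listwise-complete, zero-variance -> 0
r2_one_vs_many <- function(X, j, js) {
  vapply(js, function(k) pairwise_r2(X[, j], X[, k]), numeric(1))
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending base p-value (ties broken by position, then
#' by effect allele); each retained index variant removes all not-yet-
#' processed variants on the same chromosome within the window whose
#' r-squared with it is at or above the threshold. LD is computed from the
#' panel's own target dosages. The retained set is returned in genomic
#' order and is independent of input row order.
#'
#' @param panel a harmonized (and typically QC-filtered) panel
#' @param params a [clump_params()]
#' @return integer vector of retained variant indices (genomic order)
#' @export
clump <- function(panel, params = clump_params()) {
  stopifnot(inherits(panel, "harmonized_panel"))
  st <- panel$stats
  m <- nrow(st)
  if (m == 0) return(integer(0))
  if (anyNA(st$pvalue)) stop_input("clumping requires p-values for all variants")
  X <- panel$dosages$dosages
  window <- params$window_kb * 1000
  ord <- order(st$pvalue, st$pos, st$effect_allele)
  removed <- rep(FALSE, m)
  processed <- rep(FALSE, m)
  retained <- logical(m)
  for (i in ord) {
    processed[i] <- TRUE
    if (removed[i]) next
    retained[i] <- TRUE
    cand <- which(!processed & !removed &
                    st$chrom == st$chrom[i] &
                    abs(st$pos - st$pos[i]) <= window)
    if (length(cand) > 0) {
      r2 <- r2_one_vs_many(X, i, cand)
      removed[cand[r2 >= params$r2_threshold]] <- TRUE
    }
  }
  which(retained)[order(st$chrom[retained], st$pos[retained])]
}

#' LD pruning (p-value-agnostic)
#'
#' Walks variants in genomic order, keeping a variant only if its r-squared
#' with every already-kept variant within the window is below the threshold
#' (the first variant of a conflicting pair wins). Used to derive the
#' independent variant subset for principal-component computation.
#'
#' @param x a harmonized panel or a [dosage_set()]
#' @param r2_threshold r-squared threshold (default 0.1)
#' @param window_kb window half-width in kb (default 250)
#' @return integer vector of retained variant indices (genomic order)
#' @export
ld_prune <- function(x, r2_threshold = 0.1, window_kb = 250) {
  ds <- if (inherits(x, "harmonized_panel")) x$dosages else x
  stopifnot(inherits(ds, "dosage_set"))
  map <- ds$map
  X <- ds$dosages
  window <- window_kb * 1000
  ord <- order(map$chrom, map$pos)
  kept <- integer(0)
  for (i in ord) {
    near <- kept[map$chrom[kept] == map$chrom[i] &
                   abs(map$pos[kept] - map$pos[i]) <= window]
    if (length(near) == 0 || all(r2_one_vs_many(X, i, near) < r2_threshold))
      kept <- c(kept, i)
  }
  sort(kept)
}
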