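# Independent brute-force implementations used as oracles. These deliberately
# share no code with the package: plain double loops, explicit bookkeeping.

# Greedy clumping oracle: O(m^2), recomputing r2 from scratch each time.
brute_clump <- function(stats, D, r2_threshold, window_bp) {
  m <- nrow(stats)
  ord <- order(stats$pvalue, stats$pos, stats$effect_allele)
  alive <- rep(TRUE, m)
  done <- rep(FALSE, m)
  kept <- integer(0)
  for (i in ord) {
    done[i] <- TRUE
    if (!alive[i]) next
    kept <- c(kept, i)
    for (j in seq_len(m)) {
      if (done[j] || !alive[j]) next
      if (stats$chrom[j] != stats$chrom[i]) next
      if (abs(stats$pos[j] - stats$pos[i]) > window_bp) next
      x <- D[, i]; y <- D[, j]
      ok <- !is.na(x) & !is.na(y)
      r2 <- if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) 0
      else cor(x[ok], y[ok])^2
      if (r2 >= r2_threshold) alive[j] <- FALSE
    }
  }
  sort(kept)
}

# Sequential LD-pruning oracle: walk in genomic order, keep first of each
# conflicting pair.
brute_prune <- function(map, D, r2_threshold, window_bp) {
  ord <- order(map$chrom, map$pos)
  kept <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in kept) {
      if (map$chrom[j] != map$chrom[i]) next
      if (abs(map$pos[j] - map$pos[i]) > window_bp) next
      x <- D[, i]; y <- D[, j]
      ok <- !is.na(x) & !is.na(y)
      r2 <- if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) 0
      else cor(x[ok], y[ok])^2
      if (r2 >= r2_threshold) { conflict <- TRUE; break }
    }
    if (!conflict) kept <- c(kept, i)
  }
  sort(kept)
}

# Exhaustive threshold-scan oracle: every distinct variant subset induced by
# a p-value cut, scored and fit directly with glm.
brute_scan <- function(stats, D, y, thresholds) {
  rows <- lapply(thresholds, function(t) {
    keep <- which(stats$pvalue <= t)
    if (length(keep) == 0)
      return(data.frame(threshold = t, n_snp = 0L, pvalue = NA_real_))
    raw <- as.numeric(D[, keep, drop = FALSE] %*% stats$beta[keep])
    if (sd(raw) == 0)
      return(data.frame(threshold = t, n_snp = length(keep),
                        pvalue = NA_real_))
    z <- (raw - mean(raw)) / sd(raw)
    fit <- glm(y ~ z, family = binomial())
    co <- summary(fit)$coefficients
    data.frame(threshold = t, n_snp = length(keep),
               pvalue = 2 * pnorm(-abs(co["z", 1] / co["z", 2])))
  })
  do.call(rbind, rows)
}

# Hypergeometric upper-tail probability by explicit combinatorial summation.
brute_hyper <- function(overlap, set_size, list_size, background) {
  ks <- overlap:min(set_size, list_size)
  sum(choose(set_size, ks) * choose(background - set_size, list_size - ks)) /
    choose(background, list_size)
}

# Interval-scan oracle for variant-to-gene assignment.
brute_assign <- function(variants, domains) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    hits <- character(0)
    for (j in seq_len(nrow(domains))) {
      if (variants$chrom[i] == domains$chrom[j] &&
          variants$pos[i] >= domains$ext_start[j] &&
          variants$pos[i] <= domains$ext_end[j])
        hits <- c(hits, domains$gene[j])
    }
    out[[variants$key[i]]] <- hits
  }
  out
}
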