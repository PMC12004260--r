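toy_panel <- function(n = 40, m = 10, seed = 8) {
  set.seed(seed)
  D <- matrix(sample(0:2, n * m, replace = TRUE), nrow = n)
  ds <- make_ds(D)
  panel_for(ds, beta = round(rnorm(m), 2) / 10,
            pvalue = signif(10^runif(m, -9, 0), 3))
}

test_that("model building selects exactly the variants at the threshold", {
  p <- toy_panel()
  full <- build_model(p, 1)
  expect_identical(full$n_snp, 10L)
  expect_error(build_model(p, min(p$stats$pvalue) / 10),
               class = "prsct_empty_model")
  cut <- sort(p$stats$pvalue)[4]
  m4 <- build_model(p, cut)
  expect_identical(m4$n_snp, 4L)
  expect_true(all(m4$variants$pvalue <= cut))
  # threshold monotonicity: n_snp non-decreasing in P_T
  grid <- sort(unique(p$stats$pvalue))
  nsnp <- vapply(grid, function(t) build_model(p, t)$n_snp, integer(1))
  expect_true(all(diff(nsnp) >= 0))
})

test_that("raw scores are the weighted dosage sums, with mean imputation", {
  D <- matrix(c(0, 1, 2, 2, 2, 2), nrow = 3)
  ds <- make_ds(D)
  p <- panel_for(ds, beta = c(1, 0), pvalue = c(0.5, 0.5))
  m1 <- build_model(subset_panel(p, 1), 1)
  expect_identical(unname(compute_prs(ds, m1)), c(0, 1, 2))
  # two variants, weights (0.5, -0.25), dosages (2, 2) -> 0.5
  p2 <- panel_for(ds, beta = c(0.5, -0.25), pvalue = c(0.5, 0.5))
  expect_equal(unname(compute_prs(ds, build_model(p2, 1))[3]), 0.5)
  # all-zero weights give all-zero scores
  p0 <- panel_for(ds, beta = c(0, 0), pvalue = c(0.5, 0.5))
  expect_identical(unname(compute_prs(ds, build_model(p0, 1))), c(0, 0, 0))
  # missing dosage is imputed with the variant's sample mean
  D2 <- D; D2[1, 1] <- NA
  ds2 <- make_ds(D2)
  expect_equal(unname(compute_prs(ds2, m1)[1]), 1.5)
  # absent model variants are a hard error listing the keys
  dsx <- make_ds(D[, 1, drop = FALSE], pos = 999L)
  expect_error(compute_prs(dsx, m1), m1$variants$key[1],
               class = "prsct_missing_variant")
})

test_that("score additivity and sample-permutation invariance hold", {
  p <- toy_panel(seed = 9)
  ds <- p$dosages
  full <- build_model(p, 1)
  raw <- compute_prs(ds, full)
  split1 <- compute_prs(ds, build_model(subset_panel(p, 1:4), 1))
  split2 <- compute_prs(ds, build_model(subset_panel(p, 5:10), 1))
  expect_equal(raw, split1 + split2, tolerance = 1e-12)
  perm <- sample(nrow(ds$dosages))
  expect_equal(unname(compute_prs(subset_samples(ds, perm), full)),
               unname(raw[perm]), tolerance = 1e-12)
})

test_that("standardisation yields exact z-scores and is affine-invariant", {
  z2 <- standardize(c(0, 2))
  expect_equal(z2$z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(10)
  raw <- rnorm(50)
  sv <- standardize(raw)
  expect_lt(abs(mean(sv$z)), 1e-12)
  expect_lt(abs(sd(sv$z) - 1), 1e-12)
  sv2 <- standardize(3.7 * raw - 11)
  expect_equal(sv$z, sv2$z, tolerance = 1e-9)
  expect_error(standardize(rep(1, 5)), class = "prsct_degenerate_score")
  expect_error(standardize(1), class = "prsct_input_error")
})

test_that("threshold scan matches exhaustive enumeration on a toy panel", {
  set.seed(11)
  n <- 500
  D <- matrix(rbinom(n * 5, 2, 0.4), nrow = n)
  ds <- make_ds(D)
  p <- panel_for(ds, beta = c(0.4, 0.3, -0.2, 0.1, 0.05),
                 pvalue = c(1e-6, 1e-4, 1e-3, 0.05, 0.5))
  raw_true <- as.numeric(D %*% c(0.4, 0.3, -0.2, 0.1, 0.05))
  y <- planted_outcome(scale(raw_true)[, 1], log_or = 0.4, seed = 12)
  grid <- c(1e-7, 1e-6, 1e-4, 1e-3, 0.05, 0.5, 1)
  sc <- threshold_scan(p, ds, y, covariates = NULL, grid = grid)
  oracle <- brute_scan(p$stats, D, y, grid)
  expect_identical(sc$scan$n_snp, oracle$n_snp)
  ok <- !is.na(oracle$pvalue)
  expect_equal(sc$scan$pvalue[ok], oracle$pvalue[ok], tolerance = 1e-6)
  best_oracle <- oracle[ok, ][which.min(oracle$pvalue[ok]), ]
  expect_identical(sc$best_model$n_snp, best_oracle$n_snp)
  # returned best p is no larger than any scanned p
  expect_true(all(sc$best$pvalue <= sc$scan$pvalue[ok]))
  # a one-threshold grid returns that model
  one <- threshold_scan(p, ds, y, grid = 0.05)
  expect_identical(one$best_model$n_snp, 4L)
  expect_error(threshold_scan(p, ds, y, grid = 1e-9),
               class = "prsct_empty_model")
})

test_that("best-fit association strengthens with target sample size", {
  scen <- overlap_scenario(rho_overlap = 0.9, h2_base = 0.4)
  pv <- vapply(c(700, 2800), function(n) {
    ps <- vapply(1:5, function(s) {
      st <- sim_stage(100 * s, n = n, n_pop = round(n / 4), scenario = scen,
                      blocks = sim_blocks(n_blocks = 6, vpb = 8))
      z <- standardize(compute_prs(st$geno, build_model(st$clumped, 1)))$z
      fit_logistic(st$cohort$hospitalised, z)$pvalue
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_lt(pv[2], pv[1])
})

test_that("locus exclusion removes the inclusive 1-Mb flank on one chromosome", {
  pos <- c(1000000L, 1999999L, 2000000L, 2999999L, 3000001L, 500000L)
  chrom <- c("1", "1", "1", "1", "1", "2")
  D <- matrix(rbinom(20 * 6, 2, 0.5), nrow = 20)
  ds <- make_ds(D, chrom = chrom, pos = pos)
  p <- panel_for(ds, beta = rep(0.1, 6), pvalue = rep(0.01, 6))
  model <- build_model(p, 1)
  locus <- model$variants$key[model$variants$pos == 2000000L]
  red <- subset_exclude_locus(model, locus, flank_bp = 1e6)
  # kept: 999999 away (removed), 1000000 away (removed, inclusive),
  # 1000001 away (kept), other chromosome untouched
  expect_setequal(red$variants$pos, c(3000001L, 500000L))
  expect_true("2" %in% red$variants$chrom)
  expect_warning(unchanged <- subset_exclude_locus(model, "9:1:A:G"),
                 "not found")
  expect_identical(unchanged$n_snp, model$n_snp)
})

test_that("sentinel-only models count sentinels and match a whole-genome subset", {
  set.seed(13)
  D <- matrix(sample(0:2, 30 * 19, replace = TRUE), nrow = 30)
  ds <- make_ds(D, pos = seq(1e6, 19e6, by = 1e6))
  p <- panel_for(ds, beta = rnorm(19) / 5, pvalue = rep(1e-9, 19))
  m19 <- sentinels_model(p)
  expect_identical(m19$n_snp, 19L)
  promoter <- m19$variants$key[1]
  m18 <- sentinels_model(p, exclude_locus = TRUE, locus_key = promoter)
  expect_identical(m18$n_snp, 18L)
  expect_false(promoter %in% m18$variants$key)
  expect_error(sentinels_model(subset_panel(p, integer(0))),
               class = "prsct_empty_model")
  # sentinels PRS equals the whole-genome PRS when the panel is the sentinel set
  expect_equal(compute_prs(ds, m19), compute_prs(ds, build_model(p, 1)),
               tolerance = 1e-12)
})

test_that("quartile bins split at empirical quartiles with Q1 lowest", {
  q <- quartile_bins(1:8)
  expect_identical(as.character(q),
                   c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  set.seed(14)
  z <- rnorm(101)
  q2 <- quartile_bins(z)
  expect_true(all(diff(tapply(z, q2, max)) > 0))
  expect_true(max(table(q2)) - min(table(q2)) <= 1)
  expect_true(all(tapply(z, q2, max)[1:3] <= tapply(z, q2, min)[2:4]))
  expect_error(quartile_bins(c(1, 2, 3)), class = "prsct_input_error")
  expect_error(quartile_bins(rep(1, 10)), class = "prsct_degenerate_bins")
})
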