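test_that("principal components are orthogonal, reproducible, and recover structure", {
  g <- simulate_ld_genotypes(sim_blocks(n_blocks = 5, vpb = 10), 150, seed = 15)
  pcs <- compute_pcs(g, k = 6)
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  # duplicated sample rows get identical coordinates
  ds2 <- subset_samples(g, c(1, 1, 2:150))
  pcs2 <- compute_pcs(ds2, k = 4)
  expect_equal(unname(pcs2[1, ]), unname(pcs2[2, ]), tolerance = 1e-9)
  expect_error(compute_pcs(subset_variants(g, 1:3), k = 10),
               class = "prsct_input_error")
  # two subpopulations with divergent frequencies separate on PC1
  sil <- vapply(1:10, function(s) {
    set.seed(s)
    n1 <- 60; n2 <- 60; m <- 40
    f1 <- runif(m, 0.1, 0.5); f2 <- pmin(f1 + 0.3, 0.95)
    X <- rbind(sapply(f1, function(f) rbinom(n1, 2, f)),
               sapply(f2, function(f) rbinom(n2, 2, f)))
    pc1 <- compute_pcs(make_ds(X), k = 2)[, 1]
    grp <- rep(1:2, c(n1, n2))
    s_i <- vapply(seq_along(pc1), function(i) {
      own <- grp == grp[i] & seq_along(pc1) != i
      a <- mean(abs(pc1[i] - pc1[own]))
      b <- mean(abs(pc1[i] - pc1[grp != grp[i]]))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s_i)
  }, numeric(1))
  expect_true(all(sil > 0))
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  x <- c(rep(1, 40), rep(0, 40))
  f <- fit_logistic(y, x)
  expect_equal(f$or, 9, tolerance = 1e-6)
  expect_equal(f$beta, log(9), tolerance = 1e-6)
  expect_identical(f$n_case, 40L)
  # permuted labels give a null odds ratio on average
  set.seed(16)
  ors <- vapply(1:20, function(s) {
    z <- rnorm(1500)
    fit_logistic(sample(rep(0:1, c(1000, 500))), z)$or
  }, numeric(1))
  expect_lt(abs(mean(ors) - 1), 0.05)
  # perfect separation is flagged, never silently estimated
  sep <- fit_logistic(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 10, 11, 12))
  expect_identical(sep$status, "separation")
  expect_true(is.na(sep$or))
  expect_error(fit_logistic(rep(1, 10), rnorm(10)),
               class = "prsct_input_error")
})

test_that("liability-scale conversion matches an independent evaluation", {
  expect_identical(liability_r2(0, 0.005, 0.5), 0)
  # independent computation of the ascertainment constant
  K <- 0.005; P <- 0.5
  zK <- qnorm(0.995)
  phi <- exp(-zK^2 / 2) / sqrt(2 * pi)
  C <- (K * (1 - K))^2 / (phi^2 * P * (1 - P))
  expect_equal(liability_r2(0.01, K, P), 0.01 * C, tolerance = 1e-12)
  # linear in the observed-scale input
  expect_equal(liability_r2(0.03, K, P), 3 * liability_r2(0.01, K, P),
               tolerance = 1e-12)
  expect_error(liability_r2(0.1, 0, 0.5), class = "prsct_input_error")
  expect_error(liability_r2(0.1, 0.005, 1), class = "prsct_input_error")
})

test_that("Bonferroni thresholds reproduce the printed constants", {
  expect_identical(bonferroni(0.05, 27), 0.05 / 27)
  # printed 2-significant-figure constants are matched to within one unit in
  # the last printed digit (0.05/27 = 1.85e-3 sits between 1.8 and 1.9e-3)
  expect_lt(abs(bonferroni(0.05, 27) - 1.8e-3), 1e-4)
  expect_lt(abs(bonferroni(0.05, 9) - 5.6e-3), 1e-4)
  expect_identical(bonferroni(0.05, 4), 0.0125)
  expect_error(bonferroni(0.05, 0), class = "prsct_input_error")
})

test_that("the stratification grid encodes the covariate scheme", {
  g <- strata_grid()
  expect_identical(nrow(g), 9L)
  expect_identical(g$covariates[g$label == "all"],
                   paste(c("age", "sex", paste0("PC", 1:10)), collapse = ","))
  expect_identical(g$covariates[g$label == "males"],
                   paste(c("age", paste0("PC", 1:10)), collapse = ","))
  expect_identical(g$covariates[g$label == "<60 years"],
                   paste(c("sex", paste0("PC", 1:10)), collapse = ","))
  expect_identical(g$covariates[g$label == "<60 years, males"],
                   paste(paste0("PC", 1:10), collapse = ","))
  # stratified-on variables never appear as covariates
  for (i in seq_len(nrow(g))) {
    covs <- strsplit(g$covariates[i], ",")[[1]]
    if (g$sex_filter[i] != "all") expect_false("sex" %in% covs)
    if (g$age_filter[i] != "all") expect_false("age" %in% covs)
  }
})

test_that("the stratified grid partitions counts and flags empty strata", {
  st <- sim_stage(17, n = 1500, n_pop = 400,
                  blocks = sim_blocks(n_blocks = 8, vpb = 8))
  pcs <- compute_pcs(st$geno, ld_prune(st$geno), k = 5)
  cohort <- cbind(st$cohort, as.data.frame(pcs))
  res <- run_stratified(cohort, st$clumped, st$geno,
                        grid = c(0.01, 0.1, 1), n_pcs = 5)
  expect_identical(nrow(res), 27L)
  expect_true(all(table(res$outcome) == 9L))
  for (oc in unique(res$outcome)) {
    sub <- res[res$outcome == oc, ]
    all_row <- sub[sub$label == "all", ]
    expect_identical(sum(sub$cases[sub$label %in% c("males", "females")]),
                     all_row$cases)
    expect_identical(sum(sub$controls[sub$label %in% c("males", "females")]),
                     all_row$controls)
    expect_identical(
      sum(sub$cases[sub$label %in% c(">=60 years", "<60 years")]),
      all_row$cases)
  }
  expect_true(all(res$status == "ok"))
  expect_true(all(res$ci_lo[res$status == "ok"] <= res$or[res$status == "ok"]))
  expect_true(all(res$ci_hi[res$status == "ok"] >= res$or[res$status == "ok"]))
  expect_equal(attr(res, "bonferroni"), 0.05 / 27)
  # liability R2 present where the fit succeeded
  expect_true(any(is.finite(res$r2_liability)))
  # an all-male cohort leaves female strata empty but still emits rows
  males <- cohort$sex == "male"
  res_m <- run_stratified(cohort[males, ], st$clumped,
                          subset_samples(st$geno, males),
                          outcomes = "hospitalised",
                          grid = c(0.1, 1), n_pcs = 5)
  expect_identical(nrow(res_m), 9L)
  expect_true(all(res_m$status[grepl("female", res_m$label)] ==
                    "empty_stratum"))
})

test_that("quartile odds ratios follow the continuous effect", {
  set.seed(18)
  z <- rnorm(5000)
  y_null <- planted_outcome(z, log_or = 0, seed = 19)
  qs <- quartile_bins(z)
  null_or <- quartile_or(qs, y_null)
  expect_true(all(abs(log(null_or$or)) < 0.35))
  y_pos <- planted_outcome(z, log_or = 0.5, seed = 20)
  pos_or <- quartile_or(qs, y_pos)
  expect_true(all(pos_or$or > 1))
  cont <- fit_logistic(y_pos, z)
  expect_identical(sign(log(pos_or$or[3])), sign(cont$beta))
  expect_error(quartile_or(factor(rep("Q1", 10), levels = paste0("Q", 1:4)),
                           rep(0:1, 5)), class = "prsct_input_error")
})

test_that("sensitivity masks modify exactly the intended samples", {
  st <- sim_stage(21, n = 1200, n_pop = 300,
                  blocks = sim_blocks(n_blocks = 6, vpb = 8))
  pcs <- compute_pcs(st$geno, ld_prune(st$geno), k = 4)
  cohort <- cbind(st$cohort, as.data.frame(pcs))
  sens <- sensitivity_suite(cohort, st$clumped, st$geno,
                            grid = c(0.1, 1), n_pcs = 4)
  expect_named(sens, c("no_chronic", "at_risk_controls", "mortality"))
  # chronic-disease exclusion removes the flagged samples from all strata
  nc <- sens$no_chronic
  full_n <- sum(!cohort$chronic_resp_disease &
                  cohort$hospitalised %in% c("case", "control"))
  all_row <- nc[nc$label == "all" & nc$outcome == "hospitalised", ]
  expect_identical(all_row$cases + all_row$controls, full_n)
  # at-risk-control analysis: population controls contribute to no row
  ar <- sens$at_risk_controls
  ar_all <- ar[ar$label == "all" & ar$outcome == "hospitalised", ]
  expect_identical(ar_all$cases + ar_all$controls,
                   sum(!cohort$population_control))
  # mortality grid: 9 rows, flagged at the 9-test Bonferroni level
  expect_identical(nrow(sens$mortality), 9L)
  expect_equal(attr(sens$mortality, "bonferroni"), 0.05 / 9)
})
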