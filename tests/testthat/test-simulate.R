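test_that("genotype simulation is deterministic, bounded, and respects the map", {
  blocks <- sim_blocks(n_blocks = 4, vpb = 8, rho = 0.5, span = 50000L,
                       n_chrom = 2)
  g1 <- simulate_ld_genotypes(blocks, 300, seed = 11)
  g2 <- simulate_ld_genotypes(blocks, 300, seed = 11)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$map, g2$map)
  g3 <- simulate_ld_genotypes(blocks, 300, seed = 12)
  expect_false(identical(g1$dosages, g3$dosages))
  expect_true(all(g1$dosages %in% 0:2))
  # positions 1-based, ordered, inside the laid-out spans per chromosome
  for (ch in unique(g1$map$chrom)) {
    p <- g1$map$pos[g1$map$chrom == ch]
    expect_true(all(diff(p) > 0))
    expect_gte(min(p), 1)
    expect_lte(max(p), 2 * 50000L)
  }
  # same map, new individuals when only the cohort seed changes
  g4 <- simulate_ld_genotypes(blocks, 300, seed = 13, map_seed = 11)
  expect_identical(g1$map, g4$map)
  expect_false(identical(g1$dosages, g4$dosages))
  expect_error(simulate_ld_genotypes(blocks, 1, seed = 1),
               class = "prsct_input_error")
})

test_that("empirical frequencies track the generating frequencies", {
  g <- simulate_ld_genotypes(list(ld_block(20, maf_range = c(0.1, 0.4))),
                             4000, seed = 21)
  f <- allele_freq(g)
  # binomial sampling error on 8000 haplotypes is ~0.005-0.006
  expect_true(all(abs(f - g$map$maf_true) < 0.03))
})

test_that("LD structure: independence at rho = 0, decay with distance at rho = 0.9", {
  g0 <- simulate_ld_genotypes(list(ld_block(8, maf_range = c(0.5, 0.5),
                                            rho = 0)), 10000, seed = 31)
  cors <- cor(g0$dosages)
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.05)

  hits <- vapply(1:20, function(s) {
    g <- simulate_ld_genotypes(list(ld_block(12, rho = 0.9)), 10000, seed = s)
    adj <- mean(vapply(1:11, function(j)
      cor(g$dosages[, j], g$dosages[, j + 1])^2, numeric(1)))
    far <- mean(vapply(1:2, function(j)
      cor(g$dosages[, j], g$dosages[, j + 10])^2, numeric(1)))
    adj > far
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null base GWAS has zero effects and uniform p-values", {
  scen <- overlap_scenario(causal_fraction = 0, h2_base = 0)
  g <- simulate_ld_genotypes(sim_blocks(n_blocks = 4, vpb = 15), 500, seed = 41)
  pvals <- unlist(lapply(1:10, function(s) {
    gw <- simulate_base_gwas(g, scen, n_base = 10000, seed = s)
    expect_true(all(gw$truth$beta_true == 0))
    gw$stats$pvalue
  }))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("estimation noise vanishes as the base sample grows", {
  scen <- overlap_scenario(causal_fraction = 0.3)
  g <- simulate_ld_genotypes(sim_blocks(n_blocks = 3, vpb = 10), 400, seed = 51)
  gw <- simulate_base_gwas(g, scen, n_base = 1e9, seed = 52, swap_fraction = 0)
  expect_lt(max(abs(gw$stats$beta - gw$truth$beta_true)), 1e-3)
})

test_that("a flipped sentinel is planted at genome-wide significance", {
  scen <- overlap_scenario(sentinel_flip = TRUE)
  g <- simulate_ld_genotypes(sim_blocks(), 500, seed = 61)
  gw <- simulate_base_gwas(g, scen, n_base = 20000, seed = 62)
  expect_identical(sum(gw$truth$is_sentinel), 1L)
  s <- which(gw$truth$is_sentinel)
  expect_lt(gw$stats$pvalue[s], 5e-8)
  expect_gte(abs(gw$truth$beta_true[s]), 5 * gw$truth$se[s])
  # reported orientation may be swapped; truth is on the counted-allele scale
  key_s <- gw$truth$key[s]
  expect_identical(variant_key(gw$stats$chrom[s], gw$stats$pos[s],
                               gw$stats$effect_allele[s],
                               gw$stats$other_allele[s]), key_s)
})

test_that("severity flags nest and match the scenario composition", {
  scen <- overlap_scenario()
  st <- sim_stage(71, n = 4000, n_pop = 800, clump_it = FALSE)
  co <- st$cohort
  covid <- !co$population_control
  expect_true(all(is.na(co$severity[!covid])))
  expect_true(all(co$severity[covid] %in% 0:4))
  # nesting: critical => severe => hospitalised, scale 4 in every case set
  crit <- co$critical == "case"
  expect_true(all(co$severity[crit] == 4))
  expect_true(all(co$severe[crit] == "case"))
  expect_true(all(co$hospitalised[crit] == "case"))
  expect_true(all(co$hospitalised[co$severe == "case"] == "case"))
  # population controls are controls everywhere, excluded for mortality
  expect_true(all(co$hospitalised[!covid] == "control"))
  expect_true(all(co$mortality[!covid] == "excluded"))
  # critical fraction among hospitalised ~ K_crit / K_hosp +/- 2 binomial SE
  n_h <- sum(co$hospitalised == "case")
  ratio <- scen$target_prevalence[["critical"]] /
    scen$target_prevalence[["hospitalised"]]
  se2 <- 2 * sqrt(ratio * (1 - ratio) / n_h)
  expect_lt(abs(sum(crit) / n_h - ratio), se2 + 0.02)
  # infeasible prevalence errors out: fewer than one expected critical case
  tiny <- subset_samples(st$geno, 1:30)
  rare <- overlap_scenario(target_prevalence = c(hospitalised = 0.5,
                                                 severe = 0.295,
                                                 critical = 0.02))
  expect_error(
    simulate_target_cohort(tiny, st$gwas$truth, rare,
                           n_population_controls = 0, seed = 1),
    class = "prsct_input_error")
})

test_that("with no shared genetics the PRS association is null on average", {
  scen0 <- overlap_scenario(rho_overlap = 0)
  ors <- vapply(1:20, function(s) {
    st <- sim_stage(400 + s, n = 5000, n_pop = 1000, scenario = scen0,
                    blocks = sim_blocks(n_blocks = 8, vpb = 10),
                    clump_it = FALSE)
    model <- build_model(st$panel, 1)
    z <- standardize(compute_prs(st$geno, model))$z
    covs <- data.frame(age = st$cohort$age,
                       sex = as.integer(st$cohort$sex == "male"))
    fit_logistic(st$cohort$hospitalised, z, covs)$or
  }, numeric(1))
  expect_gt(mean(ors), 0.95)
  expect_lt(mean(ors), 1.05)
})

test_that("annotation simulation is deterministic and round-trips", {
  g <- simulate_ld_genotypes(sim_blocks(n_blocks = 6, vpb = 10), 200, seed = 81)
  a1 <- simulate_annotation(g, n_genes = 30, n_pathways = 8, seed = 91)
  a2 <- simulate_annotation(g, n_genes = 30, n_pathways = 8, seed = 91)
  expect_identical(a1, a2)
  bed <- tempfile(fileext = ".bed")
  gmt <- tempfile(fileext = ".gmt")
  write_gene_bed(a1$genes, bed)
  write_gene_sets(a1$pathways, gmt)
  b1 <- readLines(bed)
  write_gene_bed(simulate_annotation(g, 30, 8, seed = 91)$genes, bed)
  expect_identical(readLines(bed), b1)
  expect_identical(read_gene_sets(gmt), a1$pathways)
  back <- read_gene_annotation(bed)
  expect_identical(back$tss, a1$genes$tss)
  expect_identical(back$gene, a1$genes$gene)
})
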