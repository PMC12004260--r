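# Shared fixture builders. Everything is generated in code at test time.

# A dosage_set from a plain matrix plus minimal coordinates.
make_ds <- function(D, chrom = "1", pos = NULL, counted = NULL, other = NULL) {
  m <- ncol(D)
  pos <- pos %||% (seq_len(m) * 10000L)
  dosage_set(D, data.frame(
    chrom = rep_len(chrom, m), pos = pos,
    id = paste0("v", seq_len(m)),
    counted = counted %||% rep("A", m),
    other = other %||% rep("G", m),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Aligned summary statistics for a dosage_set (effect allele = counted).
stats_for <- function(ds, beta, pvalue, maf = NA_real_, info = NA_real_) {
  data.frame(chrom = ds$map$chrom, pos = ds$map$pos, id = ds$map$id,
             effect_allele = ds$map$counted, other_allele = ds$map$other,
             beta = beta, pvalue = pvalue, maf = maf, info = info,
             stringsAsFactors = FALSE)
}

panel_for <- function(ds, beta, pvalue, maf = NA_real_, info = NA_real_) {
  harmonize_alleles(stats_for(ds, beta, pvalue, maf, info), ds)
}

# Standard multi-chromosome block layout for simulation-driven tests.
sim_blocks <- function(n_blocks = 12, vpb = 10, rho = 0.7,
                       span = 200000L, n_chrom = 4) {
  chroms <- as.character(rep(seq_len(n_chrom), length.out = n_blocks))
  lapply(seq_len(n_blocks), function(b)
    ld_block(vpb, rho = rho, span_bp = span, chrom = chroms[b]))
}

# Full simulated stage: genotypes, base GWAS, cohort, QC'd clumped panel.
sim_stage <- function(seed, n = 1200, n_pop = 300, scenario = overlap_scenario(),
                      blocks = sim_blocks(), n_base = 20000, clump_it = TRUE) {
  geno <- simulate_ld_genotypes(blocks, n, seed = seed)
  gwas <- simulate_base_gwas(geno, scenario, n_base = n_base,
                             seed = seed + 1000L)
  cohort <- simulate_target_cohort(geno, gwas$truth, scenario,
                                   n_population_controls = n_pop,
                                   seed = seed + 2000L)
  panel <- qc_filter(harmonize_alleles(gwas$stats, geno))
  clumped <- if (clump_it) subset_panel(panel, clump(panel)) else panel
  list(geno = geno, gwas = gwas, cohort = cohort, panel = panel,
       clumped = clumped)
}

# Outcome generated from the package-computed standardized PRS through a
# logistic model with known per-SD log-odds effect.
planted_outcome <- function(z, log_or, base_rate = 0.3, seed = 1) {
  withr::with_seed(seed, {
    p <- plogis(qlogis(base_rate) + log_or * z)
    as.integer(runif(length(z)) < p)
  })
}
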