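#' Pipeline run configuration
#'
#' Collects every tunable of the discovery/replication workflow. Inputs come
#' either from files (`paths`) or from the built-in simulator (`simulate`);
#' exactly one of the two must be supplied.
#'
#' @param seed master RNG seed for the run
#' @param paths named list of input files: `sumstats`, `dosages`,
#'   `phenotypes`, `annotation` (BED), `gene_sets` (GMT), optionally
#'   `sentinels` (TSV of summary-stat rows for the sentinel variants)
#' @param simulate named list for the simulator: `n_blocks`,
#'   `variants_per_block`, `block_span_bp`, `block_rho`, `n_chromosomes`,
#'   `n_samples`, `n_population_controls`, `n_base`, `n_genes`,
#'   `n_pathways`, and `scenario` (arguments of [overlap_scenario()])
#' @param clump list with `r2_threshold`, `window_kb`
#' @param grid p-value threshold grid
#' @param prevalences population prevalences per outcome for the
#'   liability-scale conversion (defaults: hospitalisation 0.5%, severe
#'   0.295%, critical 0.095%)
#' @param alpha family-wise error rate
#' @param n_pcs number of principal components used as covariates
#' @param age_cut age stratification split in years
#' @param out_dir optional output directory for result TSVs and the manifest
#' @return a `run_config` list
#' @export
run_config <- function(seed = 1, paths = NULL, simulate = NULL,
                       clump = list(r2_threshold = 0.1, window_kb = 250),
                       grid = default_threshold_grid(),
                       prevalences = c(hospitalised = 0.005,
                                       severe = 0.00295,
                                       critical = 0.00095),
                       alpha = 0.05, n_pcs = 10, age_cut = 60,
                       out_dir = NULL) {
  if (is.null(paths) == is.null(simulate))
    stop_input("exactly one of `paths` or `simulate` must be given")
  if (any(prevalences <= 0) || any(prevalences >= 1))
    stop_input("prevalences must lie in (0, 1)")
  if (!is.null(paths)) {
    need <- c("sumstats", "dosages", "phenotypes")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0)
      stop_input(paste0("paths lacks: ", paste(miss, collapse = ", ")))
  }
  structure(list(seed = as.integer(seed), paths = paths, simulate = simulate,
                 clump = clump, grid = grid, prevalences = prevalences,
                 alpha = alpha, n_pcs = n_pcs, age_cut = age_cut,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input(paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$prevalences)) y$prevalences <- unlist(y$prevalences)
  if (!is.null(y$grid)) y$grid <- as.numeric(unlist(y$grid))
  do.call(run_config, y)
}

simulate_inputs <- function(config) {
  sim <- config$simulate
  nb <- sim$n_blocks %||% 12
  vpb <- sim$variants_per_block %||% 10
  span <- sim$block_span_bp %||% 200000
  rho <- sim$block_rho %||% 0.7
  nchr <- sim$n_chromosomes %||% 4
  chroms <- as.character(rep(seq_len(nchr), length.out = nb))
  blocks <- lapply(seq_len(nb), function(b)
    ld_block(vpb, rho = rho, span_bp = span, chrom = chroms[b]))
  scen <- do.call(overlap_scenario, sim$scenario %||% list())
  seed <- config$seed
  # structural seeds (variant map, base truth, target effects, annotation)
  # default to the master seed but can be pinned in the simulate block so a
  # replication run with a different master seed shares the discovery genome
  map_seed <- sim$map_seed %||% derive_seed(seed, 1)
  gwas_seed <- sim$gwas_seed %||% derive_seed(seed, 2)
  geno <- simulate_ld_genotypes(blocks, sim$n_samples %||% 3000,
                                seed = derive_seed(seed, 1),
                                map_seed = map_seed)
  gwas <- simulate_base_gwas(geno, scen, n_base = sim$n_base %||% 20000,
                             seed = gwas_seed)
  cohort <- simulate_target_cohort(geno, gwas$truth, scen,
                                   n_population_controls =
                                     sim$n_population_controls %||% 800,
                                   seed = derive_seed(seed, 3),
                                   effect_seed = derive_seed(gwas_seed, 11))
  anno <- simulate_annotation(geno, n_genes = sim$n_genes %||% 60,
                              n_pathways = sim$n_pathways %||% 12,
                              seed = sim$annotation_seed %||%
                                derive_seed(gwas_seed, 4),
                              causal_keys =
                                gwas$truth$key[gwas$truth$is_causal |
                                                 gwas$truth$is_sentinel])
  sentinel_key <- if (any(gwas$truth$is_sentinel))
    gwas$truth$key[gwas$truth$is_sentinel][1] else NULL
  list(sumstats = gwas$stats, geno = geno, cohort = cohort,
       genes = anno$genes, gene_sets = anno$pathways,
       truth = gwas$truth, scenario = scen, sentinel_key = sentinel_key)
}

load_inputs <- function(config) {
  p <- config$paths
  geno <- read_dosages(p$dosages)
  cohort <- read_phenotypes(p$phenotypes)
  ord <- match(rownames(geno$dosages), cohort$sample_id)
  if (anyNA(ord)) stop_input("phenotype table does not cover all samples")
  cohort <- cohort[ord, , drop = FALSE]
  genes <- if (!is.null(p$annotation)) read_gene_annotation(p$annotation) else NULL
  sets <- if (!is.null(p$gene_sets)) read_gene_sets(p$gene_sets) else NULL
  sentinels <- if (!is.null(p$sentinels)) read_sumstats(p$sentinels) else NULL
  list(sumstats = read_sumstats(p$sumstats), geno = geno, cohort = cohort,
       genes = genes, gene_sets = sets, sentinels = sentinels,
       truth = NULL, scenario = NULL, sentinel_key = NULL)
}

#' Run the discovery workflow
#'
#' End to end: acquire inputs (files or simulation), harmonise base summary
#' statistics against target dosages, apply QC filters, clump, compute
#' principal components on an LD-pruned variant subset, run the 27-row
#' stratified association grid with per-stratum threshold scans, derive the
#' quartile odds ratios for the full-sample hospitalisation model, run the
#' sensitivity suite (chronic-respiratory-disease exclusion, at-risk
#' controls, 90-day mortality at the 9-test Bonferroni level), the sentinel
#' locus-exclusion comparison when a sentinel locus is known, and the
#' pathway stage (regulatory-domain assignment, hypergeometric enrichment,
#' top-5 pathway-restricted PRS). Deterministic given the config seed.
#'
#' @param config a [run_config()]
#' @return a result bundle (list): `panel`, `clumped_idx`, `grid_results`
#'   (27 rows), `quartiles`, `sensitivity`, `locus_exclusion`, `pathway`
#'   (`enrichment` + `prs_tests`), `models`, `cohort`, `manifest`; result
#'   TSVs and a YAML manifest are written when `out_dir` is set
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- if (!is.null(config$simulate)) simulate_inputs(config)
  else load_inputs(config)
  cohort <- inputs$cohort
  panel <- harmonize_alleles(inputs$sumstats, inputs$geno)
  panel <- qc_filter(panel)
  cp <- clump_params(config$clump$r2_threshold %||% 0.1,
                     config$clump$window_kb %||% 250)
  keep <- clump(panel, cp)
  clumped <- subset_panel(panel, keep)
  prune_idx <- ld_prune(inputs$geno, r2_threshold = cp$r2_threshold,
                        window_kb = cp$window_kb)
  pcs <- compute_pcs(inputs$geno, prune_idx, k = config$n_pcs)
  cohort <- cbind(cohort, as.data.frame(pcs))
  grid_results <- run_stratified(cohort, clumped, inputs$geno,
                                 grid = config$grid,
                                 prevalences = config$prevalences,
                                 alpha = config$alpha,
                                 age_cut = config$age_cut,
                                 n_pcs = config$n_pcs)
  models <- attr(grid_results, "models")
  hosp_all <- models[["hospitalised | all"]]
  quartiles <- NULL
  if (!is.null(hosp_all)) {
    y <- as_binary_outcome(cohort$hospitalised)
    analysis <- which(!is.na(y))
    raw <- compute_prs(inputs$geno, hosp_all)
    sv <- standardize(raw[analysis])
    bins <- rep(NA_character_, nrow(cohort))
    bins[analysis] <- as.character(quartile_bins(sv$z))
    bins <- factor(bins, levels = paste0("Q", 1:4))
    covs <- cohort[, c("age", "sex", paste0("PC", seq_len(config$n_pcs)))]
    covs$sex <- as.integer(covs$sex == "male")
    quartiles <- quartile_or(bins[analysis], y[analysis],
                             covariates = covs[analysis, , drop = FALSE])
  }
  sens <- sensitivity_suite(cohort, clumped, inputs$geno, grid = config$grid,
                            prevalences = config$prevalences,
                            alpha = config$alpha, age_cut = config$age_cut,
                            n_pcs = config$n_pcs)
  locus_excl <- NULL
  if (!is.null(inputs$sentinel_key) && !is.null(hosp_all)) {
    locus_excl <- locus_exclusion_comparison(
      hosp_all, inputs$sentinel_key, inputs$geno, cohort, config$n_pcs)
  }
  pathway_res <- NULL
  if (!is.null(inputs$genes) && !is.null(inputs$gene_sets) &&
      !is.null(hosp_all)) {
    doms <- regulatory_domains(inputs$genes)
    asg <- assign_variants_to_genes(hosp_all$variants, doms)
    enr <- enrich(asg$genes, inputs$gene_sets, background = inputs$genes$gene)
    top5 <- top_pathways(enr, inputs$gene_sets, k = 5)
    y <- as_binary_outcome(cohort$hospitalised)
    analysis <- which(!is.na(y))
    covs <- cohort[, c("age", "sex", paste0("PC", seq_len(config$n_pcs)))]
    covs$sex <- as.integer(covs$sex == "male")
    tests <- pathway_prs_test(hosp_all, inputs$geno, y, covariates = covs,
                              gene_sets = top5, variant_map = asg$map,
                              fit_idx = analysis)
    pathway_res <- list(enrichment = enr, prs_tests = tests,
                        assignment = asg)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("prsct")),
    seed = config$seed,
    clump = list(r2_threshold = cp$r2_threshold, window_kb = cp$window_kb),
    grid = config$grid,
    prevalences = as.list(config$prevalences),
    alpha = config$alpha, n_pcs = config$n_pcs, age_cut = config$age_cut,
    n_variants_harmonized = nrow(panel$stats),
    n_variants_clumped = length(keep),
    n_samples = nrow(cohort),
    bonferroni_discovery = attr(grid_results, "bonferroni"))
  bundle <- list(panel = panel, clumped = clumped, clumped_idx = keep,
                 grid_results = grid_results, quartiles = quartiles,
                 sensitivity = sens, locus_exclusion = locus_excl,
                 pathway = pathway_res, models = models, cohort = cohort,
                 geno = inputs$geno, truth = inputs$truth,
                 scenario = inputs$scenario,
                 sentinel_key = inputs$sentinel_key, manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# whole-genome model vs the same model with the sentinel locus +/- 1 Mb removed
locus_exclusion_comparison <- function(model, sentinel_key, ds, cohort,
                                       n_pcs) {
  y <- as_binary_outcome(cohort$hospitalised)
  analysis <- which(!is.na(y))
  covs <- cohort[, c("age", "sex", paste0("PC", seq_len(n_pcs)))]
  covs$sex <- as.integer(covs$sex == "male")
  fit_one <- function(mod) {
    raw <- compute_prs(ds, mod)
    sv <- standardize(raw[analysis])
    z <- (raw - sv$mean) / sv$sd
    fit_logistic(y[analysis], z[analysis],
                 covariates = covs[analysis, , drop = FALSE])
  }
  full <- fit_one(model)
  reduced_model <- withCallingHandlers(
    subset_exclude_locus(model, sentinel_key),
    warning = function(w) invokeRestart("muffleWarning"))
  reduced <- if (reduced_model$n_snp < model$n_snp) fit_one(reduced_model)
  else NULL
  data.frame(model = c("whole_genome", "locus_excluded"),
             n_snp = c(model$n_snp, reduced_model$n_snp),
             or = c(full$or, reduced$or %||% NA_real_),
             pvalue = c(full$pvalue, reduced$pvalue %||% NA_real_),
             stringsAsFactors = FALSE)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assoc_table(bundle$grid_results, file.path(out_dir, "discovery_grid.tsv"))
  if (!is.null(bundle$quartiles))
    write_assoc_table(bundle$quartiles, file.path(out_dir, "quartile_or.tsv"))
  for (nm in names(bundle$sensitivity))
    write_assoc_table(bundle$sensitivity[[nm]],
                      file.path(out_dir, paste0("sensitivity_", nm, ".tsv")))
  if (!is.null(bundle$locus_exclusion))
    write_assoc_table(bundle$locus_exclusion,
                      file.path(out_dir, "locus_exclusion.tsv"))
  if (!is.null(bundle$pathway)) {
    write_assoc_table(bundle$pathway$enrichment,
                      file.path(out_dir, "pathway_enrichment.tsv"))
    write_assoc_table(bundle$pathway$prs_tests,
                      file.path(out_dir, "pathway_prs.tsv"))
  }
  for (nm in names(bundle$models)) {
    fn <- gsub("[^A-Za-z0-9]+", "_", nm)
    write_model(bundle$models[[nm]],
                file.path(out_dir, paste0("model_", fn, ".tsv")))
  }
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Write / read a frozen PRS model
#'
#' Tab-delimited variant, alleles, weight table for reuse on a replication
#' cohort.
#'
#' @param model a `prs_model`
#' @param path file path
#' @return `path` (write) or a `prs_model` (read)
#' @export
write_model <- function(model, path) {
  df <- model$variants
  df$threshold <- model$threshold
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  thr <- df$threshold[1]
  df$threshold <- NULL
  df$chrom <- as.character(df$chrom)
  structure(list(threshold = thr, variants = df, n_snp = nrow(df)),
            class = "prs_model")
}

#' Run the replication workflow
#'
#' Scores a replication cohort with frozen discovery models (no re-scan) and
#' tests each selected category with its stratum's covariate set.
#' Replication is restricted to the categories supplied (by default those
#' passing the discovery Bonferroni for hospitalisation), and the Bonferroni
#' correction uses the number of tested categories. If fewer than
#' `overlap_floor` of a model's variants are present in the replication
#' genotypes the run fails.
#'
#' @param config a [run_config()] describing the replication cohort (its
#'   seed drives the replication simulation when simulating)
#' @param models named list of frozen `prs_model`s, names as in the
#'   discovery grid (`"hospitalised | all"` etc.)
#' @param categories character vector of stratum labels to replicate
#' @param outcome outcome flag column (default `"hospitalised"`)
#' @param alpha family-wise error rate
#' @param overlap_floor minimum fraction of model variants that must match
#'   the replication genotypes (default 0.9)
#' @return data.frame, one row per category: `label`, `threshold`, `n_snp`,
#'   `overlap`, `or`, `ci_lo`, `ci_hi`, `pvalue`, `significant`; attribute
#'   `bonferroni` holds the applied threshold. Empty `categories` yields an
#'   empty table.
#' @export
run_replication <- function(config, models, categories,
                            outcome = "hospitalised", alpha = 0.05,
                            overlap_floor = 0.9) {
  stopifnot(inherits(config, "run_config"))
  empty <- data.frame(label = character(0), threshold = numeric(0),
                      n_snp = integer(0), overlap = numeric(0),
                      or = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), pvalue = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(categories) == 0) return(empty)
  thr <- bonferroni(alpha, length(categories))
  inputs <- if (!is.null(config$simulate)) simulate_inputs(config)
  else load_inputs(config)
  cohort <- inputs$cohort
  cohort$cohort <- "replication"
  prune_idx <- ld_prune(inputs$geno)
  pcs <- compute_pcs(inputs$geno, prune_idx, k = config$n_pcs)
  cohort <- cbind(cohort, as.data.frame(pcs))
  strata <- strata_grid(age_cut = config$age_cut, n_pcs = config$n_pcs)
  y <- as_binary_outcome(cohort[[outcome]])
  analysis <- which(!is.na(y))
  rows <- lapply(categories, function(label) {
    mod <- models[[paste(outcome, label, sep = " | ")]] %||% models[[label]]
    if (is.null(mod)) stop_input(paste0("no frozen model for category ", label))
    present <- mod$variants$key %in% inputs$geno$map$key
    overlap <- mean(present)
    if (overlap < overlap_floor)
      prsct_stop(sprintf(
        "replication variant overlap %.1f%% below floor %.1f%% for %s",
        100 * overlap, 100 * overlap_floor, label),
        class = "prsct_low_overlap")
    mod$variants <- mod$variants[present, , drop = FALSE]
    mod$n_snp <- nrow(mod$variants)
    stratum <- strata[strata$label == label, , drop = FALSE]
    if (nrow(stratum) != 1) stop_input(paste0("unknown category ", label))
    idx <- intersect(which(stratum_index(cohort, stratum[1, ],
                                         config$age_cut)), analysis)
    covs <- stratum_covariates(cohort, stratum[1, ])
    raw <- compute_prs(inputs$geno, mod)
    sv <- standardize(raw[analysis])
    z <- (raw - sv$mean) / sv$sd
    f <- fit_logistic(y[idx], z[idx], covariates = covs[idx, , drop = FALSE])
    data.frame(label = label, threshold = mod$threshold, n_snp = mod$n_snp,
               overlap = overlap, or = f$or, ci_lo = f$ci_lo,
               ci_hi = f$ci_hi, pvalue = f$pvalue,
               significant = !is.na(f$pvalue) && f$pvalue <= thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni") <- thr
  out
}
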