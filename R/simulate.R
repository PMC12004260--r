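#' LD block specification
#'
#' Describes one linkage-disequilibrium block of the simulated genome. Within
#' a block, latent Gaussian variables follow an AR(1) process with parameter
#' `rho`, so the correlation of latent variables at index distance `d` is
#' `rho^d`; thresholding the latents at each variant's allele frequency yields
#' correlated haplotypes (a Gaussian copula), and dosage r-squared decays with
#' index distance accordingly.
#'
#' @param n_variants number of variants in the block (>= 1)
#' @param maf_range length-2 numeric, allele-frequency range in (0.01, 0.5)
#'   from which per-variant frequencies are drawn uniformly
#' @param rho AR(1) correlation of adjacent latent variables, in `[0, 1)`
#' @param span_bp physical length of the block in base pairs
#' @param chrom chromosome label (one synthetic chromosome by default;
#'   multi-chromosome genomes are built by passing blocks on several labels)
#' @return an `ld_block` list
#' @export
ld_block <- function(n_variants, maf_range = c(0.05, 0.5), rho = 0.8,
                     span_bp = 100000L, chrom = "1") {
  if (n_variants < 1) stop_input("n_variants must be >= 1")
  if (rho < 0 || rho >= 1) stop_input("rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_input("maf_range must be an increasing pair within (0, 0.5]")
  if (span_bp < n_variants) stop_input("span_bp must allow distinct positions")
  structure(list(n_variants = as.integer(n_variants), maf_range = maf_range,
                 rho = rho, span_bp = as.integer(span_bp),
                 chrom = as.character(chrom)),
            class = "ld_block")
}

# non-ambiguous counted/other allele pair for each variant
draw_allele_pairs <- function(m) {
  counted <- sample(BASES, m, replace = TRUE)
  other <- vapply(counted, function(a) {
    sample(setdiff(BASES, c(a, COMPLEMENT[[a]])), 1L)
  }, character(1))
  data.frame(counted = counted, other = unname(other), stringsAsFactors = FALSE)
}

#' Simulate LD-blocked diploid dosages
#'
#' Draws two haplotypes per sample from a Gaussian copula: per block, a latent
#' AR(1) normal vector is thresholded at `qnorm(maf)` per variant so each
#' haplotype carries the counted allele with probability `maf`, and the two
#' haplotypes are summed to an additive dosage in `{0, 1, 2}`. Blocks are laid
#' end to end per chromosome; positions are 1-based and strictly increasing
#' within a chromosome.
#'
#' @param blocks list of [ld_block()] specifications
#' @param n_samples number of diploid samples (>= 2)
#' @param seed integer RNG seed; the output is deterministic given the seed
#' @param map_seed seed for the structural randomness (allele frequencies,
#'   positions, allele labels). Defaults to `seed`; fixing `map_seed` while
#'   varying `seed` yields independent cohorts genotyped on the same variant
#'   map, e.g. a discovery and a replication cohort
#' @return a [dosage_set()]; the map carries an extra `maf_true` column with
#'   the generating allele frequencies
#' @export
simulate_ld_genotypes <- function(blocks, n_samples, seed, map_seed = seed) {
  if (inherits(blocks, "ld_block")) blocks <- list(blocks)
  if (length(blocks) == 0) stop_input("at least one LD block is required")
  if (n_samples < 2) stop_input("n_samples must be >= 2")
  maps <- withr::with_seed(as.integer(map_seed), {
    offsets <- new.env(parent = emptyenv())
    idx0 <- 0L
    lapply(blocks, function(blk) {
      m <- blk$n_variants
      maf <- runif(m, blk$maf_range[1], blk$maf_range[2])
      off <- get0(blk$chrom, envir = offsets, ifnotfound = 0L)
      pos <- sort(sample.int(blk$span_bp, m)) + off
      assign(blk$chrom, off + blk$span_bp, envir = offsets)
      al <- draw_allele_pairs(m)
      mp <- data.frame(
        chrom = blk$chrom, pos = pos,
        id = paste0("var", idx0 + seq_len(m)),
        counted = al$counted, other = al$other,
        maf_true = maf, stringsAsFactors = FALSE)
      idx0 <<- idx0 + m
      mp
    })
  })
  withr::with_seed(as.integer(seed), {
    cols <- lapply(seq_along(blocks), function(b) {
      blk <- blocks[[b]]
      m <- blk$n_variants
      thr <- qnorm(maps[[b]]$maf_true)
      hap <- matrix(0, n_samples, m)
      for (h in 1:2) {
        z <- matrix(0, n_samples, m)
        z[, 1] <- rnorm(n_samples)
        if (m > 1) {
          sc <- sqrt(1 - blk$rho^2)
          for (j in 2:m) z[, j] <- blk$rho * z[, j - 1] + sc * rnorm(n_samples)
        }
        hap <- hap + sweep(z, 2, thr, `<`)
      }
      hap
    })
    G <- do.call(cbind, cols)
    rownames(G) <- sprintf("S%05d", seq_len(n_samples))
    dosage_set(G, do.call(rbind, maps))
  })
}

#' Genetic-overlap scenario
#'
#' Parameters of the simulated base trait (the IPF-like GWAS trait), of the
#' target severity trait, and of their genetic overlap.
#'
#' @param h2_base fraction of base-trait liability variance explained by
#'   genotype, in `[0, 1]`
#' @param causal_fraction share of variants with nonzero effect, in `[0, 1]`
#' @param rho_overlap correlation between base and target per-variant causal
#'   effects, in `[-1, 1]`
#' @param target_prevalence named numeric: case fractions of the phenotyped
#'   COVID-like cohort for `hospitalised`, `severe`, `critical`. Defaults keep
#'   the observed cohort composition: 59% of hospitalised cases are severe and
#'   19% critical.
#' @param age_effect,sex_effect liability-scale modifiers: coefficients on the
#'   standardized age and on male sex
#' @param sentinel_flip plant one large-effect sentinel (a MUC5B-promoter-like
#'   variant) whose target-trait effect direction is opposite to its
#'   base-trait direction?
#' @param sentinel_beta base-trait effect size of the planted sentinel
#'   (log-odds per allele)
#' @param sentinel_target_beta magnitude of the sentinel's (flipped)
#'   target-trait effect
#' @param h2_target genetic variance fraction of the target liability;
#'   defaults to `h2_base`
#' @param mortality_rate probability of 90-day death among critical cases
#' @param mortality_beta liability-scale coupling of mortality to the genetic
#'   score (0 = mortality independent of the PRS, the default)
#' @return an `overlap_scenario` list
#' @export
overlap_scenario <- function(h2_base = 0.3, causal_fraction = 0.2,
                             rho_overlap = 0.8,
                             target_prevalence = c(hospitalised = 0.5,
                                                   severe = 0.295,
                                                   critical = 0.095),
                             age_effect = 0.3, sex_effect = 0.25,
                             sentinel_flip = FALSE, sentinel_beta = 0.45,
                             sentinel_target_beta = 0.35,
                             h2_target = NULL,
                             mortality_rate = 0.25, mortality_beta = 0) {
  if (h2_base < 0 || h2_base > 1) stop_input("h2_base must lie in [0, 1]")
  if (causal_fraction < 0 || causal_fraction > 1)
    stop_input("causal_fraction must lie in [0, 1]")
  if (rho_overlap < -1 || rho_overlap > 1)
    stop_input("rho_overlap must lie in [-1, 1]")
  need <- c("hospitalised", "severe", "critical")
  if (!all(need %in% names(target_prevalence)))
    stop_input("target_prevalence must name hospitalised, severe, critical")
  K <- target_prevalence[need]
  if (any(K <= 0) || any(K >= 1)) stop_input("prevalences must lie in (0, 1)")
  if (K["critical"] > K["severe"] || K["severe"] > K["hospitalised"])
    stop_input("prevalences must nest: critical <= severe <= hospitalised")
  h2_target <- h2_target %||% h2_base
  if (h2_target < 0 || h2_target > 1) stop_input("h2_target must lie in [0, 1]")
  structure(list(h2_base = h2_base, causal_fraction = causal_fraction,
                 rho_overlap = rho_overlap, target_prevalence = K,
                 age_effect = age_effect, sex_effect = sex_effect,
                 sentinel_flip = isTRUE(sentinel_flip),
                 sentinel_beta = sentinel_beta,
                 sentinel_target_beta = sentinel_target_beta,
                 h2_target = h2_target,
                 mortality_rate = mortality_rate,
                 mortality_beta = mortality_beta),
            class = "overlap_scenario")
}

#' Simulate a base GWAS over the simulated genotypes
#'
#' True per-allele effects are point-normal: zero with probability
#' `1 - causal_fraction`, otherwise normal, rescaled so the causal effects
#' jointly explain `h2_base` of a unit-variance liability
#' (`sum(beta^2 * 2p(1-p)) = h2_base`). Reported effects add estimation noise
#' with standard error `1 / sqrt(n_base * 2p(1-p))`; p-values are two-sided
#' Wald. If the scenario plants a sentinel, the variant with the largest
#' heterozygosity receives a true effect of at least `5` standard errors and
#' its reported statistic is clamped to genome-wide significance
#' (p < 5e-8), mimicking an unambiguous MUC5B-promoter-like signal.
#'
#' A fraction of variants is reported in swapped orientation (effect and other
#' allele exchanged, effect size negated) to exercise allele harmonisation;
#' the truth is always expressed on the counted-allele scale.
#'
#' @param geno a [dosage_set()]
#' @param scenario an [overlap_scenario()]
#' @param n_base base-GWAS sample size (>= 100) controlling the noise scale
#' @param seed integer RNG seed
#' @param swap_fraction fraction of variants reported with swapped
#'   effect/other orientation
#' @return list with `stats` (a summary-statistics data.frame: `chrom`, `pos`,
#'   `id`, `effect_allele`, `other_allele`, `beta`, `pvalue`, `maf`, `info`)
#'   and `truth` (per-variant `key`, `beta_true` on the counted-allele scale,
#'   `se`, `is_causal`, `is_sentinel`)
#' @export
simulate_base_gwas <- function(geno, scenario, n_base, seed,
                               swap_fraction = 0.3) {
  stopifnot(inherits(geno, "dosage_set"), inherits(scenario, "overlap_scenario"))
  if (n_base < 100) stop_input("n_base must be >= 100")
  m <- ncol(geno$dosages)
  withr::with_seed(as.integer(seed), {
    p <- allele_freq(geno)
    het <- 2 * p * (1 - p)
    het[het <= 0] <- NA
    causal <- runif(m) < scenario$causal_fraction
    beta_true <- numeric(m)
    if (any(causal)) beta_true[causal] <- rnorm(sum(causal))
    sentinel <- rep(FALSE, m)
    se <- 1 / sqrt(n_base * het)
    se[!is.finite(se)] <- Inf
    if (scenario$sentinel_flip) {
      s <- which.max(het)
      sentinel[s] <- TRUE
      causal[s] <- FALSE # sentinel handled separately from polygenic mass
      beta_true[s] <- 0
    }
    v <- sum(beta_true[causal]^2 * het[causal], na.rm = TRUE)
    if (scenario$h2_base > 0 && v > 0)
      beta_true[causal] <- beta_true[causal] * sqrt(scenario$h2_base / v)
    else if (scenario$h2_base == 0)
      beta_true[causal] <- 0
    if (scenario$sentinel_flip) {
      s <- which(sentinel)
      beta_true[s] <- max(scenario$sentinel_beta, 5 * se[s])
    }
    beta_hat <- beta_true + rnorm(m) * ifelse(is.finite(se), se, 0)
    if (scenario$sentinel_flip) {
      s <- which(sentinel)
      # guarantee genome-wide significance of the reported sentinel statistic
      if (abs(beta_hat[s] / se[s]) < 6) beta_hat[s] <- sign(beta_true[s]) * 6 * se[s]
    }
    z <- ifelse(is.finite(se), beta_hat / se, 0)
    pval <- 2 * pnorm(-abs(z))
    pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
    info <- ifelse(runif(m) < 0.03, runif(m, 0.05, 0.3), runif(m, 0.6, 1))
    # the planted sentinel emulates a well-imputed, directly assayed top hit;
    # it must not fall into the low-quality tail
    if (scenario$sentinel_flip) info[sentinel] <- runif(1, 0.9, 1)
    swap <- runif(m) < swap_fraction
    stats <- data.frame(
      chrom = geno$map$chrom, pos = geno$map$pos, id = geno$map$id,
      effect_allele = ifelse(swap, geno$map$other, geno$map$counted),
      other_allele = ifelse(swap, geno$map$counted, geno$map$other),
      beta = ifelse(swap, -beta_hat, beta_hat),
      pvalue = pval, maf = pmin(p, 1 - p), info = round(info, 4),
      stringsAsFactors = FALSE)
    truth <- data.frame(key = geno$map$key, beta_true = beta_true, se = se,
                        is_causal = causal, is_sentinel = sentinel,
                        stringsAsFactors = FALSE)
    list(stats = stats, truth = truth)
  })
}

#' Simulate an ascertained target severity cohort
#'
#' Builds a liability-threshold severity phenotype that shares a tunable
#' fraction of the base trait's genetic effects. Target per-variant effects
#' are `rho_overlap`-correlated transforms of the base true effects on the
#' causal set; if the scenario flips the sentinel, its target effect has the
#' opposite sign. The liability is
#' `sqrt(h2) * z(G beta_target) + age_effect * z(age) + sex_effect * male +
#' N(0, 1 - h2)`. Severity scales 0-4 are assigned among the phenotyped
#' samples by ordered empirical liability thresholds calibrated so the case
#' fractions match the scenario's target prevalences; the remaining
#' `n_population_controls` samples are appended as unphenotyped population
#' controls (no severity scale, all outcome flags `control`).
#'
#' Outcome flags follow the severity-scale logic: critical = scale 4,
#' severe = scales 3-4, hospitalised = scales 3-4 plus a random fraction
#' `p_hosp2` of scale-2 patients (the admission rule for moderate disease is a
#' parameter, not an assertion). 90-day mortality is a Bernoulli event among
#' critical cases, independent of the genetic score unless `mortality_beta`
#' couples them; mortality is flagged `excluded` for population controls.
#'
#' @param geno a [dosage_set()] covering all cohort samples (phenotyped
#'   patients first, population controls last)
#' @param base_truth `truth` element of [simulate_base_gwas()] (or a numeric
#'   vector of true counted-allele effects aligned to the genotype variants)
#' @param scenario an [overlap_scenario()]
#' @param n_population_controls number of trailing samples treated as
#'   unphenotyped population controls
#' @param seed integer RNG seed for the individual-level randomness
#' @param p_hosp2 admission probability for severity-scale-2 patients
#' @param asymptomatic_fraction fraction of phenotyped patients at scale 0
#' @param cohort cohort label (`"discovery"` or `"replication"`)
#' @param effect_seed seed for drawing the target per-variant effects;
#'   defaults to a value derived from `seed`. Fix it (together with the
#'   genotype `map_seed` and the base-GWAS seed) to simulate independent
#'   cohorts of the same underlying trait architecture
#' @return a `data.frame` (one row per sample): `sample_id`, `severity`
#'   (0-4, `NA` for population controls), flags `hospitalised`, `severe`,
#'   `critical`, `mortality` in `{case, control, excluded}`, `age`, `sex`,
#'   `chronic_resp_disease`, `population_control`, `cohort`. The attribute
#'   `truth` carries the target effects, liability, and standardized genetic
#'   score for parameter-recovery checks.
#' @export
simulate_target_cohort <- function(geno, base_truth, scenario,
                                   n_population_controls = 0, seed,
                                   p_hosp2 = 0.5,
                                   asymptomatic_fraction = 0.065,
                                   cohort = "discovery",
                                   effect_seed = NULL) {
  stopifnot(inherits(geno, "dosage_set"), inherits(scenario, "overlap_scenario"))
  n <- nrow(geno$dosages)
  m <- ncol(geno$dosages)
  if (is.data.frame(base_truth)) {
    if (!identical(base_truth$key, geno$map$key))
      stop_input("base_truth is not aligned to the genotype variants")
    b <- base_truth$beta_true
    sentinel <- which(base_truth$is_sentinel)
  } else {
    b <- as.numeric(base_truth)
    if (length(b) != m) stop_input("base_truth length must match variant count")
    sentinel <- integer(0)
  }
  n_covid <- n - n_population_controls
  if (n_covid < 20) stop_input("too few phenotyped samples")
  K <- scenario$target_prevalence
  if (n_covid * K["critical"] < 1)
    stop_input("critical prevalence infeasible at this sample size")
  F2 <- (K[["hospitalised"]] - K[["severe"]]) / p_hosp2
  if (K[["severe"]] + F2 + asymptomatic_fraction >= 1)
    stop_input("severity-band fractions exceed the cohort")
  bt <- withr::with_seed(as.integer(effect_seed %||% derive_seed(seed, 11)), {
    rho <- scenario$rho_overlap
    bt <- numeric(m)
    nz <- b != 0
    sdb <- if (any(nz)) sd(b[nz]) else 0
    if (sum(nz) == 1) sdb <- abs(b[nz])
    bt[nz] <- rho * b[nz] + sqrt(1 - rho^2) * rnorm(sum(nz), 0, sdb)
    if (length(sentinel) == 1 && scenario$sentinel_flip)
      bt[sentinel] <- -sign(b[sentinel]) * scenario$sentinel_target_beta
    bt
  })
  withr::with_seed(as.integer(seed), {
    g <- impute_mean_cols(geno$dosages) %*% bt
    g_std <- if (sd(g) > 0) as.numeric(scale(g)) else numeric(n)
    age <- pmin(pmax(round(rnorm(n, 55, 16)), 18), 98)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    h2 <- scenario$h2_target
    liab <- sqrt(h2) * g_std +
      scenario$age_effect * as.numeric(scale(age)) +
      scenario$sex_effect * (sex == "male") +
      rnorm(n, 0, sqrt(max(1 - h2, 0)))
    covid <- seq_len(n_covid)
    lc <- liab[covid]
    q_crit <- quantile(lc, 1 - K[["critical"]], names = FALSE)
    q_sev <- quantile(lc, 1 - K[["severe"]], names = FALSE)
    q_mod <- quantile(lc, 1 - K[["severe"]] - F2, names = FALSE)
    q_asym <- quantile(lc, asymptomatic_fraction, names = FALSE)
    severity <- rep(NA_integer_, n)
    severity[covid] <- ifelse(lc >= q_crit, 4L,
                       ifelse(lc >= q_sev, 3L,
                       ifelse(lc >= q_mod, 2L,
                       ifelse(lc < q_asym, 0L, 1L))))
    flag <- function(case) ifelse(case, "case", "control")
    critical <- severe <- hospitalised <- rep("control", n)
    sev <- severity
    critical[covid] <- flag(sev[covid] == 4L)
    severe[covid] <- flag(sev[covid] >= 3L)
    admit2 <- sev == 2L & runif(n) < p_hosp2
    hospitalised[covid] <- flag(sev[covid] >= 3L | admit2[covid])
    mortality <- rep("excluded", n)
    mortality[covid] <- "control"
    crit_idx <- which(critical == "case")
    if (length(crit_idx) > 0) {
      pm <- plogis(qlogis(scenario$mortality_rate) +
                     scenario$mortality_beta * g_std[crit_idx])
      mortality[crit_idx] <- flag(runif(length(crit_idx)) < pm)
    }
    chronic <- rep(FALSE, n)
    chronic[covid] <- runif(n_covid) < 0.06
    pheno <- data.frame(
      sample_id = rownames(geno$dosages),
      severity = severity,
      hospitalised = hospitalised, severe = severe, critical = critical,
      mortality = mortality,
      age = age, sex = sex,
      chronic_resp_disease = chronic,
      population_control = seq_len(n) > n_covid,
      cohort = cohort, stringsAsFactors = FALSE)
    attr(pheno, "truth") <- list(beta_target = bt, liability = liab,
                                 genetic_score = g_std,
                                 sentinel = sentinel)
    pheno
  })
}

#' Simulate gene annotation and pathway gene sets
#'
#' Places gene bodies along the simulated coordinate space and partitions
#' genes into pathways. When causal variant keys are supplied, the first
#' pathway (`"set01"`) is a "causal pathway" preferentially containing the
#' genes nearest to causal variants, so enrichment-recovery experiments have a
#' known answer.
#'
#' @param geno a [dosage_set()] defining the coordinate space
#' @param n_genes number of genes (>= 2)
#' @param n_pathways number of pathways (>= 1)
#' @param seed integer RNG seed
#' @param causal_keys optional character vector of causal variant keys
#' @param pathway_size mean number of genes per random pathway
#' @return list with `genes` (data.frame `gene`, `chrom`, `start`, `end`,
#'   `strand`, `tss`; 1-based inclusive gene bodies) and `pathways` (named
#'   list of gene-id vectors); element `causal_pathway` names the planted set
#'   (or `NA` when no causal keys were given)
#' @export
simulate_annotation <- function(geno, n_genes, n_pathways, seed,
                                causal_keys = NULL, pathway_size = 15) {
  stopifnot(inherits(geno, "dosage_set"))
  if (n_genes < 2) stop_input("n_genes must be >= 2")
  if (n_pathways < 1) stop_input("n_pathways must be >= 1")
  withr::with_seed(as.integer(seed), {
    chroms <- unique(geno$map$chrom)
    span <- vapply(chroms, function(ch)
      max(geno$map$pos[geno$map$chrom == ch]) + 50000L, numeric(1))
    gchrom <- sample(chroms, n_genes, replace = TRUE,
                     prob = span / sum(span))
    tss <- vapply(gchrom, function(ch)
      sample.int(as.integer(span[[ch]]), 1L), numeric(1))
    len <- pmax(round(runif(n_genes, 5000, 100000)), 1000)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    start <- ifelse(strand == "+", tss, pmax(tss - len, 1))
    end <- ifelse(strand == "+", tss + len, tss)
    genes <- data.frame(gene = sprintf("gene%03d", seq_len(n_genes)),
                        chrom = gchrom, start = as.integer(start),
                        end = as.integer(end), strand = strand,
                        tss = as.integer(tss), stringsAsFactors = FALSE)
    genes <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
    rownames(genes) <- NULL
    sizes <- pmax(rpois(n_pathways, pathway_size), 3)
    sizes <- pmin(sizes, n_genes)
    pathways <- lapply(sizes, function(s) sort(sample(genes$gene, s)))
    names(pathways) <- sprintf("set%02d", seq_len(n_pathways))
    causal_pathway <- NA_character_
    if (!is.null(causal_keys) && length(causal_keys) > 0) {
      ck <- geno$map[geno$map$key %in% causal_keys, , drop = FALSE]
      nearest <- unique(vapply(seq_len(nrow(ck)), function(i) {
        same <- genes$chrom == ck$chrom[i]
        if (!any(same)) return(NA_character_)
        g <- genes[same, , drop = FALSE]
        g$gene[which.min(abs(g$tss - ck$pos[i]))]
      }, character(1)))
      nearest <- nearest[!is.na(nearest)]
      s1 <- max(sizes[1], length(nearest))
      pad <- setdiff(genes$gene, nearest)
      extra <- if (s1 > length(nearest))
        sample(pad, min(s1 - length(nearest), length(pad))) else character(0)
      pathways[[1]] <- sort(unique(c(nearest, extra)))
      causal_pathway <- names(pathways)[1]
    }
    list(genes = genes, pathways = pathways, causal_pathway = causal_pathway)
  })
}
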