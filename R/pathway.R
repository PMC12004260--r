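#' Regulatory domains by the basal-plus-extension rule
#'
#' Each gene receives a basal promoter interval (5 kb upstream to 1 kb
#' downstream of its TSS, strand-aware) which is then extended in both
#' directions up to `extension` bp, truncating at the basal interval of the
#' nearest neighbouring gene so extensions never invade a neighbour's basal
#' domain. This is a simplified stand-in for regulatory-annotation web tools;
#' extended domains of adjacent genes may still overlap each other.
#'
#' @param genes annotation data.frame with `gene`, `chrom`, `tss`, `strand`
#'   (e.g. from [read_gene_annotation()] or [simulate_annotation()])
#' @param basal_up,basal_down basal interval sizes in bp (upstream /
#'   downstream of the TSS)
#' @param extension maximum extension per side in bp (default 1 Mb)
#' @return data.frame: `gene`, `chrom`, `tss`, `strand`, `basal_start`,
#'   `basal_end`, `ext_start`, `ext_end` (1-based inclusive)
#' @export
regulatory_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                               extension = 1e6) {
  stopifnot(all(c("gene", "chrom", "tss", "strand") %in% names(genes)))
  up <- ifelse(genes$strand == "+", basal_up, basal_down)
  dn <- ifelse(genes$strand == "+", basal_down, basal_up)
  d <- data.frame(gene = genes$gene, chrom = genes$chrom, tss = genes$tss,
                  strand = genes$strand,
                  basal_start = as.integer(pmax(genes$tss - up, 1)),
                  basal_end = as.integer(genes$tss + dn),
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$tss), , drop = FALSE]
  d$ext_start <- pmax(d$basal_start - extension, 1)
  d$ext_end <- d$basal_end + extension
  for (ch in unique(d$chrom)) {
    i <- which(d$chrom == ch)
    if (length(i) < 2) next
    prev_end <- c(-Inf, d$basal_end[i[-length(i)]])
    next_start <- c(d$basal_start[i[-1]], Inf)
    d$ext_start[i] <- pmax(d$ext_start[i],
                           pmin(prev_end + 1, d$basal_start[i]))
    d$ext_end[i] <- pmin(d$ext_end[i],
                         pmax(next_start - 1, d$basal_end[i]))
  }
  d$ext_start <- as.integer(pmax(d$ext_start, 1))
  d$ext_end <- as.integer(d$ext_end)
  rownames(d) <- NULL
  d
}

#' Assign variants to genes through regulatory domains
#'
#' A variant maps to every gene whose extended regulatory interval contains
#' its position (inclusive ends); variants inside no interval are reported
#' unassigned.
#'
#' @param variants data.frame with `key`, `chrom`, `pos` (e.g. a
#'   `prs_model`'s `variants` element)
#' @param domains data.frame from [regulatory_domains()]
#' @return list: `map` (named list, variant key -> character vector of
#'   genes), `genes` (sorted unique assigned genes), `unassigned` (keys)
#' @export
assign_variants_to_genes <- function(variants, domains) {
  stopifnot(all(c("key", "chrom", "pos") %in% names(variants)))
  map <- lapply(seq_len(nrow(variants)), function(i) {
    hit <- domains$chrom == variants$chrom[i] &
      domains$ext_start <= variants$pos[i] &
      domains$ext_end >= variants$pos[i]
    domains$gene[hit]
  })
  names(map) <- variants$key
  hits <- lengths(map) > 0
  list(map = map[hits],
       genes = sort(unique(unlist(map))),
       unassigned = variants$key[!hits])
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of each gene set's overlap with the
#' query gene list against a background universe, with Benjamini-Hochberg
#' FDR control across sets. Sets are intersected with the background; the
#' query list must be a subset of the background.
#'
#' @param genes character vector of query genes
#' @param gene_sets named list of gene-id vectors
#' @param background character vector: the gene universe
#' @return data.frame sorted by FDR, then p, then set size: `pathway`,
#'   `overlap`, `set_size`, `list_size`, `background_size`, `pvalue`, `fdr`
#' @export
enrich <- function(genes, gene_sets, background) {
  if (length(background) == 0) stop_input("background gene universe is empty")
  background <- unique(background)
  genes <- unique(genes)
  if (!all(genes %in% background))
    stop_input("query gene list must be a subset of the background")
  N <- length(background)
  nq <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], background)
    k <- length(intersect(set, genes))
    p <- stats::phyper(k - 1, length(set), N - length(set), nq,
                       lower.tail = FALSE)
    data.frame(pathway = nm, overlap = k, set_size = length(set),
               list_size = nq, background_size = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$fdr, out$pvalue, out$set_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway-restricted PRS association
#'
#' For each of the top enriched gene sets, restricts the best whole-genome
#' model's variants to those mapping to the set's genes, recomputes the
#' standardized PRS, and fits the stratum's logistic model. Nominal
#' significance is flagged at p < 0.05. A pathway whose restriction empties
#' the model yields a flagged row rather than an error.
#'
#' @param model the best whole-genome `prs_model`
#' @param ds a [dosage_set()]
#' @param outcome binary outcome over all samples
#' @param covariates covariate data.frame (or NULL)
#' @param gene_sets named list of gene sets to test (e.g. top-5 by
#'   [top_pathways()])
#' @param variant_map `map` element of [assign_variants_to_genes()]
#' @param fit_idx samples entering the fit (default: non-missing outcome)
#' @param standardize_idx standardisation sample (default `fit_idx`)
#' @param alpha nominal significance level (default 0.05)
#' @return data.frame, one row per pathway: `pathway`, `n_snp`, `or`,
#'   `ci_lo`, `ci_hi`, `pvalue`, `significant`, `status`
#' @export
pathway_prs_test <- function(model, ds, outcome, covariates = NULL,
                             gene_sets, variant_map, fit_idx = NULL,
                             standardize_idx = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "prs_model"))
  y <- as_binary_outcome(outcome)
  fit_idx <- fit_idx %||% which(!is.na(y))
  standardize_idx <- standardize_idx %||% fit_idx
  rows <- lapply(names(gene_sets), function(nm) {
    set <- gene_sets[[nm]]
    keys <- names(variant_map)[vapply(variant_map, function(g)
      any(g %in% set), logical(1))]
    keep <- model$variants$key %in% keys
    row <- data.frame(pathway = nm, n_snp = sum(keep), or = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, pvalue = NA_real_,
                      significant = FALSE, status = "ok",
                      stringsAsFactors = FALSE)
    if (!any(keep)) {
      row$status <- "empty_pathway_model"
      return(row)
    }
    sub <- model
    sub$variants <- model$variants[keep, , drop = FALSE]
    sub$n_snp <- sum(keep)
    f <- tryCatch({
      raw <- compute_prs(ds, sub)
      sv <- standardize(raw[standardize_idx])
      z <- (raw - sv$mean) / sv$sd
      fit_logistic(y[fit_idx], z[fit_idx],
                   covariates = if (is.null(covariates)) NULL else
                     covariates[fit_idx, , drop = FALSE])
    }, prsct_error = function(e) list(status = conditionMessage(e)))
    if (!identical(f$status, "ok")) {
      row$status <- f$status
      return(row)
    }
    row$or <- f$or
    row$ci_lo <- f$ci_lo
    row$ci_hi <- f$ci_hi
    row$pvalue <- f$pvalue
    row$significant <- f$pvalue < alpha
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the top enriched pathways
#'
#' Deterministic top-k selection from an enrichment table: by FDR, then
#' p-value, then set size.
#'
#' @param enrichment data.frame from [enrich()]
#' @param gene_sets the full named list of gene sets
#' @param k number of pathways (default 5)
#' @return named list of the k selected gene sets, in rank order
#' @export
top_pathways <- function(enrichment, gene_sets, k = 5) {
  sel <- utils::head(enrichment$pathway, k)
  gene_sets[sel]
}
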