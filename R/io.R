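SUMSTAT_COLS <- c("chrom", "pos", "id", "effect_allele", "other_allele",
                  "beta", "pvalue")

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file into the package's variant
#' table. Mandatory columns are chromosome, position, id, effect allele,
#' other allele, effect size (log OR) and p-value; minor allele frequency
#' (`maf`) and imputation quality (`info`) are attached when present. Rows
#' failing validation (identical alleles, p-value outside `(0, 1]`,
#' non-numeric effect) are rejected with their line numbers in a warning;
#' missing mandatory columns are a configuration error.
#'
#' @param path file path
#' @param column_map optional named character vector mapping the package's
#'   column names (names) to the file's header names (values), e.g.
#'   `c(chrom = "CHR", pos = "BP", beta = "OR")`
#' @param or_column is the effect column an odds ratio? If so `beta = log(OR)`
#' @return data.frame with columns `chrom`, `pos`, `id`, `effect_allele`,
#'   `other_allele`, `beta`, `pvalue`, `maf`, `info` (the last two `NA` when
#'   absent from the file)
#' @export
read_sumstats <- function(path, column_map = NULL, or_column = FALSE) {
  if (!file.exists(path)) stop_input(paste0("no such file: ", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  cmap <- stats::setNames(c(SUMSTAT_COLS, "maf", "info"),
                          c(SUMSTAT_COLS, "maf", "info"))
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  miss <- setdiff(SUMSTAT_COLS, names(cmap)[cmap %in% names(raw)])
  if (length(miss) > 0)
    prsct_stop(paste0("summary-statistics file lacks mandatory column(s): ",
                      paste(cmap[miss], collapse = ", ")),
               class = "prsct_config_error")
  get_col <- function(nm) if (cmap[[nm]] %in% names(raw)) raw[[cmap[[nm]]]] else NA
  out <- data.frame(
    chrom = as.character(get_col("chrom")),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    id = as.character(get_col("id")),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    maf = suppressWarnings(as.numeric(get_col("maf"))),
    info = suppressWarnings(as.numeric(get_col("info"))),
    stringsAsFactors = FALSE)
  if (or_column) out$beta <- log(out$beta)
  bad <- is.na(out$pos) | is.na(out$beta) | !is.finite(out$beta) |
    is.na(out$pvalue) | out$pvalue <= 0 | out$pvalue > 1 |
    !(out$effect_allele %in% BASES) | !(out$other_allele %in% BASES) |
    out$effect_allele == out$other_allele
  if (any(bad)) {
    lines <- which(bad) + 1L # header is line 1
    warning(sprintf("rejected %d malformed summary-statistic row(s) at line(s): %s",
                    sum(bad), paste(lines, collapse = ", ")), call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write summary statistics
#'
#' @param stats a summary-statistics data.frame
#' @param path output path (tab-delimited, with header)
#' @return `path`, invisibly
#' @export
write_sumstats <- function(stats, path) {
  cols <- intersect(c(SUMSTAT_COLS, "maf", "info"), names(stats))
  utils::write.table(stats[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages (VCF or dosage TSV)
#'
#' For VCF input the per-genotype `DS` field is preferred; when absent,
#' hard genotype calls (`GT`) are converted to 0/1/2 counts of the ALT
#' allele. Missing calls become the missing marker (`NA`), never 0.
#' Multi-allelic records must be split upstream and are an error, as are
#' duplicated variant keys. The TSV layout is the one written by
#' [write_dosages()]: columns `chrom`, `pos`, `id`, `counted`, `other`, then
#' one column per sample, one row per variant.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`
#' @return a [dosage_set()] whose dosages count the ALT (VCF) or `counted`
#'   (TSV) allele
#' @export
read_dosages <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input(paste0("no such file: ", path))
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") read_dosages_vcf(path) else read_dosages_tsv(path)
}

read_dosages_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop_parse("VCF contains no variant records")
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop_parse("multi-allelic VCF records must be split upstream")
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    D <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al == "1")
    }
    D <- apply(gt, c(1, 2), count_alt)
  }
  map <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = fix$ID, counted = toupper(fix$ALT),
                    other = toupper(fix$REF), stringsAsFactors = FALSE)
  key <- variant_key(map$chrom, map$pos, map$counted, map$other)
  if (anyDuplicated(key))
    prsct_stop(paste0("duplicated variant key: ", key[duplicated(key)][1]),
               class = "prsct_duplicate_variant")
  dosage_set(t(D), map)
}

read_dosages_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "counted", "other")
  if (!all(need %in% names(tab)))
    stop_parse("dosage TSV must start with columns chrom, pos, id, counted, other")
  samp <- setdiff(names(tab), need)
  if (length(samp) == 0) stop_parse("dosage TSV has no sample columns")
  D <- t(as.matrix(tab[, samp, drop = FALSE]))
  storage.mode(D) <- "double"
  rownames(D) <- samp
  dosage_set(D, tab[, need, drop = FALSE])
}

#' Write genotype dosages (VCF with DS field, or dosage TSV)
#'
#' The VCF writer emits an uncompressed VCFv4.2 file whose single FORMAT
#' field is the additive ALT-allele dosage `DS`; the counted allele is
#' written as ALT. Round-trips through [read_dosages()].
#'
#' @param ds a [dosage_set()]
#' @param path output path
#' @param format `"vcf"` or `"tsv"`
#' @param digits significant digits for dosage values
#' @return `path`, invisibly
#' @export
write_dosages <- function(ds, path, format = c("vcf", "tsv"), digits = 8) {
  stopifnot(inherits(ds, "dosage_set"))
  format <- match.arg(format)
  fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, digits = digits,
                                                       format = "g"))
  if (format == "tsv") {
    tab <- cbind(ds$map[, c("chrom", "pos", "id", "counted", "other")],
                 as.data.frame(t(ds$dosages), check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Additive ALT allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(ds$dosages)), collapse = "\t")), con)
  body <- vapply(seq_len(ncol(ds$dosages)), function(j) {
    paste(c(ds$map$chrom[j], ds$map$pos[j], ds$map$id[j], ds$map$other[j],
            ds$map$counted[j], ".", "PASS", ".", "DS",
            fmt_num(ds$dosages[, j])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path
#' @return named list of unique gene-id character vectors
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_input(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_parse(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene-id vectors
#' @param path output path
#' @param descriptions optional character vector of set descriptions
#' @return `path`, invisibly
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read gene annotation from BED
#'
#' BED intervals are 0-based half-open; they are converted to 1-based
#' inclusive coordinates at this boundary, and the transcription start site
#' is the 5' end of the interval on the annotated strand (start for `+`,
#' end for `-`).
#'
#' @param path BED file path (>= 6 columns: chrom, start, end, name, score,
#'   strand)
#' @return data.frame `gene`, `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `tss`
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop_input(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, integer(1)) < 6)
  if (length(bad) > 0)
    stop_parse(sprintf("malformed BED line(s) (fewer than 6 fields): %s",
                       paste(bad, collapse = ", ")))
  tab <- do.call(rbind, lapply(parts, function(f) f[1:6]))
  start0 <- suppressWarnings(as.integer(tab[, 2]))
  end0 <- suppressWarnings(as.integer(tab[, 3]))
  if (anyNA(start0) || anyNA(end0) || any(end0 <= start0))
    stop_parse("BED intervals must have numeric start < end")
  strand <- tab[, 6]
  if (!all(strand %in% c("+", "-"))) stop_parse("BED strand must be + or -")
  data.frame(gene = tab[, 4], chrom = tab[, 1],
             start = start0 + 1L, end = end0,
             strand = strand,
             tss = ifelse(strand == "+", start0 + 1L, end0),
             stringsAsFactors = FALSE)
}

#' Write gene annotation as BED (0-based half-open)
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_bed <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                     genes$start - 1L, genes$end, genes$gene, genes$strand),
             path)
  invisible(path)
}

#' Write an association-results table
#'
#' Tab-delimited with a header; an empty result set yields a header-only
#' file. Column layout mirrors the per-stratum association grid (category,
#' covariates, counts, threshold, number of variants, OR with CI, p-value).
#'
#' @param results data.frame of association rows (possibly 0-row)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_assoc_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' @param path tab-delimited file with a `sample_id` column
#' @return data.frame
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_input(paste0("no such file: ", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop_parse("phenotype table must have a sample_id column")
  tab
}

#' Write a phenotype/covariate table
#'
#' @param pheno data.frame with a `sample_id` column
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
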