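#' Dosage set: samples x variants additive dosages plus a variant map
#'
#' The container used throughout the package for individual-level genotypes:
#' a dense numeric matrix of additive allele dosages in `[0, 2]` (rows =
#' samples, columns = variants; `NA` marks a missing call) together with a
#' variant map describing each column. The dosage counts the `counted` allele;
#' `other` is the remaining allele.
#'
#' @param dosages numeric matrix, samples x variants, values in `[0, 2]` or `NA`
#' @param map data.frame with columns `chrom`, `pos`, `id`, `counted`, `other`
#'   (one row per dosage column)
#' @return an object of class `dosage_set`: a list with elements `dosages`
#'   (the matrix, with sample ids as rownames and variant keys as colnames)
#'   and `map` (the variant table, with a `key` column added)
#' @export
dosage_set <- function(dosages, map) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  need <- c("chrom", "pos", "id", "counted", "other")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0)
    stop_input(paste0("variant map lacks column(s): ", paste(miss, collapse = ", ")))
  if (nrow(map) != ncol(dosages))
    stop_input("variant map rows must match dosage columns")
  if (length(dosages) > 0 && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop_input("dosages must lie in [0, 2] (or be NA)")
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$key <- variant_key(map$chrom, map$pos, map$counted, map$other)
  if (anyDuplicated(map$key)) {
    dup <- map$key[duplicated(map$key)][1]
    prsct_stop(paste0("duplicated variant key: ", dup), class = "prsct_duplicate_variant")
  }
  colnames(dosages) <- map$key
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  rownames(map) <- NULL
  structure(list(dosages = dosages, map = map), class = "dosage_set")
}

#' @export
print.dosage_set <- function(x, ...) {
  cat(sprintf("<dosage_set> %d samples x %d variants, %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.dosage_set <- function(x) dim(x$dosages)

#' Subset a dosage set by variant index
#'
#' @param ds a [dosage_set()]
#' @param idx integer or logical index over variants (columns)
#' @return a `dosage_set` restricted to the selected variants
#' @export
subset_variants <- function(ds, idx) {
  dosage_set(ds$dosages[, idx, drop = FALSE],
             ds$map[idx, setdiff(names(ds$map), "key"), drop = FALSE])
}

#' Per-variant empirical allele frequency
#'
#' Frequency of the counted allele (`colMeans(dosage)/2`, missing calls
#' excluded); `folded = TRUE` returns the minor allele frequency.
#'
#' @param ds a [dosage_set()]
#' @param folded fold frequencies above 0.5?
#' @return numeric vector, one value per variant
#' @export
allele_freq <- function(ds, folded = FALSE) {
  f <- colMeans(ds$dosages, na.rm = TRUE) / 2
  if (folded) f <- pmin(f, 1 - f)
  f
}
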