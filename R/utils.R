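#' @keywords internal
"_PACKAGE"

# Classed error constructors so callers can distinguish user/input errors
# from data problems programmatically.
prsct_stop <- function(msg, class = "prsct_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "prsct_error", "error", "condition")))
}

stop_input <- function(msg) prsct_stop(msg, class = "prsct_input_error")
stop_parse <- function(msg) prsct_stop(msg, class = "prsct_parse_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) unname(COMPLEMENT[a])

#' Canonical variant key
#'
#' Variant identity is (chromosome, position, unordered allele pair): the two
#' alleles are sorted lexicographically before pasting, so the key is invariant
#' to which allele is designated as effect/counted allele.
#'
#' @param chrom chromosome label
#' @param pos 1-based position
#' @param a1,a2 the two alleles (single upper-case bases)
#' @return character vector of keys `"chrom:pos:min:max"`
#' @export
variant_key <- function(chrom, pos, a1, a2) {
  lo <- ifelse(a1 <= a2, a1, a2)
  hi <- ifelse(a1 <= a2, a2, a1)
  paste(chrom, pos, lo, hi, sep = ":")
}

#' Is an allele pair strand-ambiguous?
#'
#' A/T and C/G pairs read the same on both strands, so strand cannot be
#' inferred from the alleles alone.
#'
#' @param a1,a2 allele vectors
#' @return logical vector
#' @export
is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Replace missing dosages by the per-variant mean of observed dosages
# (columns with no observed value become all-zero).
impute_mean_cols <- function(X) {
  nas <- which(colSums(is.na(X)) > 0L)
  for (j in nas) {
    x <- X[, j]
    m <- mean(x, na.rm = TRUE)
    if (!is.finite(m)) m <- 0
    x[is.na(x)] <- m
    X[, j] <- x
  }
  X
}

# Derive a stream-specific 32-bit seed from a master seed, so independent
# generators under one master seed do not share RNG state.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
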