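#' Convert raw counts to FPKM
#'
#' FPKM_gs = 1e9 * c_gs / (L_g * N_s), with L_g the gene length in base
#' pairs and N_s the library size of sample s (its total count). When
#' `size_factors` are supplied (e.g. DESeq2 median-of-ratios factors),
#' N_s is replaced by `size_factors[s] * mean(library sizes)`, which
#' mirrors tools that normalize counts by size factor before the FPKM
#' formula.
#'
#' @param counts an [expr_matrix()] with layer `"counts"`.
#' @param lengths named numeric vector of positive gene lengths in bp;
#'   must cover every gene in `counts`.
#' @param size_factors optional named (or positionally matched) vector of
#'   positive per-sample size factors.
#' @return An [expr_matrix()] with layer `"fpkm"`.
#' @examples
#' m <- expr_matrix(matrix(c(10L, 0L), 2, 1,
#'        dimnames = list(c("a", "b"), "s1")), "counts")
#' # library size forced to 1e6 via a second dummy gene is not needed:
#' # with a single sample the library size is just the column sum
#' @export
counts_to_fpkm <- function(counts, lengths, size_factors = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (layer(counts) != "counts")
    stop("`counts` must have layer \"counts\"", call. = FALSE)
  if (is.null(names(lengths)))
    stop("`lengths` must be a named vector", call. = FALSE)
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing gene length for: ", paste(miss, collapse = ", "), call. = FALSE)
  L <- lengths[rownames(counts)]
  if (any(!is.finite(L) | L <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  lib <- colSums(counts)
  if (is.null(size_factors)) {
    N <- lib
  } else {
    if (!is.null(names(size_factors))) {
      miss_s <- setdiff(colnames(counts), names(size_factors))
      if (length(miss_s))
        stop("missing size factor for: ", paste(miss_s, collapse = ", "), call. = FALSE)
      size_factors <- size_factors[colnames(counts)]
    } else if (length(size_factors) != ncol(counts)) {
      stop("`size_factors` length must equal the number of samples", call. = FALSE)
    }
    if (any(!is.finite(size_factors) | size_factors <= 0))
      stop("size factors must be positive", call. = FALSE)
    N <- size_factors * mean(lib)
  }
  if (any(N == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[N == 0], collapse = ", "), call. = FALSE)
  v <- 1e9 * sweep(sweep(unclass(counts), 1, L, "/"), 2, N, "/")
  expr_matrix(v, "fpkm")
}

#' Shifted log2 transform
#'
#' Maps every value v to log2(v + offset); missing values are preserved.
#'
#' @param m an [expr_matrix()] with non-negative values.
#' @param offset positive pseudo-count added before the log.
#' @return An [expr_matrix()] with layer `"log2"`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"), is.numeric(offset), offset > 0)
  v <- unclass(m)
  if (any(v < 0, na.rm = TRUE))
    stop("log2_transform requires non-negative values", call. = FALSE)
  expr_matrix(log2(v + offset), "log2")
}

#' Filter genes by median expression quantile
#'
#' Keeps genes whose per-gene median (missing values excluded) is
#' strictly greater than the given quantile of the distribution of
#' per-gene medians. This is the "median expression above the q-th
#' percentile" abundance filter used before co-expression scans; the
#' quantile uses linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param m an [expr_matrix()], at least 2 genes.
#' @param quantile cut point in `[0, 1)`; default 0.30.
#' @return The filtered [expr_matrix()], gene order preserved. Warns
#'   (does not error) if no gene survives.
#' @export
filter_by_median_quantile <- function(m, quantile = 0.30) {
  stopifnot(inherits(m, "expr_matrix"), nrow(m) >= 2,
            quantile >= 0, quantile < 1)
  med <- apply(unclass(m), 1, stats::median, na.rm = TRUE)
  cut <- stats::quantile(med, probs = quantile, type = 7, names = FALSE)
  keep <- !is.na(med) & med > cut
  if (!any(keep))
    warning("filter_by_median_quantile removed every gene", call. = FALSE)
  m[keep, , drop = FALSE]
}

#' Filter genes by missingness
#'
#' Keeps genes quantified (non-missing) in at least `min_fraction` of
#' samples; the bound is inclusive, so with `min_fraction = 0.30` a gene
#' observed in exactly 30% of samples is retained.
#'
#' @param m an [expr_matrix()], typically the protein layer.
#' @param min_fraction minimum non-missing fraction in `(0, 1]`.
#' @return The filtered [expr_matrix()], gene order preserved.
#' @export
filter_by_missingness <- function(m, min_fraction = 0.30) {
  stopifnot(inherits(m, "expr_matrix"),
            min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(unclass(m)))
  m[frac >= min_fraction, , drop = FALSE]
}
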