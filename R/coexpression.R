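#' Fisher z transform of a correlation
#'
#' z = atanh(r), the variance-stabilising transform whose sampling
#' variance is approximately 1/(n - 3); defined for |r| < 1.
#'
#' @param r correlation(s) strictly inside (-1, 1); NA passes through.
#' @return Numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("fisher_z requires |r| < 1", call. = FALSE)
  atanh(r)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values. Missing entries are excluded
#' from the adjustment and returned as missing (undefined correlations
#' never enter the FDR computation).
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

# Vectorised masked partial-correlation core.
#
# X: genes x samples matrix (NA allowed); a: anchor vector; z: covariate.
# For each gene row the pairwise-complete sample set is the intersection
# of non-missing entries of (row, a, z); the single-covariate closed form
#   (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
# is evaluated on that set, which is algebraically identical to
# residualising both variables on the covariate over the same samples and
# correlating the residuals.
#
# Returns list(r, n): partial correlation and pairwise-complete n per
# gene. r is NA when n < 4 or any variance involved is (numerically)
# zero. With `partial = FALSE` the plain Pearson r of row vs a on the
# pairwise-complete set (ignoring z for the value but not the mask when
# `mask_covariate`) is returned.
.masked_partial_cor <- function(X, a, z = NULL, partial = !is.null(z)) {
  X <- as.matrix(X)
  col_ok <- !is.na(a)
  if (!is.null(z)) col_ok <- col_ok & !is.na(z)
  M <- !is.na(X)
  if (!all(col_ok)) M[, !col_ok] <- FALSE
  X0 <- X; X0[!M] <- 0
  a0 <- ifelse(is.na(a), 0, a)
  n  <- rowSums(M)
  Sx  <- rowSums(X0)
  Sxx <- rowSums(X0 * X0)
  Sa  <- as.vector(M %*% a0)
  Saa <- as.vector(M %*% (a0 * a0))
  Sxa <- as.vector(X0 %*% a0)
  nn <- pmax(n, 1)
  vx <- Sxx - Sx^2 / nn
  va <- Saa - Sa^2 / nn
  cxa <- Sxa - Sx * Sa / nn
  eps <- 1e-12
  denom_xa <- vx * va
  r_xy <- ifelse(denom_xa > eps, cxa / sqrt(pmax(denom_xa, eps)), NA_real_)
  if (!partial) {
    r <- ifelse(n >= 4, r_xy, NA_real_)
    return(list(r = pmin(1, pmax(-1, r)), n = n))
  }
  z0 <- ifelse(is.na(z), 0, z)
  Sz  <- as.vector(M %*% z0)
  Szz <- as.vector(M %*% (z0 * z0))
  Sxz <- as.vector(X0 %*% z0)
  Saz <- as.vector(M %*% (a0 * z0))
  vz  <- Szz - Sz^2 / nn
  cxz <- Sxz - Sx * Sz / nn
  caz <- Saz - Sa * Sz / nn
  r_xz <- ifelse(vx * vz > eps, cxz / sqrt(pmax(vx * vz, eps)), NA_real_)
  r_az <- ifelse(va * vz > eps, caz / sqrt(pmax(va * vz, eps)), NA_real_)
  d <- (1 - r_xz^2) * (1 - r_az^2)
  r <- ifelse(!is.na(r_xy) & !is.na(r_xz) & !is.na(r_az) & d > eps,
              (r_xy - r_xz * r_az) / sqrt(pmax(d, eps)), NA_real_)
  r <- ifelse(n >= 4, r, NA_real_)
  list(r = pmin(1, pmax(-1, r)), n = n)
}

#' Regress a covariate out of every gene row
#'
#' Each gene row is replaced by the residuals of an ordinary
#' least-squares fit of that row on intercept + covariate, computed over
#' the row's non-missing samples. Residual rows therefore have zero mean
#' and zero sample correlation with the covariate on the samples used;
#' missingness is preserved.
#'
#' @param m an [expr_matrix()] or plain numeric matrix (genes x samples).
#' @param covariate numeric vector, one value per sample (e.g. tumor
#'   purity); must be non-constant on the samples used.
#' @return Matrix of residuals with the same dimensions, dimnames and
#'   (for `expr_matrix` input) layer as `m`.
#' @export
residualize <- function(m, covariate) {
  X <- as.matrix(m)
  if (length(covariate) != ncol(X))
    stop("covariate must have one value per sample", call. = FALSE)
  if (anyNA(covariate))
    stop("covariate must be defined for every sample", call. = FALSE)
  if (stats::sd(covariate) == 0)
    stop("covariate is constant; cannot residualize", call. = FALSE)
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  n  <- rowSums(M)
  if (any(n < 2))
    stop("every gene needs >= 2 non-missing samples to residualize", call. = FALSE)
  Sx <- rowSums(X0)
  Sz <- as.vector(M %*% covariate)
  Szz <- as.vector(M %*% covariate^2)
  Sxz <- as.vector(X0 %*% covariate)
  vz <- Szz - Sz^2 / n
  if (any(vz <= 1e-12))
    stop("covariate is constant on the used samples of some gene", call. = FALSE)
  beta  <- (Sxz - Sx * Sz / n) / vz
  alpha <- Sx / n - beta * Sz / n
  fit <- outer(beta, covariate) + alpha
  res <- X - fit
  res[!M] <- NA
  if (inherits(m, "expr_matrix")) res <- expr_matrix(res, layer(m)) else res
  res
}

#' Single-covariate partial correlation
#'
#' Pearson correlation between `x` and `y` after removing the linear
#' effect of one covariate from both, computed on the pairwise-complete
#' samples of (x, y, covariate) via the closed form
#' (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#'
#' @param x,y numeric vectors (NA allowed).
#' @param covariate numeric vector of the same length.
#' @return List with `r` (NA when a residual variance is zero) and
#'   `n_used`, the number of complete samples actually used.
#' @export
partial_correlation <- function(x, y, covariate) {
  stopifnot(length(x) == length(y), length(x) == length(covariate))
  res <- .masked_partial_cor(matrix(x, nrow = 1), y, covariate)
  if (res$n[1] < 4)
    stop("partial_correlation needs >= 4 pairwise-complete samples", call. = FALSE)
  list(r = res$r[1], n_used = as.integer(res$n[1]))
}

#' Anchor-gene partial-correlation scan
#'
#' Computes the purity-adjusted partial correlation between one anchor
#' gene and every other gene in the matrix. The p-value uses the
#' t-distribution test of a partial correlation with `n_used - 3`
#' degrees of freedom (n - 2 - k with k = 1 covariate); q-values are
#' Benjamini-Hochberg over the scan (undefined correlations excluded).
#'
#' @param m an [expr_matrix()] (typically the log2 mRNA or protein
#'   layer).
#' @param anchor_id gene id of the anchor (e.g. `"EZH2"`).
#' @param covariate per-sample confounder (e.g. tumor purity); `NULL`
#'   for a plain Pearson scan.
#' @param method `"pearson"` (default) or `"spearman"` (ranks are taken
#'   per pairwise-complete set before the same machinery).
#' @return A data.frame (classed `anchor_scan`) with columns `gene_id`,
#'   `anchor_id`, `r`, `n_used`, `z`, `p`, `q`.
#' @export
anchor_scan <- function(m, anchor_id, covariate = NULL,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- as.matrix(m)
  if (!anchor_id %in% rownames(X))
    stop("anchor gene ", anchor_id, " not found in matrix", call. = FALSE)
  a <- X[anchor_id, ]
  G <- X[setdiff(rownames(X), anchor_id), , drop = FALSE]
  if (method == "spearman") {
    # rank-transform each row and the anchor/covariate on all non-missing
    # entries; pairwise sets then reuse the Pearson machinery on ranks
    rk <- function(v) { out <- rep(NA_real_, length(v)); ok <- !is.na(v)
                        out[ok] <- rank(v[ok]); out }
    G <- t(apply(G, 1, rk)); a <- rk(a)
    if (!is.null(covariate)) covariate <- rk(covariate)
  }
  pc <- .masked_partial_cor(G, a, covariate)
  r <- pc$r; n <- pc$n
  k <- if (is.null(covariate)) 0 else 1
  df <- n - 2 - k
  tt <- r * sqrt(pmax(df, 0) / pmax(1 - r^2, 1e-300))
  p <- ifelse(is.na(r) | df < 1, NA_real_, 2 * stats::pt(-abs(tt), pmax(df, 1)))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(gene_id = rownames(G), anchor_id = anchor_id,
                    r = r, n_used = as.integer(n),
                    z = ifelse(abs(r) < 1, atanh(r), sign(r) * Inf),
                    p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("anchor_scan", "data.frame")
  out
}

#' @export
print.anchor_scan <- function(x, ...) {
  cat(sprintf("Anchor co-expression scan: %s vs %d genes\n",
              x$anchor_id[1], nrow(x)))
  ok <- !is.na(x$q)
  cat(sprintf("  significant at q < 0.05: %d (%d positive, %d negative)\n",
              sum(ok & x$q < 0.05), sum(ok & x$q < 0.05 & x$r > 0),
              sum(ok & x$q < 0.05 & x$r < 0)))
  if (anyNA(x$r)) cat(sprintf("  undefined correlations: %d\n", sum(is.na(x$r))))
  print.data.frame(utils::head(x[order(x$p), ], 10), row.names = FALSE, digits = 3)
  invisible(x)
}
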