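# run expr with a private RNG state seeded at `seed`; the caller's
# .Random.seed is untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_groups <- function(groups, n) {
  if (length(groups) != n)
    stop("`groups` must have one label per sample", call. = FALSE)
  g <- as.character(groups)
  lv <- intersect(.rtt_levels, unique(g))
  if (length(lv) != 2 || !all(g %in% .rtt_levels))
    stop("`groups` must contain exactly the levels \"sensitive\" and \"resistant\"",
         call. = FALSE)
  factor(g, levels = .rtt_levels)
}

.clamp_r <- function(r) pmin(1 - 1e-12, pmax(-1 + 1e-12, r))

# per-gene Fisher z-difference between two sample index sets; r is
# computed by the masked partial-correlation core within each set
# (residualisation is implicit and group-wise by construction)
.group_zdiff <- function(X, a, covariate, idx1, idx2) {
  g1 <- .masked_partial_cor(X[, idx1, drop = FALSE], a[idx1],
                            if (!is.null(covariate)) covariate[idx1])
  g2 <- .masked_partial_cor(X[, idx2, drop = FALSE], a[idx2],
                            if (!is.null(covariate)) covariate[idx2])
  se <- sqrt(1 / pmax(g1$n - 3, 1) + 1 / pmax(g2$n - 3, 1))
  z <- (atanh(.clamp_r(g1$r)) - atanh(.clamp_r(g2$r))) / se
  z[g1$n < 4 | g2$n < 4] <- NA_real_
  list(z = z, r1 = g1$r, n1 = g1$n, r2 = g2$r, n2 = g2$n)
}

#' Per-group anchor correlations
#'
#' Runs the purity-adjusted anchor scan separately within each outcome
#' group (residualisation is performed within group, so the purity
#' adjustment cannot leak information across groups).
#'
#' @param m an [expr_matrix()].
#' @param anchor_id anchor gene id.
#' @param groups per-sample labels, `"sensitive"` / `"resistant"`.
#' @param covariate per-sample confounder or `NULL`.
#' @return Named list of two [anchor_scan()] data.frames
#'   (`sensitive`, `resistant`).
#' @export
group_correlations <- function(m, anchor_id, groups, covariate = NULL) {
  X <- as.matrix(m)
  g <- .check_groups(groups, ncol(X))
  if (any(table(g) < 5))
    stop("each outcome group needs >= 5 samples", call. = FALSE)
  out <- lapply(levels(g), function(lv) {
    idx <- which(g == lv)
    anchor_scan(m[, idx, drop = FALSE], anchor_id,
                if (!is.null(covariate)) covariate[idx])
  })
  names(out) <- levels(g)
  out
}

#' Fisher z-difference statistic for two correlations
#'
#' z_diff = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), the
#' standard two-sample comparison of correlation coefficients on the
#' Fisher z scale.
#'
#' @param r1,r2 correlations with |r| < 1 (vectorised).
#' @param n1,n2 sample sizes (> 3).
#' @return Numeric z-difference(s).
#' @export
diffcorr_zstat <- function(r1, n1, r2, n2) {
  if (any(n1 <= 3 | n2 <= 3, na.rm = TRUE))
    stop("diffcorr_zstat requires group sizes > 3", call. = FALSE)
  if (any(abs(c(r1, r2)) >= 1, na.rm = TRUE))
    stop("diffcorr_zstat requires |r| < 1", call. = FALSE)
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

#' Permutation empirical p-values for differential correlation
#'
#' Outcome labels are permuted across samples while each sample keeps
#' its expression and covariate value (preserving the confounding
#' structure); per permutation the within-group purity-adjusted
#' correlations and the per-gene |z_diff| are recomputed. One shared set
#' of permuted label vectors is used for all genes. The empirical
#' p-value per gene is (1 + #\{permutations with |z*| >= |z_obs|\}) /
#' (1 + n_perm). When every distinct label assignment fits in the budget
#' (choose(n, n1) <= n_perm) they are enumerated exhaustively instead
#' and p = #\{assignments with |z*| >= |z_obs|\} / N, with the observed
#' assignment among the N — the two conventions coincide and the
#' exhaustive p is exact.
#'
#' @param m an [expr_matrix()].
#' @param anchor_id anchor gene id.
#' @param groups per-sample `"sensitive"`/`"resistant"` labels.
#' @param covariate per-sample confounder or `NULL`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; the result is deterministic given it.
#' @return A data.frame with `gene_id`, `z_diff` (observed), `p_perm`,
#'   and an attribute `exhaustive` (logical).
#' @export
permutation_pvalues <- function(m, anchor_id, groups, covariate = NULL,
                                n_perm = 1000, seed = 1) {
  if (n_perm < 100)
    stop("n_perm must be >= 100", call. = FALSE)
  X <- as.matrix(m)
  g <- .check_groups(groups, ncol(X))
  a <- X[anchor_id, ]
  G <- X[setdiff(rownames(X), anchor_id), , drop = FALSE]
  n <- ncol(X); n1 <- sum(g == levels(g)[1])
  idx1 <- which(g == levels(g)[1]); idx2 <- which(g == levels(g)[2])
  obs <- .group_zdiff(G, a, covariate, idx1, idx2)
  n_total <- suppressWarnings(choose(n, n1))
  exhaustive <- is.finite(n_total) && n_total <= n_perm
  if (exhaustive) {
    sets <- utils::combn(n, n1, simplify = FALSE)
    Z <- vapply(sets, function(s)
      abs(.group_zdiff(G, a, covariate, s, setdiff(seq_len(n), s))$z),
      numeric(nrow(G)))
    cnt <- rowSums(Z >= abs(obs$z), na.rm = TRUE)
    p <- cnt / length(sets)
  } else {
    Z <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
      s <- sample.int(n, n1)
      abs(.group_zdiff(G, a, covariate, s, setdiff(seq_len(n), s))$z)
    }, numeric(nrow(G))))
    cnt <- rowSums(Z >= abs(obs$z), na.rm = TRUE)
    p <- (1 + cnt) / (1 + n_perm)
  }
  p[is.na(obs$z)] <- NA_real_
  out <- data.frame(gene_id = rownames(G), z_diff = obs$z, p_perm = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Sign-pair class labels for differential correlation
#'
#' Each gene gets a label "s/r" where s and r are the signs ("+", "-" or
#' "0") of its anchor correlation in the sensitive and resistant group:
#' the sign of r when the per-group correlation p-value is below `alpha`,
#' "0" otherwise.
#'
#' @param res named list of two [anchor_scan()] frames as returned by
#'   [group_correlations()].
#' @param alpha per-group significance threshold (default 0.05).
#' @return Character vector of labels, one per gene, named by gene id.
#' @export
classify_pairs <- function(res, alpha = 0.05) {
  stopifnot(all(.rtt_levels %in% names(res)))
  sen <- res$sensitive; rs <- res$resistant
  stopifnot(identical(sen$gene_id, rs$gene_id))
  sgn <- function(r, p) ifelse(!is.na(p) & p < alpha,
                               ifelse(r > 0, "+", "-"), "0")
  lab <- paste(sgn(sen$r, sen$p), sgn(rs$r, rs$p), sep = "/")
  names(lab) <- sen$gene_id
  lab
}

#' Group-exclusive anchor co-expression networks
#'
#' Among genes whose permutation p-value is below `alpha`, genes
#' significantly correlated with the anchor in the sensitive group only
#' (class "+/0" or "-/0") form the sensitive-exclusive network; genes
#' significant in the resistant group only ("0/+" or "0/-") form the
#' resistant-exclusive network. Genes significant in both groups belong
#' to neither.
#'
#' @param diff a `anchor_diffcorr` result (or any data.frame with
#'   `gene_id`, `class` and `p_perm` columns).
#' @param alpha threshold applied to `p_perm` (default 0.05).
#' @return List with `sensitive_exclusive`, `resistant_exclusive`
#'   (character vectors, disjoint) and `alpha`.
#' @export
exclusive_networks <- function(diff, alpha = 0.05) {
  d <- as.data.frame(diff)
  stopifnot(all(c("gene_id", "class", "p_perm") %in% names(d)))
  sig <- !is.na(d$p_perm) & d$p_perm < alpha
  list(sensitive_exclusive = d$gene_id[sig & d$class %in% c("+/0", "-/0")],
       resistant_exclusive = d$gene_id[sig & d$class %in% c("0/+", "0/-")],
       alpha = alpha)
}

#' Anchor-gene differential correlation between outcome groups
#'
#' The full differential co-expression analysis for one anchor gene:
#' per-group purity-adjusted correlations, Fisher z-difference,
#' permutation empirical p-values and sign-pair classification.
#'
#' @inheritParams permutation_pvalues
#' @param alpha per-group significance threshold used for the class
#'   labels (default 0.05).
#' @return An object of class `anchor_diffcorr`: a data.frame with
#'   columns `gene_id`, `r_sensitive`, `n_sensitive`, `p_sensitive`,
#'   `r_resistant`, `n_resistant`, `p_resistant`, `z_diff`, `p_perm`,
#'   `class`; attributes `anchor_id`, `alpha`, `n_perm`, `seed`,
#'   `exhaustive`.
#' @export
anchor_diffcorr <- function(m, anchor_id, groups, covariate = NULL,
                            alpha = 0.05, n_perm = 1000, seed = 1) {
  gc_ <- group_correlations(m, anchor_id, groups, covariate)
  pp <- permutation_pvalues(m, anchor_id, groups, covariate,
                            n_perm = n_perm, seed = seed)
  sen <- gc_$sensitive; rs <- gc_$resistant
  stopifnot(identical(sen$gene_id, pp$gene_id))
  out <- data.frame(gene_id = sen$gene_id,
                    r_sensitive = sen$r, n_sensitive = sen$n_used,
                    p_sensitive = sen$p,
                    r_resistant = rs$r, n_resistant = rs$n_used,
                    p_resistant = rs$p,
                    z_diff = pp$z_diff, p_perm = pp$p_perm,
                    class = unname(classify_pairs(gc_, alpha)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "anchor_id") <- anchor_id
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "exhaustive") <- attr(pp, "exhaustive")
  class(out) <- c("anchor_diffcorr", "data.frame")
  out
}

#' @export
print.anchor_diffcorr <- function(x, ...) {
  ex <- exclusive_networks(x, attr(x, "alpha"))
  cat(sprintf("Differential correlation with %s (%d genes, n_perm = %d%s)\n",
              attr(x, "anchor_id"), nrow(x), attr(x, "n_perm"),
              if (isTRUE(attr(x, "exhaustive"))) ", exhaustive" else ""))
  cat(sprintf("  p_perm < %.3g: %d genes\n", attr(x, "alpha"),
              sum(x$p_perm < attr(x, "alpha"), na.rm = TRUE)))
  cat(sprintf("  sensitive-exclusive: %d, resistant-exclusive: %d\n",
              length(ex$sensitive_exclusive), length(ex$resistant_exclusive)))
  print.data.frame(utils::head(x[order(x$p_perm), ], 10),
                   row.names = FALSE, digits = 3)
  invisible(x)
}
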