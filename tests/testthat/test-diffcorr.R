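test_that("group_correlations runs the scan within each outcome group", {
  set.seed(1)
  n <- 30
  X <- rbind(EZH2 = rnorm(n), g1 = rnorm(n), g2 = rnorm(n))
  colnames(X) <- sprintf("s%03d", 1:n)
  m <- expr_matrix(X, "log2")
  grp <- rep(c("sensitive", "resistant"), each = 15)
  z <- runif(n)
  gc_ <- group_correlations(m, "EZH2", grp, z)
  # per-group values equal a direct scan on the subset
  direct <- anchor_scan(m[, 1:15], "EZH2", z[1:15])
  expect_equal(gc_$sensitive$r, direct$r)
  # identical expression in both groups gives identical r
  X2 <- cbind(X[, 1:15], X[, 1:15])
  colnames(X2) <- sprintf("s%03d", 1:30)
  gc2 <- group_correlations(expr_matrix(X2, "log2"), "EZH2", grp, c(z[1:15], z[1:15]))
  expect_equal(gc2$sensitive$r, gc2$resistant$r)
  expect_error(group_correlations(m, "EZH2", c(rep("sensitive", 27),
                                               rep("resistant", 3)), z),
               ">= 5")
  # a gene constant within one group gets a missing r there
  X3 <- X; X3["g1", 1:15] <- 5
  gc3 <- group_correlations(expr_matrix(X3, "log2"), "EZH2", grp, z)
  expect_true(is.na(gc3$sensitive$r[gc3$sensitive$gene_id == "g1"]))
  expect_false(is.na(gc3$resistant$r[gc3$resistant$gene_id == "g1"]))
})

test_that("diffcorr_zstat follows the Fisher z-difference closed form", {
  expect_equal(diffcorr_zstat(0.4, 50, 0.4, 80), 0)
  expect_equal(diffcorr_zstat(0.5, 103, 0, 103), atanh(0.5) / sqrt(0.02))
  expect_equal(diffcorr_zstat(0.5, 103, 0, 103), 3.884, tolerance = 1e-3)
  expect_equal(diffcorr_zstat(0.3, 40, -0.2, 60),
               -diffcorr_zstat(-0.2, 60, 0.3, 40))
  expect_error(diffcorr_zstat(0.5, 3, 0.2, 50), "> 3")
  expect_error(diffcorr_zstat(1, 50, 0.2, 50), "\\|r\\| < 1")
})

test_that("permutation p equals exhaustive enumeration on small cohorts", {
  set.seed(5)
  X <- matrix(rnorm(3 * 8), 3, 8,
              dimnames = list(c("EZH2", "g1", "g2"), sprintf("s%d", 1:8)))
  m <- expr_matrix(X, "log2")
  grp <- rep(c("sensitive", "resistant"), each = 4)
  pp <- permutation_pvalues(m, "EZH2", grp, covariate = NULL,
                            n_perm = 100, seed = 1)
  expect_true(attr(pp, "exhaustive"))
  expect_equal(unname(pp$p_perm), unname(perm_p_oracle(X, "EZH2", 4)))
  # deterministic given seed even in the sampled regime
  n <- 40
  X2 <- matrix(rnorm(4 * n), 4, n,
               dimnames = list(c("EZH2", "a", "b", "c"), sprintf("s%02d", 1:n)))
  m2 <- expr_matrix(X2, "log2")
  grp2 <- rep(c("sensitive", "resistant"), each = 20)
  z2 <- runif(n)
  p1 <- permutation_pvalues(m2, "EZH2", grp2, z2, n_perm = 150, seed = 9)
  p2 <- permutation_pvalues(m2, "EZH2", grp2, z2, n_perm = 150, seed = 9)
  expect_identical(p1, p2)
  expect_false(attr(p1, "exhaustive"))
  # add-one correction bounds p away from zero
  expect_true(all(p1$p_perm >= 1 / 151))
  expect_error(permutation_pvalues(m2, "EZH2", grp2, z2, n_perm = 50),
               ">= 100")
})

test_that("a planted differential gene reaches small permutation p", {
  cfg <- generator_config(n_sensitive = 100, n_resistant = 100, n_genes = 20,
                          n_diff_sensitive = 0, n_diff_resistant = 1,
                          n_shared = 0, r_planted = 0.6, seed = 77)
  sim <- generate_diffcorr_cohort(cfg)
  pp <- permutation_pvalues(sim$expr, "EZH2", sim$annotations$rtt,
                            sim$annotations$purity, n_perm = 500, seed = 78)
  planted <- sim$truth$planted$gene_id[sim$truth$planted$role == "resistant"]
  expect_lt(pp$p_perm[pp$gene_id == planted], 0.05)
})

test_that("classify_pairs applies the sign rule at alpha", {
  mk <- function(r, p) data.frame(gene_id = c("a", "b", "c"), r = r, p = p)
  res <- list(sensitive = mk(c(0.5, 0.4, 0.1), c(0.01, 0.001, 0.8)),
              resistant = mk(c(-0.2, -0.5, 0.3), c(0.8, 0.002, 0.9)))
  lab <- classify_pairs(res, alpha = 0.05)
  expect_identical(unname(lab), c("+/0", "+/-", "0/0"))
})

test_that("exclusive networks collect single-group classes below alpha", {
  d <- data.frame(gene_id = letters[1:6],
                  class = c("0/+", "+/-", "+/0", "0/-", "-/0", "0/+"),
                  p_perm = c(0.01, 0.01, 0.02, 0.2, 0.03, 0.04))
  ex <- exclusive_networks(d, 0.05)
  expect_setequal(ex$resistant_exclusive, c("a", "f"))
  expect_setequal(ex$sensitive_exclusive, c("c", "e"))
  expect_length(intersect(ex$sensitive_exclusive, ex$resistant_exclusive), 0)
})

test_that("diffcorr results are invariant to gene order and consistent sample permutation", {
  cfg <- generator_config(n_sensitive = 40, n_resistant = 40, n_genes = 30,
                          n_diff_sensitive = 5, n_diff_resistant = 5,
                          n_shared = 0, seed = 13)
  sim <- generate_diffcorr_cohort(cfg)
  run <- function(m, grp, z) {
    d <- anchor_diffcorr(m, "EZH2", grp, z, n_perm = 120, seed = 3)
    ex <- exclusive_networks(d, 0.05)
    list(sen = sort(ex$sensitive_exclusive), res = sort(ex$resistant_exclusive))
  }
  base <- run(sim$expr, sim$annotations$rtt, sim$annotations$purity)
  # shuffle gene rows (anchor stays findable by name)
  set.seed(4); gperm <- sample(nrow(sim$expr))
  r1 <- run(sim$expr[gperm, ], sim$annotations$rtt, sim$annotations$purity)
  expect_identical(r1, base)
  # permute samples consistently in matrix, labels and covariate
  set.seed(5); sperm <- sample(ncol(sim$expr))
  r2 <- run(sim$expr[, sperm], sim$annotations$rtt[sperm],
            sim$annotations$purity[sperm])
  expect_identical(r2, base)
})

test_that("planted exclusive genes are recovered into the correct lists", {
  cfg <- generator_config(n_sensitive = 100, n_resistant = 100, n_genes = 200,
                          n_diff_sensitive = 25, n_diff_resistant = 25,
                          n_shared = 0, r_planted = 0.5, seed = 88)
  sim <- generate_diffcorr_cohort(cfg)
  d <- anchor_diffcorr(sim$expr, "EZH2", sim$annotations$rtt,
                       sim$annotations$purity, n_perm = 300, seed = 89)
  ex <- exclusive_networks(d, 0.05)
  tr <- sim$truth$planted
  sens_hits <- mean(ex$sensitive_exclusive %in%
                      tr$gene_id[tr$role == "sensitive"])
  res_hits <- mean(ex$resistant_exclusive %in%
                     tr$gene_id[tr$role == "resistant"])
  # lists are strongly enriched for the correct planted sets
  expect_gt(sens_hits, 0.7)
  expect_gt(res_hits, 0.7)
  expect_gt(length(ex$sensitive_exclusive), 10)
  expect_gt(length(ex$resistant_exclusive), 10)
})
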