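test_that("compare_groups matches hand-computed statistics", {
  # Pearson chi-square on the TIL x response 2x2 table, no Yates correction
  O <- matrix(c(10, 22, 8, 37), 2, 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  cg <- compare_groups(O, test = "chisq")
  expect_equal(cg$statistic, sum((O - E)^2 / E))
  # identical distributions in both groups: Wilcoxon p = 1
  w <- compare_groups(c(1:5, 1:5), rep(c("a", "b"), each = 5), "wilcoxon")
  expect_equal(w$p, 1)
  # extreme separation: t-test p below 1e-10
  tt <- compare_groups(c(rnorm(50), rnorm(50) + 10),
                       rep(c("a", "b"), each = 50), "t")
  expect_lt(tt$p, 1e-10)
  expect_error(compare_groups(1:4, rep("a", 4), "wilcoxon"), "two non-empty")
  expect_error(compare_groups(matrix(1:6, 2, 3), test = "chisq"), "2x2")
})

test_that("logistic RTT fit matches a brute-force likelihood oracle", {
  x <- c(-1.2, -0.5, 0.3, -0.1, 0.8, 1.5)
  y <- c(0, 1, 1, 0, 1, 0)
  ann <- toy_annotations(ifelse(y == 1, "resistant", "sensitive"))
  est <- fit_logistic_rtt(x, ann)
  nll <- function(b) -sum(y * (b[1] + b[2] * x) - log1p(exp(b[1] + b[2] * x)))
  oracle <- optim(c(0, 0), nll, method = "BFGS")$par[2]
  expect_equal(log(est$estimate), oracle, tolerance = 1e-4)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
  # perfect separation raises a diagnostic error
  ann_sep <- toy_annotations(ifelse(x > median(x), "resistant", "sensitive"))
  expect_error(fit_logistic_rtt(x, ann_sep), "separation")
})

test_that("a feature independent of outcome has OR near 1", {
  set.seed(7)
  n <- 400
  ann <- toy_annotations(sample(c("sensitive", "resistant"), n, TRUE,
                                prob = c(0.7, 0.3)))
  est <- fit_logistic_rtt(rnorm(n), ann)
  expect_lt(abs(log(est$estimate)), 0.3)
  expect_gt(est$p, 0.05)
})

test_that("Cox fit matches a brute-force partial-likelihood oracle", {
  # 4 subjects: (time, event, x) = (1,1,1), (2,1,0), (3,0,1), (4,1,0)
  ann <- sample_annotations(data.frame(
    sample_id = paste0("s", 1:4),
    survival_months = c(1, 2, 3, 4),
    event = c("died", "died", "censored", "died")))
  x <- c(1, 0, 1, 0)
  est <- fit_cox(x, ann)
  nplik <- function(b) {
    times <- c(1, 2, 3, 4); ev <- c(1, 1, 0, 1); risk <- exp(b * x)
    -sum(vapply(which(ev == 1), function(i)
      b * x[i] - log(sum(risk[times >= times[i]])), numeric(1)))
  }
  oracle <- optimize(nplik, c(-10, 10))$minimum
  expect_equal(log(est$estimate), oracle, tolerance = 1e-4)
  # doubling all times leaves the HR unchanged (rank invariance)
  ann2 <- ann; ann2$survival_months <- 2 * ann$survival_months
  expect_equal(fit_cox(x, ann2)$estimate, est$estimate)
  expect_error(fit_cox(rep(1, 4), ann), "constant")
  ann3 <- ann; ann3$event <- rep("censored", 4)
  expect_error(fit_cox(x, ann3), "no events")
})

test_that("forward stepwise selection follows the entry rule", {
  set.seed(17)
  n <- 300
  z1 <- rnorm(n)
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)     # collinear with z1
  z3 <- rnorm(n)                                  # pure noise
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * z1))
  ann <- toy_annotations(ifelse(y == 1, "resistant", "sensitive"),
                         f1 = z1, f2 = z2, f3 = z3)
  sel <- stepwise_select(c("f1", "f2", "f3"), "logistic", ann, entry_p = 0.10)
  # the stronger of the correlated pair enters first
  expect_identical(sel[1], "f1")
  expect_false("f3" %in% sel)
  # manual trace: selection equals a hand-run of the procedure
  cand <- c("f1", "f2", "f3")
  manual <- character()
  repeat {
    rem <- setdiff(cand, manual)
    if (!length(rem)) break
    ps <- vapply(rem, function(v) {
      fml <- as.formula(paste("y ~", paste(c(manual, v), collapse = " + ")))
      df <- data.frame(y = y, f1 = z1, f2 = z2, f3 = z3)
      summary(glm(fml, df, family = binomial()))$coefficients[v, 4]
    }, numeric(1))
    if (!any(ps < 0.10)) break
    manual <- c(manual, rem[which.min(ps)])
  }
  expect_identical(sel, manual)
  # single candidate: selected iff its p is below the entry threshold
  ann_null <- toy_annotations(ifelse(rbinom(50, 1, 0.4) == 1,
                                     "resistant", "sensitive"),
                              f1 = rnorm(50))
  set.seed(18)
  expect_length(stepwise_select("f1", "logistic", ann_null, entry_p = 1e-6), 0)
})

test_that("stratified association detects a stratum-specific effect", {
  set.seed(9)
  n <- 240
  s <- rep(c("present", "absent"), each = n / 2)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + ifelse(s == "present", 1.2, 0) * x))
  ann <- toy_annotations(ifelse(y == 1, "resistant", "sensitive"), til = s)
  sa <- stratified_association(x, ann, "til", model = "logistic")
  expect_lt(sa$p_interaction[1], 0.05)
  expect_lt(sa$p[sa$stratum == "present"], 0.01)
  expect_gt(sa$p[sa$stratum == "absent"], 0.05)
  # invariant to which stratum level is reference (two-sided Wald)
  ann_rec <- ann
  ann_rec$til <- ifelse(s == "present", "absent", "present")
  sa_rec <- stratified_association(x, ann_rec, "til", model = "logistic")
  expect_equal(sa_rec$p_interaction[1], sa$p_interaction[1], tolerance = 1e-6)
  ann_const <- ann; ann_const$til <- "present"
  expect_error(stratified_association(x, ann_const, "til", "logistic"),
               "two observed levels")
})

test_that("null interactions are rarely significant", {
  hits <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    s <- rep(c("present", "absent"), each = 60)
    x <- rnorm(120)
    y <- rbinom(120, 1, plogis(-0.5 + 0.8 * x))
    ann <- toy_annotations(ifelse(y == 1, "resistant", "sensitive"), til = s)
    tryCatch(stratified_association(x, ann, "til",
                                    "logistic")$p_interaction[1] <= 0.05,
             error = function(e) NA)
  }, logical(1))
  expect_gte(mean(!hits, na.rm = TRUE), 0.90)
})

test_that("cytolytic activity is the offset geometric mean of GZMA and PRF1", {
  m <- expr_matrix(matrix(c(4, 9, 0, 0), 2, 2,
                          dimnames = list(c("GZMA", "PRF1"), c("s1", "s2"))),
                   "fpkm")
  expect_equal(unname(cytolytic_activity(m, offset = 0)["s1"]), 6)
  expect_equal(unname(cytolytic_activity(m, offset = 0.01)["s2"]), 0.01)
  # equal expression recovers the common value when offset = 0
  m2 <- expr_matrix(matrix(c(5, 5), 2, 1,
                           dimnames = list(c("GZMA", "PRF1"), "s1")), "fpkm")
  expect_equal(unname(cytolytic_activity(m2, offset = 0)), 5)
  expect_error(cytolytic_activity(m[1, , drop = FALSE]), "not found")
})

test_that("modifier screen flags planted attenuating interactions with direction", {
  set.seed(23)
  n <- 400
  a <- rnorm(n); g <- rnorm(n)
  # anchor effect positive, interaction negative: attenuating modifier
  y <- rbinom(n, 1, plogis(-0.8 + 1 * a - 1.2 * a * g))
  X <- rbind(EZH2 = a, mod = g, null1 = rnorm(n), null2 = rnorm(n))
  colnames(X) <- sprintf("s%03d", 1:n)
  ann <- toy_annotations(ifelse(y == 1, "resistant", "sensitive"))
  ms <- modifier_screen(expr_matrix(X, "log2"), "EZH2", ann,
                        flag_rule = "p_threshold", threshold = 0.02)
  row <- ms[ms$gene_id == "mod", ]
  expect_true(row$flagged)
  expect_identical(row$direction, "negative")
  expect_lt(row$p_interaction, 0.001)
})

test_that("modifier screen is calibrated under the no-interaction null", {
  cfg <- generator_config(n_sensitive = 150, n_resistant = 150, n_genes = 500,
                          n_modifiers = 0, beta_anchor = 0, seed = 22)
  sim <- generate_modifier_cohort(cfg)
  ms <- modifier_screen(sim$expr, "EZH2", sim$annotations,
                        flag_rule = "p_threshold", threshold = 0.05)
  expect_lt(abs(mean(ms$flagged, na.rm = TRUE) - 0.05), 0.02)
})
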