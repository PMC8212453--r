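test_that("TSV round trip preserves values, layer and missingness", {
  m <- toy_matrix(3, 2, layer = "protein", seed = 4)
  m[2, 1] <- NA
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, f)
  m2 <- read_expression_matrix(f, "protein")
  expect_identical(dim(m2), c(3L, 2L))
  expect_identical(rownames(m2), rownames(m))
  expect_equal(unclass(m2), unclass(m))
  expect_identical(layer(m2), "protein")
  expect_identical(is.na(unclass(m2)), is.na(unclass(m)))
})

test_that("malformed input is rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "a\t1", "a\t2"), f)
  expect_error(read_expression_matrix(f, "counts"), "duplicate gene ids")
  writeLines("justonefield", f)
  expect_error(read_expression_matrix(f, "counts"), "malformed header")
  expect_error(expr_matrix(matrix(1:4, 2, 2), "counts"), "rownames")
  expect_error(
    expr_matrix(matrix(c(1, -1, 0, 2), 2, 2,
                       dimnames = list(c("a", "b"), c("s1", "s2"))), "counts"),
    "non-negative")
  expect_error(
    expr_matrix(matrix(c(1, NA, 0, 2), 2, 2,
                       dimnames = list(c("a", "b"), c("s1", "s2"))), "fpkm"),
    "missing")
})

test_that("blank protein cells parse as missing with correct counts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "p1\t0.5\t\t1.2",
               "p2\t\t\t-0.7",
               "p3\t0.1\t0.2\t0.3"), f)
  m <- read_expression_matrix(f, "protein")
  expect_identical(sum(!is.na(unclass(m))), 6L)
  expect_equal(unname(rowSums(!is.na(unclass(m)))), c(2, 1, 3))
})

test_that("counts_to_fpkm applies the FPKM formula", {
  # single gene: c = 10, L = 1000 bp, library = 1e6 -> FPKM = 10
  cm <- expr_matrix(matrix(c(10L, 999990L), 2, 1,
                           dimnames = list(c("a", "fill"), "s1")), "counts")
  f <- counts_to_fpkm(cm, c(a = 1000, fill = 1000))
  expect_equal(unclass(f)["a", 1], 10)

  # two-gene toy, hand-computed: L = (500, 2000), c = (5, 20), N = 25
  cm2 <- expr_matrix(matrix(c(5L, 20L), 2, 1,
                            dimnames = list(c("a", "b"), "s1")), "counts")
  f2 <- counts_to_fpkm(cm2, c(a = 500, b = 2000))
  expect_equal(unname(unclass(f2)[, 1]),
               c(1e9 * 5 / (500 * 25), 1e9 * 20 / (2000 * 25)))

  # all-zero gene row stays zero; conservation: sum FPKM * L / 1e9 = 1
  cm3 <- expr_matrix(matrix(c(0L, 7L, 3L, 0L, 14L, 6L), 3, 2,
                            dimnames = list(c("z", "a", "b"),
                                            c("s1", "s2"))), "counts")
  L <- c(z = 100, a = 250, b = 4000)
  f3 <- counts_to_fpkm(cm3, L)
  expect_true(all(unclass(f3)["z", ] == 0))
  expect_equal(unname(colSums(unclass(f3) * L / 1e9)), c(1, 1))
})

test_that("counts_to_fpkm honours size factors and rejects bad input", {
  cm <- expr_matrix(matrix(c(5L, 20L, 10L, 40L), 2, 2,
                           dimnames = list(c("a", "b"), c("s1", "s2"))),
                    "counts")
  L <- c(a = 500, b = 2000)
  sf <- c(s1 = 0.5, s2 = 1.5)
  f <- counts_to_fpkm(cm, L, size_factors = sf)
  mean_lib <- mean(colSums(cm))
  expect_equal(unclass(f)["a", "s1"], 1e9 * 5 / (500 * 0.5 * mean_lib))
  expect_error(counts_to_fpkm(cm, c(a = 500)), "missing gene length")
  cm0 <- expr_matrix(matrix(c(0L, 0L), 2, 1,
                            dimnames = list(c("a", "b"), "s1")), "counts")
  expect_error(counts_to_fpkm(cm0, L), "zero library size")
  expect_error(counts_to_fpkm(log2_transform(cm), L), "layer")
})

test_that("log2_transform is the shifted log and preserves missingness", {
  m <- expr_matrix(matrix(c(0, 3, 7, NA), 2, 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))),
                   "protein")
  lt <- log2_transform(m, offset = 1)
  expect_equal(unclass(lt)[1:3], c(0, 2, 3))
  expect_true(is.na(unclass(lt)[2, 2]))
  expect_identical(layer(lt), "log2")
  m2 <- expr_matrix(matrix(c(-1, 1), 1, 2,
                           dimnames = list("a", c("s1", "s2"))), "protein")
  expect_error(log2_transform(m2), "non-negative")
})

test_that("median-quantile filter keeps genes strictly above the cut", {
  # medians exactly 1..10; type-7 30th percentile of 1..10 is 3.7
  m <- expr_matrix(matrix(rep(1:10, times = 4), 10, 4,
                          dimnames = list(sprintf("g%02d", 1:10),
                                          sprintf("s%d", 1:4))), "log2")
  kept <- filter_by_median_quantile(m, 0.30)
  expect_identical(rownames(kept), sprintf("g%02d", 4:10))  # order preserved
  # quantile 0 with distinct medians keeps everything above the minimum
  expect_identical(rownames(filter_by_median_quantile(m, 0)),
                   sprintf("g%02d", 2:10))
  # identical medians: strict inequality removes everything, with warning
  m2 <- expr_matrix(matrix(5, 4, 3,
                           dimnames = list(letters[1:4], c("s1", "s2", "s3"))),
                    "log2")
  expect_warning(out <- filter_by_median_quantile(m2, 0.30), "every gene")
  expect_identical(nrow(out), 0L)
})

test_that("missingness filter uses an inclusive bound and is idempotent", {
  vals <- matrix(NA_real_, 3, 100,
                 dimnames = list(c("keep30", "drop29", "full"),
                                 sprintf("s%03d", 1:100)))
  vals["keep30", 1:30] <- 1
  vals["drop29", 1:29] <- 1
  vals["full", ] <- 1
  m <- expr_matrix(vals, "protein")
  kept <- filter_by_missingness(m, 0.30)
  expect_identical(rownames(kept), c("keep30", "full"))
  expect_identical(unclass(filter_by_missingness(kept, 0.30)), unclass(kept))
  expect_identical(rownames(filter_by_missingness(m, 1)), "full")
})

test_that("annotation validation enforces the controlled vocabulary", {
  good <- data.frame(sample_id = c("a", "b"), rtt = c("sensitive", "resistant"),
                     purity = c(0.5, 1), survival_months = c(0, 12),
                     event = c("censored", "died"), til = c("present", "absent"))
  expect_s3_class(sample_annotations(good), "sample_annotations")
  bad <- good; bad$rtt[1] <- "refractory"
  expect_error(sample_annotations(bad), "invalid value")
  bad <- good; bad$purity[1] <- 0
  expect_error(sample_annotations(bad), "purity")
  bad <- good; bad$survival_months[1] <- -1
  expect_error(sample_annotations(bad), "non-negative")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_annotations(sample_annotations(good), f)
  expect_equal(read_sample_annotations(f)$purity, good$purity)
})
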