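# shared fixtures and independent oracles, built in code at test time

toy_matrix <- function(nr = 3, nc = 4, layer = "log2", seed = 1,
                       genes = sprintf("g%02d", seq_len(nr)),
                       samples = sprintf("s%02d", seq_len(nc))) {
  set.seed(seed)
  expr_matrix(matrix(rnorm(nr * nc), nr, nc,
                     dimnames = list(genes, samples)), layer)
}

toy_annotations <- function(rtt, ...) {
  sample_annotations(data.frame(sample_id = sprintf("s%03d", seq_along(rtt)),
                                rtt = rtt, ..., stringsAsFactors = FALSE))
}

# independent planarity oracle: networkx via the system python
nx_is_planar <- function(edges) {
  ef <- tempfile(fileext = ".txt")
  writeLines(paste(edges[, 1], edges[, 2]), ef)
  script <- paste0(
    "import sys, networkx as nx\n",
    "G = nx.Graph()\n",
    "for line in open(sys.argv[1]):\n",
    "    a, b = line.split()\n",
    "    G.add_edge(a, b)\n",
    "print(int(nx.check_planarity(G)[0]))\n")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2("python", c(sf, ef), stdout = TRUE)
  unlink(c(ef, sf))
  identical(trimws(out[length(out)]), "1")
}

# brute-force Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exhaustive-enumeration oracle for the differential-correlation
# permutation p-value (plain Pearson within groups, no covariate)
perm_p_oracle <- function(X, anchor_id, n1) {
  n <- ncol(X)
  a <- X[anchor_id, ]
  G <- X[setdiff(rownames(X), anchor_id), , drop = FALSE]
  zd <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    vapply(rownames(G), function(g) {
      r1 <- cor(a[idx1], G[g, idx1]); r2 <- cor(a[idx2], G[g, idx2])
      abs((atanh(r1) - atanh(r2)) /
            sqrt(1 / (length(idx1) - 3) + 1 / (length(idx2) - 3)))
    }, numeric(1))
  }
  sets <- combn(n, n1, simplify = FALSE)
  Z <- vapply(sets, zd, numeric(nrow(G)))
  obs <- zd(seq_len(n1))
  rowMeans(Z >= obs)
}

# adjusted Rand index between two partitions (contingency-table form)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2)); sum_b <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  exp_ij <- sum_a * sum_b / np
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}
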