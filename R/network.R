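# ---- left-right planarity test -------------------------------------------
#
# Boolean planarity check via the left-right (LR) criterion: a DFS
# orientation phase computes lowpoints and nesting depths, then a
# constraint phase maintains a stack of conflict pairs of back-edge
# intervals; the graph is planar iff the constraints never force a
# same-side conflict. Both phases are iterative (explicit stacks), so
# deep DFS trees cannot overflow the call stack.
#
# edges: 2-column integer matrix (1-based vertex ids), simple undirected
# graph (no self-loops / duplicates). Intervals are encoded as pairs of
# edge ids with 0 = "none".

.lr_planarity <- function(edges, n) {
  m <- nrow(edges)
  if (m == 0 || m <= 8) return(TRUE)   # smallest non-planar graph (K3,3) has 9 edges
  if (m > 3 * n - 6) return(FALSE)

  # adjacency: per vertex, incident edge ids and the opposite endpoint
  adj_e <- vector("list", n); adj_w <- vector("list", n)
  for (k in seq_len(m)) {
    u <- edges[k, 1]; v <- edges[k, 2]
    adj_e[[u]] <- c(adj_e[[u]], k); adj_w[[u]] <- c(adj_w[[u]], v)
    adj_e[[v]] <- c(adj_e[[v]], k); adj_w[[v]] <- c(adj_w[[v]], u)
  }

  height <- rep(-1L, n)
  parent_edge <- integer(n)              # 0 = root
  src <- dst <- integer(m)               # orientation assigned in dfs1
  oriented <- logical(m)
  is_tree <- logical(m)
  lowpt <- lowpt2 <- integer(m)
  nesting <- integer(m)

  finalize <- function(k) {
    nesting[k] <<- 2L * lowpt[k]
    if (lowpt2[k] < height[src[k]]) nesting[k] <<- nesting[k] + 1L
    e <- parent_edge[src[k]]
    if (e > 0L) {
      if (lowpt[k] < lowpt[e]) {
        lowpt2[e] <<- min(lowpt[e], lowpt2[k]); lowpt[e] <<- lowpt[k]
      } else if (lowpt[k] > lowpt[e]) {
        lowpt2[e] <<- min(lowpt2[e], lowpt[k])
      } else {
        lowpt2[e] <<- min(lowpt2[e], lowpt2[k])
      }
    }
  }

  # phase 1: iterative DFS orientation
  for (root in seq_len(n)) {
    if (height[root] != -1L) next
    height[root] <- 0L
    sv <- root; si <- 1L                  # current vertex / adjacency index
    stack_v <- integer(0); stack_i <- integer(0)
    repeat {
      advanced <- FALSE
      ae <- adj_e[[sv]]
      while (si <= length(ae)) {
        k <- ae[si]; w <- adj_w[[sv]][si]; si <- si + 1L
        if (oriented[k]) next
        oriented[k] <- TRUE; src[k] <- sv; dst[k] <- w
        lowpt[k] <- height[sv]; lowpt2[k] <- height[sv]
        if (height[w] == -1L) {           # tree edge: descend
          is_tree[k] <- TRUE
          parent_edge[w] <- k
          height[w] <- height[sv] + 1L
          stack_v <- c(stack_v, sv); stack_i <- c(stack_i, si)
          sv <- w; si <- 1L
          advanced <- TRUE
          break
        } else {                          # back edge: finalize now
          lowpt[k] <- height[w]
          finalize(k)
        }
      }
      if (advanced) next
      # adjacency of sv exhausted: pop, finalizing the tree edge into sv
      if (sv == root) break
      k <- parent_edge[sv]
      top <- length(stack_v)
      sv <- stack_v[top]; si <- stack_i[top]
      stack_v <- stack_v[-top]; stack_i <- stack_i[-top]
      finalize(k)
    }
  }

  # ordered outgoing adjacency by nesting depth
  out_adj <- vector("list", n)
  for (k in seq_len(m)) out_adj[[src[k]]] <- c(out_adj[[src[k]]], k)
  for (v in seq_len(n)) {
    ks <- out_adj[[v]]
    if (length(ks) > 1) out_adj[[v]] <- ks[order(nesting[ks])]
  }

  # phase 2: constraint resolution. The stack of conflict pairs lives in
  # four parallel integer vectors (left/right interval low/high edge ids,
  # 0 = none); stack_bottom stores stack heights.
  ref <- integer(m)
  lowpt_edge <- integer(m)
  stack_bottom <- integer(m)
  s_top <- 0L
  SL <- SH <- SRl <- SRh <- integer(m + 2L)

  pushS <- function(ll, lh, rl, rh) {
    s_top <<- s_top + 1L
    SL[s_top] <<- ll; SH[s_top] <<- lh; SRl[s_top] <<- rl; SRh[s_top] <<- rh
  }
  conflicting <- function(lo, hi, b) hi != 0L && lowpt[hi] > lowpt[b]
  lowest_top <- function() {
    # lowest lowpoint of the top conflict pair
    ll <- SL[s_top]; rl <- SRl[s_top]
    if (ll == 0L) return(lowpt[rl])
    if (rl == 0L) return(lowpt[ll])
    min(lowpt[ll], lowpt[rl])
  }

  add_constraints <- function(ei, e) {
    pll <- plh <- prl <- prh <- 0L
    # merge return edges of ei into P.R
    repeat {
      ll <- SL[s_top]; lh <- SH[s_top]; rl <- SRl[s_top]; rh <- SRh[s_top]
      s_top <<- s_top - 1L
      if (ll != 0L || lh != 0L) { t1 <- ll; ll <- rl; rl <- t1
                                  t2 <- lh; lh <- rh; rh <- t2 }
      if (ll != 0L || lh != 0L) return(FALSE)      # not planar
      if (rl != 0L || rh != 0L) {                  # skip fully trimmed pairs
        if (lowpt[rl] > lowpt[e]) {                # merge interval
          if (prl == 0L && prh == 0L) { prl <- rl; prh <- rh }
          else { ref[prl] <<- rh; prl <- rl }
        } else {                                   # align
          ref[rl] <<- lowpt_edge[e]
        }
      }
      if (s_top == stack_bottom[ei]) break
    }
    # merge conflicting return edges of e_1 .. e_{i-1} into P.L
    while (s_top > 0L &&
           (conflicting(SL[s_top], SH[s_top], ei) ||
            conflicting(SRl[s_top], SRh[s_top], ei))) {
      ll <- SL[s_top]; lh <- SH[s_top]; rl <- SRl[s_top]; rh <- SRh[s_top]
      s_top <<- s_top - 1L
      if (conflicting(rl, rh, ei)) { t1 <- ll; ll <- rl; rl <- t1
                                     t2 <- lh; lh <- rh; rh <- t2 }
      if (conflicting(rl, rh, ei)) return(FALSE)   # not planar
      # merge interval below lowpt(ei) into P.R
      ref[prl] <<- rh
      if (rl != 0L) prl <- rl
      if (pll == 0L && plh == 0L) { pll <- ll; plh <- lh }
      else { ref[pll] <<- lh; pll <- ll }
    }
    if (pll != 0L || plh != 0L || prl != 0L || prh != 0L)
      pushS(pll, plh, prl, prh)
    TRUE
  }

  remove_back_edges <- function(e) {
    u <- src[e]
    # drop conflict pairs consisting solely of back edges returning to u
    while (s_top > 0L && lowest_top() == height[u]) s_top <<- s_top - 1L
    if (s_top > 0L) {                              # trim the next pair
      ll <- SL[s_top]; lh <- SH[s_top]; rl <- SRl[s_top]; rh <- SRh[s_top]
      s_top <<- s_top - 1L
      while (lh != 0L && dst[lh] == u) lh <- ref[lh]
      if (lh == 0L && ll != 0L) { ref[ll] <<- rl; ll <- 0L }
      while (rh != 0L && dst[rh] == u) rh <- ref[rh]
      if (rh == 0L && rl != 0L) { ref[rl] <<- ll; rl <- 0L }
      pushS(ll, lh, rl, rh)
    }
    # side of e is the side of its highest return edge
    if (lowpt[e] < height[u] && s_top > 0L) {
      hl <- SH[s_top]; hr <- SRh[s_top]
      if (hl != 0L && (hr == 0L || lowpt[hl] > lowpt[hr])) ref[e] <- hl
      else ref[e] <- hr
    }
  }

  # iterative dfs over the ordered adjacency (mirrors the orientation DFS)
  for (root in seq_len(n)) {
    if (parent_edge[root] != 0L || height[root] != 0L) next
    sv <- root; si <- 1L; pending <- 0L  # pending tree edge just returned from
    stack_v <- integer(0); stack_i <- integer(0)
    repeat {
      advanced <- FALSE
      oe <- out_adj[[sv]]
      while (si <= length(oe)) {
        ei <- oe[si]
        if (pending == ei) {
          pending <- 0L                    # resumed after child: skip init
        } else {
          stack_bottom[ei] <- s_top
          if (is_tree[ei]) {               # descend into child
            stack_v <- c(stack_v, sv); stack_i <- c(stack_i, si)
            sv <- dst[ei]; si <- 1L
            advanced <- TRUE
            break
          }
          lowpt_edge[ei] <- ei             # back edge
          pushS(0L, 0L, ei, ei)
        }
        # integrate new return edges of ei
        if (lowpt[ei] < height[sv]) {
          e <- parent_edge[sv]
          if (ei == oe[1]) lowpt_edge[e] <- lowpt_edge[ei]
          else if (!add_constraints(ei, e)) return(FALSE)
        }
        si <- si + 1L
      }
      if (advanced) next
      # adjacency of sv exhausted: remove back edges returning to parent
      e <- parent_edge[sv]
      if (e != 0L) remove_back_edges(e)
      if (sv == root) break
      top <- length(stack_v)
      sv <- stack_v[top]; si <- stack_i[top]
      stack_v <- stack_v[-top]; stack_i <- stack_i[-top]
      pending <- e                         # finish the integrate block for e
    }
  }
  TRUE
}

#' Planarity test for an undirected simple graph
#'
#' Left-right planarity criterion; linear-time in vertices + edges.
#'
#' @param edges two-column matrix (or data.frame) of vertex ids
#'   (integers or labels) describing undirected edges; self-loops and
#'   duplicate edges are rejected.
#' @return `TRUE` if the graph admits a planar embedding.
#' @export
is_planar_graph <- function(edges) {
  edges <- as.matrix(edges)
  if (nrow(edges) == 0) return(TRUE)
  labs <- sort(unique(as.vector(edges)))
  a <- match(edges[, 1], labs); b <- match(edges[, 2], labs)
  if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
  key <- paste(pmin(a, b), pmax(a, b))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed", call. = FALSE)
  .lr_planarity(cbind(a, b), length(labs))
}

# ---- planar filtered network ---------------------------------------------

.new_gene_network <- function(nodes, edges, modules = NULL) {
  structure(list(nodes = nodes, edges = edges, modules = modules),
            class = "gene_network")
}

#' Build a planar filtered network from candidate edges
#'
#' Candidate edges are ranked by ascending significance p, ties broken
#' by descending |z| then lexicographic gene pair, and inserted greedily:
#' an edge is kept iff the growing graph stays planar. The result is the
#' planar filtered network (PFN) of the candidate set, a deterministic
#' function of the candidate list (input order is irrelevant).
#'
#' @param candidate_edges data.frame with columns `gene_a`, `gene_b`,
#'   `p` (significance of the pair) and `weight` (|z_diff| or another
#'   tie-breaking strength). Pairs are undirected; duplicates keep the
#'   best-ranked record.
#' @return A `gene_network`: list with `nodes`, `edges` (gene_a, gene_b,
#'   weight, rank — gene_a < gene_b lexicographically), and `modules`
#'   (NULL until [detect_modules()] is run).
#' @export
build_pfn <- function(candidate_edges) {
  d <- as.data.frame(candidate_edges)
  stopifnot(all(c("gene_a", "gene_b", "p") %in% names(d)))
  if (!"weight" %in% names(d)) d$weight <- 0
  if (nrow(d) == 0) stop("candidate edge list is empty", call. = FALSE)
  a <- pmin(as.character(d$gene_a), as.character(d$gene_b))
  b <- pmax(as.character(d$gene_a), as.character(d$gene_b))
  if (any(a == b)) stop("self-loop in candidate edges", call. = FALSE)
  d$gene_a <- a; d$gene_b <- b
  d <- d[order(d$p, -abs(d$weight), d$gene_a, d$gene_b), , drop = FALSE]
  d <- d[!duplicated(paste(d$gene_a, d$gene_b, sep = "\r")), , drop = FALSE]

  labs <- sort(unique(c(d$gene_a, d$gene_b)))
  ia <- match(d$gene_a, labs); ib <- match(d$gene_b, labs)
  nv <- length(labs)
  seen <- logical(nv)
  parent <- seq_len(nv)                    # union-find over components
  csize <- rep(1L, nv); cedge <- integer(nv)  # per-component bookkeeping
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  acc_a <- integer(0); acc_b <- integer(0)
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    u <- ia[i]; v <- ib[i]
    ok <- if (!seen[u] || !seen[v]) {
      TRUE                                  # pendant vertex: planarity kept
    } else if (find(u) != find(v)) {
      TRUE                                  # bridges two planar components
    } else {
      # test only the component the new edge lands in; the 3n - 6 edge
      # bound rejects saturated components without running the test
      comp <- find(u)
      if (csize[comp] >= 3 && cedge[comp] + 1L > 3L * csize[comp] - 6L) {
        FALSE
      } else {
        inc <- vapply(seq_along(acc_a), function(j) find(acc_a[j]) == comp,
                      logical(1))
        is_planar_graph(cbind(c(acc_a[inc], u), c(acc_b[inc], v)))
      }
    }
    if (ok) {
      keep[i] <- TRUE
      acc_a <- c(acc_a, u); acc_b <- c(acc_b, v)
      seen[u] <- TRUE; seen[v] <- TRUE
      ru <- find(u); rv <- find(v)
      if (ru == rv) {
        cedge[ru] <- cedge[ru] + 1L
      } else {
        parent[ru] <- rv
        csize[rv] <- csize[rv] + csize[ru]
        cedge[rv] <- cedge[rv] + cedge[ru] + 1L
      }
    }
  }
  ed <- d[keep, c("gene_a", "gene_b", "weight"), drop = FALSE]
  ed$rank <- seq_len(nrow(ed))
  rownames(ed) <- NULL
  .new_gene_network(sort(unique(c(ed$gene_a, ed$gene_b))), ed)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (!is.null(x$modules))
    cat(sprintf(", %d modules", length(unique(x$modules))))
  cat("\n")
  invisible(x)
}

# leading-eigenvector bipartition of one subgraph's modularity matrix;
# returns logical side vector or NULL if no modularity-improving split
.modularity_bipartition <- function(A) {
  deg <- rowSums(A); m2 <- sum(deg)
  if (m2 == 0) return(NULL)
  B <- A - outer(deg, deg) / m2
  es <- eigen(B, symmetric = TRUE)
  v <- es$vectors[, 1]
  nz <- which(abs(v) > 1e-12)
  if (!length(nz)) return(NULL)
  if (v[nz[1]] < 0) v <- -v                # deterministic sign convention
  s <- ifelse(v >= 0, 1, -1)
  if (all(s == s[1])) return(NULL)
  gain <- sum(s * (B %*% s)) / (2 * m2)    # dQ of the bipartition
  if (gain <= 1e-10) return(NULL)
  s > 0
}

#' Hierarchical module detection on a gene network
#'
#' Connected components are split recursively by the
#' modularity-maximising spectral bipartition (leading eigenvector of
#' the subgraph's modularity matrix) until the modularity gain is
#' non-positive or a component falls below `min_size`. Module labels
#' encode the split path (e.g. `"2.1.2"`). Deterministic given node
#' ordering.
#'
#' @param net a `gene_network` from [build_pfn()].
#' @param min_size smallest component that may be split further
#'   (default 10).
#' @return The network with `modules`: a named character vector mapping
#'   every node to its module label (a partition).
#' @export
detect_modules <- function(net, min_size = 10) {
  stopifnot(inherits(net, "gene_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  comp <- igraph::components(g)
  modules <- stats::setNames(character(length(net$nodes)), net$nodes)
  recurse <- function(nodes, label) {
    if (length(nodes) < min_size) { modules[nodes] <<- label; return() }
    A <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, nodes), sparse = FALSE)
    A <- A[nodes, nodes, drop = FALSE]     # fix ordering
    side <- .modularity_bipartition(A)
    if (is.null(side)) { modules[nodes] <<- label; return() }
    left <- nodes[side]; right <- nodes[!side]
    # child 1 = the side containing the alphabetically first node
    if (min(right) < min(left)) { tmp <- left; left <- right; right <- tmp }
    recurse(left, paste0(label, ".1"))
    recurse(right, paste0(label, ".2"))
  }
  ord <- order(vapply(seq_len(comp$no), function(k)
    min(net$nodes[comp$membership == k]), character(1)))
  for (k in seq_along(ord))
    recurse(net$nodes[comp$membership == ord[k]], as.character(k))
  net$modules <- modules
  net
}

#' Export a gene network
#'
#' `edge_list`: TSV with columns gene_a, gene_b, weight, rank, plus
#' node module labels in the companion columns module_a/module_b;
#' re-importable with [import_network()]. `graphml`: GraphML with module
#' written as a node attribute, consumable by Cytoscape and igraph.
#'
#' @param net a `gene_network`.
#' @param path output file path.
#' @param format `"edge_list"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_list", "graphml")) {
  stopifnot(inherits(net, "gene_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network format",
                                              call. = FALSE))
  mods <- net$modules
  if (is.null(mods)) mods <- stats::setNames(rep(NA_character_, length(net$nodes)),
                                             net$nodes)
  if (format == "edge_list") {
    ed <- net$edges
    ed$module_a <- unname(mods[ed$gene_a])
    ed$module_b <- unname(mods[ed$gene_b])
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b", "weight")],
                                       directed = FALSE, vertices = net$nodes)
    igraph::V(g)$module <- unname(mods[igraph::V(g)$name])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an exported edge-list network
#'
#' @param path file written by [export_network()] with
#'   `format = "edge_list"`.
#' @return A `gene_network` (with modules if they were present).
#' @export
import_network <- function(path) {
  ed <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "weight", "rank") %in% names(ed)))
  nodes <- sort(unique(c(ed$gene_a, ed$gene_b)))
  modules <- NULL
  if ("module_a" %in% names(ed) && !all(is.na(ed$module_a))) {
    modules <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
    modules[ed$gene_a] <- ed$module_a
    modules[ed$gene_b] <- ed$module_b
  }
  .new_gene_network(nodes, ed[, c("gene_a", "gene_b", "weight", "rank")], modules)
}
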