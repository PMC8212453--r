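#' Read a gene-set collection in GMT format
#'
#' One set per line: set id, description, then member gene ids, tab
#' delimited. Members duplicated within a set are removed with a
#' warning; a line with fewer than 3 fields is a format error.
#'
#' @param path GMT file path.
#' @return A named list (classed `gene_set_collection`); each element
#'   has `description` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(list(), class = "gene_set_collection"))
  }
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (need id, description, >= 1 member): ",
           substr(ln, 1, 50), call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate member(s) in set ", f[1], "; deduplicated",
              call. = FALSE)
      genes <- unique(genes)
    }
    list(id = f[1], description = f[2], genes = genes)
  })
  out <- stats::setNames(lapply(sets, function(s) s[c("description", "genes")]),
                         vapply(sets, `[[`, character(1), "id"))
  structure(out, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets\n", length(x)))
  invisible(x)
}

#' Gene-set overrepresentation test
#'
#' Hypergeometric upper-tail test of the overlap between a query gene
#' list and each set, within a stated universe: for overlap k the
#' p-value is P(X >= k) with X hypergeometric on (|universe|,
#' |set within universe|, |query|). Sets are intersected with the
#' universe first; sets with no universe overlap are skipped. q-values
#' are Benjamini-Hochberg across the tested sets.
#'
#' @param query character vector of genes of interest; must be a subset
#'   of `universe`.
#' @param universe character vector of all genes eligible to be in the
#'   query (e.g. all genes surviving the expression filter).
#' @param sets a [read_gmt()] collection (or named list of gene id
#'   vectors).
#' @return data.frame with `set_id`, `set_size` (within universe),
#'   `k` (overlap), `p`, `q`, ordered as in `sets`.
#' @export
overrepresentation <- function(query, universe, sets) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  out_q <- setdiff(query, universe)
  if (length(out_q))
    stop("query gene(s) outside universe: ",
         paste(utils::head(out_q, 5), collapse = ", "), call. = FALSE)
  members <- lapply(sets, function(s) if (is.list(s)) s$genes else s)
  rows <- lapply(names(members), function(id) {
    g <- intersect(members[[id]], universe)
    if (!length(g)) return(NULL)
    k <- length(intersect(g, query))
    # upper tail including k: P(X >= k)
    p <- stats::phyper(k - 1, length(g), length(universe) - length(g),
                       length(query), lower.tail = FALSE)
    data.frame(set_id = id, set_size = length(g), k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(set_id = character(), set_size = integer(),
                      k = integer(), p = numeric(), q = numeric()))
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
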