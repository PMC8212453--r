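#' Expression matrix container
#'
#' A light container for one expression layer: a numeric genes x samples
#' matrix with unique row (gene) and column (sample) names plus a `layer`
#' tag declaring what the values are. Protein layers may carry missing
#' values; count layers must be non-negative integers.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   have unique, non-empty dimnames.
#' @param layer one of `"counts"`, `"fpkm"`, `"log2"`, `"protein"`.
#' @return An object of class `expr_matrix`: the matrix with a `layer`
#'   attribute.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- expr_matrix(m, "counts")
#' layer(em)
#' @export
expr_matrix <- function(values, layer = c("counts", "fpkm", "log2", "protein")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gn <- rownames(values); sn <- colnames(values)
  if (is.null(gn) || is.null(sn))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(gn))
    stop("duplicate gene ids: ", paste(unique(gn[duplicated(gn)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sn))
    stop("duplicate sample ids: ", paste(unique(sn[duplicated(sn)]), collapse = ", "),
         call. = FALSE)
  if (layer %in% c("counts", "fpkm")) {
    if (anyNA(values))
      stop(layer, " layer must not contain missing values", call. = FALSE)
    if (any(values < 0))
      stop(layer, " layer must be non-negative", call. = FALSE)
    if (layer == "counts" && any(values != round(values)))
      stop("counts layer must be integer-valued", call. = FALSE)
  }
  structure(values, layer = layer, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
layer <- function(x) attr(x, "layer")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, layer = %s",
              nrow(x), ncol(x), layer(x)))
  nm <- sum(is.na(x))
  if (nm > 0) cat(sprintf(", %d missing (%.1f%%)", nm, 100 * nm / length(x)))
  cat("\n")
  invisible(x)
}

# subsetting keeps class and layer; drops to plain numeric when dims drop
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, layer = attr(x, "layer"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, first column of gene ids, tab
#' delimited; empty cells are parsed as missing. Duplicate gene or sample
#' ids are rejected.
#'
#' @param path file path.
#' @param layer layer tag, see [expr_matrix()].
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, layer = c("counts", "fpkm", "log2", "protein")) {
  layer <- match.arg(layer)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header: expected gene-id column plus >= 1 sample column",
         call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = c("character", rep("numeric", length(header) - 1L)),
                          na.strings = c("", "NA"))
  if (anyDuplicated(df[[1]]))
    stop("duplicate gene ids in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, layer)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: missing values are written as
#' empty cells, full double precision is preserved.
#'
#' @param m an [expr_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = rownames(m),
                   format(unclass(m), digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(unclass(m))] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.rtt_levels     <- c("sensitive", "resistant")
.event_levels   <- c("censored", "died")
.stage_levels   <- c("early", "advanced")
.rd_levels      <- c("optimal", "suboptimal")
.subtype_levels <- c("immunoreactive", "proliferative", "mesenchymal", "differentiated")
.immune_levels  <- c("desert", "excluded", "infiltrated")
.flag_levels    <- c("absent", "present")
.brca_levels    <- c("carrier", "noncarrier", "unknown")
.morph_flags    <- c("til", "lvi", "stic", "cystic",
                     "papillary", "micropapillary", "solid", "pseudoglandular")

#' Validate a sample annotation table
#'
#' Checks the controlled vocabulary and numeric ranges of the per-sample
#' clinical record used throughout the pipeline: response to therapy
#' (`rtt`: sensitive/resistant), survival, tumor purity in (0, 1],
#' covariates and optional morphology flags.
#'
#' @param ann a data.frame with at least `sample_id`; recognised columns
#'   are `rtt`, `survival_months`, `event`, `purity`, `age_years`,
#'   `stage`, `residual_disease`, `subtype`, `immune_phenotype`, `brca`
#'   and the morphology flags `til`, `lvi`, `stic`, `cystic`,
#'   `papillary`, `micropapillary`, `solid`, `pseudoglandular`.
#' @return The validated data.frame (classed `sample_annotations`).
#' @export
sample_annotations <- function(ann) {
  stopifnot(is.data.frame(ann), "sample_id" %in% names(ann))
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample ids in annotations", call. = FALSE)
  chk <- function(col, levels) {
    if (!col %in% names(ann)) return()
    v <- ann[[col]]
    bad <- !is.na(v) & !(v %in% levels)
    if (any(bad))
      stop(sprintf("invalid value(s) in `%s`: %s (allowed: %s)", col,
                   paste(unique(v[bad]), collapse = ", "),
                   paste(levels, collapse = ", ")), call. = FALSE)
  }
  chk("rtt", .rtt_levels); chk("event", .event_levels)
  chk("stage", .stage_levels); chk("residual_disease", .rd_levels)
  chk("subtype", .subtype_levels); chk("immune_phenotype", .immune_levels)
  chk("brca", .brca_levels)
  for (f in .morph_flags) chk(f, .flag_levels)
  if ("purity" %in% names(ann)) {
    p <- ann$purity
    if (any(!is.na(p) & (p <= 0 | p > 1)))
      stop("purity must lie in (0, 1]", call. = FALSE)
  }
  if ("survival_months" %in% names(ann)) {
    s <- ann$survival_months
    if (any(!is.na(s) & s < 0))
      stop("survival_months must be non-negative", call. = FALSE)
  }
  class(ann) <- c("sample_annotations", "data.frame")
  ann
}

#' Read sample annotations from TSV
#'
#' @param path file path to a tab-delimited annotation table with a
#'   `sample_id` column.
#' @return A validated [sample_annotations()] data.frame.
#' @export
read_sample_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c("", "NA"), stringsAsFactors = FALSE)
  sample_annotations(ann)
}

#' Write sample annotations to TSV
#' @param ann a [sample_annotations()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotations <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
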