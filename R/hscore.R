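#' H-score from nuclei intensity bins
#'
#' The immunohistochemistry H-score of a core is the percentage of
#' positively stained nuclei weighted by intensity bin:
#' H = sum over i in \{1, 2, 3\} of i * 100 * count_i / total, giving a
#' value in [0, 300]. The same formula serves manual and digital
#' (algorithm-derived) bin counts.
#'
#' @param counts named numeric vector (or 1-row data.frame) of nuclei
#'   counts per intensity bin with names `"0"`, `"1"`, `"2"`, `"3"`
#'   (missing bins count as zero); total must be >= 1.
#' @return H-score in [0, 300].
#' @examples
#' hscore(c(`0` = 40, `1` = 20, `2` = 30, `3` = 10))  # 110
#' @export
hscore <- function(counts) {
  counts <- unlist(counts)
  bins <- as.character(0:3)
  bad <- setdiff(names(counts), bins)
  if (length(bad))
    stop("unknown intensity bin(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  full <- stats::setNames(numeric(4), bins)
  full[names(counts)] <- counts
  if (any(full < 0) || any(full != round(full)))
    stop("bin counts must be non-negative integers", call. = FALSE)
  total <- sum(full)
  if (total < 1)
    stop("a core must contain at least one cell", call. = FALSE)
  sum((1:3) * 100 * full[c("1", "2", "3")] / total)
}

#' Average H-scores across cores of one sample
#'
#' Readings from multiple cores of the same sample are combined by
#' arithmetic mean.
#'
#' @param scores numeric vector of per-core H-scores (>= 1 core).
#' @return The mean H-score.
#' @export
aggregate_cores <- function(scores) {
  if (!length(scores)) stop("need at least one core", call. = FALSE)
  mean(scores)
}

#' Read a per-core nuclei intensity table
#'
#' TSV with columns `sample_id`, `core_id` and bin counts `bin0`,
#' `bin1`, `bin2`, `bin3`.
#'
#' @param path file path.
#' @return data.frame of the validated table.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "core_id", paste0("bin", 0:3))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(rowSums(df[paste0("bin", 0:3)]) < 1))
    stop("every core must contain at least one cell", call. = FALSE)
  df
}

#' Per-sample H-scores from a cell table
#'
#' Computes per-core H-scores and averages them within sample.
#'
#' @param cells a [read_cell_table()] data.frame.
#' @return data.frame with `sample_id`, `n_cores`, `hscore`.
#' @export
sample_hscores <- function(cells) {
  per_core <- vapply(seq_len(nrow(cells)), function(i)
    hscore(stats::setNames(as.numeric(cells[i, paste0("bin", 0:3)]),
                           as.character(0:3))), numeric(1))
  agg <- tapply(per_core, cells$sample_id, aggregate_cores)
  data.frame(sample_id = names(agg),
             n_cores = as.integer(table(cells$sample_id)[names(agg)]),
             hscore = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}
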