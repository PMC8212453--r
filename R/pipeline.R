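#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Required fields: `expr`
#' (TSV path or an [expr_matrix()]), `annotations` (TSV path or
#' [sample_annotations()]), `anchor_id`. Optional fields with defaults:
#' `purity_column` ("purity"), `group_column` ("rtt"), `alpha_diff`
#' (0.05), `n_perm` (1000), `seed` (1), `modifier_covariates`
#' (c("purity", "residual_disease", "subtype")), `modifier_flag_rule`
#' ("p_threshold"), `modifier_threshold` (0.02), `fdr_level` (0.15),
#' `min_module_size` (10), `gmt` (optional path), `outdir` (optional:
#' when set, per-stage TSVs and a JSON report are written).
#'
#' @param config list or YAML file path.
#' @return Validated config list (classed `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(purity_column = "purity", group_column = "rtt",
                   alpha_diff = 0.05, n_perm = 1000, seed = 1,
                   modifier_covariates = c("purity", "residual_disease",
                                           "subtype"),
                   modifier_flag_rule = "p_threshold",
                   modifier_threshold = 0.02, fdr_level = 0.15,
                   min_module_size = 10, gmt = NULL, outdir = NULL)
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  for (f in c("expr", "annotations", "anchor_id"))
    if (is.null(config[[f]]))
      stop("pipeline config lacks required field `", f, "`", call. = FALSE)
  for (f in c("alpha_diff", "modifier_threshold", "fdr_level"))
    if (config[[f]] <= 0 || config[[f]] >= 1)
      stop("`", f, "` must lie in (0, 1)", call. = FALSE)
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the full anchor differential co-expression pipeline
#'
#' Executes, in order: input loading and validation, the purity-adjusted
#' anchor co-expression scan, differential correlation between outcome
#' groups with permutation p-values, exclusive network extraction, the
#' modifier-gene interaction screen, planar filtered network
#' construction with module detection, and (when a GMT collection is
#' configured) overrepresentation of the exclusive networks against the
#' scan universe. All randomness flows from the single config seed, so a
#' rerun with the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by
#'   it).
#' @return Invisibly, a list with per-stage results (`scan`, `diffcorr`,
#'   `exclusive`, `modifiers`, `network`, `enrichment`) and `report`
#'   (stage counts, parameters, seed). When `outdir` is set, stage TSVs
#'   and `report.json` are written there.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  expr <- cfg$expr
  if (is.character(expr)) expr <- read_expression_matrix(expr, "log2")
  ann <- cfg$annotations
  if (is.character(ann)) ann <- read_sample_annotations(ann)
  # configuration errors surface before any compute
  for (col in c(cfg$purity_column, cfg$group_column))
    if (!col %in% names(ann))
      stop("annotation column not found: ", col, call. = FALSE)
  miss_cov <- setdiff(cfg$modifier_covariates, names(ann))
  if (length(miss_cov))
    stop("modifier covariate column(s) not found: ",
         paste(miss_cov, collapse = ", "), call. = FALSE)
  if (!all(colnames(expr) %in% ann$sample_id))
    stop("expression samples missing from annotations", call. = FALSE)
  ann <- ann[match(colnames(expr), ann$sample_id), , drop = FALSE]
  if (!cfg$anchor_id %in% rownames(expr))
    stop("anchor gene ", cfg$anchor_id, " not in expression matrix",
         call. = FALSE)
  purity <- ann[[cfg$purity_column]]
  groups <- ann[[cfg$group_column]]

  scan <- anchor_scan(expr, cfg$anchor_id, purity)
  diff <- anchor_diffcorr(expr, cfg$anchor_id, groups, purity,
                          alpha = cfg$alpha_diff, n_perm = cfg$n_perm,
                          seed = cfg$seed)
  excl <- exclusive_networks(diff, cfg$alpha_diff)
  mods <- modifier_screen(expr, cfg$anchor_id, ann,
                          covariates = cfg$modifier_covariates,
                          flag_rule = cfg$modifier_flag_rule,
                          threshold = cfg$modifier_threshold)

  sig <- !is.na(diff$p_perm) & diff$p_perm < cfg$alpha_diff
  net <- NULL
  if (any(sig)) {
    cand <- data.frame(gene_a = cfg$anchor_id, gene_b = diff$gene_id[sig],
                       p = diff$p_perm[sig], weight = abs(diff$z_diff[sig]),
                       stringsAsFactors = FALSE)
    net <- detect_modules(build_pfn(cand), cfg$min_module_size)
  }

  enr <- NULL
  if (!is.null(cfg$gmt)) {
    sets <- if (is.character(cfg$gmt)) read_gmt(cfg$gmt) else cfg$gmt
    universe <- scan$gene_id
    enr <- list(
      sensitive = overrepresentation(intersect(excl$sensitive_exclusive,
                                               universe), universe, sets),
      resistant = overrepresentation(intersect(excl$resistant_exclusive,
                                               universe), universe, sets))
  }

  report <- list(
    anchor_id = cfg$anchor_id,
    seed = cfg$seed, n_perm = cfg$n_perm, alpha_diff = cfg$alpha_diff,
    n_samples = ncol(expr), n_genes_scanned = nrow(scan),
    n_scan_significant_fdr = sum(scan$q < cfg$fdr_level, na.rm = TRUE),
    n_diffcorr_significant = sum(sig),
    n_sensitive_exclusive = length(excl$sensitive_exclusive),
    n_resistant_exclusive = length(excl$resistant_exclusive),
    n_modifiers_flagged = sum(mods$flagged),
    n_modifiers_negative = sum(mods$direction == "negative", na.rm = TRUE),
    n_network_nodes = if (is.null(net)) 0L else length(net$nodes),
    n_network_edges = if (is.null(net)) 0L else nrow(net$edges),
    n_modules = if (is.null(net)) 0L else length(unique(net$modules)),
    version = as.character(utils::packageVersion("anchordc")))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      as.data.frame(d), file.path(cfg$outdir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "")
    wt(scan, "anchor_scan.tsv")
    wt(diff, "diffcorr.tsv")
    wt(mods, "modifiers.tsv")
    wt(data.frame(gene_id = c(excl$sensitive_exclusive,
                              excl$resistant_exclusive),
                  network = rep(c("sensitive_exclusive",
                                  "resistant_exclusive"),
                                c(length(excl$sensitive_exclusive),
                                  length(excl$resistant_exclusive)))),
       "exclusive_networks.tsv")
    if (!is.null(net))
      export_network(net, file.path(cfg$outdir, "network.tsv"), "edge_list")
    if (!is.null(enr)) {
      wt(enr$sensitive, "enrichment_sensitive.tsv")
      wt(enr$resistant, "enrichment_resistant.tsv")
    }
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(scan = scan, diffcorr = diff, exclusive = excl,
                 modifiers = mods, network = net, enrichment = enr,
                 report = report))
}
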