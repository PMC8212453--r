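#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the synthetic data generators with defaults
#' mirroring the cohort the pipeline was designed around: 336 samples of
#' which 29% are platinum resistant, an anchor mRNA-protein cross-layer
#' correlation of 0.29, 30% protein missingness, and a desk-scale gene
#' count of 2,000.
#'
#' @param n_sensitive,n_resistant outcome group sizes (239 / 97).
#' @param n_genes number of non-anchor genes (2,000).
#' @param anchor_id anchor gene id (`"EZH2"`).
#' @param n_diff_sensitive,n_diff_resistant,n_shared planted set sizes:
#'   genes correlated with the anchor only in the sensitive group, only
#'   in the resistant group, or in both (50 each).
#' @param r_planted target anchor correlation of planted genes (0.4).
#' @param purity_shape Beta(a, b) parameters of the latent tumor purity
#'   (5, 2: mean 0.71, typical of bulk tumor series).
#' @param purity_loading_sd SD of the per-gene Gaussian purity loading
#'   (0.5); every gene, anchor included, receives loading * purity.
#' @param n_modifiers planted interaction genes in the modifier cohort
#'   (10).
#' @param modifier_cor pairwise correlation of the planted modifier
#'   genes (0.8): modifiers are generated as readouts of one latent
#'   co-expression program, the way empirical modifier genes travel in
#'   correlated regulatory modules.
#' @param beta_anchor anchor main effect in the resistance logistic
#'   model (-0.5: higher anchor expression associated with sensitivity).
#' @param beta_interaction interaction coefficient of planted modifiers
#'   (1.5, shared by the program; opposite in sign to `beta_anchor`, so
#'   the program attenuates the anchor association).
#' @param resistant_fraction target marginal resistant fraction (0.29);
#'   the logistic intercept is calibrated to it.
#' @param surv_shape,surv_scale Weibull baseline survival (shape 1.5,
#'   scale 60 months: median about 4.1 years).
#' @param hr_resistant hazard ratio of resistant vs sensitive disease
#'   (3.3).
#' @param censor_range administrative censoring drawn uniformly on this
#'   interval in months (24-120).
#' @param protein_cross_corr target anchor mRNA-protein correlation
#'   (0.29).
#' @param protein_missing_frac protein missing-completely-at-random
#'   fraction (0.30).
#' @param cells_per_core mean nuclei per IHC core (800).
#' @param seed root seed; all generators are deterministic given it.
#' @return A classed list (`generator_config`).
#' @export
generator_config <- function(n_sensitive = 239, n_resistant = 97,
                             n_genes = 2000, anchor_id = "EZH2",
                             n_diff_sensitive = 50, n_diff_resistant = 50,
                             n_shared = 50, r_planted = 0.4,
                             purity_shape = c(5, 2), purity_loading_sd = 0.5,
                             n_modifiers = 10, modifier_cor = 0.8,
                             beta_anchor = -0.5, beta_interaction = 1.5,
                             resistant_fraction = 0.29,
                             surv_shape = 1.5, surv_scale = 60,
                             hr_resistant = 3.3, censor_range = c(24, 120),
                             protein_cross_corr = 0.29,
                             protein_missing_frac = 0.30,
                             cells_per_core = 800, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_sensitive >= 5, n_resistant >= 5, n_genes >= 1,
            abs(r_planted) < 1,
            n_diff_sensitive + n_diff_resistant + n_shared <= n_genes,
            n_modifiers <= n_genes,
            modifier_cor >= 0, modifier_cor < 1,
            resistant_fraction > 0, resistant_fraction < 1,
            protein_missing_frac >= 0, protein_missing_frac < 1,
            abs(protein_cross_corr) <= 1,
            length(purity_shape) == 2, all(purity_shape > 0))
  class(cfg) <- "generator_config"
  cfg
}

.gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# shared clinical scaffolding: purity, age, stage, residual disease,
# subtype, and Weibull survival with group hazard ratio
.simulate_clinical <- function(cfg, rtt) {
  n <- length(rtt)
  purity <- stats::rbeta(n, cfg$purity_shape[1], cfg$purity_shape[2])
  purity <- pmin(pmax(purity, 1e-3), 1)
  lp <- log(cfg$hr_resistant) * (rtt == "resistant")
  u <- stats::runif(n)
  t_event <- cfg$surv_scale * (-log(u) / exp(lp))^(1 / cfg$surv_shape)
  t_cens <- stats::runif(n, cfg$censor_range[1], cfg$censor_range[2])
  sample_annotations(data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    rtt = rtt,
    survival_months = pmin(t_event, t_cens),
    event = ifelse(t_event <= t_cens, "died", "censored"),
    purity = purity,
    age_years = round(stats::rnorm(n, 61, 11), 1),
    stage = sample(.stage_levels, n, TRUE, prob = c(0.10, 0.90)),
    residual_disease = sample(.rd_levels, n, TRUE, prob = c(0.76, 0.24)),
    subtype = sample(.subtype_levels, n, TRUE),
    stringsAsFactors = FALSE))
}

#' Simulate a cohort with group-specific anchor correlations
#'
#' Group labels are drawn first; the anchor gene is standard normal.
#' Genes planted in a group-specific set follow
#' r * anchor + sqrt(1 - r^2) * noise within their active group and are
#' independent noise in the other group; shared genes are correlated in
#' both groups, null genes in neither. A latent tumor purity
#' u ~ Beta(purity_shape) is then added to every gene (anchor included)
#' with a gene-specific Gaussian loading, so marginal correlations are
#' confounded while purity-adjusted partial correlations recover the
#' planted structure.
#'
#' @param cfg a [generator_config()].
#' @return List with `expr` (an [expr_matrix()], layer `"log2"`),
#'   `annotations` (a [sample_annotations()] table) and `truth` (planted
#'   roles per gene, purity, loadings and the config).
#' @export
generate_diffcorr_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_sensitive + cfg$n_resistant
    rtt <- sample(c(rep("sensitive", cfg$n_sensitive),
                    rep("resistant", cfg$n_resistant)))
    anchor <- stats::rnorm(n)
    ids <- .gene_ids(cfg$n_genes)
    role <- rep("null", cfg$n_genes)
    idx <- 0
    for (r in c("sensitive", "resistant", "shared")) {
      k <- cfg[[paste0("n_", if (r == "shared") "shared"
                       else paste0("diff_", r))]]
      if (k > 0) role[idx + seq_len(k)] <- r
      idx <- idx + k
    }
    rr <- cfg$r_planted
    X <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                dimnames = list(ids, sprintf("s%03d", seq_len(n))))
    for (grp in .rtt_levels) {
      cols <- which(rtt == grp)
      rows <- which(role == grp | role == "shared")
      if (length(rows) && length(cols))
        X[rows, cols] <- rr * matrix(anchor[cols], length(rows),
                                     length(cols), byrow = TRUE) +
          sqrt(1 - rr^2) * X[rows, cols, drop = FALSE]
    }
    ann <- .simulate_clinical(cfg, rtt)
    loading <- stats::rnorm(cfg$n_genes + 1, 0, cfg$purity_loading_sd)
    full <- rbind(X, matrix(anchor, 1, n,
                            dimnames = list(cfg$anchor_id, colnames(X))))
    full <- full + outer(loading, ann$purity)
    truth <- list(planted = data.frame(gene_id = ids, role = role,
                                       r_planted = ifelse(role == "null", 0, rr),
                                       stringsAsFactors = FALSE),
                  purity = ann$purity,
                  loadings = stats::setNames(loading, rownames(full)),
                  config = cfg)
    list(expr = expr_matrix(full, "log2"), annotations = ann, truth = truth)
  })
}

#' Simulate a cohort with planted outcome-modifier interactions
#'
#' Expression is generated first (anchor plus independent genes, all
#' confounded by purity as in [generate_diffcorr_cohort()], without
#' group-specific correlation structure). The planted modifier genes
#' are readouts of one latent co-expression program with pairwise
#' correlation `modifier_cor`, mirroring the way empirical modifier
#' genes travel in correlated regulatory modules. The binary outcome is
#' then drawn from the logistic model
#' logit P(resistant) = b0 + beta_anchor * anchor +
#' sum over modifiers of beta_int * anchor * gene_g,
#' with b0 calibrated so the mean resistance probability equals
#' `resistant_fraction`. Survival is Weibull with the configured hazard
#' ratio and independent censoring.
#'
#' @param cfg a [generator_config()].
#' @return List with `expr`, `annotations`, `truth` (modifier ids and
#'   coefficients, the calibrated intercept, the config).
#' @export
generate_modifier_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_sensitive + cfg$n_resistant
    anchor <- stats::rnorm(n)
    ids <- .gene_ids(cfg$n_genes)
    X <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n,
                dimnames = list(ids, sprintf("s%03d", seq_len(n))))
    mod_idx <- seq_len(cfg$n_modifiers)
    if (cfg$n_modifiers > 0 && cfg$modifier_cor > 0) {
      # modifiers = latent program + gene-specific noise
      latent <- stats::rnorm(n)
      X[mod_idx, ] <- sqrt(cfg$modifier_cor) *
        matrix(latent, cfg$n_modifiers, n, byrow = TRUE) +
        sqrt(1 - cfg$modifier_cor) * X[mod_idx, , drop = FALSE]
    }
    purity <- pmin(pmax(stats::rbeta(n, cfg$purity_shape[1],
                                     cfg$purity_shape[2]), 1e-3), 1)
    loading <- stats::rnorm(cfg$n_genes + 1, 0, cfg$purity_loading_sd)
    full <- rbind(X, matrix(anchor, 1, n,
                            dimnames = list(cfg$anchor_id, colnames(X))))
    full <- full + outer(loading, purity)
    a <- full[cfg$anchor_id, ]
    beta_int <- rep(cfg$beta_interaction, cfg$n_modifiers)
    lp <- cfg$beta_anchor * a
    if (cfg$n_modifiers > 0) {
      Ma <- sweep(full[ids[mod_idx], , drop = FALSE], 2, a, "*")
      lp <- lp + as.vector(crossprod(Ma, beta_int))
    }
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) -
                           cfg$resistant_fraction,
                         c(-30, 30))$root
    y <- stats::rbinom(n, 1, stats::plogis(b0 + lp))
    rtt <- ifelse(y == 1, "resistant", "sensitive")
    ann <- .simulate_clinical(cfg, rtt)
    ann$purity <- purity                  # purity already used in expression
    truth <- list(modifiers = data.frame(gene_id = ids[mod_idx],
                                         beta_interaction = beta_int,
                                         stringsAsFactors = FALSE),
                  beta_anchor = cfg$beta_anchor, intercept = b0,
                  loadings = stats::setNames(loading, rownames(full)),
                  config = cfg)
    list(expr = expr_matrix(full, "log2"), annotations = ann, truth = truth)
  })
}

#' Simulate a protein layer from an mRNA layer
#'
#' Each protein is a scaled copy of its transcript plus unit Gaussian
#' noise; the per-gene scale is chosen so the expected mRNA-protein
#' correlation equals `protein_cross_corr` (the anchor's cross-layer
#' correlation in particular). Values are then masked missing
#' completely at random at `protein_missing_frac`.
#'
#' @param mrna an [expr_matrix()] (any continuous layer).
#' @param cfg a [generator_config()]; uses `protein_cross_corr`,
#'   `protein_missing_frac` and `seed` (offset so the draw is
#'   independent of the cohort draw).
#' @return An [expr_matrix()] with layer `"protein"`.
#' @export
generate_protein_layer <- function(mrna, cfg = generator_config()) {
  stopifnot(inherits(mrna, "expr_matrix"), inherits(cfg, "generator_config"))
  .with_seed(cfg$seed + 1L, {
    X <- unclass(mrna)
    rho <- cfg$protein_cross_corr
    sds <- apply(X, 1, stats::sd)
    sds[sds < 1e-12] <- 1
    if (abs(rho) == 1) {
      P <- X / sds                        # exact scaled copy
    } else {
      a <- rho / sqrt(1 - rho^2) / sds
      P <- X * a + matrix(stats::rnorm(length(X)), nrow(X), ncol(X))
    }
    if (cfg$protein_missing_frac > 0) {
      mask <- matrix(stats::runif(length(P)) < cfg$protein_missing_frac,
                     nrow(P), ncol(P))
      P[mask] <- NA
    }
    expr_matrix(P, "protein")
  })
}

# bin probabilities whose expected H-score equals h (in [0, 300]):
# below H = 200 the three positive bins share mass equally; above, the
# zero bin is exhausted and mass shifts to 3+
.hscore_bin_probs <- function(h) {
  q <- h / 300
  if (q <= 2 / 3) c(1 - 3 * q / 2, q / 2, q / 2, q / 2)
  else c(0, 1 - q, 1 - q, 2 * q - 1)
}

#' Simulate per-core nuclei intensity tables
#'
#' Each sample receives a true H-score drawn from a Beta(2, 2) scaled to
#' [0, 300]; each core draws its nuclei counts from a multinomial whose
#' expected H-score equals the sample's true score.
#'
#' @param n_samples number of samples.
#' @param cores_per_sample cores per sample (>= 1; default 2, duplicate
#'   cores).
#' @param cfg a [generator_config()] (uses `cells_per_core`).
#' @param seed integer seed.
#' @return List with `cells` (a data.frame suitable for
#'   [sample_hscores()]) and `truth` (per-sample true H).
#' @export
generate_cell_tables <- function(n_samples, cores_per_sample = 2,
                                 cfg = generator_config(), seed = 1) {
  stopifnot(cores_per_sample >= 1)
  .with_seed(seed, {
    true_h <- 300 * stats::rbeta(n_samples, 2, 2)
    rows <- lapply(seq_len(n_samples), function(i) {
      probs <- .hscore_bin_probs(true_h[i])
      do.call(rbind, lapply(seq_len(cores_per_sample), function(j) {
        ncell <- max(1L, stats::rpois(1, cfg$cells_per_core))
        cnt <- as.vector(stats::rmultinom(1, ncell, probs))
        data.frame(sample_id = sprintf("s%03d", i),
                   core_id = sprintf("s%03d_c%d", i, j),
                   bin0 = cnt[1], bin1 = cnt[2], bin2 = cnt[3], bin3 = cnt[4],
                   stringsAsFactors = FALSE)
      }))
    })
    list(cells = do.call(rbind, rows),
         truth = data.frame(sample_id = sprintf("s%03d", seq_len(n_samples)),
                            true_h = true_h, stringsAsFactors = FALSE))
  })
}
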