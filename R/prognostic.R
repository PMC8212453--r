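.assoc_estimate <- function(feature_id, model, estimate, ci_low, ci_high, p,
                            covariates_used = character(), stratum = NA_character_,
                            p_interaction = NA_real_) {
  out <- data.frame(feature_id = feature_id, model = model,
                    estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                    p = p, stratum = stratum, p_interaction = p_interaction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "covariates_used") <- covariates_used
  class(out) <- c("association_estimate", "data.frame")
  out
}

#' Two-group comparison tests
#'
#' Wilcoxon rank-sum (normal approximation with tie correction, no
#' continuity correction), Welch t-test, or Pearson chi-square without
#' Yates correction on a 2x2 count table.
#'
#' @param values numeric per-sample values (for `wilcoxon`/`t`), or a
#'   2x2 count matrix (for `chisq`, `groups` ignored).
#' @param groups two-level labels aligned with `values`.
#' @param test one of `"wilcoxon"`, `"t"`, `"chisq"`.
#' @return List with `statistic` and two-sided `p`.
#' @export
compare_groups <- function(values, groups = NULL,
                           test = c("wilcoxon", "t", "chisq")) {
  test <- match.arg(test)
  if (test == "chisq") {
    tab <- as.matrix(values)
    if (!all(dim(tab) == c(2, 2)))
      stop("chisq test expects a 2x2 count table", call. = FALSE)
    ht <- stats::chisq.test(tab, correct = FALSE)
    return(list(statistic = unname(ht$statistic), p = ht$p.value))
  }
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("need two non-empty groups", call. = FALSE)
  x <- values[g == levels(g)[1]]; y <- values[g == levels(g)[2]]
  ht <- switch(test,
    wilcoxon = stats::wilcox.test(x, y, exact = FALSE, correct = FALSE),
    t        = stats::t.test(x, y))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

.binary_outcome <- function(ann) {
  if (!"rtt" %in% names(ann))
    stop("annotations lack an `rtt` column", call. = FALSE)
  y <- as.integer(ann$rtt == "resistant")
  if (length(unique(stats::na.omit(y))) < 2)
    stop("outcome must have both levels", call. = FALSE)
  y
}

.model_frame <- function(ann, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(ann))
  if (length(miss))
    stop("covariate(s) not in annotations: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(ann)[, covariates, drop = FALSE]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  df
}

.fit_glm_checked <- function(df) {
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(cond) {
      w <<- conditionMessage(cond); invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic model did not converge", call. = FALSE)
  if (!is.null(w) && grepl("fitted probabilities numerically 0 or 1", w) &&
      fit$deviance < 1e-6)
    stop("perfect separation detected in logistic model", call. = FALSE)
  fit
}

#' Logistic regression of response to therapy on a feature
#'
#' Maximum-likelihood logistic fit of platinum resistance (resistant = 1)
#' on a continuous feature plus optional clinical covariates; reports the
#' odds ratio per unit feature with Wald 95% CI.
#'
#' @param feature per-sample numeric feature (e.g. anchor expression).
#' @param ann a [sample_annotations()] table with `rtt`.
#' @param covariates character vector of annotation columns to adjust
#'   for (e.g. `c("purity", "residual_disease", "subtype")`).
#' @param feature_id label for the reported estimate.
#' @return An `association_estimate` row (`estimate` is the OR).
#' @export
fit_logistic_rtt <- function(feature, ann, covariates = character(),
                             feature_id = "feature") {
  y <- .binary_outcome(ann)
  df <- data.frame(y = y, x = feature)
  cf <- .model_frame(ann, covariates)
  if (!is.null(cf)) df <- cbind(df, cf)
  df <- stats::na.omit(df)
  fit <- .fit_glm_checked(df)
  sm <- summary(fit)$coefficients
  b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  .assoc_estimate(feature_id, "logistic", exp(b), exp(b - 1.96 * se),
                  exp(b + 1.96 * se), sm["x", "Pr(>|z|)"], covariates)
}

#' Cox proportional hazards model for a feature
#'
#' Partial-likelihood fit (Efron tie handling) of overall survival on a
#' continuous feature plus optional covariates; reports the hazard ratio
#' per unit feature with Wald 95% CI.
#'
#' @inheritParams fit_logistic_rtt
#' @param ann a [sample_annotations()] table with `survival_months` and
#'   `event` (`"died"`/`"censored"`).
#' @return An `association_estimate` row (`estimate` is the HR).
#' @export
fit_cox <- function(feature, ann, covariates = character(),
                    feature_id = "feature") {
  stopifnot(all(c("survival_months", "event") %in% names(ann)))
  if (stats::sd(feature, na.rm = TRUE) == 0)
    stop("feature is constant; hazard ratio undefined", call. = FALSE)
  ev <- as.integer(ann$event == "died")
  if (sum(ev, na.rm = TRUE) < 1)
    stop("no events; cannot fit a Cox model", call. = FALSE)
  df <- data.frame(time = ann$survival_months, ev = ev, x = feature)
  cf <- .model_frame(ann, covariates)
  if (!is.null(cf)) df <- cbind(df, cf)
  df <- stats::na.omit(df)
  rhs <- paste(setdiff(names(df), c("time", "ev")), collapse = " + ")
  fit <- survival::coxph(stats::as.formula(paste("survival::Surv(time, ev) ~", rhs)),
                         data = df, ties = "efron")
  sm <- summary(fit)$coefficients
  b <- sm["x", "coef"]; se <- sm["x", "se(coef)"]
  .assoc_estimate(feature_id, "cox", exp(b), exp(b - 1.96 * se),
                  exp(b + 1.96 * se), sm["x", "Pr(>|z|)"], covariates)
}

# Wald p-value of `var`'s coefficient when added to base columns
.candidate_p <- function(candidate, selected, ann, outcome_model) {
  est <- tryCatch({
    if (outcome_model == "logistic") {
      y <- .binary_outcome(ann)
      df <- data.frame(y = y, .model_frame(ann, c(candidate, selected)))
      df <- stats::na.omit(df)
      fit <- .fit_glm_checked(df)
      sm <- summary(fit)$coefficients
    } else {
      ev <- as.integer(ann$event == "died")
      df <- data.frame(time = ann$survival_months, ev = ev,
                       .model_frame(ann, c(candidate, selected)))
      df <- stats::na.omit(df)
      rhs <- paste(setdiff(names(df), c("time", "ev")), collapse = " + ")
      fit <- survival::coxph(stats::as.formula(
        paste("survival::Surv(time, ev) ~", rhs)), data = df, ties = "efron")
      sm <- summary(fit)$coefficients
    }
    rows <- grep(paste0("^", candidate), rownames(sm))
    min(sm[rows, "Pr(>|z|)"])
  }, error = function(e) NA_real_)
  est
}

#' Forward stepwise covariate selection
#'
#' Iteratively adds the candidate with the smallest Wald p-value among
#' those below `entry_p` when added to the current model; stops when no
#' candidate qualifies. Deterministic: ties are broken by candidate
#' order. Candidates whose fit fails are skipped.
#'
#' @param candidates character vector of annotation column names.
#' @param outcome_model `"logistic"` (response to therapy) or `"cox"`
#'   (overall survival).
#' @param ann a [sample_annotations()] table.
#' @param entry_p entrance criterion (default 0.10).
#' @return Character vector of selected columns, in entry order.
#' @export
stepwise_select <- function(candidates, outcome_model = c("logistic", "cox"),
                            ann, entry_p = 0.10) {
  outcome_model <- match.arg(outcome_model)
  stopifnot(length(candidates) > 0)
  selected <- character()
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    ps <- vapply(remaining, .candidate_p, numeric(1),
                 selected = selected, ann = ann, outcome_model = outcome_model)
    ok <- !is.na(ps) & ps < entry_p
    if (!any(ok)) break
    best <- remaining[ok][which.min(ps[ok])]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' Stratified association with interaction test
#'
#' Fits the full model with a feature x stratifier interaction term
#' (two-sided Wald p for the interaction) and separate per-stratum
#' models. Strata too small to fit are flagged with a missing estimate.
#'
#' @inheritParams fit_logistic_rtt
#' @param stratifier name of a two-level annotation column (e.g. a
#'   morphology flag such as `til` or `lvi`).
#' @param model `"logistic"` or `"cox"`.
#' @return An `association_estimate` data.frame with one row per
#'   stratum; every row carries the shared `p_interaction`.
#' @export
stratified_association <- function(feature, ann, stratifier,
                                   model = c("logistic", "cox"),
                                   covariates = character(),
                                   feature_id = "feature") {
  model <- match.arg(model)
  if (!stratifier %in% names(ann))
    stop("stratifier column not found: ", stratifier, call. = FALSE)
  s <- factor(ann[[stratifier]])
  if (nlevels(droplevels(s[!is.na(s)])) != 2)
    stop("stratifier must have exactly two observed levels", call. = FALSE)
  cf <- .model_frame(ann, covariates)
  if (model == "logistic") {
    df <- data.frame(y = .binary_outcome(ann), x = feature, s = s)
    if (!is.null(cf)) df <- cbind(df, cf)
    df <- stats::na.omit(df)
    full <- .fit_glm_checked2(df)
  } else {
    df <- data.frame(time = ann$survival_months,
                     ev = as.integer(ann$event == "died"),
                     x = feature, s = s)
    if (!is.null(cf)) df <- cbind(df, cf)
    df <- stats::na.omit(df)
    rhs <- paste(c("x * s", setdiff(names(df), c("time", "ev", "x", "s"))),
                 collapse = " + ")
    full <- survival::coxph(stats::as.formula(
      paste("survival::Surv(time, ev) ~", rhs)), data = df, ties = "efron")
  }
  sm <- summary(full)$coefficients
  int_row <- grep("^x:s", rownames(sm))
  pcol <- grep("^Pr", colnames(sm))
  p_int <- unname(sm[int_row[1], pcol])
  strata <- levels(droplevels(df$s))
  rows <- lapply(strata, function(lv) {
    sub <- ann[which(s == lv), , drop = FALSE]
    fsub <- feature[which(s == lv)]
    est <- tryCatch({
      if (model == "logistic")
        fit_logistic_rtt(fsub, sub, covariates, feature_id)
      else fit_cox(fsub, sub, covariates, feature_id)
    }, error = function(e)
      .assoc_estimate(feature_id, model, NA_real_, NA_real_, NA_real_, NA_real_,
                      covariates))
    est$stratum <- lv
    est
  })
  out <- do.call(rbind, rows)
  out$p_interaction <- p_int
  attr(out, "covariates_used") <- covariates
  class(out) <- c("association_estimate", "data.frame")
  out
}

# glm with x*s interaction, same convergence/separation guards
.fit_glm_checked2 <- function(df) {
  w <- NULL
  rhs <- paste(c("x * s", setdiff(names(df), c("y", "x", "s"))),
               collapse = " + ")
  fit <- withCallingHandlers(
    stats::glm(stats::as.formula(paste("y ~", rhs)), data = df,
               family = stats::binomial()),
    warning = function(cond) {
      w <<- conditionMessage(cond); invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic model did not converge", call. = FALSE)
  if (!is.null(w) && grepl("fitted probabilities numerically 0 or 1", w) &&
      fit$deviance < 1e-6)
    stop("perfect separation detected in logistic model", call. = FALSE)
  fit
}

#' Tumor cytolytic activity score
#'
#' Geometric mean of GZMA and PRF1 expression per sample,
#' CYT_s = sqrt((GZMA_s + offset) (PRF1_s + offset)), a proxy for T-cell
#' cytolytic infiltration.
#'
#' @param m an [expr_matrix()] containing genes `GZMA` and `PRF1`.
#' @param offset small positive constant added before the product
#'   (default 0.01).
#' @param genes the two gene ids (override for non-symbol identifiers).
#' @return Named numeric vector, one score per sample.
#' @export
cytolytic_activity <- function(m, offset = 0.01, genes = c("GZMA", "PRF1")) {
  X <- as.matrix(m)
  miss <- setdiff(genes, rownames(X))
  if (length(miss))
    stop("gene(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  sqrt((X[genes[1], ] + offset) * (X[genes[2], ] + offset))
}

#' Genome-wide modifier-gene interaction screen
#'
#' For every gene g other than the anchor, fits the logistic outcome
#' model `rtt ~ anchor + g + anchor:g + covariates` and records the
#' interaction coefficient and its Wald p-value. Genes are flagged
#' either by a p-value threshold or as the smallest `threshold` fraction
#' of interaction p-values. A flagged modifier is classified `negative`
#' (it attenuates the anchor's association) when the interaction
#' coefficient's sign is opposite to the anchor main-effect coefficient
#' in the same model, `positive` otherwise.
#'
#' @param m an [expr_matrix()] containing the anchor and candidate
#'   genes.
#' @param anchor_id anchor gene id.
#' @param ann a [sample_annotations()] table with `rtt`.
#' @param covariates annotation columns to adjust for.
#' @param flag_rule `"p_threshold"` (default) or `"top_fraction"`.
#' @param threshold p cut (default 0.02) or top fraction (e.g. 0.01).
#' @return A data.frame (classed `modifier_screen`) with `gene_id`,
#'   `beta_interaction`, `se_interaction`, `p_interaction`,
#'   `beta_anchor`, `flagged`, `direction`; attribute `n_failed` counts
#'   gene fits that did not converge (excluded from flagging).
#' @export
modifier_screen <- function(m, anchor_id, ann, covariates = character(),
                            flag_rule = c("p_threshold", "top_fraction"),
                            threshold = 0.02) {
  flag_rule <- match.arg(flag_rule)
  X <- as.matrix(m)
  if (!anchor_id %in% rownames(X))
    stop("anchor gene ", anchor_id, " not found", call. = FALSE)
  y_all <- .binary_outcome(ann)
  a_all <- X[anchor_id, ]
  cf <- .model_frame(ann, covariates)
  # rows with complete outcome/anchor/covariates; per-gene completeness
  # handled inside the loop
  ok0 <- !is.na(y_all) & !is.na(a_all)
  Cmat <- NULL
  if (!is.null(cf)) {
    cc <- stats::complete.cases(cf)
    mm <- stats::model.matrix(~ ., data = cf[cc, , drop = FALSE])[, -1, drop = FALSE]
    Cmat <- matrix(NA_real_, length(y_all), ncol(mm),
                   dimnames = list(NULL, colnames(mm)))
    Cmat[cc, ] <- mm
    ok0 <- ok0 & cc
  }
  genes <- setdiff(rownames(X), anchor_id)
  n_genes <- length(genes)
  beta_int <- se_int <- p_int <- beta_a <- rep(NA_real_, n_genes)
  fam <- stats::binomial()
  for (i in seq_len(n_genes)) {
    g <- X[genes[i], ]
    ok <- ok0 & !is.na(g)
    if (sum(ok) < 10) next
    Z <- cbind(`(Intercept)` = 1, anchor = a_all[ok], gene = g[ok],
               interaction = a_all[ok] * g[ok])
    if (!is.null(Cmat)) Z <- cbind(Z, Cmat[ok, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(Z, y_all[ok], family = fam)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < ncol(Z)) next
    p_mod <- ncol(Z)
    cov_un <- tryCatch(chol2inv(fit$qr$qr[seq_len(p_mod), seq_len(p_mod),
                                          drop = FALSE]),
                       error = function(e) NULL)
    if (is.null(cov_un)) next
    se <- sqrt(diag(cov_un))
    b <- fit$coefficients
    beta_int[i] <- b["interaction"]; se_int[i] <- se[4]
    beta_a[i] <- b["anchor"]
    p_int[i] <- 2 * stats::pnorm(-abs(b["interaction"] / se[4]))
  }
  tested <- !is.na(p_int)
  flagged <- rep(FALSE, n_genes)
  if (flag_rule == "p_threshold") {
    flagged[tested] <- p_int[tested] < threshold
  } else {
    k <- max(1L, round(threshold * sum(tested)))
    ord <- order(p_int, na.last = NA)
    flagged[utils::head(ord, k)] <- TRUE
  }
  direction <- rep(NA_character_, n_genes)
  direction[flagged] <- ifelse(sign(beta_int[flagged]) != sign(beta_a[flagged]),
                               "negative", "positive")
  out <- data.frame(gene_id = genes, beta_interaction = beta_int,
                    se_interaction = se_int, p_interaction = p_int,
                    beta_anchor = beta_a, flagged = flagged,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  n_failed <- sum(!tested)
  if (n_failed > 0)
    message("modifier_screen: ", n_failed,
            " gene fit(s) failed to converge and were excluded from flagging")
  attr(out, "n_failed") <- n_failed
  attr(out, "anchor_id") <- anchor_id
  attr(out, "flag_rule") <- flag_rule
  attr(out, "threshold") <- threshold
  class(out) <- c("modifier_screen", "data.frame")
  out
}

#' @export
print.modifier_screen <- function(x, ...) {
  cat(sprintf("Modifier screen for anchor %s: %d genes tested, %d flagged (%s = %g)\n",
              attr(x, "anchor_id"), sum(!is.na(x$p_interaction)),
              sum(x$flagged), attr(x, "flag_rule"), attr(x, "threshold")))
  if (sum(x$flagged))
    cat(sprintf("  negative modifiers: %d (%.0f%%), positive: %d\n",
                sum(x$direction == "negative", na.rm = TRUE),
                100 * mean(x$direction[x$flagged] == "negative"),
                sum(x$direction == "positive", na.rm = TRUE)))
  print.data.frame(utils::head(x[order(x$p_interaction), ], 10),
                   row.names = FALSE, digits = 3)
  invisible(x)
}
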