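#' Covariate-adjusted logistic association for one feature
#'
#' Fits a maximum-likelihood logistic regression of case status on the
#' mean-centred feature plus the adjustment covariates (APOE-e4 allele count,
#' age, sex and batch indicators by default). The odds ratio is per log2 unit
#' of the feature, with a Wald 95% confidence interval and p-value.
#' Non-convergence or (quasi-)separation is reported through `converged` /
#' `separation` flags; estimates are still returned.
#'
#' @param values feature values (log2 scale), aligned with `meta` rows.
#' @param meta sample metadata containing `diagnosis` and the covariates.
#' @param outcome two diagnosis labels, case first (default AD vs CTL).
#' @param covariates adjustment covariates among the metadata columns;
#'   `batch` always enters as indicators with the first batch as reference.
#' @param conf_level Wald confidence level.
#' @return one-row tibble: `estimate` (log-OR), `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `converged`, `separation`, `n`.
#' @export
fit_logistic_single <- function(values, meta,
                                outcome = c("AD", "CTL"),
                                covariates = c("apoe4", "age", "sex", "batch"),
                                conf_level = 0.95) {
  d <- .assoc_frame(values, meta, outcome, covariates)
  fit <- .fit_glm(d, interaction = FALSE)
  .wald_row(fit, "feat", conf_level)
}

.assoc_frame <- function(values, meta, outcome, covariates) {
  meta <- as_tibble(meta)
  values <- as.numeric(values)
  if (length(values) != nrow(meta)) {
    abort("`values` must align with the rows of `meta`.")
  }
  keep <- meta$diagnosis %in% outcome
  d <- meta[keep, , drop = FALSE]
  v <- values[keep]
  if (anyNA(v)) abort("Feature values must be complete (impute first).")
  if (length(unique(v)) == 1) abort("Constant feature cannot be tested.")
  y <- as.integer(d$diagnosis == outcome[1])
  if (length(unique(y)) < 2) abort("Outcome is constant in the data.")
  miss <- setdiff(covariates, names(d))
  if (length(miss)) abort(paste0("Missing covariate column(s): ",
                                 paste(miss, collapse = ", ")))
  cov_d <- d[covariates]
  if (anyNA(cov_d)) abort("Covariates must be complete.")
  if ("batch" %in% covariates) cov_d$batch <- factor(cov_d$batch)
  if ("sex" %in% covariates) cov_d$sex <- factor(cov_d$sex)
  cbind(data.frame(y = y, feat = v - mean(v)), cov_d)
}

.fit_glm <- function(d, interaction) {
  drop <- names(d)[vapply(d, function(col) length(unique(col)) == 1, logical(1))]
  drop <- setdiff(drop, c("y", "feat"))
  d <- d[setdiff(names(d), drop)]
  rhs <- setdiff(names(d), "y")
  if (interaction) {
    if (!"apoe4" %in% rhs) abort("APOE-e4 count is constant; interaction term inestimable.")
    rhs <- c(rhs, "feat:apoe4")
  }
  f <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  withCallingHandlers(
    glm(f, family = binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

.wald_row <- function(fit, term, conf_level) {
  sm <- summary(fit)$coefficients
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  z <- qnorm(1 - (1 - conf_level) / 2)
  separation <- !fit$converged || abs(est) > 10 || se > 100
  tibble(estimate = est, se = se, or = exp(est),
         ci_low = exp(est - z * se), ci_high = exp(est + z * se),
         p = 2 * pnorm(-abs(est / se)),
         converged = fit$converged, separation = separation,
         n = length(fit$y))
}

#' Feature-by-APOE interaction test
#'
#' Refits the single-analyte model of [fit_logistic_single()] with a
#' `feature x APOE-e4 count` product term and returns the Wald p-value of
#' that term (plus the main-model row).
#'
#' @inheritParams fit_logistic_single
#' @return one-row tibble: the main-effect columns plus `interaction_p`.
#' @export
fit_interaction <- function(values, meta, outcome = c("AD", "CTL"),
                            covariates = c("apoe4", "age", "sex", "batch"),
                            conf_level = 0.95) {
  d <- .assoc_frame(values, meta, outcome, covariates)
  if (length(unique(d$apoe4)) == 1) {
    abort("APOE-e4 count is constant; interaction term inestimable.")
  }
  fit <- .fit_glm(d, interaction = TRUE)
  sm <- summary(fit)$coefficients
  term <- grep("^feat:apoe4|^apoe4:feat", rownames(sm), value = TRUE)[1]
  main <- .wald_row(fit, "feat", conf_level)
  main$interaction_p <- 2 * pnorm(-abs(sm[term, "Estimate"] / sm[term, "Std. Error"]))
  main
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, returned in the original order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, `q[i] >= p[i]`, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Per-feature association scan
#'
#' Applies [fit_logistic_single()] (and optionally [fit_interaction()]) to
#' every feature of an imputed matrix and adds BH q-values.
#'
#' @param x imputed-scale [feature_matrix()] (log2 intensities).
#' @param meta sample metadata.
#' @inheritParams fit_logistic_single
#' @param interaction also compute the APOE interaction p-value?
#' @return tibble, one row per feature, ordered as the matrix columns:
#'   `feature`, `or`, `ci_low`, `ci_high`, `p`, `q`, flags, and
#'   `interaction_p` when requested.
#' @export
associate_features <- function(x, meta, outcome = c("AD", "CTL"),
                               covariates = c("apoe4", "age", "sex", "batch"),
                               interaction = FALSE) {
  meta <- .align_meta(meta, x)
  res <- purrr::map_dfr(colnames(x), function(f) {
    row <- if (interaction) {
      fit_interaction(x[, f], meta, outcome, covariates)
    } else {
      fit_logistic_single(x[, f], meta, outcome, covariates)
    }
    dplyr::bind_cols(tibble(feature = f), row)
  })
  res$q <- bh_fdr(res$p)
  dplyr::relocate(res, "q", .after = "p")
}

#' One-way ANOVA with Tukey HSD follow-up
#'
#' @param values numeric response.
#' @param group group labels (>= 2 groups, >= 2 values each).
#' @param alpha run Tukey HSD only when the ANOVA p is below this level.
#' @return list: `F`, `df1`, `df2`, `p`, and `tukey` (tibble of pairwise
#'   adjusted p-values, or `NULL` when the ANOVA is not significant).
#' @export
group_anova_tukey <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) abort("Need at least two groups.")
  if (any(table(group) < 2)) abort("Each group needs at least two values.")
  if (anyNA(values)) abort("`values` must be complete.")
  fit <- aov(values ~ group)
  an <- summary(fit)[[1]]
  out <- list(F = an["group", "F value"], df1 = an["group", "Df"],
              df2 = an["Residuals", "Df"], p = an["group", "Pr(>F)"],
              tukey = NULL)
  if (is.finite(out$p) && out$p < alpha) {
    tk <- TukeyHSD(fit)$group
    out$tukey <- tibble(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"])
  }
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Classic `sum((O - E)^2 / E)` with expected counts from the margins and
#' `(r - 1)(c - 1)` degrees of freedom; no continuity correction.
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @return list: `statistic`, `df`, `p`.
#' @examples
#' # female/male by diagnostic group
#' pearson_chisq(matrix(c(17, 26, 21, 18, 22, 19), nrow = 2, byrow = TRUE))
#' @export
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("Need at least a 2x2 table.")
  if (any(tab < 0) || any(tab != floor(tab))) {
    abort("Counts must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Zero row or column margin.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Correlation of feature levels with MMSE
#'
#' Spearman by default (the relationship need not be linear and MMSE is a
#' bounded score); Pearson available.
#'
#' @param values feature values.
#' @param mmse MMSE scores, same length.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list: `r`, `p`, `n` (complete pairs).
#' @export
mmse_correlation <- function(values, mmse, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(mmse)
  if (sum(ok) < 3) abort("Need at least 3 complete pairs.")
  if (length(unique(values[ok])) == 1 || length(unique(mmse[ok])) == 1) {
    abort("Constant input; correlation undefined.")
  }
  ct <- suppressWarnings(cor.test(values[ok], mmse[ok], method = method,
                                  exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
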