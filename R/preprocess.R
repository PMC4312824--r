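#' Normalise to total mean area
#'
#' Scales each sample so that its total present peak area equals the grand
#' mean of per-sample totals, the normalisation applied by common LC-MS
#' alignment software. Missing entries are ignored and preserved.
#'
#' @param x raw-scale [feature_matrix()].
#' @return normalized-scale [feature_matrix()].
#' @examples
#' m <- matrix(c(40, 60, 120, 180), 2, 2,
#'             dimnames = list(c("A", "B"), c("f1", "f2")))
#' normalize_total_mean_area(feature_matrix(m, "raw"))
#' @export
normalize_total_mean_area <- function(x) {
  assert_scale(x, "raw", "normalize_total_mean_area")
  totals <- rowSums(x, na.rm = TRUE)
  empty <- rowSums(!is.na(x)) == 0
  if (any(empty)) {
    abort(paste0("Sample(s) with no present values: ",
                 paste(rownames(x)[empty], collapse = ", ")))
  }
  out <- unclass(x) * (mean(totals) / totals)
  feature_matrix(out, "normalized")
}

#' Filter features by stratified detection rate
#'
#' Keeps a feature only if it is detected (present and positive) in at least
#' `threshold` of the samples of *every* diagnostic group and of *every*
#' batch. QC injections are excluded from the rates.
#'
#' @param x [feature_matrix()] (raw or normalized scale).
#' @param meta sample metadata with `sample_id`, `diagnosis`, `batch`;
#'   diagnosis `"QC"` marks pooled-QC samples.
#' @param threshold minimum detection rate in each stratum (default 0.80).
#' @return a list: `matrix` (features kept), `dropped` (feature ids removed)
#'   and `rates`, a tibble of per-feature detection rates by stratum.
#' @export
filter_detection <- function(x, meta, threshold = 0.80) {
  assert_scale(x, c("raw", "normalized"), "filter_detection")
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1].")
  meta <- .align_meta(meta, x)
  clin <- meta$diagnosis != "QC"
  if (!any(clin)) abort("No non-QC samples to compute detection rates from.")
  xm <- unclass(x)[clin, , drop = FALSE]
  detected <- !is.na(xm) & xm > 0

  strata <- c(split(seq_len(nrow(xm)), paste0("diagnosis:", meta$diagnosis[clin])),
              split(seq_len(nrow(xm)), paste0("batch:", meta$batch[clin])))
  rate_m <- vapply(strata, function(i) colMeans(detected[i, , drop = FALSE]),
                   numeric(ncol(xm)))
  if (ncol(xm) == 1) rate_m <- matrix(rate_m, nrow = 1,
                                      dimnames = list(colnames(xm), names(strata)))
  keep <- apply(rate_m, 1, function(r) all(r >= threshold))
  rates <- as_tibble(rate_m, rownames = "feature")
  list(matrix = x[, keep, drop = FALSE],
       dropped = colnames(x)[!keep],
       rates = rates)
}

.align_meta <- function(meta, x) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "diagnosis", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("`meta` lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  i <- match(rownames(x), meta$sample_id)
  if (anyNA(i)) abort("`meta` does not cover all samples in the matrix.")
  bad <- setdiff(unique(meta$diagnosis), c("CTL", "MCI", "AD", "QC"))
  if (length(bad)) abort(paste0("Unknown diagnosis label(s): ",
                                paste(bad, collapse = ", ")))
  meta[i, ]
}

#' Log2-transform a normalized feature matrix
#'
#' @param x normalized-scale [feature_matrix()] with positive present values.
#' @return log2-scale [feature_matrix()]; missing entries preserved.
#' @export
log2_transform <- function(x) {
  assert_scale(x, "normalized", "log2_transform")
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-positive value at sample '%s', feature '%s'.",
                  rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  retag(log2(unclass(x)), "log2")
}

#' Shapiro-Wilk normality assessment per feature
#'
#' @param x [feature_matrix()] on any log-like scale.
#' @param alpha significance level for the summary rejection fraction.
#' @return tibble with `feature`, `n`, `W`, `p`; the fraction of features
#'   rejecting normality at `alpha` is attached as attribute `prop_reject`.
#'   Features with fewer than 3 present values, or constant values, are
#'   skipped with a warning.
#' @export
assess_normality <- function(x, alpha = 0.05) {
  res <- purrr::map(colnames(x), function(f) {
    v <- x[, f]
    v <- v[!is.na(v)]
    if (length(v) < 3 || length(unique(v)) == 1) return(NULL)
    sw <- shapiro.test(v[seq_len(min(length(v), 5000))])
    tibble(feature = f, n = length(v), W = unname(sw$statistic),
           p = sw$p.value)
  })
  skipped <- colnames(x)[purrr::map_lgl(res, is.null)]
  if (length(skipped)) {
    warn(paste0("Skipped ", length(skipped),
                " feature(s) with <3 values or constant values."))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "prop_reject") <- if (nrow(out)) mean(out$p < alpha) else NA_real_
  out
}

#' Empirical-Bayes batch correction (ComBat model)
#'
#' Implements the parametric empirical-Bayes location/scale batch adjustment
#' for feature tables. Per feature, intensities are modelled as
#' `y = alpha + X beta + gamma_b + delta_b * eps`; features are standardised
#' by their fitted grand mean and pooled variance, per-batch location
#' (`gamma`) and scale (`delta^2`) estimates are shrunk towards batch-level
#' normal / inverse-gamma priors whose hyperparameters are moment-matched
#' across features, and the shrunk estimates are removed. Missing entries are
#' ignored during estimation and preserved in the output.
#'
#' @param x log2-scale [feature_matrix()].
#' @param batch batch label per sample (coerced to factor).
#' @param covariates optional data frame of biological covariates to protect
#'   (expanded via `model.matrix`); default none.
#' @return a list: `matrix` (corrected-scale [feature_matrix()]) and
#'   `params`, a `batch_model_params` object holding per-feature/batch raw
#'   and shrunk estimates, the batch-level hyperpriors, and per-feature grand
#'   means / pooled variances.
#' @references Johnson, Li & Rabinovic (2007) Biostatistics 8(1):118-127.
#' @export
combat_correct <- function(x, batch, covariates = NULL) {
  assert_scale(x, "log2", "combat_correct")
  batch <- factor(batch)
  if (length(batch) != nrow(x)) abort("`batch` must match the sample count.")
  n_b <- table(batch)
  if (nlevels(batch) == 1) {
    return(list(matrix = retag(unclass(x), "corrected"), params = NULL))
  }
  if (any(n_b < 2)) {
    abort(paste0("Singleton batch(es): ",
                 paste(names(n_b)[n_b < 2], collapse = ", ")))
  }

  B <- model.matrix(~ 0 + batch)
  Xc <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    Xc <- model.matrix(~ ., covariates)[, -1, drop = FALSE]
    if (qr(cbind(B, Xc))$rank < ncol(B) + ncol(Xc)) {
      abort("Covariates are confounded with batch; cannot correct.")
    }
  }
  D <- cbind(B, Xc)
  n_feat <- ncol(x)
  levs <- levels(batch)
  nb <- length(levs)
  frac <- as.numeric(n_b) / length(batch)

  xm <- unclass(x)
  alpha <- sigma2 <- numeric(n_feat)
  covfit <- matrix(0, nrow(xm), n_feat)
  Z <- matrix(NA_real_, nrow(xm), n_feat, dimnames = dimnames(xm))

  for (j in seq_len(n_feat)) {
    y <- xm[, j]
    ok <- !is.na(y)
    fit <- tryCatch(qr.coef(qr(D[ok, , drop = FALSE]), y[ok]),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit[seq_len(nb)])) {
      abort(sprintf("Non-finite batch estimates for feature '%s'.",
                    colnames(xm)[j]))
    }
    fit[is.na(fit)] <- 0
    alpha[j] <- sum(frac * fit[seq_len(nb)])
    if (!is.null(Xc)) {
      covfit[, j] <- Xc %*% fit[-seq_len(nb)]
    }
    resid <- y[ok] - D[ok, , drop = FALSE] %*% fit
    sigma2[j] <- mean(resid^2)
    if (!is.finite(sigma2[j]) || sigma2[j] <= 0) {
      abort(sprintf("Degenerate pooled variance for feature '%s'.",
                    colnames(xm)[j]))
    }
    Z[, j] <- (y - alpha[j] - covfit[, j]) / sqrt(sigma2[j])
  }

  gamma_hat <- delta2_hat <- gamma_star <- delta2_star <-
    matrix(NA_real_, n_feat, nb, dimnames = list(colnames(xm), levs))
  hyper <- tibble(batch = levs, gamma_bar = NA_real_, tau2 = NA_real_,
                  a_prior = NA_real_, b_prior = NA_real_)
  out <- xm

  for (b in seq_along(levs)) {
    rows <- which(batch == levs[b])
    Zb <- Z[rows, , drop = FALSE]
    n_jb <- colSums(!is.na(Zb))
    if (any(n_jb < 2)) {
      abort(sprintf("Fewer than 2 present values in batch '%s' for feature '%s'.",
                    levs[b], colnames(xm)[which(n_jb < 2)[1]]))
    }
    g_hat <- colMeans(Zb, na.rm = TRUE)
    d_hat <- apply(Zb, 2, var, na.rm = TRUE)
    gamma_hat[, b] <- g_hat
    delta2_hat[, b] <- d_hat

    if (n_feat >= 2) {
      g_bar <- mean(g_hat); t2 <- var(g_hat)
      m <- mean(d_hat); s2 <- var(d_hat)
      a_pr <- (2 * s2 + m^2) / s2
      b_pr <- (m * s2 + m^3) / s2
      ok_prior <- is.finite(t2) && t2 > 0 && is.finite(s2) && s2 > 0
    } else ok_prior <- FALSE

    if (ok_prior) {
      g_new <- g_hat; d_new <- d_hat
      for (it in seq_len(1000)) {
        g_old <- g_new; d_old <- d_new
        g_new <- (n_jb * t2 * g_hat + d_old * g_bar) / (n_jb * t2 + d_old)
        sse <- colSums((Zb - matrix(g_new, nrow(Zb), n_feat, byrow = TRUE))^2,
                       na.rm = TRUE)
        d_new <- (b_pr + 0.5 * sse) / (n_jb / 2 + a_pr - 1)
        ch <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / (abs(d_old) + 1e-12))
        if (ch < 1e-8) break
      }
      gamma_star[, b] <- g_new
      delta2_star[, b] <- d_new
      hyper[b, -1] <- tibble(gamma_bar = g_bar, tau2 = t2,
                             a_prior = a_pr, b_prior = b_pr)
    } else {
      gamma_star[, b] <- g_hat
      delta2_star[, b] <- d_hat
    }
    if (any(!is.finite(gamma_star[, b])) || any(delta2_star[, b] <= 0)) {
      abort(sprintf("Non-finite shrunk estimates in batch '%s'.", levs[b]))
    }

    adj <- sweep(sweep(Zb, 2, gamma_star[, b]), 2,
                 sqrt(delta2_star[, b]), "/")
    out[rows, ] <- sweep(adj, 2, sqrt(sigma2), "*") +
      matrix(alpha, length(rows), n_feat, byrow = TRUE) +
      covfit[rows, , drop = FALSE]
  }

  params <- structure(list(
    estimates = tidyr::pivot_longer(
      dplyr::mutate(as_tibble(gamma_hat, rownames = "feature")),
      -"feature", names_to = "batch", values_to = "gamma_hat") |>
      dplyr::mutate(
        delta2_hat = as.vector(t(delta2_hat)),
        gamma_star = as.vector(t(gamma_star)),
        delta2_star = as.vector(t(delta2_star))),
    hyper = hyper,
    feature = tibble(feature = colnames(xm), alpha_hat = alpha,
                     sigma2_hat = sigma2)
  ), class = "batch_model_params")

  list(matrix = retag(out, "corrected"), params = params)
}

#' @export
print.batch_model_params <- function(x, ...) {
  cat(sprintf("<batch_model_params> %d features x %d batches\n",
              nrow(x$feature), nrow(x$hyper)))
  print(x$hyper)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.batch_model_params <- function(x, ...) x$estimates

#' PCA-based outlier and pooled-QC assessment
#'
#' Runs PCA on mean-centred, unit-variance features (missing entries replaced
#' by the feature mean in a provisional copy; zero-variance features dropped)
#' and flags samples whose score on any of the leading components exceeds
#' `outlier_sd` score standard deviations. QC-replicate tightness is
#' summarised as the mean distance of QC samples to the QC centroid divided
#' by the mean distance of all samples to the grand centroid.
#'
#' @param x [feature_matrix()] (log2 or corrected scale).
#' @param meta sample metadata (see [filter_detection()]).
#' @param n_components number of leading components inspected.
#' @param outlier_sd flag threshold in score standard deviations.
#' @return a `pca_qc` list: `scores` tibble, `outliers` (sample ids),
#'   `qc_dispersion`, and the PCA `sdev`.
#' @export
pca_qc <- function(x, meta, n_components = 2, outlier_sd = 3) {
  assert_scale(x, c("log2", "corrected", "imputed"), "pca_qc")
  meta <- .align_meta(meta, x)
  if (n_components > min(dim(x))) {
    abort("`n_components` exceeds min(n_samples, n_features).")
  }
  xm <- unclass(x)
  for (j in seq_len(ncol(xm))) {
    miss <- is.na(xm[, j])
    if (any(miss)) xm[miss, j] <- mean(xm[, j], na.rm = TRUE)
  }
  v <- apply(xm, 2, var)
  xm <- xm[, v > 0, drop = FALSE]
  if (ncol(xm) == 0) {
    scores <- matrix(0, nrow(x), n_components,
                     dimnames = list(rownames(x),
                                     paste0("PC", seq_len(n_components))))
  } else {
    pc <- prcomp(xm, center = TRUE, scale. = TRUE)
    k <- min(n_components, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
  }
  score_sd <- apply(scores, 2, sd)
  flagged <- apply(scores, 1, function(r) any(abs(r) > outlier_sd * score_sd &
                                                score_sd > 0))
  qc_rows <- meta$diagnosis == "QC"
  qc_disp <- NA_real_
  grand_d <- mean(sqrt(rowSums(sweep(scores, 2, colMeans(scores))^2)))
  if (any(qc_rows)) {
    qc_sc <- scores[qc_rows, , drop = FALSE]
    qc_d <- mean(sqrt(rowSums(sweep(qc_sc, 2, colMeans(qc_sc))^2)))
    qc_disp <- if (grand_d > 0) qc_d / grand_d else 0
  }
  structure(list(
    scores = dplyr::bind_cols(
      tibble(sample_id = rownames(x), diagnosis = meta$diagnosis,
             batch = meta$batch),
      as_tibble(scores)),
    outliers = rownames(x)[flagged],
    qc_dispersion = qc_disp,
    sdev = if (exists("pc", inherits = FALSE)) pc$sdev else numeric(0)
  ), class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat(sprintf("<pca_qc> %d samples; %d outlier(s); QC dispersion %.3f\n",
              nrow(x$scores), length(x$outliers), x$qc_dispersion))
  if (length(x$outliers)) cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Feature-space KNN imputation within diagnostic groups
#'
#' Missing values are imputed separately within each diagnostic group (QC
#' injections form their own group): a missing value of feature `f` in sample
#' `s` is the unweighted mean, over the `k` features nearest to `f`, of their
#' values in `s`. Feature-feature distance is the root mean squared difference
#' over samples of the group where both features are present; candidate
#' neighbours must share at least half the group's samples with `f` and be
#' present in `s`. A feature with no present value in a group falls back to
#' its grand mean across all samples, with a warning.
#'
#' @param x corrected-scale [feature_matrix()].
#' @param meta sample metadata (see [filter_detection()]).
#' @param k number of neighbouring features (default 10).
#' @return imputed-scale [feature_matrix()] with no missing entries; present
#'   values are never altered.
#' @export
knn_impute <- function(x, meta, k = 10) {
  assert_scale(x, "corrected", "knn_impute")
  if (k < 1) abort("`k` must be >= 1.")
  meta <- .align_meta(meta, x)
  out <- unclass(x)
  grand_mean <- colMeans(out, na.rm = TRUE)
  if (anyNA(grand_mean)) {
    abort("Feature(s) with no present value anywhere cannot be imputed.")
  }
  fallback <- character(0)
  for (g in unique(meta$diagnosis)) {
    rows <- which(meta$diagnosis == g)
    M0 <- out[rows, , drop = FALSE]   # original missingness pattern
    M <- M0
    miss_feats <- which(colSums(is.na(M0)) > 0)
    for (f in miss_feats) {
      miss_rows <- which(is.na(M0[, f]))
      if (all(is.na(M0[, f]))) {
        M[miss_rows, f] <- grand_mean[f]
        fallback <- c(fallback, colnames(M)[f])
        next
      }
      diffs <- M0 - M0[, f]            # column recycling: each col minus f
      overlap <- colSums(!is.na(diffs))
      d2 <- colMeans(diffs^2, na.rm = TRUE)
      d2[f] <- Inf
      d2[overlap < max(1, ceiling(0.5 * nrow(M0)))] <- Inf
      for (s in miss_rows) {
        cand <- which(is.finite(d2) & !is.na(M0[s, ]))
        if (length(cand) == 0) {
          gm <- mean(M0[, f], na.rm = TRUE)
          M[s, f] <- if (is.finite(gm)) gm else grand_mean[f]
          fallback <- c(fallback, colnames(M)[f])
        } else {
          nn <- cand[order(d2[cand], cand)][seq_len(min(k, length(cand)))]
          M[s, f] <- mean(M0[s, nn])
        }
      }
    }
    out[rows, ] <- M
  }
  if (length(fallback)) {
    warn(paste0("Group-mean fallback used for feature(s): ",
                paste(unique(fallback), collapse = ", ")))
  }
  feature_matrix(out, "imputed")
}

#' Peak-ratio quantification against an internal standard
#'
#' Divides every analyte's peak area by the internal-standard area in the
#' same sample, and flags analytes that are not consistently above the limit
#' of quantification (present and `> loq` in every sample) as
#' non-quantifiable.
#'
#' @param quant data frame of peak areas, one row per sample; must contain
#'   `internal_standard` plus analyte columns.
#' @param internal_standard name of the internal-standard column.
#' @param loq limit of quantification on the raw area scale.
#' @return a list: `ratios` tibble (analyte areas divided by IS) and `flags`
#'   tibble with per-analyte `frac_above` and `quantifiable`.
#' @export
peak_ratio_quantify <- function(quant, internal_standard, loq) {
  quant <- as_tibble(quant)
  if (!internal_standard %in% names(quant)) {
    abort(paste0("No internal-standard column '", internal_standard, "'."))
  }
  is_area <- quant[[internal_standard]]
  if (anyNA(is_area) || any(is_area <= 0)) {
    abort("Internal-standard area must be present and > 0 for every sample.")
  }
  analytes <- setdiff(names(quant), internal_standard)
  num <- vapply(quant[analytes], is.numeric, logical(1))
  analytes <- analytes[num]
  ratios <- purrr::map_dfc(quant[analytes], function(a) a / is_area)
  flags <- purrr::map_dfr(analytes, function(a) {
    v <- quant[[a]]
    frac <- mean(!is.na(v) & v > loq)
    tibble(analyte = a, frac_above = frac, quantifiable = frac == 1)
  })
  list(ratios = ratios, flags = flags)
}
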