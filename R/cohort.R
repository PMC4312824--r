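#' Specify a synthetic lipidomics case-control cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults describe
#' the kind of cohort the package targets: three diagnostic groups
#' (40 controls, 48 MCI, 36 AD) plus 20 pooled-plasma QC injections analysed
#' in 4 batches, ~1900 aligned LC-MS features with log-normal intensities,
#' additive + multiplicative per-feature batch effects, a small set of
#' informative features whose levels decrease monotonically
#' control > MCI > AD, left-censored (limit-of-detection) plus completely
#' random missingness, and covariates (age, sex, APOE-e4 count, MMSE, statin,
#' smoking) drawn from a demographic model typical of elderly memory-clinic
#' cohorts.
#'
#' @param n_ctl,n_mci,n_ad,n_qc group sizes (controls, MCI, AD, pooled QC).
#' @param n_features number of aligned features.
#' @param n_informative number of features carrying a true group effect.
#' @param effect_log2 total control-to-AD decrease of informative features, in
#'   log2 units; MCI sits halfway. Must be >= 0 (0 = null cohort).
#' @param n_batches number of acquisition batches.
#' @param batch_additive_sd sd of the per-feature additive batch offsets
#'   (gamma), log2 units.
#' @param batch_scale_shape shape of the scaled inverse-gamma from which the
#'   per-feature multiplicative batch variance factors (delta^2, mean 1) are
#'   drawn; larger = less batch-to-batch variance heterogeneity.
#' @param lod_quantile per-feature intensity quantile below which values are
#'   censored with probability `lod_miss_prob`.
#' @param mcar_rate additional completely-at-random missingness fraction.
#' @param lod_miss_prob probability that a below-LOD intensity is missing.
#' @param planted_outlier if `TRUE`, one AD sample is shifted far from the
#'   cloud (a gross acquisition failure) so outlier detection has work to do.
#' @param seed integer seed; identical spec + seed gives identical cohorts.
#' @return a `cohort_spec` list.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_ctl = 40, n_mci = 48, n_ad = 36, n_qc = 20,
                        n_features = 1878, n_informative = 10,
                        effect_log2 = 1.5, n_batches = 4,
                        batch_additive_sd = 0.5, batch_scale_shape = 20,
                        lod_quantile = 0.05, mcar_rate = 0.01,
                        lod_miss_prob = 0.9, planted_outlier = TRUE,
                        seed = 1L) {
  counts <- c(n_ctl = n_ctl, n_mci = n_mci, n_ad = n_ad, n_qc = n_qc,
              n_features = n_features, n_batches = n_batches)
  if (any(counts <= 0) || any(counts != floor(counts))) {
    abort("All counts in a cohort spec must be positive integers.")
  }
  if (n_informative < 0 || n_informative > n_features) {
    abort("`n_informative` must lie in [0, n_features].")
  }
  if (lod_quantile < 0 || lod_quantile >= 1 || mcar_rate < 0 || mcar_rate >= 1) {
    abort("`lod_quantile` and `mcar_rate` must lie in [0, 1).")
  }
  if (lod_miss_prob < 0 || lod_miss_prob > 1) abort("`lod_miss_prob` in [0,1].")
  if (effect_log2 < 0) abort("`effect_log2` must be >= 0.")
  if (batch_additive_sd < 0) abort("`batch_additive_sd` must be >= 0.")
  if (batch_scale_shape <= 2) abort("`batch_scale_shape` must exceed 2.")
  structure(list(
    n_ctl = n_ctl, n_mci = n_mci, n_ad = n_ad, n_qc = n_qc,
    n_features = n_features, n_informative = n_informative,
    effect_log2 = effect_log2, n_batches = n_batches,
    batch_additive_sd = batch_additive_sd,
    batch_scale_shape = batch_scale_shape,
    lod_quantile = lod_quantile, mcar_rate = mcar_rate,
    lod_miss_prob = lod_miss_prob, planted_outlier = planted_outlier,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# demographic model for elderly memory-clinic cohorts: group-wise age and MMSE
# moments, female fraction, APOE-e4 genotype frequencies, statin/smoking rates
.covariate_model <- list(
  groups   = c("CTL", "MCI", "AD"),
  age_mean = c(78.46, 78.96, 78.14), age_sd = c(6.7, 5.6, 7.7),
  mmse_mean = c(29.00, 26.94, 21.49), mmse_sd = c(1.1, 1.9, 4.8),
  p_female = c(17 / 35, 26 / 48, 21 / 40),
  apoe     = list(CTL = c(33, 7, 0) / 40, MCI = c(28, 12, 3) / 43,
                  AD = c(15, 15, 6) / 36),
  p_statin = c(10 / 40, 20 / 48, 14 / 36),
  p_smoke  = c(6 / 29, 0, 9 / 34)
)

#' Generate a synthetic lipidomics cohort with known ground truth
#'
#' Draws a complete log2-scale intensity matrix from the generative model
#' described in [cohort_spec()] (per-feature baselines mu_f ~ U(10, 20) and
#' sds sigma_f ~ U(0.3, 1) on the log2 scale; informative features shifted
#' down by `effect_log2`/2 in MCI and `effect_log2` in AD; per-feature batch
#' effects following the location/scale model gamma_fb + delta_fb * noise
#' with gamma ~ N(0, sd^2) and delta^2 ~ scaled inverse-gamma with mean 1;
#' QC rows equal to the pooled mean profile plus batch effects and 0.05-sd
#' noise), exponentiates to raw peak areas, and censors intensities with
#' [inject_missingness()]. Covariates are drawn per diagnostic group from the
#' demographic model; QC injections carry no covariates.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `lipid_cohort`:
#' \describe{
#'   \item{matrix}{raw-scale [feature_matrix()] with missing values.}
#'   \item{meta}{tibble: `sample_id`, `diagnosis` (CTL/MCI/AD/QC), `age`,
#'     `sex`, `apoe4`, `batch`, `mmse`, `statin`, `smoking`.}
#'   \item{truth}{ground truth: `informative` feature ids, `gamma` and
#'     `delta2` matrices (features x batches), the complete pre-missingness
#'     `log2_complete` matrix, and `outlier_id` (or `NA`).}
#' }
#' @examples
#' ch <- generate_cohort(cohort_spec(n_features = 50, seed = 7))
#' ch$matrix
#' dplyr::count(ch$meta, diagnosis)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  withr::with_seed(spec$seed, {
    p <- spec$n_features
    groups <- rep(c("CTL", "MCI", "AD", "QC"),
                  times = c(spec$n_ctl, spec$n_mci, spec$n_ad, spec$n_qc))
    n <- length(groups)
    n_clin <- n - spec$n_qc
    ids <- sprintf("S%03d", seq_len(n))
    ids[groups == "QC"] <- sprintf("QC%02d", seq_len(spec$n_qc))

    feat_mass <- round(runif(p, 100, 1000), 4)
    feat_ids <- sprintf("mz%.4f_%d", feat_mass, seq_len(p))

    mu_f <- runif(p, 10, 20)
    sigma_f <- runif(p, 0.3, 1.0)
    informative <- sort(sample.int(p, spec$n_informative))

    # group shifts on the log2 scale (informative features only)
    shift_of <- c(CTL = 0, MCI = -spec$effect_log2 / 2, AD = -spec$effect_log2,
                  QC = 0)
    shift <- matrix(0, n, p)
    if (length(informative) > 0) {
      shift[, informative] <- unname(shift_of[groups])
    }

    # batch assignment: clinical samples randomised within group, QC spread
    # at regular intervals across batches
    batch <- integer(n)
    for (g in c("CTL", "MCI", "AD")) {
      idx <- which(groups == g)
      batch[idx] <- sample(rep_len(seq_len(spec$n_batches), length(idx)))
    }
    batch[groups == "QC"] <- rep_len(seq_len(spec$n_batches), spec$n_qc)

    gamma <- matrix(rnorm(p * spec$n_batches, 0, spec$batch_additive_sd),
                    p, spec$n_batches)
    a <- spec$batch_scale_shape
    delta2 <- matrix(1 / rgamma(p * spec$n_batches, shape = a, rate = a - 1),
                     p, spec$n_batches)
    rownames(gamma) <- rownames(delta2) <- feat_ids

    # pooled mean profile for the QC material: clinical-sample average
    pool_shift <- colMeans(shift[seq_len(n_clin), , drop = FALSE])

    log2m <- matrix(NA_real_, n, p, dimnames = list(ids, feat_ids))
    for (s in seq_len(n)) {
      b <- batch[s]
      if (groups[s] == "QC") {
        log2m[s, ] <- mu_f + pool_shift + gamma[, b] + rnorm(p, 0, 0.05)
      } else {
        log2m[s, ] <- mu_f + shift[s, ] + gamma[, b] +
          sqrt(delta2[, b]) * sigma_f * rnorm(p)
      }
    }

    outlier_id <- NA_character_
    if (isTRUE(spec$planted_outlier)) {
      s_out <- max(which(groups == "AD"))
      log2m[s_out, ] <- log2m[s_out, ] + 6 * sigma_f
      outlier_id <- ids[s_out]
    }

    meta <- .draw_covariates(ids, groups, batch)
    raw <- feature_matrix(2^log2m, "raw")
    observed <- .censor_matrix(raw, spec$lod_quantile, spec$mcar_rate,
                               spec$lod_miss_prob)

    structure(list(
      matrix = observed, meta = meta,
      truth = list(informative = feat_ids[informative], gamma = gamma,
                   delta2 = delta2, log2_complete = log2m,
                   outlier_id = outlier_id)
    ), class = "lipid_cohort")
  })
}

.draw_covariates <- function(ids, groups, batch) {
  cm <- .covariate_model
  n <- length(ids)
  age <- mmse <- rep(NA_real_, n)
  sex <- rep(NA_character_, n)
  apoe4 <- statin <- smoking <- rep(NA_integer_, n)
  for (g in cm$groups) {
    i <- which(groups == g)
    k <- match(g, cm$groups)
    age[i] <- rnorm(length(i), cm$age_mean[k], cm$age_sd[k])
    mmse[i] <- pmin(30, pmax(0, rnorm(length(i), cm$mmse_mean[k], cm$mmse_sd[k])))
    sex[i] <- ifelse(runif(length(i)) < cm$p_female[k], "F", "M")
    apoe4[i] <- sample(0:2, length(i), replace = TRUE, prob = cm$apoe[[g]])
    statin[i] <- rbinom(length(i), 1, cm$p_statin[k])
    smoking[i] <- rbinom(length(i), 1, cm$p_smoke[k])
  }
  tibble(sample_id = ids, diagnosis = groups, age = age, sex = sex,
         apoe4 = apoe4, batch = batch, mmse = round(mmse, 1),
         statin = statin, smoking = smoking)
}

#' Inject limit-of-detection and random missingness
#'
#' Emulates how peak-alignment software loses low-abundance signals: within
#' each feature, intensities below that feature's `lod_quantile` quantile go
#' missing with probability `lod_miss_prob` (left-censoring, missing not at
#' random), and an additional `mcar_rate` fraction of the remaining entries
#' goes missing completely at random.
#'
#' @param x complete, positive [feature_matrix()] (raw scale).
#' @param lod_quantile,mcar_rate censoring quantile and MCAR fraction, each in
#'   `[0, 1)`.
#' @param lod_miss_prob probability a below-LOD entry is lost (default 0.9).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return a [feature_matrix()] with `NA`s where intensities were lost.
#' @export
inject_missingness <- function(x, lod_quantile, mcar_rate,
                               lod_miss_prob = 0.9, seed = NULL) {
  if (anyNA(x)) abort("`x` must be complete before missingness injection.")
  if (lod_quantile < 0 || lod_quantile >= 1 || mcar_rate < 0 || mcar_rate >= 1) {
    abort("`lod_quantile` and `mcar_rate` must lie in [0, 1).")
  }
  with_seed_opt(seed, .censor_matrix(x, lod_quantile, mcar_rate, lod_miss_prob))
}

.censor_matrix <- function(x, lod_quantile, mcar_rate, lod_miss_prob) {
  out <- unclass(x)
  if (lod_quantile > 0 && lod_miss_prob > 0) {
    for (j in seq_len(ncol(out))) {
      q <- quantile(out[, j], lod_quantile, names = FALSE)
      low <- which(out[, j] < q)
      hit <- low[runif(length(low)) < lod_miss_prob]
      out[hit, j] <- NA_real_
    }
  }
  if (mcar_rate > 0) {
    pres <- which(!is.na(out))
    hit <- pres[runif(length(pres)) < mcar_rate]
    out[hit] <- NA_real_
  }
  feature_matrix(out, fm_scale(x))
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat(sprintf("<lipid_cohort> %d samples x %d features (%d informative)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$truth$informative)))
  print(table(x$meta$diagnosis))
  invisible(x)
}
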