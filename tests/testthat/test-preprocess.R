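test_that("total-mean-area normalisation scales samples to the mean total", {
  m <- toy_matrix(c(40, 100, 60, 200), 2, 2)
  out <- normalize_total_mean_area(m)
  # totals 100 and 300, mean 200 -> factors 2 and 2/3
  expect_equal(unname(unclass(out)[1, ]), c(40, 60) * 2)
  expect_equal(unname(unclass(out)[2, ]), c(100, 200) * 2 / 3)
  expect_equal(fm_scale(out), "normalized")
  # equal totals -> unchanged
  m2 <- toy_matrix(c(1, 2, 3, 2), 2, 2)
  expect_equal(unclass(normalize_total_mean_area(m2))[, ], unclass(m2)[, ])
  # all-missing sample errors with the sample named
  m3 <- unclass(m); m3[1, ] <- NA
  expect_error(normalize_total_mean_area(feature_matrix(m3, "raw")), "S01")
})

test_that("the scale tag enforces pipeline order", {
  m <- toy_matrix(1:4, 2, 2)
  expect_error(log2_transform(m), "normalized")
  expect_error(combat_correct(m, c(1, 2)), "log2")
  expect_error(knn_impute(normalize_total_mean_area(m), toy_meta(2, c("AD", "CTL"))),
               "corrected")
  expect_error(normalize_total_mean_area(normalize_total_mean_area(m)), "raw")
})

test_that("detection filter applies the every-group-and-every-batch rule", {
  n <- 20
  meta <- toy_meta(n, rep(c("CTL", "MCI", "AD", "QC"), each = 5),
                   batch = rep(1:4, times = 5))
  vals <- matrix(2, n, 3, dimnames = list(meta$sample_id, c("fA", "fB", "fC")))
  # fB: one missing entry in batch 3 among its 4 non-QC samples -> 75% there
  b3 <- which(meta$batch == 3 & meta$diagnosis != "QC")
  vals[b3[1], "fB"] <- NA
  # fC: detected everywhere but missing in ALL QC samples (QC must not count)
  vals[meta$diagnosis == "QC", "fC"] <- NA
  out <- filter_detection(feature_matrix(vals, "raw"), meta, threshold = 0.80)
  expect_setequal(colnames(out$matrix), c("fA", "fC"))
  expect_equal(out$dropped, "fB")
  # threshold 0 keeps everything
  expect_equal(ncol(filter_detection(feature_matrix(vals, "raw"), meta, 0)$matrix), 3)
  # unknown labels error
  meta_bad <- meta; meta_bad$diagnosis[1] <- "XX"
  expect_error(filter_detection(feature_matrix(vals, "raw"), meta_bad), "XX")
})

test_that("detection filter is monotone in the threshold", {
  sp <- cohort_spec(n_features = 60, lod_quantile = 0.15, mcar_rate = 0.05,
                    seed = 9)
  ch <- generate_cohort(sp)
  x <- normalize_total_mean_area(ch$matrix)
  kept <- lapply(c(0.5, 0.7, 0.8, 0.9), function(t) {
    colnames(filter_detection(x, ch$meta, t)$matrix)
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("log2 transform maps present values and preserves missingness", {
  m <- toy_matrix(c(8, 1, NA, 2), 2, 2, scale = "normalized")
  out <- log2_transform(m)
  expect_equal(unclass(out)[1, 1], 3)
  expect_equal(unclass(out)[2, 1], 0)
  expect_true(is.na(unclass(out)[1, 2]))
  # non-positive present values cannot even be represented on this scale
  m0 <- unclass(m); m0[2, 2] <- 0
  expect_error(feature_matrix(m0, "normalized"), "strictly positive")
})

test_that("normality assessment has power and holds its size", {
  # exponential data: rejected nearly always
  rej <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      m <- toy_matrix(rexp(100), 100, 1, scale = "log2")
      assess_normality(m)$p < 0.05
    })
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  # normal data: near-nominal rejection
  rej0 <- vapply(1:500, function(s) {
    withr::with_seed(1000 + s, {
      m <- toy_matrix(rnorm(100), 100, 1, scale = "log2")
      assess_normality(m)$p < 0.05
    })
  }, logical(1))
  expect_lt(abs(mean(rej0) - 0.05), 0.03)
  # constant feature skipped with warning
  m <- toy_matrix(c(1, 1, 1, 1, 2, 3), 3, 2, scale = "log2")
  expect_warning(res <- assess_normality(m), "constant")
  expect_equal(nrow(res), 1)
})

test_that("batch correction removes planted batch effects and recovers gamma", {
  withr::with_seed(21, {
    n_b <- 200; p <- 40
    batch <- rep(c("b1", "b2"), each = n_b)
    gam <- c(b1 = 1, b2 = -1)
    base <- matrix(rnorm(2 * n_b * p, 14, 1), 2 * n_b, p,
                   dimnames = list(sprintf("S%03d", 1:(2 * n_b)),
                                   sprintf("f%02d", 1:p)))
    y <- base + gam[batch]
    cc <- combat_correct(feature_matrix(y, "log2"), batch)
    out <- unclass(cc$matrix)
    gaps <- colMeans(out[batch == "b1", ]) - colMeans(out[batch == "b2", ])
    expect_lt(abs(mean(gaps)), 0.05)       # batch means agree overall
    expect_lt(mean(abs(gaps)), 0.1)        # per-feature residue is noise-level
    # data-scale recovered gamma within 0.1 of +/-1
    est <- tidy(cc$params) |>
      dplyr::left_join(cc$params$feature, by = "feature") |>
      dplyr::mutate(gamma_data = gamma_hat * sqrt(sigma2_hat))
    expect_lt(mean(abs(est$gamma_data[est$batch == "b1"] - 1)), 0.1)
    expect_lt(mean(abs(est$gamma_data[est$batch == "b2"] + 1)), 0.1)
    # shrunk location estimates lie between raw estimates and the prior mean
    for (b in c("b1", "b2")) {
      e <- est[est$batch == b, ]
      gbar <- cc$params$hyper$gamma_bar[cc$params$hyper$batch == b]
      expect_true(all(
        (e$gamma_star >= pmin(e$gamma_hat, gbar) - 1e-10) &
          (e$gamma_star <= pmax(e$gamma_hat, gbar) + 1e-10)))
    }
  })
})

test_that("single-batch correction is the identity", {
  m <- toy_matrix(rnorm(30, 14), 10, 3, scale = "log2")
  cc <- combat_correct(m, rep(1, 10))
  expect_equal(unclass(cc$matrix)[, ], unclass(m)[, ], tolerance = 1e-8)
  expect_equal(fm_scale(cc$matrix), "corrected")
  expect_error(combat_correct(toy_matrix(rnorm(9, 14), 3, 3, scale = "log2"),
                              c(1, 1, 2)), "Singleton")
})

test_that("EB correction matches sva::ComBat on complete data", {
  skip_if_not_installed("sva")
  withr::with_seed(34, {
    n <- 30; p <- 25
    batch <- rep(1:3, each = 10)
    gam <- matrix(rnorm(p * 3, 0, 0.8), p, 3)
    y <- matrix(rnorm(n * p, 12, 1), n, p,
                dimnames = list(sprintf("S%02d", 1:n), sprintf("f%02d", 1:p)))
    for (b in 1:3) y[batch == b, ] <- y[batch == b, ] +
        matrix(gam[, b], sum(batch == b), p, byrow = TRUE)
    ours <- combat_correct(feature_matrix(y, "log2"), batch)
    theirs <- t(suppressMessages(
      sva::ComBat(dat = t(y), batch = batch, par.prior = TRUE,
                  prior.plots = FALSE)))
    expect_equal(unclass(ours$matrix)[, ], theirs, tolerance = 1e-4)
  })
})

test_that("with many samples the EB adjustment approaches plain standardization", {
  withr::with_seed(55, {
    n_b <- 2500; p <- 30
    batch <- rep(1:2, each = n_b)
    gam <- matrix(rnorm(p * 2, 0, 0.7), p, 2)
    dl <- matrix(exp(rnorm(p * 2, 0, 0.5)), p, 2)
    y <- matrix(NA_real_, 2 * n_b, p,
                dimnames = list(sprintf("S%04d", 1:(2 * n_b)),
                                sprintf("f%02d", 1:p)))
    for (b in 1:2) {
      rows <- which(batch == b)
      y[rows, ] <- matrix(rnorm(length(rows) * p), length(rows), p) *
        matrix(sqrt(dl[, b]), length(rows), p, byrow = TRUE) +
        matrix(14 + gam[, b], length(rows), p, byrow = TRUE)
    }
    ours <- unclass(combat_correct(feature_matrix(y, "log2"), batch)$matrix)
    oracle <- combat_nonparam_oracle(y, batch)
    expect_lt(mean(abs(ours - oracle)), 1e-2)
    expect_lt(max(abs(ours - oracle)), 0.1)
  })
})

test_that("batch correction ignores and preserves missing entries", {
  withr::with_seed(66, {
    y <- matrix(rnorm(200 * 10, 14), 200, 10,
                dimnames = list(sprintf("S%03d", 1:200), sprintf("f%02d", 1:10)))
    y[sample(length(y), 150)] <- NA
    cc <- combat_correct(feature_matrix(y, "log2"), rep(1:2, each = 100))
    expect_identical(is.na(unclass(cc$matrix)), is.na(y))
  })
})

test_that("group contrasts survive balanced-batch correction", {
  sp <- cohort_spec(n_features = 60, n_informative = 6, effect_log2 = 1.5,
                    lod_quantile = 0, mcar_rate = 0, planted_outlier = FALSE,
                    seed = 12)
  ch <- generate_cohort(sp)
  x <- log2_transform(normalize_total_mean_area(ch$matrix))
  cc <- combat_correct(x, ch$meta$batch)
  g <- ch$meta$diagnosis
  for (f in ch$truth$informative) {
    before <- mean(x[g == "AD", f]) - mean(x[g == "CTL", f])
    after <- mean(unclass(cc$matrix)[g == "AD", f]) -
      mean(unclass(cc$matrix)[g == "CTL", f])
    expect_lt(abs(before - after), 0.1)
  }
})

test_that("PCA QC flags gross outliers and measures QC tightness", {
  withr::with_seed(8, {
    n <- 100; p <- 40
    y <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("S%03d", 1:n), sprintf("f%02d", 1:p)))
    y[1, ] <- y[1, ] + 10
    meta <- toy_meta(n, rep("CTL", n), ids = rownames(y))
    meta$diagnosis[95:100] <- "QC"
    y[95:100, ] <- matrix(rnorm(6 * p, 0, 0.05), 6, p)   # tight QC replicates
    qc <- pca_qc(feature_matrix(y, "log2"), meta)
    expect_true("S001" %in% qc$outliers)
    expect_lt(qc$qc_dispersion, 0.2)
  })
  # identical samples: no outliers, zero dispersion
  y0 <- matrix(5, 10, 4, dimnames = list(sprintf("S%02d", 1:10),
                                         sprintf("f%02d", 1:4)))
  meta0 <- toy_meta(10, c(rep("CTL", 8), "QC", "QC"))
  qc0 <- pca_qc(feature_matrix(y0, "log2"), meta0)
  expect_length(qc0$outliers, 0)
  expect_equal(qc0$qc_dispersion, 0)
  expect_error(pca_qc(feature_matrix(y0, "log2"), meta0, n_components = 50),
               "n_components")
})

test_that("KNN imputation follows feature-neighbour semantics", {
  withr::with_seed(77, {
    n <- 12; p <- 6
    meta <- toy_meta(n, rep("CTL", n))
    y <- matrix(rnorm(n * p, 10), n, p,
                dimnames = list(meta$sample_id, sprintf("f%02d", 1:p)))
    # duplicated feature, one missing entry, k = 1 -> copies the duplicate
    y[, 2] <- y[, 1]
    y1 <- y; y1[3, 2] <- NA
    out1 <- knn_impute(feature_matrix(y1, "corrected"), meta, k = 1)
    expect_equal(unclass(out1)[3, 2], y[3, 1])
    # k >= p - 1 -> mean of all other present features in that sample
    y2 <- y; y2[5, 4] <- NA
    out2 <- knn_impute(feature_matrix(y2, "corrected"), meta, k = p - 1)
    expect_equal(unclass(out2)[5, 4], mean(y[5, -4]))
    # complete matrix: values unchanged, idempotent
    out3 <- knn_impute(feature_matrix(y, "corrected"), meta, k = 3)
    expect_equal(unclass(out3)[, ], y)
    # present values never altered
    pres <- !is.na(y1)
    expect_equal(unclass(out1)[pres], y1[pres])
    expect_equal(fm_scale(out1), "imputed")
  })
})

test_that("KNN imputation is per-phenotype and falls back to the grand mean", {
  withr::with_seed(78, {
    meta <- toy_meta(12, rep(c("CTL", "AD"), each = 6))
    y <- matrix(rnorm(12 * 4, 10), 12, 4,
                dimnames = list(meta$sample_id, sprintf("f%02d", 1:4)))
    # f1 entirely missing within AD -> grand-mean fallback with warning
    y[7:12, 1] <- NA
    expect_warning(out <- knn_impute(feature_matrix(y, "corrected"), meta, k = 2),
                   "fallback")
    expect_equal(unique(unclass(out)[7:12, 1]), mean(y[1:6, 1]))
    # imputation in one group does not depend on the other group's samples:
    # duplicate-feature trick confined to CTL
    y2 <- matrix(rnorm(12 * 4, 10), 12, 4,
                 dimnames = list(meta$sample_id, sprintf("f%02d", 1:4)))
    y2[, 2] <- y2[, 1] + c(rep(0, 6), rep(100, 6))  # duplicate only within CTL
    y2[3, 2] <- NA
    out2 <- knn_impute(feature_matrix(y2, "corrected"), meta, k = 1)
    expect_equal(unclass(out2)[3, 2], y2[3, 1])
  })
})

test_that("peak-ratio quantification divides by the IS and applies the LOQ rule", {
  q <- tibble::tibble(IS = c(1000, 1000), a1 = c(2000, 3000),
                      a2 = c(1000, 1000), a3 = c(400, 3000))
  out <- peak_ratio_quantify(q, "IS", loq = 500)
  expect_equal(out$ratios$a1, c(2, 3))
  expect_equal(out$ratios$a2, c(1, 1))
  expect_true(out$flags$quantifiable[out$flags$analyte == "a1"])
  # below LOQ in one sample -> non-quantifiable
  expect_false(out$flags$quantifiable[out$flags$analyte == "a3"])
  expect_error(peak_ratio_quantify(tibble::tibble(IS = c(0, 1), a = c(1, 2)),
                                   "IS", 1), "Internal-standard")
})
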