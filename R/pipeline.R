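#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] into one validated
#' list. Either a [cohort_spec()] (synthetic input) or `matrix_csv` +
#' `meta_csv` paths must be supplied.
#'
#' @param cohort a [cohort_spec()], or `NULL` when reading CSVs.
#' @param matrix_csv,meta_csv input paths (see [read_feature_matrix()]);
#'   ignored when `cohort` is given.
#' @param detection_threshold stratified detection-rate cutoff.
#' @param combat apply batch correction?
#' @param knn_k imputation neighbours.
#' @param outlier_sd PCA outlier threshold (score sds); flagged non-QC
#'   samples are removed before imputation.
#' @param associate,classify stage toggles.
#' @param interaction also run APOE-interaction models?
#' @param split_fraction,split_mode train/test split (see
#'   [split_train_test()]).
#' @param n_boot,ntree,top_fraction,tolerance_pct,include_apoe classifier
#'   parameters; `include_apoe` appends the APOE-e4 count as a candidate
#'   predictor.
#' @param seed global seed driving every stochastic stage.
#' @param out_dir if non-`NULL`, every intermediate artifact is written here.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            matrix_csv = NULL, meta_csv = NULL,
                            detection_threshold = 0.80, combat = TRUE,
                            knn_k = 10, outlier_sd = 3,
                            associate = TRUE, classify = TRUE,
                            interaction = FALSE,
                            split_fraction = 2 / 3,
                            split_mode = "stratified",
                            n_boot = 100, ntree = 500, top_fraction = 0.10,
                            tolerance_pct = 1.5, include_apoe = FALSE,
                            seed = 1L, out_dir = NULL) {
  if (is.null(cohort) && (is.null(matrix_csv) || is.null(meta_csv))) {
    abort("Supply either a cohort_spec or matrix_csv + meta_csv paths.")
  }
  if (!is.null(matrix_csv) && !is.null(cohort)) {
    abort("Supply a cohort_spec or CSV paths, not both.")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `cohort` mapping
#' maps to [cohort_spec()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(cohort_spec, y$cohort)
  do.call(pipeline_config, y)
}

#' Run the full case-control lipidomics pipeline
#'
#' Executes simulate/load -> normalise -> detection filter -> log2 ->
#' batch correction -> PCA QC (outlier removal) -> KNN imputation ->
#' association scan -> two-stage random-forest classifier -> group-trend
#' summary, logging per-stage feature and sample counts. Identical config +
#' seed reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages?
#' @return a `run_report` list with elements `counts`, `qc`, `normality`,
#'   `association`, `selection`, `metrics`, `external`, `trend`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, name, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    obj
  }

  withr::with_seed(as.integer(config$seed), {
    # ---- input ----
    if (!is.null(config$cohort)) {
      cohort <- generate_cohort(config$cohort)
      x <- cohort$matrix; meta <- cohort$meta
      truth <- cohort$truth
    } else {
      x <- read_feature_matrix(config$matrix_csv)
      meta <- readr::read_csv(config$meta_csv, show_col_types = FALSE)
      truth <- NULL
    }
    emit(x, "matrix_raw.csv", write_feature_matrix)
    emit(meta, "meta.csv", function(o, p) readr::write_csv(o, p))
    counts <- list(n_samples = nrow(x), n_features_extracted = ncol(x))
    say("input: %d samples x %d features", nrow(x), ncol(x))

    # ---- preprocess ----
    x <- normalize_total_mean_area(x)
    filt <- filter_detection(x, meta, config$detection_threshold)
    x <- filt$matrix
    counts$n_features_detected <- ncol(x)
    say("detection filter: %d -> %d features",
        counts$n_features_extracted, ncol(x))
    x <- log2_transform(x)
    params <- NULL
    if (isTRUE(config$combat)) {
      cc <- combat_correct(x, meta$batch[match(rownames(x), meta$sample_id)])
      x <- cc$matrix; params <- cc$params
      say("batch correction applied (%d batches)",
          length(unique(meta$batch)))
    } else {
      x <- retag(unclass(x), "corrected")
    }
    qc <- pca_qc(x, meta, outlier_sd = config$outlier_sd)
    drop_ids <- setdiff(qc$outliers,
                        meta$sample_id[meta$diagnosis == "QC"])
    if (length(drop_ids)) {
      say("removing %d outlier sample(s): %s", length(drop_ids),
          paste(drop_ids, collapse = ", "))
      x <- x[!rownames(x) %in% drop_ids, , drop = FALSE]
      meta <- meta[!meta$sample_id %in% drop_ids, , drop = FALSE]
    }
    counts$n_outliers_removed <- length(drop_ids)
    counts$n_samples_analysed <- nrow(x)
    x <- knn_impute(x, meta, k = config$knn_k)
    emit(x, "matrix_imputed.csv", write_feature_matrix)

    # clinical (non-QC) view used by the statistical stages
    clin <- meta$diagnosis != "QC"
    xc <- unclass(x)[clin, , drop = FALSE]
    mc <- meta[clin, , drop = FALSE]
    norm <- assess_normality(x[clin, , drop = FALSE])
    say("imputation complete; %.1f%% of features reject normality at 0.05",
        100 * attr(norm, "prop_reject"))

    report <- list(
      counts = counts,
      qc = list(qc_dispersion = qc$qc_dispersion, outliers = drop_ids,
                prop_nonnormal = attr(norm, "prop_reject")),
      normality = norm, association = NULL, selection = NULL,
      metrics = NULL, external = NULL, trend = NULL)

    # ---- association ----
    if (isTRUE(config$associate)) {
      assoc <- associate_features(x, meta, interaction = config$interaction)
      report$association <- assoc
      say("association: %d features, %d at q < 0.05",
          nrow(assoc), sum(assoc$q < 0.05))
      emit(assoc, "association.csv", function(o, p) readr::write_csv(o, p))
    }

    # ---- classifier ----
    if (isTRUE(config$classify)) {
      plan <- split_train_test(mc, config$split_fraction, config$split_mode)
      ytr_meta <- mc[match(plan$train, mc$sample_id), ]
      yte_meta <- mc[match(plan$test, mc$sample_id), ]
      xtr <- xc[plan$train, , drop = FALSE]
      xte <- xc[plan$test, , drop = FALSE]
      if (isTRUE(config$include_apoe)) {
        xtr <- cbind(xtr, APOE4 = ytr_meta$apoe4)
        xte <- cbind(xte, APOE4 = yte_meta$apoe4)
      }
      ytr <- factor(ytr_meta$diagnosis, levels = c("CTL", "AD"))
      yte <- factor(yte_meta$diagnosis, levels = c("CTL", "AD"))

      ranks <- bootstrap_rank_features(xtr, ytr, n_boot = config$n_boot,
                                       ntree = config$ntree)
      top <- select_top_fraction(ranks, config$top_fraction)
      say("rank aggregation: top %d of %d candidates (mtry = %d)",
          length(top), ncol(xtr), attr(ranks, "mtry"))
      profile <- rfe_profile(xtr, ytr, top, n_boot = config$n_boot,
                             ntree = config$ntree)
      size <- pick_size_tolerance(profile, config$tolerance_pct)
      selected <- attr(profile, "subsets")[[as.character(size)]]
      say("rfe: selected size %d (profile max %.3f)", size,
          max(profile$mean_auc))
      final <- fit_final_and_evaluate(xtr, ytr, xte, yte, selected,
                                      ntree = config$ntree,
                                      mtry = attr(ranks, "mtry"))
      say("test set: accuracy %.3f, AUC %.3f",
          final$test_metrics$accuracy, final$test_metrics$auc)

      mci_rows <- mc$diagnosis == "MCI"
      external <- NULL
      if (any(mci_rows)) {
        external <- classify_external(final, xc[mci_rows, , drop = FALSE])
        say("MCI application: %s",
            paste(names(external$counts), external$counts,
                  sep = "=", collapse = ", "))
      }
      report$selection <- list(
        split = plan, ranks = tidy(ranks), mtry = attr(ranks, "mtry"),
        top_candidates = top, profile = tidy(profile),
        selected_size = size, selected_features = selected)
      report$metrics <- tidy(final)
      report$final_model <- final
      report$external <- external
      emit(tibble(feature = selected), "selected_features.csv",
           function(o, p) readr::write_csv(o, p))
    }

    # ---- trend summary ----
    if (all(c("CTL", "MCI", "AD") %in% mc$diagnosis)) {
      feats <- report$selection$selected_features %||% colnames(xc)
      report$trend <- trend_summary(x, meta, feats)
    }
    if (!is.null(truth)) report$truth <- truth

    report <- structure(report, class = "run_report")
    if (!is.null(out_dir)) {
      write_report_json(report, file.path(out_dir, "report.json"))
    }
    report
  })
}

#' Group-trend summary of selected features
#'
#' Per feature: group means and sds across CTL / MCI / AD, the one-way ANOVA
#' p-value, and a monotone-direction call from the strict ordering of the
#' three group means (`decreasing` = CTL > MCI > AD, `increasing` =
#' CTL < MCI < AD, otherwise `non-monotone`).
#'
#' @param x imputed-scale [feature_matrix()].
#' @param meta sample metadata; all three diagnostic groups must be present.
#' @param features feature ids to summarise.
#' @return tibble, one row per feature.
#' @export
trend_summary <- function(x, meta, features) {
  meta <- .align_meta(meta, x)
  if (!all(c("CTL", "MCI", "AD") %in% meta$diagnosis)) {
    abort("All three diagnostic groups must be present.")
  }
  if (!all(features %in% colnames(x))) {
    abort("Unknown feature id(s) in `features`.")
  }
  clin <- meta$diagnosis %in% c("CTL", "MCI", "AD")
  g <- factor(meta$diagnosis[clin], levels = c("CTL", "MCI", "AD"))
  xm <- unclass(x)[clin, , drop = FALSE]
  purrr::map_dfr(features, function(f) {
    v <- xm[, f]
    mns <- tapply(v, g, mean, na.rm = TRUE)
    sds <- tapply(v, g, sd, na.rm = TRUE)
    an <- group_anova_tukey(v[!is.na(v)], g[!is.na(v)], alpha = -1)
    dir <- if (mns["CTL"] > mns["MCI"] && mns["MCI"] > mns["AD"]) {
      "decreasing"
    } else if (mns["CTL"] < mns["MCI"] && mns["MCI"] < mns["AD"]) {
      "increasing"
    } else "non-monotone"
    tibble(feature = f,
           mean_ctl = mns[["CTL"]], mean_mci = mns[["MCI"]],
           mean_ad = mns[["AD"]], sd_ctl = sds[["CTL"]],
           sd_mci = sds[["MCI"]], sd_ad = sds[["AD"]],
           anova_p = an$p, direction = dir)
  })
}

#' Serialise a run report to JSON
#'
#' Writes a stable, schema-validatable JSON rendering of the report
#' (tibbles as column-oriented records, full numeric precision) so that
#' identical runs produce byte-identical files.
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

report_as_list <- function(report) {
  sel <- report$selection
  list(
    counts = report$counts,
    qc = report$qc,
    association = if (!is.null(report$association)) {
      as.list(report$association)
    },
    selection = if (!is.null(sel)) list(
      train = sel$split$train, test = sel$split$test,
      mode = sel$split$mode, mtry = sel$mtry,
      top_candidates = sel$top_candidates,
      profile = as.list(sel$profile),
      selected_size = sel$selected_size,
      selected_features = sel$selected_features),
    metrics = if (!is.null(report$metrics)) as.list(report$metrics),
    external = if (!is.null(report$external)) {
      list(counts = as.list(report$external$counts))
    },
    trend = if (!is.null(report$trend)) as.list(report$trend)
  )
}

#' Validate the structure of a run report
#'
#' Checks the report (or a JSON file written by [write_report_json()])
#' against the schema shipped in `inst/extdata/run_report_schema.json`:
#' required top-level fields, count consistency across stages, and legal
#' trend directions.
#'
#' @param report a `run_report` or a path to a report JSON.
#' @return `TRUE` invisibly; aborts with a message otherwise.
#' @export
validate_run_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata",
                                            "run_report_schema.json",
                                            package = "lipidcc"))
  need <- unlist(schema$required)
  obj <- if (inherits(report, "run_report")) report_as_list(report) else report
  miss <- setdiff(need, names(obj))
  if (length(miss)) abort(paste0("Report lacks field(s): ",
                                 paste(miss, collapse = ", ")))
  cn <- obj$counts
  if (cn$n_features_detected > cn$n_features_extracted) {
    abort("Detected feature count exceeds extracted count.")
  }
  if (!is.null(obj$trend)) {
    bad <- setdiff(unique(unlist(obj$trend$direction)),
                   c("decreasing", "increasing", "non-monotone"))
    if (length(bad)) abort("Illegal trend direction label.")
  }
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  features: %d extracted -> %d analysed; %d sample(s) removed\n",
              x$counts$n_features_extracted, x$counts$n_features_detected,
              x$counts$n_outliers_removed))
  if (!is.null(x$association)) {
    cat(sprintf("  association: %d at q < 0.05\n",
                sum(x$association$q < 0.05)))
  }
  if (!is.null(x$selection)) {
    cat(sprintf("  classifier: %d features selected, test AUC %.3f\n",
                x$selection$selected_size,
                x$metrics$auc[x$metrics$set == "test"]))
  }
  invisible(x)
}
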