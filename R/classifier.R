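#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' case scores above a randomly chosen control, with ties counted 1/2.
#'
#' @param scores numeric classifier scores, higher = more case-like.
#' @param is_case logical, `TRUE` for cases.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, is_case) {
  is_case <- as.logical(is_case)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) abort("Both classes required to compute an AUC.")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train/test split of the case-control samples
#'
#' Splits the case and control samples into a training fraction and a
#' held-out test set. `"stratified"` preserves class proportions (per-class
#' training count rounded); `"balanced"` takes equal numbers of each class
#' into training (the training fraction of the smaller class, floored),
#' leaving the remainder as the test set.
#'
#' @param meta sample metadata with `sample_id` and `diagnosis`.
#' @param fraction training fraction, in (0, 1) (default 2/3).
#' @param mode `"stratified"` (default) or `"balanced"`.
#' @param classes two diagnosis labels, case first.
#' @param seed optional seed.
#' @return a `split_plan` list: `train`, `test` (sample ids), `mode`,
#'   `fraction`.
#' @export
split_train_test <- function(meta, fraction = 2 / 3,
                             mode = c("stratified", "balanced"),
                             classes = c("AD", "CTL"), seed = NULL) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  if (length(classes) != 2) abort("`classes` must name exactly two groups.")
  meta <- as_tibble(meta)
  with_seed_opt(seed, {
    ids <- list()
    sizes <- vapply(classes,
                    function(cl) sum(meta$diagnosis == cl), integer(1))
    if (any(sizes < 4)) abort("Need at least 4 samples per class.")
    n_train <- switch(mode,
      stratified = pmax(1, pmin(sizes - 1, round(fraction * sizes))),
      balanced = rep(max(1, floor(fraction * min(sizes))), 2))
    train <- unlist(lapply(seq_along(classes), function(i) {
      pool <- meta$sample_id[meta$diagnosis == classes[i]]
      sample(pool, n_train[i])
    }))
    all_cc <- meta$sample_id[meta$diagnosis %in% classes]
    plan <- structure(list(train = sort(train),
                           test = sort(setdiff(all_cc, train)),
                           mode = mode, fraction = fraction),
                      class = "split_plan")
    test_cls <- meta$diagnosis[match(plan$test, meta$sample_id)]
    if (length(unique(test_cls)) < 2) {
      abort("Both classes must be present in the test set; lower `fraction`.")
    }
    plan
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d train / %d test\n", x$mode,
              length(x$train), length(x$test)))
  invisible(x)
}

# stratified 75/25 resample of the training indices; returns list(tr, te).
# replace = TRUE draws the inner training part with replacement, the inner
# test part is then the never-drawn samples.
.resample <- function(y, inner_fraction, replace) {
  idx_by <- split(seq_along(y), y)
  tr <- unlist(lapply(idx_by, function(ix) {
    n_tr <- max(1, round(inner_fraction * length(ix)))
    if (replace) return(sample(ix, n_tr, replace = TRUE))
    sample(ix, min(n_tr, length(ix) - 1))   # keep >= 1 of each class out
  }))
  te <- setdiff(seq_along(y), unique(tr))
  list(tr = tr, te = te)
}

.resample_checked <- function(y, inner_fraction, replace, max_redraws = 10) {
  for (i in seq_len(max_redraws)) {
    rs <- .resample(y, inner_fraction, replace)
    if (length(unique(y[rs$tr])) == 2 && length(unique(y[rs$te])) == 2) {
      return(rs)
    }
  }
  abort("Could not draw a resample containing both classes in both parts.")
}

.fit_rf <- function(x, y, ntree, mtry, importance = FALSE) {
  randomForest::randomForest(x = x, y = y, ntree = ntree,
                             mtry = min(mtry, ncol(x)),
                             importance = importance)
}

.rf_scores <- function(fit, x, case_level) {
  predict(fit, x, type = "prob")[, case_level]
}

.rf_importance <- function(fit, measure) {
  if (measure == "permutation") {
    imp <- randomForest::importance(fit, type = 1)[, 1]
  } else {
    imp <- randomForest::importance(fit, type = 2)[, 1]
  }
  imp
}

default_mtry_grid <- function(p) {
  s <- floor(sqrt(p))
  sort(unique(pmin(p, pmax(1, c(floor(s / 2), s, 2 * s)))))
}

#' Bootstrapped random-forest variable-importance rank aggregation
#'
#' First stage of the feature-selection procedure. The training samples are
#' resampled `n_boot` times into stratified 75% / 25% parts. In each
#' resample, a random forest is fitted on the 75% part for every `mtry` in
#' the grid and scored by AUC on the 25% part; the importance ranking of the
#' best-`mtry` forest (rank 1 = most important, ties broken by feature
#' order) contributes to each feature's summed rank. The overall `mtry` is
#' the grid value with the best mean resample AUC.
#'
#' @param x complete numeric matrix of training samples x features.
#' @param y two-level factor of class labels; the *last* level is treated as
#'   the case (scored) class.
#' @param n_boot number of resamples (default 100).
#' @param ntree trees per forest (default 500).
#' @param mtry_grid candidate `mtry` values; default
#'   `{floor(sqrt(p)/2), floor(sqrt(p)), 2 floor(sqrt(p))}` clipped to
#'   `[1, p]`.
#' @param importance `"impurity"` (mean decrease in Gini, default) or
#'   `"permutation"`.
#' @param inner_fraction inner training fraction (default 0.75).
#' @param replace draw the inner training part with replacement?
#' @param seed optional seed.
#' @return a `rank_aggregate`: tibble of `feature`, `summed_rank`,
#'   `mean_importance` plus attributes `n_boot`, `mtry` (chosen),
#'   `mtry_auc` (mean AUC per grid value).
#' @export
bootstrap_rank_features <- function(x, y, n_boot = 100, ntree = 500,
                                    mtry_grid = NULL,
                                    importance = c("impurity", "permutation"),
                                    inner_fraction = 0.75, replace = FALSE,
                                    seed = NULL) {
  importance <- match.arg(importance)
  y <- droplevels(factor(y))
  .check_xy(x, y)
  if (is.null(mtry_grid)) mtry_grid <- default_mtry_grid(ncol(x))
  case_level <- levels(y)[nlevels(y)]

  with_seed_opt(seed, {
    p <- ncol(x)
    summed <- setNames(numeric(p), colnames(x))
    imp_sum <- setNames(numeric(p), colnames(x))
    auc_m <- matrix(NA_real_, n_boot, length(mtry_grid),
                    dimnames = list(NULL, as.character(mtry_grid)))
    for (b in seq_len(n_boot)) {
      rs <- .resample_checked(y, inner_fraction, replace)
      fits <- lapply(mtry_grid, function(m) {
        .fit_rf(x[rs$tr, , drop = FALSE], y[rs$tr], ntree, m,
                importance = (importance == "permutation"))
      })
      aucs <- vapply(fits, function(f) {
        auc_score(.rf_scores(f, x[rs$te, , drop = FALSE], case_level),
                  y[rs$te] == case_level)
      }, numeric(1))
      auc_m[b, ] <- aucs
      best <- fits[[which.max(aucs)]]
      imp <- .rf_importance(best, importance)[colnames(x)]
      rk <- rank(-imp, ties.method = "first")
      summed <- summed + rk
      imp_sum <- imp_sum + imp
    }
    mean_auc <- colMeans(auc_m)
    structure(
      tibble(feature = colnames(x), summed_rank = unname(summed),
             mean_importance = unname(imp_sum) / n_boot),
      n_boot = n_boot, mtry = mtry_grid[which.max(mean_auc)],
      mtry_auc = mean_auc, case_level = case_level,
      class = c("rank_aggregate", class(tibble())))
  })
}

.check_xy <- function(x, y) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix.")
  if (anyNA(x)) abort("`x` must be complete (impute first).")
  if (is.null(colnames(x))) abort("`x` must have feature (column) names.")
  if (nlevels(y) != 2 || length(y) != nrow(x)) {
    abort("`y` must be a two-level factor aligned with the rows of `x`.")
  }
  if (any(table(y) < 2)) abort("Need at least 2 samples per class.")
}

#' @exportS3Method generics::tidy
tidy.rank_aggregate <- function(x, ...) {
  dplyr::arrange(as_tibble(x), .data$summed_rank)
}

#' Select the top fraction of features by summed importance rank
#'
#' The selected count is `fraction * p` rounded half-to-even (so 10% of 573
#' features selects 57), at least 1. Ties on summed rank are broken by the
#' larger mean raw importance, then by feature order.
#'
#' @param ranks a `rank_aggregate` from [bootstrap_rank_features()].
#' @param fraction fraction to keep, in (0, 1] (default 0.10).
#' @return character vector of selected feature ids.
#' @export
select_top_fraction <- function(ranks, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  p <- nrow(ranks)
  n_keep <- min(p, max(1L, as.integer(round(fraction * p))))
  ord <- order(ranks$summed_rank, -ranks$mean_importance,
               seq_len(p))
  ranks$feature[ord[seq_len(n_keep)]]
}

#' Subset sizes for recursive feature elimination
#'
#' The profile evaluates the top 50 down to 10 candidates in steps of five,
#' then 9 down to 2 in steps of one, dropping sizes above the number of
#' candidates.
#'
#' @param n_candidates number of candidate features.
#' @return strictly decreasing integer vector of subset sizes.
#' @export
rfe_sizes <- function(n_candidates) {
  s <- c(seq(50L, 10L, -5L), 9:2)
  s[s <= n_candidates]
}

#' Recursive-feature-elimination AUC profile
#'
#' Second stage of the selection procedure. For each of `n_boot` stratified
#' 75/25 resamples of the training samples: a forest on all candidate
#' features is fitted to the 75% part and its importance ranking taken; for
#' each subset size, the forest is refitted on the top-ranked features *of
#' that resample* and scored by AUC on the 25% part. The profile is the mean
#' (and sd) AUC per size; the per-size feature lists are the top features by
#' rank aggregation over these resamples.
#'
#' @inheritParams bootstrap_rank_features
#' @param candidates character vector of candidate feature ids.
#' @param sizes subset sizes (default [rfe_sizes()] of the candidate count).
#' @param mtry `mtry` for the forests (default `floor(sqrt(s))` per size).
#' @return an `rfe_profile`: tibble of `size`, `mean_auc`, `sd_auc`, with
#'   attribute `subsets` (per-size aggregate feature lists).
#' @export
rfe_profile <- function(x, y, candidates, sizes = NULL, n_boot = 100,
                        ntree = 500, mtry = NULL,
                        importance = c("impurity", "permutation"),
                        inner_fraction = 0.75, replace = FALSE, seed = NULL) {
  importance <- match.arg(importance)
  y <- droplevels(factor(y))
  if (!all(candidates %in% colnames(x))) {
    abort("All candidate features must be columns of `x`.")
  }
  x <- x[, candidates, drop = FALSE]
  .check_xy(x, y)
  if (is.null(sizes)) sizes <- rfe_sizes(length(candidates))
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  if (any(sizes < 2) || any(sizes > length(candidates))) {
    abort("`sizes` must lie in [2, number of candidates].")
  }
  case_level <- levels(y)[nlevels(y)]

  with_seed_opt(seed, {
    p <- ncol(x)
    auc_m <- matrix(NA_real_, n_boot, length(sizes),
                    dimnames = list(NULL, as.character(sizes)))
    summed <- setNames(numeric(p), colnames(x))
    for (b in seq_len(n_boot)) {
      rs <- .resample_checked(y, inner_fraction, replace)
      xtr <- x[rs$tr, , drop = FALSE]; ytr <- y[rs$tr]
      xte <- x[rs$te, , drop = FALSE]; yte <- y[rs$te] == case_level
      full <- .fit_rf(xtr, ytr, ntree,
                      mtry %||% floor(sqrt(p)),
                      importance = (importance == "permutation"))
      imp <- .rf_importance(full, importance)[colnames(x)]
      rk <- rank(-imp, ties.method = "first")
      summed <- summed + rk
      ord <- colnames(x)[order(rk)]
      for (si in seq_along(sizes)) {
        keep <- ord[seq_len(sizes[si])]
        fit_s <- .fit_rf(xtr[, keep, drop = FALSE], ytr, ntree,
                         mtry %||% floor(sqrt(sizes[si])))
        auc_m[b, si] <- auc_score(
          .rf_scores(fit_s, xte[, keep, drop = FALSE], case_level), yte)
      }
    }
    agg_ord <- colnames(x)[order(summed, seq_len(p))]
    subsets <- lapply(sizes, function(s) agg_ord[seq_len(s)])
    names(subsets) <- as.character(sizes)
    structure(
      tibble(size = sizes, mean_auc = colMeans(auc_m),
             sd_auc = apply(auc_m, 2, sd)),
      subsets = subsets, n_boot = n_boot, case_level = case_level,
      class = c("rfe_profile", class(tibble())))
  })
}

#' @exportS3Method generics::tidy
tidy.rfe_profile <- function(x, ...) as_tibble(x)

#' Pick a subset size by performance tolerance
#'
#' Returns the smallest subset size whose mean AUC is within
#' `tolerance_pct` percent of the best mean AUC across the profile — a small
#' model that does not sacrifice too much performance.
#'
#' @param profile an [rfe_profile()] result, or a tibble/data frame with
#'   `size` and `mean_auc` columns.
#' @param tolerance_pct allowed performance loss, percent (default 1.5).
#' @return the selected size (integer).
#' @examples
#' pr <- tibble::tibble(size = c(25, 10, 5), mean_auc = c(0.880, 0.867, 0.800))
#' pick_size_tolerance(pr, 1.5)  # 10
#' @export
pick_size_tolerance <- function(profile, tolerance_pct = 1.5) {
  pr <- as_tibble(profile)
  if (!all(c("size", "mean_auc") %in% names(pr)) || nrow(pr) == 0) {
    abort("`profile` must have rows with `size` and `mean_auc`.")
  }
  thr <- (1 - tolerance_pct / 100) * max(pr$mean_auc)
  min(pr$size[pr$mean_auc >= thr])
}

#' Confusion-matrix evaluation metrics
#'
#' @param truth logical, `TRUE` for cases.
#' @param call logical predicted case calls.
#' @param scores numeric case scores for the AUC.
#' @return tibble: `tp`, `fn`, `fp`, `tn`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `auc`.
#' @export
eval_metrics <- function(truth, call, scores) {
  truth <- as.logical(truth); call <- as.logical(call)
  tp <- sum(truth & call); fn <- sum(truth & !call)
  fp <- sum(!truth & call); tn <- sum(!truth & !call)
  tibble(tp = tp, fn = fn, fp = fp, tn = tn,
         accuracy = (tp + tn) / length(truth),
         sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         ppv = tp / (tp + fp), npv = tn / (tn + fn),
         auc = auc_score(scores, truth))
}

#' Fit the final model and evaluate on the held-out test set
#'
#' Fits a random forest on the complete training data restricted to the
#' selected features and evaluates it on the training data and on the
#' untouched test set. Class calls use the majority vote (case vote fraction
#' > 0.5); the AUC uses the vote fractions.
#'
#' @param x_train,y_train training matrix and two-level factor labels (last
#'   level = case).
#' @param x_test,y_test held-out test matrix and labels.
#' @param features selected feature ids.
#' @param ntree trees (default 500).
#' @param mtry forest `mtry` (default `floor(sqrt(length(features)))`).
#' @param seed optional seed.
#' @return a `final_model` list: `model` (the randomForest fit), `features`,
#'   `train_metrics`, `test_metrics`, `case_level`.
#' @export
fit_final_and_evaluate <- function(x_train, y_train, x_test, y_test,
                                   features, ntree = 500, mtry = NULL,
                                   seed = NULL) {
  y_train <- droplevels(factor(y_train))
  y_test <- factor(y_test, levels = levels(y_train))
  if (!all(features %in% colnames(x_train))) {
    abort("Selected features missing from the training matrix.")
  }
  if (!all(features %in% colnames(x_test))) {
    abort("Selected features missing from the test matrix.")
  }
  case_level <- levels(y_train)[nlevels(y_train)]
  with_seed_opt(seed, {
    fit <- .fit_rf(x_train[, features, drop = FALSE], y_train, ntree,
                   mtry %||% max(1, floor(sqrt(length(features)))))
    ev <- function(x, y) {
      sc <- .rf_scores(fit, x[, features, drop = FALSE], case_level)
      eval_metrics(y == case_level, sc > 0.5, sc)
    }
    structure(list(model = fit, features = features,
                   train_metrics = ev(x_train, y_train),
                   test_metrics = ev(x_test, y_test),
                   case_level = case_level),
              class = "final_model")
  })
}

#' @export
print.final_model <- function(x, ...) {
  cat(sprintf("<final_model> %d features; test accuracy %.3f, AUC %.3f\n",
              length(x$features), x$test_metrics$accuracy,
              x$test_metrics$auc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.final_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$train_metrics, set = "train", .before = 1),
    dplyr::mutate(x$test_metrics, set = "test", .before = 1))
}

#' @exportS3Method generics::glance
glance.final_model <- function(x, ...) {
  dplyr::mutate(x$test_metrics, n_features = length(x$features))
}

#' Apply the final model to external samples
#'
#' Classifies samples that took no part in training or testing (e.g. the MCI
#' group) and tabulates the calls.
#'
#' @param model a `final_model` from [fit_final_and_evaluate()].
#' @param x matrix of external samples (must contain the model's features).
#' @return list: `calls` tibble (`sample_id`, `score`, `call`) and `counts`
#'   (named call counts). Empty input gives empty output.
#' @export
classify_external <- function(model, x) {
  if (!inherits(model, "final_model")) abort("`model` must be a final_model.")
  if (!all(model$features %in% colnames(x))) {
    abort("External matrix lacks model features.")
  }
  lv <- levels(model$model$y)
  if (nrow(x) == 0) {
    return(list(calls = tibble(sample_id = character(0), score = numeric(0),
                               call = character(0)),
                counts = setNames(rep(0L, length(lv)), lv)))
  }
  sc <- .rf_scores(model$model, x[, model$features, drop = FALSE],
                   model$case_level)
  call <- ifelse(sc > 0.5, model$case_level, setdiff(lv, model$case_level))
  counts <- vapply(lv, function(l) sum(call == l), integer(1))
  list(calls = tibble(sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                      score = unname(sc), call = unname(call)),
       counts = counts)
}
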