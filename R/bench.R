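#' Repeated cross-validation protocol
#'
#' The within-domain evaluation protocol: k-fold cross-validation repeated
#' with fresh resample indices; selector and scaler are refitted inside
#' each training fold by default so no held-out information leaks into
#' selection or scaling.
#'
#' @param n_folds Folds per repeat (default 4).
#' @param n_repeats Number of repeats with distinct fold assignments
#'   (default 20).
#' @param seed Integer seed; repeat r uses a child seed derived from it.
#' @param refit_per_fold If `FALSE`, supervised selectors are fitted once
#'   on the full dataset before cross-validation (the whole-dataset
#'   variant).
#' @return An object of class `cv_protocol`.
#' @export
cv_protocol <- function(n_folds = 4L, n_repeats = 20L, seed = 1L,
                        refit_per_fold = TRUE) {
  if (n_folds < 2) stop_bad_arg("n_folds must be >= 2")
  if (n_repeats < 1) stop_bad_arg("n_repeats must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = seed, refit_per_fold = isTRUE(refit_per_fold)),
            class = "cv_protocol")
}

# Kendall's tau-b (tie-corrected), O(n^2); fold-level n keeps this cheap.
kendall_tau_b <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  iu <- upper.tri(dx)
  s <- sum(dx[iu] * dy[iu])
  n0 <- n * (n - 1) / 2
  tx <- n0 - sum(dx[iu] != 0)
  ty <- n0 - sum(dy[iu] != 0)
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  s / den
}

#' Regression metric bundle
#'
#' Computes the six benchmark metrics between observed and predicted AAC:
#' Pearson, Spearman (Pearson on mid-ranks) and Kendall tau-b correlations,
#' RMSE, MSE and MAE. If either vector has zero variance the correlations
#' are returned as `NA` and the result is flagged `degenerate`.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 3.
#' @return Named numeric vector `pearson`, `spearman`, `kendall`, `rmse`,
#'   `mse`, `mae`, with attribute `degenerate`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 3) {
    stop_bad_arg("y_true and y_pred must have equal length >= 3")
  }
  err <- y_pred - y_true
  degenerate <- stats::sd(y_true) == 0 || stats::sd(y_pred) == 0
  if (degenerate) {
    pe <- sp <- kd <- NA_real_
  } else {
    pe <- stats::cor(y_true, y_pred)
    sp <- stats::cor(rank(y_true), rank(y_pred))
    kd <- kendall_tau_b(y_true, y_pred)
  }
  out <- c(pearson = pe, spearman = sp, kendall = kd,
           rmse = sqrt(mean(err^2)), mse = mean(err^2), mae = mean(abs(err)))
  attr(out, "degenerate") <- degenerate
  out
}

metric_names <- c("pearson", "spearman", "kendall", "rmse", "mse", "mae")

bench_row <- function(drug, selector, family, split_kind, metrics, n) {
  data.frame(drug = drug, selector = selector, model_family = family,
             split_kind = split_kind, t(metrics[metric_names]), n = n,
             stringsAsFactors = FALSE)
}

# Fit selector -> scaler -> tuned model on (train rows), predict new rows.
fit_predict <- function(train, drug, fs, model_spec, newx) {
  d <- aligned_xy(train, drug)
  genes <- intersect(fs$genes, colnames(d$x))
  if (!length(genes)) stop_bad_arg("feature set is empty for drug ", drug)
  sc <- fit_scaler(d$x[, genes, drop = FALSE])
  Xtr <- apply_scaler(sc, d$x[, genes, drop = FALSE])
  model <- train_model(model_spec, Xtr, d$y)
  Xte <- apply_scaler(sc, newx[, genes, drop = FALSE])
  list(pred = predict(model, Xte), model = model, scaler = sc)
}

subset_samples <- function(ds, ids) {
  pharmaco_dataset(ds$expression[ids, , drop = FALSE],
                   ds$responses[ds$responses$sample_id %in% ids, , drop = FALSE],
                   ds$sample_meta)
}

#' Within-domain repeated cross-validation benchmark
#'
#' For each drug and each repeat x fold: the selector is fitted on the
#' fold-training portion only (unless the protocol's whole-dataset variant
#' is requested), a scaler is fitted on the same portion, the model is
#' tuned by inner grid search and evaluated on the held-out fold. Reported
#' per-drug metrics are means over all folds and repeats.
#'
#' @param ds A filtered [pharmaco_dataset()].
#' @param selector_cfg A [selector_config()].
#' @param model_spec A [model_spec()].
#' @param protocol A [cv_protocol()].
#' @param drugs Drug ids to evaluate (default: all in `ds`).
#' @return A `data.frame` of benchmark rows (drug, selector, model_family,
#'   split_kind = "within", the six metrics, n).
#' @export
run_cv <- function(ds, selector_cfg, model_spec, protocol,
                   drugs = dataset_drugs(ds)) {
  stopifnot(inherits(ds, "pharmaco_dataset"), inherits(protocol, "cv_protocol"))
  rows <- list()
  for (drug in drugs) {
    y_all <- drug_response(ds, drug)
    ids <- intersect(rownames(ds$expression), names(y_all))
    n <- length(ids)
    if (n < 2 * protocol$n_folds) {
      warning("drug ", drug, " skipped: too few samples")
      next
    }
    fs_whole <- if (!protocol$refit_per_fold) {
      select_features(subset_samples(ds, ids), drug, selector_cfg)
    } else NULL
    fold_metrics <- list()
    for (rep_i in seq_len(protocol$n_repeats)) {
      folds <- with_seed(child_seed(protocol$seed, rep_i),
                         sample(rep_len(seq_len(protocol$n_folds), n)))
      for (f in seq_len(protocol$n_folds)) {
        tr_ids <- ids[folds != f]
        te_ids <- ids[folds == f]
        tr <- subset_samples(ds, tr_ids)
        fs <- if (is.null(fs_whole)) {
          tryCatch(select_features(tr, drug, selector_cfg),
                   error = function(e) NULL)
        } else fs_whole
        if (is.null(fs) || !length(fs$genes)) {
          warning("selector returned no genes for drug ", drug, "; skipped")
          next
        }
        fp <- fit_predict(tr, drug, fs, model_spec,
                          ds$expression[te_ids, , drop = FALSE])
        fold_metrics[[length(fold_metrics) + 1L]] <-
          compute_metrics(y_all[te_ids], fp$pred)
      }
    }
    if (!length(fold_metrics)) next
    m <- colMeans(do.call(rbind, fold_metrics), na.rm = TRUE)
    m["rmse"] <- sqrt(m["mse"])  # pooled so that rmse^2 = mse holds per row
    rows[[length(rows) + 1L]] <- bench_row(drug, selector_cfg$method,
                                           model_spec$family, "within", m, n)
  }
  do.call(rbind, rows)
}

#' Cross-domain validation benchmark
#'
#' The gene universes of the two domains are intersected; the selector,
#' scaler and model tuning all use the training domain only (the model with
#' the best inner-CV hyperparameters is refitted on the full training
#' domain) and the tuned model is applied once to the test domain's
#' responding samples.
#'
#' @param train_ds,test_ds Filtered [pharmaco_dataset()] objects.
#' @inheritParams run_cv
#' @return A `data.frame` of benchmark rows with `split_kind = "cross"`.
#' @export
run_cross_domain <- function(train_ds, test_ds, selector_cfg, model_spec,
                             protocol = cv_protocol(),
                             drugs = dataset_drugs(train_ds)) {
  shared <- intersect(colnames(train_ds$expression), colnames(test_ds$expression))
  if (!length(shared)) stop_bad_arg("domains share no genes")
  tr <- pharmaco_dataset(train_ds$expression[, shared, drop = FALSE],
                         train_ds$responses, train_ds$sample_meta)
  rows <- list()
  for (drug in drugs) {
    y_te <- drug_response(test_ds, drug)
    te_ids <- intersect(rownames(test_ds$expression), names(y_te))
    if (length(te_ids) < 10) {
      stop_bad_arg("fewer than 10 overlapping test samples with responses for ", drug)
    }
    fs <- select_features(tr, drug, selector_cfg)
    if (!length(fs$genes)) {
      warning("selector returned no genes for drug ", drug, "; skipped")
      next
    }
    fp <- fit_predict(tr, drug, fs, model_spec,
                      test_ds$expression[te_ids, shared, drop = FALSE])
    m <- compute_metrics(y_te[te_ids], fp$pred)
    rows[[length(rows) + 1L]] <- bench_row(drug, selector_cfg$method,
                                           model_spec$family, "cross", m,
                                           length(te_ids))
  }
  do.call(rbind, rows)
}

#' Paired comparison of two selectors
#'
#' Paired Student's t-test of a metric between two selectors over the
#' drugs they were both evaluated on (rows may mix model families; pass a
#' pre-filtered result to compare within one family).
#'
#' @param result A benchmark `data.frame` from [run_cv()] /
#'   [run_cross_domain()].
#' @param metric One of the six metric columns (default `"pearson"`).
#' @param method_a,method_b Selector tags to compare (a minus b).
#' @param split_kind Optionally restrict to `"within"` or `"cross"` rows.
#' @return List with `t`, `df`, `p_value`, `mean_diff`, `n`, and
#'   `zero_variance` flag (if all paired differences are identical the
#'   p-value is reported as 1).
#' @export
compare_selectors <- function(result, metric = "pearson", method_a, method_b,
                              split_kind = NULL) {
  stopifnot(metric %in% metric_names)
  if (!is.null(split_kind)) result <- result[result$split_kind == split_kind, ]
  a <- result[result$selector == method_a, c("drug", "model_family", metric)]
  b <- result[result$selector == method_b, c("drug", "model_family", metric)]
  m <- merge(a, b, by = c("drug", "model_family"), suffixes = c("_a", "_b"))
  if (nrow(m) < 3) stop_bad_arg("need at least 3 paired drugs")
  d <- m[[paste0(metric, "_a")]] - m[[paste0(metric, "_b")]]
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = nrow(m) - 1L, p_value = 1,
                mean_diff = mean(d), n = nrow(m), zero_variance = TRUE))
  }
  tt <- stats::t.test(m[[paste0(metric, "_a")]], m[[paste0(metric, "_b")]],
                      paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), n = nrow(m),
       zero_variance = FALSE)
}
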