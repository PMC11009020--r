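#' Univariate biomarker analysis for one drug
#'
#' Computes the absolute Pearson correlation between every gene's
#' expression and the drug's AAC, partitions genes into the text-mining
#' group and the rest, and tests the difference of the two `|r|`
#' distributions with a two-sample t-test (Welch by default; group sizes
#' are typically very unequal). Zero-variance genes get `|r| = 0` and are
#' flagged.
#'
#' @param ds A [pharmaco_dataset()].
#' @param drug Drug id.
#' @param tm_genes Character vector (or [feature_set()]) of the drug's
#'   text-mining genes; must intersect the dataset universe.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return An object of class `univariate_report`: list with `per_gene`
#'   (data.frame gene, abs_r, group, zero_var), group means, `t`, `df`,
#'   `p_value`.
#' @export
univariate_analysis <- function(ds, drug, tm_genes, var_equal = FALSE) {
  stopifnot(inherits(ds, "pharmaco_dataset"))
  if (inherits(tm_genes, "feature_set")) tm_genes <- tm_genes$genes
  if (!length(tm_genes)) stop_bad_arg("tm_genes must be nonempty")
  d <- aligned_xy(ds, drug)
  if (length(d$y) < 3) stop_bad_arg("need at least 3 samples with responses")
  r <- abs(cor_with(d$x, d$y))
  zero_var <- col_vars(d$x) == 0
  group <- ifelse(colnames(d$x) %in% tm_genes, "text-mining", "other")
  if (!any(group == "text-mining")) {
    stop_bad_arg("no text-mining gene present in the dataset universe")
  }
  tt <- tryCatch(
    stats::t.test(r[group == "text-mining"], r[group == "other"],
                  var.equal = var_equal),
    error = function(e) list(statistic = NA_real_, parameter = NA_real_,
                             p.value = NA_real_))
  structure(list(
    drug_id = drug,
    per_gene = data.frame(gene = colnames(d$x), abs_r = unname(r),
                          group = group, zero_var = unname(zero_var),
                          stringsAsFactors = FALSE),
    mean_tm = mean(r[group == "text-mining"]),
    mean_other = mean(r[group == "other"]),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, welch = !var_equal
  ), class = "univariate_report")
}

#' @export
print.univariate_report <- function(x, ...) {
  cat(sprintf(
    "Univariate |r| analysis for %s: mean |r| text-mining %.3f vs other %.3f (t = %.2f, p = %.3g)\n",
    x$drug_id, x$mean_tm, x$mean_other, x$t, x$p_value))
  invisible(x)
}

#' Median dichotomization of predicted responses
#'
#' Splits subjects at the median prediction: values at or above the median
#' go to the `high` group, values below to `low` (ties at the median go
#' high, a fixed rule for reproducibility).
#'
#' @param predictions Named numeric vector (>= 2 subjects).
#' @return Named character vector of `"high"` / `"low"`.
#' @export
dichotomize <- function(predictions) {
  if (length(predictions) < 2) stop_bad_arg("need at least 2 subjects")
  if (max(predictions) == min(predictions)) {
    stop_bad_arg("all predictions identical: degenerate split")
  }
  med <- stats::median(predictions)
  stats::setNames(ifelse(predictions >= med, "high", "low"),
                  names(predictions))
}

as_survival_records <- function(records) {
  need <- c("time_days", "event", "group")
  if (!all(need %in% names(records))) {
    stop_bad_arg("records must have columns time_days, event, group")
  }
  if (any(records$time_days <= 0)) stop_bad_arg("survival times must be positive")
  if (!all(records$event %in% c(0, 1))) stop_bad_arg("event must be 0/1")
  records
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate of the survival function within each group,
#' computed with the survival package: right-continuous, nonincreasing,
#' S(0) = 1; censored subjects leave later risk sets without stepping the
#' curve down.
#'
#' @param records data.frame with columns `time_days`, `event` (1 = event,
#'   0 = censored) and `group`; every group nonempty.
#' @return An object of class `km_fit`: list of per-group data.frames
#'   (`time`, `n_risk`, `n_event`, `surv`) plus the underlying
#'   [survival::survfit] object.
#' @export
km_estimate <- function(records) {
  records <- as_survival_records(records)
  sf <- survival::survfit(
    survival::Surv(time_days, event) ~ group, data = records)
  strata <- if (is.null(sf$strata)) {
    stats::setNames(length(sf$time), paste0("group=", records$group[1]))
  } else sf$strata
  idx <- rep(names(strata), strata)
  curves <- lapply(split(seq_along(sf$time), idx), function(i) {
    data.frame(time = sf$time[i], n_risk = sf$n.risk[i],
               n_event = sf$n.event[i], surv = sf$surv[i])
  })
  names(curves) <- sub("^group=", "", names(curves))
  structure(list(curves = curves, survfit = sf), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    cat(sprintf("group %s: %d time points, final S(t) = %.3f\n",
                g, nrow(cv), utils::tail(cv$surv, 1)))
  }
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  plot(x$survfit, col = seq_along(x$curves), lty = 1,
       xlab = "time (days)", ylab = "survival probability", ...)
  graphics::legend("topright", legend = names(x$curves),
                   col = seq_along(x$curves), lty = 1, bty = "n")
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: over the pooled event times,
#' `U = sum(d1_i - e1_i)` (observed minus expected events in group 1) with
#' hypergeometric variance terms `V`; the statistic `U^2 / V` is referred
#' to chi-square with 1 df.
#'
#' @param records data.frame as in [km_estimate()] with exactly two groups
#'   and at least one event.
#' @return List with `chi_square`, `p_value`, `df = 1`, and per-group
#'   observed/expected event counts.
#' @export
logrank_test <- function(records) {
  records <- as_survival_records(records)
  if (length(unique(records$group)) != 2) stop_bad_arg("need exactly two groups")
  if (sum(records$event) < 1) stop_bad_arg("need at least one event")
  sd_ <- survival::survdiff(
    survival::Surv(time_days, event) ~ group, data = records)
  if (!is.finite(sd_$chisq)) stop_bad_arg("log-rank variance is zero")
  list(chi_square = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       df = 1L,
       observed = sd_$obs, expected = sd_$exp)
}

#' Xenograft-style survival validation of a trained response model
#'
#' Restricts to the genes shared by the training dataset and the cohort
#' expression, trains a random forest on the training domain's text-mining
#' features for the drug, predicts each cohort subject's response,
#' dichotomizes predictions at the median, and compares the two groups'
#' survival with Kaplan-Meier curves and the log-rank test.
#'
#' @param train_ds Training [pharmaco_dataset()].
#' @param drug Drug id.
#' @param tm_genes Text-mining [feature_set()] or character vector.
#' @param cohort_expression Subjects-by-genes matrix.
#' @param cohort_survival data.frame with `subject_id`, `time_days`,
#'   `event`.
#' @param ntree Random forest size.
#' @param seed Integer seed for the forest.
#' @return List with `predictions`, `groups`, `km` ([km_estimate()]),
#'   `chi_square`, `p_value`, `n_high`, `n_low`, `small_groups` flag
#'   (TRUE when either group has < 5 subjects).
#' @export
pdx_style_validation <- function(train_ds, drug, tm_genes,
                                 cohort_expression, cohort_survival,
                                 ntree = 500, seed = 1L) {
  if (inherits(tm_genes, "feature_set")) tm_genes <- tm_genes$genes
  genes <- intersect(tm_genes,
                     intersect(colnames(train_ds$expression),
                               colnames(cohort_expression)))
  if (!length(genes)) stop_bad_arg("no shared text-mining genes between domains")
  d <- aligned_xy(train_ds, drug)
  sc <- fit_scaler(d$x[, genes, drop = FALSE])
  Xtr <- apply_scaler(sc, d$x[, genes, drop = FALSE])
  rf <- with_seed(seed, randomForest::randomForest(x = Xtr, y = d$y,
                                                   ntree = ntree))
  Xco <- apply_scaler(sc, cohort_expression[, genes, drop = FALSE])
  pred <- stats::setNames(as.vector(stats::predict(rf, Xco)),
                          rownames(cohort_expression))
  groups <- dichotomize(pred)
  rec <- cohort_survival
  rec$group <- groups[rec$subject_id]
  km <- km_estimate(rec)
  lr <- logrank_test(rec)
  n_high <- sum(groups == "high"); n_low <- sum(groups == "low")
  if (min(n_high, n_low) < 5) {
    warning("fewer than 5 subjects in a dichotomized group")
  }
  list(predictions = pred, groups = groups, km = km,
       chi_square = lr$chi_square, p_value = lr$p_value,
       n_high = n_high, n_low = n_low,
       small_groups = min(n_high, n_low) < 5)
}
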