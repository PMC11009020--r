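#' Construct a pharmacogenomic dataset
#'
#' Bundles a samples-by-genes expression matrix (log-scale, arbitrary units)
#' with a long-format drug-response table of AAC values in `[0, 1]`.
#' Samples are inner-joined: only samples present in both the expression
#' matrix and the response table are kept.
#'
#' @param expression Numeric matrix, rows = samples (rownames required),
#'   columns = genes (colnames required). Values must be finite or NA.
#' @param responses data.frame with columns `sample_id`, `drug_id`, `aac`.
#' @param sample_meta Optional data.frame keyed by `sample_id` (e.g. tissue).
#' @return An object of class `pharmaco_dataset`.
#' @export
pharmaco_dataset <- function(expression, responses, sample_meta = NULL) {
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop_bad_arg("expression must carry sample rownames and gene colnames")
  }
  if (anyDuplicated(rownames(expression))) stop_bad_arg("sample ids must be unique")
  if (anyDuplicated(colnames(expression))) stop_bad_arg("gene ids must be unique")
  need <- c("sample_id", "drug_id", "aac")
  if (!all(need %in% names(responses))) {
    stop_bad_arg("responses must have columns sample_id, drug_id, aac")
  }
  bad <- !is.na(responses$aac) & (responses$aac < 0 | responses$aac > 1)
  if (any(bad)) {
    stop_bad_arg("AAC outside [0, 1] at response row(s) ",
                 paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (any(is.infinite(expression))) stop_bad_arg("expression must be finite")
  keep <- intersect(rownames(expression), unique(responses$sample_id))
  if (!length(keep)) stop_bad_arg("no samples shared between expression and responses")
  expression <- expression[keep, , drop = FALSE]
  responses <- responses[responses$sample_id %in% keep, need, drop = FALSE]
  rownames(responses) <- NULL
  structure(list(expression = expression, responses = responses,
                 sample_meta = sample_meta),
            class = "pharmaco_dataset")
}

#' @export
print.pharmaco_dataset <- function(x, ...) {
  cat("Pharmacogenomic dataset:", nrow(x$expression), "samples x",
      ncol(x$expression), "genes;", length(unique(x$responses$drug_id)),
      "drug(s)\n")
  invisible(x)
}

#' @export
dim.pharmaco_dataset <- function(x) dim(x$expression)

#' Drugs and per-drug responses of a dataset
#'
#' `dataset_drugs()` lists drug ids; `drug_response()` returns the named AAC
#' vector for one drug, dropping samples whose response is missing.
#'
#' @param ds A [pharmaco_dataset()].
#' @param drug Drug id.
#' @return A character vector of drug ids, or a named numeric AAC vector.
#' @export
dataset_drugs <- function(ds) unique(ds$responses$drug_id)

#' @rdname dataset_drugs
#' @export
drug_response <- function(ds, drug) {
  r <- ds$responses[ds$responses$drug_id == drug & !is.na(ds$responses$aac), ]
  if (!nrow(r)) stop_bad_arg("no responses recorded for drug ", drug)
  stats::setNames(r$aac, r$sample_id)
}

#' Read and write pharmacogenomic data as TSV
#'
#' The expression file is a TSV with a header row of gene ids and first
#' column `sample_id`; the response file has columns `sample_id`, `drug_id`,
#' `aac`. Reading inner-joins the samples present in both files and
#' validates the AAC range.
#'
#' @param expression_path,response_path File paths.
#' @param ds A [pharmaco_dataset()] (for the writer).
#' @return `read_pharmaco_dataset()` returns a [pharmaco_dataset()];
#'   the writer returns its paths invisibly.
#' @export
read_pharmaco_dataset <- function(expression_path, response_path) {
  for (p in c(expression_path, response_path)) {
    if (!file.exists(p)) stop_bad_arg("file not found: ", p)
  }
  ex <- utils::read.delim(expression_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(ex)[1] != "sample_id") {
    stop_bad_arg("expression TSV must start with a sample_id column (line 1)")
  }
  m <- as.matrix(ex[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_col <- which(!vapply(ex[-1], is.numeric, logical(1)))[1]
    stop_bad_arg("non-numeric expression values in column ", names(ex)[bad_col + 1])
  }
  rownames(m) <- ex$sample_id
  resp <- utils::read.delim(response_path, stringsAsFactors = FALSE)
  pharmaco_dataset(m, resp)
}

#' @rdname read_pharmaco_dataset
#' @export
write_pharmaco_dataset <- function(ds, expression_path, response_path) {
  stopifnot(inherits(ds, "pharmaco_dataset"))
  ex <- data.frame(sample_id = rownames(ds$expression), ds$expression,
                   check.names = FALSE)
  utils::write.table(ex, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$responses, response_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression_path, response_path))
}

#' Remove degenerate samples from a dataset
#'
#' Drops samples with missing expression values, then drops any sample
#' whose profile is degenerate: more than `frac_threshold` of its gene
#' values equal the sample's modal value. With `margin = "gene"` the same
#' modal-fraction rule is applied to genes instead (an alternative reading
#' of low-variance filtering; the per-sample rule is the default).
#'
#' @param ds A [pharmaco_dataset()].
#' @param frac_threshold Modal-fraction threshold in (0, 1].
#' @param margin `"sample"` (default) or `"gene"`.
#' @return The filtered [pharmaco_dataset()].
#' @export
filter_samples <- function(ds, frac_threshold = 0.85,
                           margin = c("sample", "gene")) {
  stopifnot(inherits(ds, "pharmaco_dataset"))
  margin <- match.arg(margin)
  if (!(frac_threshold > 0 && frac_threshold <= 1)) {
    stop_bad_arg("frac_threshold must lie in (0, 1]")
  }
  x <- ds$expression
  modal_frac <- function(v) max(tabulate(match(v, unique(v)))) / length(v)
  if (margin == "sample") {
    complete <- rowSums(is.na(x)) == 0
    x2 <- x[complete, , drop = FALSE]
    mf <- apply(x2, 1L, modal_frac)
    keep <- mf <= frac_threshold & mf < 1  # all-constant profiles always go
    if (!any(keep)) stop_bad_arg("all samples removed by filter")
    pharmaco_dataset(x2[keep, , drop = FALSE],
                     ds$responses[ds$responses$sample_id %in% rownames(x2)[keep], ],
                     ds$sample_meta)
  } else {
    keep <- apply(x, 2L, modal_frac) <= frac_threshold
    if (!any(keep)) stop_bad_arg("all genes removed by filter")
    pharmaco_dataset(x[, keep, drop = FALSE], ds$responses, ds$sample_meta)
  }
}

#' Fit and apply per-gene standardization
#'
#' `fit_scaler()` records per-gene means and standard deviations on a
#' training dataset; `apply_scaler()` centers and scales any dataset (or
#' bare matrix) with those *training* statistics. Genes with zero training
#' SD map to 0. The scaler carries a provenance tag naming the data it was
#' fitted on, so downstream code can assert that test-domain statistics
#' never enter the transformation.
#'
#' @param train A [pharmaco_dataset()] or samples-by-genes matrix.
#' @param scaler An `expr_scaler` from `fit_scaler()`.
#' @param ds Dataset or matrix to transform; must contain every scaler gene.
#' @return `fit_scaler()`: an `expr_scaler`; `apply_scaler()`: object of the
#'   same shape as `ds` with transformed expression.
#' @export
fit_scaler <- function(train) {
  x <- if (inherits(train, "pharmaco_dataset")) train$expression else train
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  mu <- colMeans(x)
  sd <- sqrt(col_vars(x))
  structure(list(mean = mu, sd = sd, genes = colnames(x),
                 fitted_on = sprintf("train[n=%d]", nrow(x))),
            class = "expr_scaler")
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, ds) {
  stopifnot(inherits(scaler, "expr_scaler"))
  x <- if (inherits(ds, "pharmaco_dataset")) ds$expression else ds
  missing <- setdiff(scaler$genes, colnames(x))
  if (length(missing)) {
    stop_bad_arg("gene(s) absent from data at apply time: ",
                 paste(utils::head(missing, 3), collapse = ", "))
  }
  x <- x[, scaler$genes, drop = FALSE]
  sd <- ifelse(scaler$sd == 0, 1, scaler$sd)
  z <- sweep(sweep(x, 2L, scaler$mean, `-`), 2L, sd, `/`)
  z[, scaler$sd == 0] <- 0
  if (inherits(ds, "pharmaco_dataset")) {
    out <- ds
    out$expression <- z
    out
  } else {
    z
  }
}
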