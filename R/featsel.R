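#' Ordered gene feature set
#'
#' The common currency of all selectors: an ordered, duplicate-free gene
#' list for one drug, tagged with the selection method that produced it
#' (best gene first).
#'
#' @param drug_id Drug label.
#' @param method Selector tag, one of `"text-mining"`, `"var_100"`,
#'   `"var_500"`, `"cor_500"`, `"L1000"`, `"L1000-tm"`, `"MRMR"`, `"GA"`,
#'   `"RFE"`, or `"oracle"` (ground-truth genes, used in benchmarks).
#' @param genes Ordered character vector of gene ids.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(drug_id, method, genes) {
  methods <- c("text-mining", "var_100", "var_500", "cor_500", "L1000",
               "L1000-tm", "MRMR", "GA", "RFE", "oracle")
  if (!method %in% methods) {
    stop_bad_arg("unknown selector method: ", method)
  }
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop_bad_arg("feature set genes must be unique")
  structure(list(drug_id = drug_id, method = method, genes = genes),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s / %s: %d genes\n", x$drug_id, x$method,
              length(x$genes)))
  invisible(x)
}

#' Write / read a feature set as JSON
#' @param fs A [feature_set()].
#' @param path File path.
#' @export
write_feature_set <- function(fs, path) {
  jsonlite::write_json(list(drug = fs$drug_id, method = fs$method,
                            genes = fs$genes),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  x <- jsonlite::fromJSON(path)
  feature_set(x$drug, x$method, as.character(x$genes))
}

expr_matrix <- function(train) {
  if (inherits(train, "pharmaco_dataset")) train$expression else train
}

# Expression rows restricted to samples with a response for `drug`,
# plus the aligned response vector.
aligned_xy <- function(train, drug) {
  stopifnot(inherits(train, "pharmaco_dataset"))
  y <- drug_response(train, drug)
  keep <- intersect(rownames(train$expression), names(y))
  list(x = train$expression[keep, , drop = FALSE], y = y[keep])
}

#' Unsupervised variance selection
#'
#' Orders genes by descending sample variance of the unscaled training
#' expression (scaling would equalize variances and void the criterion) and
#' returns the top `k`. Ties break by gene id.
#'
#' @param train A [pharmaco_dataset()] or expression matrix.
#' @param k Number of genes to keep.
#' @param drug_id Label for the output.
#' @return A [feature_set()] tagged `var_100` or `var_500` when `k` matches,
#'   otherwise `var_<k>` is not a registered tag so the nearest of the two
#'   is used; pass `method` to override.
#' @param method Selector tag recorded on the output.
#' @export
variance_select <- function(train, k, drug_id = "drug",
                            method = if (k == 100) "var_100" else "var_500") {
  x <- expr_matrix(train)
  if (k > ncol(x)) stop_bad_arg("k exceeds the number of genes")
  v <- col_vars(x)
  ord <- order(-v, colnames(x))
  feature_set(drug_id, method, colnames(x)[ord][seq_len(k)])
}

#' Supervised correlation selection
#'
#' Orders genes by descending absolute Pearson correlation with the drug's
#' AAC on the training data only; zero-variance genes count as `|r| = 0`.
#'
#' @param train A [pharmaco_dataset()].
#' @param drug Drug id.
#' @param k Number of genes (default 500).
#' @return A [feature_set()] tagged `cor_500`.
#' @export
correlation_select <- function(train, drug, k = 500) {
  d <- aligned_xy(train, drug)
  if (length(d$y) < 3) stop_bad_arg("need at least 3 samples with responses")
  if (k > ncol(d$x)) stop_bad_arg("k exceeds the number of genes")
  r <- abs(cor_with(d$x, d$y))
  ord <- order(-r, colnames(d$x))
  feature_set(drug, "cor_500", colnames(d$x)[ord][seq_len(k)])
}

#' Select genes from an external list
#'
#' Intersects a provided gene list (e.g. the L1000 landmark genes, or a
#' mined list used as features) with the dataset's gene universe, keeping
#' the input order and de-duplicating on first occurrence.
#'
#' @param gene_list Character vector of gene ids.
#' @param universe Character vector of available gene ids.
#' @param drug_id,method Labels for the output feature set.
#' @return A [feature_set()].
#' @export
list_select <- function(gene_list, universe, drug_id = "drug",
                        method = "L1000") {
  if (!length(gene_list)) stop_bad_arg("gene list is empty")
  genes <- gene_list[!duplicated(gene_list)]
  genes <- genes[genes %in% universe]
  if (!length(genes)) stop_bad_arg("gene list has empty intersection with the universe")
  feature_set(drug_id, method, genes)
}

#' Landmark list minus text-mining genes
#'
#' Removes a drug's mined genes from the landmark list, preserving order;
#' an empty result is returned as-is for the caller to handle.
#'
#' @param l1000 Character vector (landmark gene list).
#' @param tm A text-mining [feature_set()] (or character vector).
#' @param drug_id Label for the output.
#' @return A [feature_set()] tagged `L1000-tm`.
#' @export
l1000_minus_tm <- function(l1000, tm, drug_id = "drug") {
  if (!length(l1000)) stop_bad_arg("l1000 list is empty")
  tm_genes <- if (inherits(tm, "feature_set")) tm$genes else as.character(tm)
  if (!length(tm_genes)) stop_bad_arg("text-mining gene list is empty")
  keep <- l1000[!duplicated(l1000)]
  feature_set(drug_id, "L1000-tm", keep[!keep %in% tm_genes])
}

#' Minimum-redundancy maximum-relevance selection (MID scheme)
#'
#' Greedy forward selection for a continuous target. Relevance of gene g is
#' `|Pearson r(x_g, y)|`; redundancy against the selected set S is the mean
#' of `|Pearson r(x_g, x_s)|` over s in S. Each step adds the gene
#' maximizing relevance minus redundancy (the MID difference scheme); the
#' first pick is the most relevant gene. Deterministic; ties break by gene
#' id.
#'
#' @param train A [pharmaco_dataset()].
#' @param drug Drug id.
#' @param k Number of genes to select.
#' @return A [feature_set()] tagged `MRMR`, in selection order.
#' @export
mrmr_select <- function(train, drug, k = 500) {
  d <- aligned_xy(train, drug)
  if (length(d$y) < 3) stop_bad_arg("need at least 3 samples with responses")
  genes <- colnames(d$x)
  if (k > length(genes)) stop_bad_arg("k exceeds the number of genes")
  rel <- abs(cor_with(d$x, d$y))
  selected <- character(k)
  in_pool <- rep(TRUE, length(genes))
  red_sum <- numeric(length(genes))  # running sum of |r| with selected genes
  for (step in seq_len(k)) {
    score <- if (step == 1L) rel else rel - red_sum / (step - 1L)
    score[!in_pool] <- -Inf
    best <- which(score == max(score))
    if (length(best) > 1L) best <- best[order(genes[best])][1L]
    selected[step] <- genes[best]
    in_pool[best] <- FALSE
    if (step < k) {
      red_sum <- red_sum + abs(cor_with(d$x, d$x[, best]))
    }
  }
  feature_set(drug, "MRMR", selected)
}

# Ridge least squares; dual form when p > n to keep the solve small.
ridge_coefs <- function(x, y, lambda = 1e-3) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  n <- nrow(xc); p <- ncol(xc)
  if (p <= n) {
    as.vector(solve(crossprod(xc) + lambda * diag(p), crossprod(xc, yc)))
  } else {
    alpha <- solve(tcrossprod(xc) + lambda * diag(n), yc)
    as.vector(crossprod(xc, alpha))
  }
}

#' Recursive feature elimination with a ridge base model
#'
#' Standardizes the training expression, fits a ridge-regularized linear
#' model, drops the `step` fraction of remaining genes with the smallest
#' absolute coefficients, and repeats until `k` genes remain. Survivors are
#' returned ranked by final absolute coefficient.
#'
#' @param train A [pharmaco_dataset()].
#' @param drug Drug id.
#' @param k Number of surviving genes.
#' @param step Fraction of remaining genes dropped per iteration (default
#'   0.1); at least one gene is dropped per round.
#' @param lambda Ridge penalty of the base model.
#' @return A [feature_set()] tagged `RFE`.
#' @export
rfe_select <- function(train, drug, k, step = 0.1, lambda = 1e-3) {
  d <- aligned_xy(train, drug)
  if (k > ncol(d$x)) stop_bad_arg("k exceeds the number of genes")
  x <- scale(d$x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  active <- colnames(d$x)
  coefs <- NULL
  repeat {
    coefs <- stats::setNames(ridge_coefs(x[, active, drop = FALSE], d$y, lambda),
                             active)
    if (length(active) <= k) break
    n_drop <- min(max(1L, floor(step * length(active))), length(active) - k)
    ord <- order(abs(coefs), names(coefs))  # weakest first, ties by gene id
    active <- setdiff(active, names(coefs)[ord][seq_len(n_drop)])
  }
  ranked <- names(coefs)[order(-abs(coefs), names(coefs))]
  feature_set(drug, "RFE", ranked)
}

ridge_cv_r <- function(x, y, folds, lambda = 1e-3) {
  rs <- vapply(unique(folds), function(f) {
    tr <- folds != f
    if (sum(tr) < 2 || stats::sd(y[!tr]) == 0) return(0)
    beta <- ridge_coefs(x[tr, , drop = FALSE], y[tr], lambda)
    mu_x <- colMeans(x[tr, , drop = FALSE])
    pred <- as.vector(sweep(x[!tr, , drop = FALSE], 2L, mu_x) %*% beta) + mean(y[tr])
    if (stats::sd(pred) == 0) 0 else stats::cor(pred, y[!tr])
  }, numeric(1))
  mean(rs)
}

#' Genetic-algorithm feature selection
#'
#' Binary-mask genetic algorithm over a variance-prefiltered candidate
#' pool: tournament selection, uniform crossover, per-bit flip mutation,
#' elitism of the best mask. Fitness of a mask is the mean inner-CV Pearson
#' correlation of a fast ridge base model on the masked features, minus
#' `lambda_size` times the mask size (a sparsity penalty). Fully seeded.
#'
#' @param train A [pharmaco_dataset()].
#' @param drug Drug id.
#' @param ga_params List overriding any of: `pop_size` (50), `generations`
#'   (30), `mutation_rate` (1/L), `tournament` (3), `pool_size` (2000),
#'   `lambda_size` (0.001), `init_prob` (0.1), `cv_folds` (3),
#'   `ridge_lambda` (1e-3).
#' @param seed Integer seed.
#' @return A [feature_set()] tagged `GA` (genes of the best mask, ordered
#'   by relevance).
#' @export
ga_select <- function(train, drug, ga_params = list(), seed = 1L) {
  defaults <- list(pop_size = 50L, generations = 30L, mutation_rate = NULL,
                   tournament = 3L, pool_size = 2000L, lambda_size = 0.001,
                   init_prob = 0.1, cv_folds = 3L, ridge_lambda = 1e-3)
  bad <- setdiff(names(ga_params), names(defaults))
  if (length(bad)) stop_bad_arg("unknown ga_params: ", paste(bad, collapse = ", "))
  p <- utils::modifyList(defaults, ga_params)
  if (p$pop_size < 2 || p$generations < 1 || p$tournament < 1) {
    stop_bad_arg("invalid ga_params")
  }
  d <- aligned_xy(train, drug)
  v <- col_vars(d$x)
  pool <- colnames(d$x)[order(-v, colnames(d$x))][seq_len(min(p$pool_size, ncol(d$x)))]
  x <- d$x[, pool, drop = FALSE]
  L <- length(pool)
  mut <- if (is.null(p$mutation_rate)) 1 / L else p$mutation_rate
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(p$cv_folds), length(d$y)))
    fitness <- function(mask) {
      if (!any(mask)) return(-Inf)
      ridge_cv_r(x[, mask, drop = FALSE], d$y, folds, p$ridge_lambda) -
        p$lambda_size * sum(mask)
    }
    pop <- matrix(stats::runif(p$pop_size * L) < p$init_prob, nrow = p$pop_size)
    empty <- rowSums(pop) == 0
    if (any(empty)) pop[empty, sample.int(L, 1)] <- TRUE
    fit <- apply(pop, 1L, fitness)
    for (gen in seq_len(p$generations)) {
      newpop <- matrix(FALSE, p$pop_size, L)
      best <- which.max(fit)
      newpop[1L, ] <- pop[best, ]  # elitism
      for (i in 2:p$pop_size) {
        pick <- function() {
          cand <- sample.int(p$pop_size, p$tournament, replace = TRUE)
          cand[which.max(fit[cand])]
        }
        pa <- pop[pick(), ]; pb <- pop[pick(), ]
        child <- ifelse(stats::runif(L) < 0.5, pa, pb)
        flip <- stats::runif(L) < mut
        child[flip] <- !child[flip]
        if (!any(child)) child[sample.int(L, 1)] <- TRUE
        newpop[i, ] <- child
      }
      pop <- newpop
      fit <- apply(pop, 1L, fitness)
    }
    best_mask <- pop[which.max(fit), ]
    genes <- pool[best_mask]
    rel <- abs(cor_with(x[, best_mask, drop = FALSE], d$y))
    fs <- feature_set(drug, "GA", genes[order(-rel, genes)])
    attr(fs, "fitness") <- max(fit)
    fs
  })
}

#' Selector configuration and dispatch
#'
#' `selector_config()` records a selection method and its parameters;
#' `select_features()` runs it on a training dataset. External gene lists
#' (text-mining features, the L1000 landmark list) are supplied through the
#' config rather than recomputed, matching how they arrive in practice.
#'
#' @param method One of the feature-set method tags (see [feature_set()]).
#' @param k Target number of genes (where the method takes one).
#' @param genes External gene list for `text-mining`, `L1000` and `oracle`.
#' @param tm_genes Text-mining list to subtract for `L1000-tm`.
#' @param seed Seed for stochastic selectors (GA).
#' @param ... Method-specific parameters (`step`, `lambda`, `ga_params`).
#' @return `selector_config()`: an object of class `selector_config`;
#'   `select_features()`: a [feature_set()].
#' @export
selector_config <- function(method, k = 500, genes = NULL, tm_genes = NULL,
                            seed = 1L, ...) {
  structure(list(method = method, k = k, genes = genes, tm_genes = tm_genes,
                 seed = seed, extra = list(...)),
            class = "selector_config")
}

#' @rdname selector_config
#' @param train A [pharmaco_dataset()].
#' @param drug Drug id.
#' @param config A `selector_config`.
#' @export
select_features <- function(train, drug, config) {
  stopifnot(inherits(config, "selector_config"))
  universe <- colnames(expr_matrix(train))
  ex <- config$extra
  switch(config$method,
    "var_100" = variance_select(train, 100, drug_id = drug, method = "var_100"),
    "var_500" = variance_select(train, min(500, length(universe)),
                                drug_id = drug, method = "var_500"),
    "cor_500" = correlation_select(train, drug, k = min(config$k, length(universe))),
    "text-mining" = ,
    "L1000" = ,
    "oracle" = list_select(config$genes, universe, drug_id = drug,
                           method = config$method),
    "L1000-tm" = {
      fs <- l1000_minus_tm(config$genes, config$tm_genes, drug_id = drug)
      fs$genes <- intersect(fs$genes, universe)
      fs
    },
    "MRMR" = mrmr_select(train, drug, k = min(config$k, length(universe))),
    "RFE" = do.call(rfe_select, c(list(train, drug,
                                       k = min(config$k, length(universe))), ex)),
    "GA" = do.call(ga_select, c(list(train, drug, seed = config$seed),
                                ex["ga_params"][!vapply(ex["ga_params"], is.null, logical(1))])),
    stop_bad_arg("unknown selector method: ", config$method)
  )
}
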