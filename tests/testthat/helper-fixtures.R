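# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# The default study-scale corpus (5000 abstracts, 50 planted / 1000 genes).
default_corpus <- function() {
  fixture("default_corpus", generate_corpus(corpus_spec(seed = 42)))
}

mined_default <- function() {
  fixture("mined_default", mine_features(default_corpus(), seed = 7))
}

# 20-drug paired domains whose signal pool equals the corpus's planted genes.
bench_pair <- function() {
  fixture("bench_pair", generate_pharmaco_pair(pharmaco_spec(n_drugs = 20, seed = 2024)))
}

# Small handmade dataset: expression matrix with named samples/genes.
toy_dataset <- function(x, y = NULL, drug = "drugA") {
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("g%d", seq_len(ncol(x)))
  resp <- if (is.null(y)) {
    data.frame(sample_id = character(), drug_id = character(), aac = numeric())
  } else {
    data.frame(sample_id = rownames(x), drug_id = drug, aac = y)
  }
  pharmaco_dataset(x, resp)
}

# Linear-signal toy: y = plogis(X w + noise), for selector/model tests.
toy_signal_dataset <- function(n, genes, weights, noise_sd = 0.1, seed = 1,
                               drug = "drugA") {
  set.seed(seed)
  x <- matrix(rnorm(n * genes), n,
              dimnames = list(sprintf("s%03d", 1:n), paste0("g", 1:genes)))
  eta <- as.vector(x[, seq_along(weights), drop = FALSE] %*% weights)
  y <- plogis(eta + rnorm(n, 0, noise_sd))
  toy_dataset(x, y, drug)
}

# Brute-force one-sided Fisher p: hypergeometric enumeration over all
# tables with the observed margins and count >= a.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  hi <- min(k, m)
  if (a > hi) return(0)
  xs <- a:hi
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# Direct Benjamini-Hochberg step-up with monotonization.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(p[o] * n / seq(n, 1)))[order(o)]
}

# Exhaustive greedy MID-scheme selection, recomputed from scratch.
mrmr_oracle <- function(x, y, k) {
  genes <- colnames(x)
  rel <- abs(as.vector(cor(x, y)))
  rel[is.na(rel)] <- 0
  names(rel) <- genes
  sel <- character(0)
  for (step in seq_len(k)) {
    pool <- setdiff(genes, sel)
    score <- vapply(pool, function(g) {
      red <- if (!length(sel)) 0 else mean(abs(cor(x[, g], x[, sel, drop = FALSE])))
      rel[g] - red
    }, numeric(1))
    best <- pool[score == max(score)]
    sel <- c(sel, sort(best)[1])
  }
  sel
}
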