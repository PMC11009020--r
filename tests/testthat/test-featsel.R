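test_that("variance selection orders by descending variance with id ties", {
  x <- cbind(g1 = c(0, 1, 2), g2 = c(0, 3, 6), g3 = c(0, 2, 4))
  rownames(x) <- paste0("s", 1:3)
  ds <- toy_dataset(x, c(0.1, 0.5, 0.9))
  expect_identical(variance_select(ds, 2)$genes, c("g2", "g3"))
  expect_identical(variance_select(ds, 3)$genes, c("g2", "g3", "g1"))
  expect_error(variance_select(ds, 4), "exceeds")

  # constant gene loses to any varying gene
  x2 <- cbind(gc = rep(1, 5), gv = rnorm(5))
  rownames(x2) <- paste0("s", 1:5)
  expect_identical(variance_select(toy_dataset(x2, runif(5)), 1)$genes, "gv")
})

test_that("correlation selection ranks by |r| and matches a brute-force scan", {
  ds <- toy_signal_dataset(200, 20, numeric(0), seed = 41)
  y <- drug_response(ds, "drugA")
  x <- ds$expression[names(y), ]
  # exact linear response puts its gene first with |r| = 1
  ds1 <- toy_dataset(x, (x[, "g7"] - min(x[, "g7"])) / diff(range(x[, "g7"])))
  expect_identical(correlation_select(ds1, "drugA", k = 1)$genes, "g7")
  # k = 1 equals the argmax of a direct correlation scan
  r <- abs(as.vector(cor(x, y)))
  expect_identical(correlation_select(ds, "drugA", k = 1)$genes,
                   colnames(x)[which.max(r)])
  # permuted responses: no spurious strong correlation at n = 200
  set.seed(42)
  ds_perm <- toy_dataset(x, sample(y))
  top <- correlation_select(ds_perm, "drugA", k = 1)$genes
  expect_lt(abs(cor(x[, top], drug_response(ds_perm, "drugA"))), 0.3)
})

test_that("list selection intersects, de-duplicates, and preserves order", {
  uni <- paste0("g", 1:10)
  expect_identical(list_select(c("g3", "g1"), uni)$genes, c("g3", "g1"))
  expect_identical(list_select(c("g3", "gX", "g1", "gY"), uni)$genes,
                   c("g3", "g1"))
  expect_identical(list_select(c("g2", "g2", "g5"), uni)$genes, c("g2", "g5"))
  expect_error(list_select(c("gX", "gY"), uni), "empty intersection")
})

test_that("landmark-minus-text-mining is an order-preserving set difference", {
  l1000 <- c("g1", "g2", "g3", "g4", "g5")
  expect_identical(l1000_minus_tm(l1000, c("gX", "gY"))$genes, l1000)
  expect_length(l1000_minus_tm(l1000, l1000)$genes, 0)
  expect_identical(l1000_minus_tm(l1000, c("g2", "g4", "g9"))$genes,
                   c("g1", "g3", "g5"))
})

test_that("MRMR prefers an independent gene over a duplicate of the best", {
  set.seed(51)
  n <- 200
  sig <- rnorm(n)
  indep <- rnorm(n)
  y <- plogis(2 * sig + 0.8 * indep + rnorm(n, 0, 0.1))
  x <- cbind(g1 = sig, g2 = sig, g3 = indep)
  rownames(x) <- paste0("s", 1:n)
  ds <- toy_dataset(x, y)
  fs <- mrmr_select(ds, "drugA", k = 2)
  expect_identical(fs$genes[1], "g1")     # tie g1/g2 broken lexically
  expect_identical(fs$genes[2], "g3")     # duplicate penalized away
  # k = 1 reduces to plain max relevance
  expect_identical(mrmr_select(ds, "drugA", k = 1)$genes,
                   correlation_select(ds, "drugA", k = 1)$genes)
})

test_that("MRMR greedy path equals an exhaustive greedy oracle", {
  set.seed(52)
  for (i in 1:20) {
    n <- 40
    x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("g", 1:8)))
    x[, 2] <- x[, 1] + rnorm(n, 0, 0.3)     # induce redundancy
    y <- plogis(x[, 1] - x[, 3] + rnorm(n, 0, 0.5))
    rownames(x) <- paste0("s", 1:n)
    ds <- toy_dataset(x, y)
    k <- sample(2:4, 1)
    expect_identical(mrmr_select(ds, "drugA", k = k)$genes,
                     mrmr_oracle(x, y, k))
  }
})

test_that("RFE survives the signal gene and is the identity at k = p", {
  set.seed(61)
  n <- 120
  x <- matrix(rnorm(n * 10), n, dimnames = list(paste0("s", 1:n), paste0("g", 1:10)))
  y <- plogis(3 * x[, 1] + rnorm(n, 0, 0.2))
  ds <- toy_dataset(x, y)
  expect_identical(rfe_select(ds, "drugA", k = 1)$genes, "g1")
  expect_setequal(rfe_select(ds, "drugA", k = 10)$genes, paste0("g", 1:10))
})

test_that("RFE ranks orthogonal designs by coefficient magnitude", {
  # orthonormal columns: least-squares coefficients equal the true weights,
  # so elimination follows |w| exactly
  set.seed(62)
  n <- 64
  x <- qr.Q(qr(matrix(rnorm(n * 4), n)))
  colnames(x) <- paste0("g", 1:4)
  rownames(x) <- paste0("s", 1:n)
  w <- c(0.05, 0.4, 0.2, 0.1)
  y <- 0.5 + as.vector(x %*% w)
  stopifnot(all(y > 0 & y < 1))
  ds <- toy_dataset(x, y)
  fs <- rfe_select(ds, "drugA", k = 2, step = 0.5)
  expect_identical(fs$genes, c("g2", "g3"))
})

test_that("GA selection is seeded, recovers planted genes, beats random masks", {
  set.seed(71)
  n <- 100
  x <- matrix(rnorm(n * 12), n, dimnames = list(paste0("s", 1:n), paste0("g", 1:12)))
  y <- plogis(1.5 * x[, 3] - 1.5 * x[, 8] + rnorm(n, 0, 0.2))
  ds <- toy_dataset(x, y)
  params <- list(pop_size = 30, generations = 30, pool_size = 12)
  fs1 <- ga_select(ds, "drugA", ga_params = params, seed = 5)
  fs2 <- ga_select(ds, "drugA", ga_params = params, seed = 5)
  expect_identical(fs1$genes, fs2$genes)
  expect_true(all(c("g3", "g8") %in% fs1$genes))
  expect_error(ga_select(ds, "drugA", ga_params = list(pop_size = 1)), "invalid")

  # fitness of the returned mask beats the median random mask of equal size
  yv <- drug_response(ds, "drugA")
  xx <- ds$expression[names(yv), ]
  set.seed(72)
  folds <- sample(rep_len(1:3, n))
  fit_of <- function(genes) {
    litsel:::ridge_cv_r(xx[, genes, drop = FALSE], yv, folds) - 0.001 * length(genes)
  }
  rand <- replicate(100, fit_of(sample(colnames(xx), length(fs1$genes))))
  expect_gte(fit_of(fs1$genes), median(rand))
})

test_that("select_features dispatches every method tag", {
  ds <- toy_signal_dataset(60, 120, c(1.5, -1.5), seed = 81)
  expect_identical(select_features(ds, "drugA", selector_config("var_100"))$genes,
                   variance_select(ds, 100, method = "var_100")$genes)
  expect_length(select_features(ds, "drugA", selector_config("var_500"))$genes, 120)
  expect_length(select_features(ds, "drugA", selector_config("cor_500", k = 10))$genes, 10)
  fs_tm <- select_features(ds, "drugA",
                           selector_config("text-mining", genes = c("g2", "g5", "gZ")))
  expect_identical(fs_tm$genes, c("g2", "g5"))
  fs_lt <- select_features(ds, "drugA",
                           selector_config("L1000-tm", genes = c("g1", "g2", "g3"),
                                           tm_genes = "g2"))
  expect_identical(fs_lt$genes, c("g1", "g3"))
  expect_length(select_features(ds, "drugA", selector_config("MRMR", k = 5))$genes, 5)
  expect_length(select_features(ds, "drugA", selector_config("RFE", k = 5))$genes, 5)
})
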