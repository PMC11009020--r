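test_that("metric bundle reproduces hand-computed values and identities", {
  m <- compute_metrics(c(0, 0.5, 1), c(0, 0.5, 1))
  expect_equal(unname(m[c("pearson", "spearman", "kendall")]), rep(1, 3))
  expect_equal(unname(m[c("rmse", "mse", "mae")]), rep(0, 3))

  rev_m <- compute_metrics(c(1, 2, 3) / 3, c(3, 2, 1) / 3)
  expect_equal(unname(rev_m["kendall"]), -1)
  expect_equal(unname(rev_m["spearman"]), -1)

  hand <- compute_metrics(c(0, 0.5, 1), c(0.1, 0.4, 0.9))
  expect_equal(unname(hand["mae"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(hand["mse"]), 0.01, tolerance = 1e-12)
  expect_equal(unname(hand["rmse"]), 0.1, tolerance = 1e-12)

  # degenerate target flagged, not propagated as NaN correlations silently
  dg <- compute_metrics(rep(0.5, 5), runif(5))
  expect_true(attr(dg, "degenerate"))
  expect_true(all(is.na(dg[c("pearson", "spearman", "kendall")])))
})

test_that("metric identities hold across random benchmark-style vectors", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    m <- compute_metrics(runif(n), runif(n))
    expect_equal(unname(m["rmse"]^2), unname(m["mse"]), tolerance = 1e-10)
    expect_lte(m["mae"], m["rmse"] + 1e-12)
    expect_true(all(abs(m[c("pearson", "spearman", "kendall")]) <= 1 + 1e-12))
  }
})

test_that("Kendall component is tie-corrected tau-b", {
  x <- c(1, 1, 2, 3, 4)
  y <- c(2, 1, 1, 3, 3)
  expect_equal(litsel:::kendall_tau_b(x, y),
               unname(cor.test(x, y, method = "kendall", exact = FALSE)$estimate),
               tolerance = 1e-12)
})

test_that("elastic net recovers a clean linear signal on held-out data", {
  ds <- toy_signal_dataset(160, 10, c(1.2, -1, 0.8), noise_sd = 0.05, seed = 101)
  y <- drug_response(ds, "drugA")
  x <- ds$expression[names(y), ]
  tr <- 1:120; te <- 121:160
  sc <- fit_scaler(x[tr, ])
  spec <- model_spec("elastic_net", seed = 7)
  fit <- train_model(spec, apply_scaler(sc, x[tr, ]), y[tr])
  pred <- predict(fit, apply_scaler(sc, x[te, ]))
  expect_gt(cor(pred, y[te]), 0.95)
})

test_that("a constant target yields near-constant predictions, flagged metrics", {
  set.seed(102)
  x <- matrix(rnorm(40 * 5), 40, dimnames = list(paste0("s", 1:40), paste0("g", 1:5)))
  fit <- train_model(model_spec("elastic_net", seed = 1), x, rep(0.4, 40))
  pred <- predict(fit, x)
  expect_lt(max(pred) - min(pred), 1e-8)
  m <- compute_metrics(rep(0.4, 40), pred)
  expect_true(attr(m, "degenerate"))
})

test_that("the MLP keeps predictions inside the unit interval", {
  set.seed(103)
  x <- matrix(rnorm(60 * 8), 60, dimnames = list(paste0("s", 1:60), paste0("g", 1:8)))
  y <- plogis(2 * x[, 1] + rnorm(60, 0, 0.3))
  spec <- model_spec("mlp", grid = list(hidden = list(c(16, 8))),
                     mlp = list(restarts = 2, epochs = 10), seed = 5)
  fit <- train_model(spec, x, y)
  extreme <- matrix(rnorm(50 * 8, sd = 10), 50,
                    dimnames = list(NULL, paste0("g", 1:8)))
  pred <- predict(fit, extreme)
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("within-domain CV is deterministic and near zero under a null", {
  # selection intensity kept at study-like proportions (30 of 300 genes):
  # aggressive selection from a tiny universe leaves a winner's-curse
  # negative bias in held-out folds even under a permuted target
  pair <- generate_pharmaco_pair(pharmaco_spec(
    n_samples_train = 300, n_samples_test = 20, n_genes = 300,
    signal_genes = paste0("g", 1:3), effect_sizes = rep(1.2, 3), seed = 111))
  prot <- cv_protocol(n_folds = 4, n_repeats = 2, seed = 31)
  cfg <- selector_config("cor_500", k = 30)
  spec <- model_spec("elastic_net", grid = list(alpha = 0.5), seed = 3)
  r1 <- run_cv(pair$train, cfg, spec, prot)
  r2 <- run_cv(pair$train, cfg, spec, prot)
  expect_identical(r1, r2)
  expect_gt(r1$pearson, 0.5)   # real signal is learnable

  # permuted responses: mean within-domain r stays in a null band
  ds_null <- pair$train
  set.seed(32)
  ds_null$responses$aac <- sample(ds_null$responses$aac)
  r0 <- run_cv(ds_null, cfg, spec, prot)
  expect_gt(r0$pearson, -0.1)
  expect_lt(r0$pearson, 0.1)
})

test_that("duplicating every sample leaves fold metrics roughly unchanged", {
  pair <- generate_pharmaco_pair(pharmaco_spec(
    n_samples_train = 80, n_samples_test = 20, n_genes = 40,
    signal_genes = paste0("g", 1:3), effect_sizes = rep(1.2, 3), seed = 117))
  ds <- pair$train
  dup_x <- rbind(ds$expression,
                 `rownames<-`(ds$expression, paste0(rownames(ds$expression), "b")))
  dup_resp <- rbind(ds$responses,
                    transform(ds$responses, sample_id = paste0(sample_id, "b")))
  ds_dup <- pharmaco_dataset(dup_x, dup_resp)
  prot <- cv_protocol(n_folds = 4, n_repeats = 2, seed = 33)
  cfg <- selector_config("cor_500", k = 15)
  spec <- model_spec("elastic_net", grid = list(alpha = 0.5), seed = 3)
  r <- run_cv(ds, cfg, spec, prot)
  r_dup <- run_cv(ds_dup, cfg, spec, prot)
  expect_lt(abs(r$pearson - r_dup$pearson), 0.15)
})

test_that("cross-domain validation tracks within-domain under zero shift", {
  spec0 <- pharmaco_spec(n_samples_train = 120, n_samples_test = 120,
                         n_genes = 60, signal_genes = paste0("g", 1:3),
                         effect_sizes = rep(1.5, 3), noise_sd = 0.2,
                         domain_shift_sd = 0, seed = 121)
  pair <- generate_pharmaco_pair(spec0)
  cfg <- selector_config("cor_500", k = 20)
  mspec <- model_spec("elastic_net", grid = list(alpha = 0.5), seed = 3)
  prot <- cv_protocol(n_folds = 4, n_repeats = 2, seed = 34)
  r_in <- run_cv(pair$train, cfg, mspec, prot)
  r_x <- run_cross_domain(pair$train, pair$test, cfg, mspec, prot)
  expect_lt(abs(r_in$pearson - r_x$pearson), 0.1)

  # independently regenerated test responses are unpredictable
  null_test <- pair$test
  set.seed(35)
  null_test$responses$aac <- runif(nrow(null_test$responses))
  r_null <- run_cross_domain(pair$train, null_test, cfg, mspec, prot)
  expect_lt(abs(r_null$pearson), 0.25)
})

test_that("ground-truth features dominate variance features cross-domain", {
  pair <- bench_pair()
  drugs <- dataset_drugs(pair$train)[1:4]
  mspec <- model_spec("elastic_net", grid = list(alpha = 0.5), seed = 3)
  rows <- list()
  for (d in drugs) {
    rows[[length(rows) + 1L]] <- run_cross_domain(
      pair$train, pair$test,
      selector_config("oracle", genes = pair$truth[[d]]$genes),
      mspec, drugs = d)
    rows[[length(rows) + 1L]] <- run_cross_domain(
      pair$train, pair$test, selector_config("var_100"), mspec, drugs = d)
  }
  res <- do.call(rbind, rows)
  # flat predictions (flagged NA correlation) carry no association: score 0
  res$pearson[is.na(res$pearson)] <- 0
  mean_by <- tapply(res$pearson, res$selector, mean)
  expect_gt(mean_by["oracle"], mean_by["var_100"])
})

test_that("paired selector comparison matches the t formula and null flags", {
  res <- data.frame(
    drug = rep(paste0("d", 1:3), 2),
    selector = rep(c("A", "B"), each = 3),
    model_family = "elastic_net", split_kind = "within",
    pearson = c(0.5 + c(1, 2, 3) / 10, 0.5, 0.5, 0.5),
    spearman = 0, kendall = 0, rmse = 0, mse = 0, mae = 0, n = 10)
  cmp <- compare_selectors(res, "pearson", "A", "B")
  expect_equal(cmp$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$mean_diff, 0.2, tolerance = 1e-12)

  cmp_self <- compare_selectors(res, "pearson", "A", "A")
  expect_equal(cmp_self$mean_diff, 0)
  expect_true(cmp_self$zero_variance)
  expect_equal(cmp_self$p_value, 1)

  expect_error(compare_selectors(res[c(1, 4), ], "pearson", "A", "B"), "3 paired")
})

test_that("paired t direction agrees with a sign-permutation oracle", {
  set.seed(131)
  a <- runif(10, 0.4, 0.8)
  b <- a - rnorm(10, 0.1, 0.05)
  res <- data.frame(
    drug = rep(paste0("d", 1:10), 2),
    selector = rep(c("A", "B"), each = 10),
    model_family = "rf", split_kind = "cross",
    pearson = c(a, b), spearman = 0, kendall = 0, rmse = 0, mse = 0, mae = 0,
    n = 10)
  cmp <- compare_selectors(res, "pearson", "A", "B")
  d <- a - b
  perm <- replicate(2000, mean(d * sample(c(-1, 1), 10, replace = TRUE)))
  p_perm <- mean(abs(perm) >= abs(mean(d)))
  expect_identical(sign(cmp$mean_diff), 1)
  expect_lt(cmp$p_value, 0.05)
  expect_lt(p_perm, 0.05)   # same direction and significance as the oracle
})
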