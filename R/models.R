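#' Model specification for the drug-response regressors
#'
#' Three regression families predict AAC from scaled expression:
#' elastic net (glmnet), random forest, and a small fully connected
#' multilayer perceptron trained by stochastic gradient descent with
#' momentum 0.9 and learning rate 0.01, dropout 0.2 after each hidden
#' layer, ReLU hidden activations, a sigmoid output (so predictions stay in
#' `[0, 1]`), mean-squared-error loss, 15 epochs, and 6 restarts keeping
#' the best validation model.
#'
#' @param family `"elastic_net"`, `"random_forest"` or `"mlp"`.
#' @param grid Family-specific hyperparameter grid, a list:
#'   elastic net — `alpha` (mixing values; ridge penalty path is tuned
#'   internally by cross-validation); random forest — `ntree`, `maxnodes`
#'   (NA = unlimited depth); mlp — `hidden` (list of hidden-layer size
#'   vectors). Defaults: `alpha = seq(0.1, 0.9, 0.2)`;
#'   `ntree = c(250, 500)`, `maxnodes = c(NA, 1024)`; `hidden =
#'   list(c(256, 64))`.
#' @param tune_folds Inner cross-validation folds for the grid search.
#' @param seed Integer seed for fold assignment and stochastic fits.
#' @param mlp Overrides for the fixed mlp training parameters
#'   (`lr`, `momentum`, `dropout`, `epochs`, `restarts`, `batch`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("elastic_net", "random_forest", "mlp"),
                       grid = NULL, tune_folds = 3L, seed = 1L,
                       mlp = list()) {
  family <- match.arg(family)
  default_grid <- switch(family,
    elastic_net = list(alpha = seq(0.1, 0.9, by = 0.2)),
    random_forest = list(ntree = c(250, 500), maxnodes = c(NA, 1024)),
    mlp = list(hidden = list(c(256, 64)))
  )
  grid <- utils::modifyList(default_grid, if (is.null(grid)) list() else grid)
  if (!length(grid) || !all(lengths(grid) >= 1)) stop_bad_arg("grid must be nonempty")
  mlp_defaults <- list(lr = 0.01, momentum = 0.9, dropout = 0.2, epochs = 15L,
                       restarts = 6L, batch = 32L, val_frac = 0.2)
  structure(list(family = family, grid = grid, tune_folds = as.integer(tune_folds),
                 seed = seed, mlp = utils::modifyList(mlp_defaults, mlp)),
            class = "model_spec")
}

#' Train a drug-response regressor with inner grid-search tuning
#'
#' Fits the family requested by a [model_spec()] on a scaled feature matrix
#' and AAC vector, choosing hyperparameters from the spec's grid by inner
#' cross-validated mean-squared error, then refitting on all rows.
#'
#' @param spec A [model_spec()].
#' @param X Numeric matrix (samples x selected genes), already scaled with a
#'   train-fitted scaler.
#' @param y AAC vector in `[0, 1]`, length `nrow(X)`.
#' @return An object of class `litsel_model` supporting [predict()].
#' @export
train_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"), nrow(X) == length(y))
  if (any(y < 0 | y > 1)) stop_bad_arg("y must lie in [0, 1]")
  if (nrow(X) < spec$tune_folds + 1) stop_bad_arg("too few samples for tuning folds")
  if (stats::sd(y) == 0) {
    # degenerate target: every family would fit a constant anyway
    return(structure(list(family = "constant",
                          fit = list(value = y[1]), chosen = list(),
                          genes = colnames(X), spec = spec),
                     class = "litsel_model"))
  }
  fit <- with_seed(spec$seed, switch(spec$family,
    elastic_net = fit_enet(spec, X, y),
    random_forest = fit_rf(spec, X, y),
    mlp = fit_mlp(spec, X, y)
  ))
  structure(list(family = spec$family, fit = fit$fit, chosen = fit$chosen,
                 genes = colnames(X), spec = spec),
            class = "litsel_model")
}

#' @export
print.litsel_model <- function(x, ...) {
  cat(sprintf("<litsel_model> %s on %d genes; tuned: %s\n", x$family,
              length(x$genes),
              paste(names(x$chosen), unlist(x$chosen), sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
predict.litsel_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "pharmaco_dataset")) newdata$expression else newdata
  x <- x[, object$genes, drop = FALSE]
  switch(object$family,
    constant = rep(object$fit$value, nrow(x)),
    elastic_net = as.vector(stats::predict(object$fit$glmnet,
                                           newx = pad2(x),
                                           s = object$fit$lambda)),
    random_forest = as.vector(stats::predict(object$fit, x)),
    mlp = as.vector(mlp_forward(object$fit, x)$out)
  )
}

# glmnet needs >= 2 columns; pad single-gene designs with a zero column.
pad2 <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

fit_enet <- function(spec, X, y) {
  foldid <- sample(rep_len(seq_len(spec$tune_folds), length(y)))
  fits <- lapply(spec$grid$alpha, function(a) {
    glmnet::cv.glmnet(pad2(X), y, alpha = a, foldid = foldid,
                      family = "gaussian")
  })
  cvmin <- vapply(fits, function(f) min(f$cvm), numeric(1))
  best <- which.min(cvmin)
  cv <- fits[[best]]
  list(fit = list(glmnet = cv$glmnet.fit, lambda = cv$lambda.min),
       chosen = list(alpha = spec$grid$alpha[best], lambda = cv$lambda.min))
}

rf_one <- function(X, y, ntree, maxnodes) {
  args <- list(x = X, y = y, ntree = ntree)
  if (!is.na(maxnodes)) args$maxnodes <- maxnodes
  do.call(randomForest::randomForest, args)
}

fit_rf <- function(spec, X, y) {
  grid <- expand.grid(ntree = spec$grid$ntree, maxnodes = spec$grid$maxnodes)
  if (nrow(grid) > 1L) {
    foldid <- sample(rep_len(seq_len(spec$tune_folds), length(y)))
    mse <- vapply(seq_len(nrow(grid)), function(i) {
      errs <- vapply(seq_len(spec$tune_folds), function(f) {
        tr <- foldid != f
        m <- rf_one(X[tr, , drop = FALSE], y[tr], grid$ntree[i], grid$maxnodes[i])
        mean((stats::predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- which.min(mse)
  } else {
    best <- 1L
  }
  fit <- rf_one(X, y, grid$ntree[best], grid$maxnodes[best])
  list(fit = fit, chosen = as.list(grid[best, , drop = FALSE]))
}

# ---- minimal fully connected MLP regressor (base R) ----------------------

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], 0, sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

mlp_forward <- function(net, x, dropout = 0, train = FALSE) {
  acts <- list(x)
  h <- x
  L <- length(net$layers)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z <- sweep(h %*% net$layers[[l]]$W, 2L, net$layers[[l]]$b, `+`)
    if (l < L) {
      h <- pmax(z, 0)
      if (train && dropout > 0) {
        m <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
        h <- h * m / (1 - dropout)  # inverted dropout
        masks[[l]] <- m
      }
    } else {
      h <- stats::plogis(z)
    }
    acts[[l + 1L]] <- h
  }
  list(out = h, acts = acts, masks = masks)
}

mlp_train_once <- function(X, y, hidden, p) {
  net <- list(layers = mlp_init(c(ncol(X), hidden, 1L)))
  L <- length(net$layers)
  vel <- lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  n <- nrow(X)
  for (epoch in seq_len(p$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = p$batch)) {
      rows <- idx[start:min(start + p$batch - 1L, n)]
      xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      fw <- mlp_forward(net, xb, dropout = p$dropout, train = TRUE)
      out <- fw$acts[[L + 1L]]
      # MSE loss with sigmoid output: delta = 2/n (out - y) * out(1 - out)
      delta <- (2 / length(rows)) * (out - yb) * out * (1 - out)
      for (l in rev(seq_len(L))) {
        a_prev <- fw$acts[[l]]
        gW <- crossprod(a_prev, delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(net$layers[[l]]$W)
          delta <- delta * (fw$acts[[l]] > 0)
          if (!is.null(fw$masks[[l - 1L]])) {
            delta <- delta * fw$masks[[l - 1L]] / (1 - p$dropout)
          }
        }
        vel[[l]]$W <- p$momentum * vel[[l]]$W - p$lr * gW
        vel[[l]]$b <- p$momentum * vel[[l]]$b - p$lr * gb
        net$layers[[l]]$W <- net$layers[[l]]$W + vel[[l]]$W
        net$layers[[l]]$b <- net$layers[[l]]$b + vel[[l]]$b
      }
    }
  }
  net
}

fit_mlp <- function(spec, X, y) {
  p <- spec$mlp
  n <- nrow(X)
  n_val <- max(2L, floor(p$val_frac * n))
  best <- NULL; best_mse <- Inf; best_hidden <- NULL
  for (hidden in spec$grid$hidden) {
    hidden <- pmin(hidden, max(4L, 4L * ncol(X)))  # cap width for tiny inputs
    for (r in seq_len(p$restarts)) {
      val <- sample.int(n, n_val)
      net <- mlp_train_once(X[-val, , drop = FALSE], y[-val], hidden, p)
      pred <- mlp_forward(net, X[val, , drop = FALSE])$out
      mse <- mean((pred - y[val])^2)
      if (mse < best_mse) {
        best_mse <- mse; best <- net; best_hidden <- hidden
      }
    }
  }
  list(fit = best, chosen = list(hidden = paste(best_hidden, collapse = "x"),
                                 val_mse = best_mse))
}
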