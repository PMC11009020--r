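#' Specification for a paired synthetic pharmacogenomic domain
#'
#' Describes two domains (train and test) of log-scale expression profiles
#' sharing a sparse linear expression-to-response signal, with additive
#' per-gene mean shift in the test domain. Drug sensitivity is recorded as
#' the area above the dose-response curve (AAC), squashed into (0, 1) with a
#' logistic link: `AAC = plogis(eta + noise)` where
#' `eta = sum_g w_g * x_g` runs over a drug's signal genes.
#'
#' When `n_drugs > 1`, each drug's signal genes are a random subset of size
#' `genes_per_drug` drawn from the `signal_genes` pool, with weights
#' recycled from `effect_sizes`; the realized per-drug sets are returned as
#' ground truth.
#'
#' @param n_samples_train,n_samples_test Sample counts for the two domains.
#' @param n_genes Size of the shared gene universe (`g1..g<n>`).
#' @param signal_genes Pool of causal gene ids (subset of the universe).
#' @param effect_sizes Numeric weights, recycled over a drug's signal genes.
#' @param noise_sd Standard deviation of the additive noise inside the
#'   logistic link (>= 0).
#' @param domain_shift_sd SD of the per-gene additive mean shift applied to
#'   the test domain (>= 0).
#' @param n_drugs Number of drugs to simulate.
#' @param genes_per_drug Signal genes per drug when `n_drugs > 1`.
#' @param seed Integer seed.
#' @return An object of class `pharmaco_spec`.
#' @seealso [generate_pharmaco_pair()]
#' @export
pharmaco_spec <- function(n_samples_train = 150,
                          n_samples_test = 150,
                          n_genes = 1000,
                          signal_genes = paste0("g", 1:50),
                          effect_sizes = rep(1, length(signal_genes)),
                          noise_sd = 0.3,
                          domain_shift_sd = 0.5,
                          n_drugs = 1,
                          genes_per_drug = 5,
                          seed = 1L) {
  universe <- paste0("g", seq_len(n_genes))
  if (!all(signal_genes %in% universe)) {
    stop_bad_arg("signal_genes must be a subset of the gene universe g1..g", n_genes)
  }
  if (noise_sd < 0) stop_bad_arg("noise_sd must be >= 0")
  if (domain_shift_sd < 0) stop_bad_arg("domain_shift_sd must be >= 0")
  if (n_drugs < 1) stop_bad_arg("n_drugs must be >= 1")
  structure(list(
    n_samples_train = as.integer(n_samples_train),
    n_samples_test = as.integer(n_samples_test),
    n_genes = as.integer(n_genes),
    signal_genes = signal_genes,
    effect_sizes = effect_sizes,
    noise_sd = noise_sd,
    domain_shift_sd = domain_shift_sd,
    n_drugs = as.integer(n_drugs),
    genes_per_drug = as.integer(genes_per_drug),
    seed = as.integer(seed)
  ), class = "pharmaco_spec")
}

sim_domain_expression <- function(n, genes, shift, prefix) {
  x <- matrix(stats::rnorm(n * length(genes)), nrow = n,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n)), genes))
  sweep(x, 2L, shift, `+`)
}

#' Generate a paired train/test pharmacogenomic domain
#'
#' Draws the two domains of a [pharmaco_spec()]. Both share the same linear
#' predictor over each drug's signal genes; the test domain's per-gene means
#' are shifted by `N(0, domain_shift_sd)`. Responses are
#' `plogis(eta + N(0, noise_sd))`, so all AAC values lie in (0, 1). Output
#' is deterministic given the spec seed.
#'
#' @param spec A [pharmaco_spec()].
#' @return An object of class `pharmaco_pair`: list with `train` and `test`
#'   ([pharmaco_dataset()] objects), `truth` (per-drug list with `genes` and
#'   `weights`), and the `spec`.
#' @export
generate_pharmaco_pair <- function(spec) {
  stopifnot(inherits(spec, "pharmaco_spec"))
  with_seed(spec$seed, {
    genes <- paste0("g", seq_len(spec$n_genes))
    shift <- stats::rnorm(spec$n_genes, 0, spec$domain_shift_sd)
    x_tr <- sim_domain_expression(spec$n_samples_train, genes, 0, "TR")
    x_te <- sim_domain_expression(spec$n_samples_test, genes, shift, "TE")

    drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
    truth <- vector("list", spec$n_drugs)
    names(truth) <- drugs
    resp <- list()
    for (d in seq_len(spec$n_drugs)) {
      if (spec$n_drugs == 1L) {
        sg <- spec$signal_genes
        w <- rep_len(spec$effect_sizes, length(sg))
      } else {
        sg <- sort(sample(spec$signal_genes,
                          min(spec$genes_per_drug, length(spec$signal_genes))))
        w <- rep_len(spec$effect_sizes, length(sg))
      }
      truth[[d]] <- list(genes = sg, weights = stats::setNames(w, sg))
      for (dom in c("train", "test")) {
        x <- if (dom == "train") x_tr else x_te
        eta <- as.vector(x[, sg, drop = FALSE] %*% w)
        aac <- stats::plogis(eta + stats::rnorm(nrow(x), 0, spec$noise_sd))
        resp[[length(resp) + 1L]] <- data.frame(
          sample_id = rownames(x), drug_id = drugs[d], aac = aac,
          domain = dom, stringsAsFactors = FALSE)
      }
    }
    resp <- do.call(rbind, resp)
    tr <- pharmaco_dataset(x_tr, resp[resp$domain == "train", c("sample_id", "drug_id", "aac")])
    te <- pharmaco_dataset(x_te, resp[resp$domain == "test", c("sample_id", "drug_id", "aac")])
    structure(list(train = tr, test = te, truth = truth, spec = spec),
              class = "pharmaco_pair")
  })
}

#' Generate a synthetic xenograft-style survival cohort
#'
#' Draws a small cohort of subjects from the same generative model as a
#' [pharmaco_pair()]'s domains: expression from the shared gene universe and
#' a true response through the pair's recorded signal for `drug`. Survival
#' times are exponential with hazard `base_hazard * exp(-hazard_scale *
#' (response - mean(response)))`, so more sensitive subjects progress later;
#' times beyond `censor_time` are right-censored. `hazard_scale = 0` yields
#' times independent of response (a null cohort).
#'
#' @param pair A [generate_pharmaco_pair()] result.
#' @param drug Drug id within the pair's truth.
#' @param n_subjects Cohort size.
#' @param hazard_scale Log-hazard units per unit of true response.
#' @param base_hazard Baseline event rate per day.
#' @param censor_time Administrative censoring horizon (days).
#' @param seed Integer seed.
#' @return List with `expression` (subjects x genes), `response` (true AAC),
#'   and `survival` (data.frame: subject_id, time_days, event).
#' @export
generate_pdx_cohort <- function(pair, drug = names(pair$truth)[1],
                                n_subjects = 24, hazard_scale = 3,
                                base_hazard = 1 / 150, censor_time = 600,
                                seed = 1L) {
  stopifnot(inherits(pair, "pharmaco_pair"), drug %in% names(pair$truth))
  with_seed(seed, {
    genes <- paste0("g", seq_len(pair$spec$n_genes))
    x <- sim_domain_expression(n_subjects, genes, 0, "PDX")
    th <- pair$truth[[drug]]
    eta <- as.vector(x[, th$genes, drop = FALSE] %*% th$weights)
    response <- stats::plogis(eta + stats::rnorm(n_subjects, 0, pair$spec$noise_sd))
    rate <- base_hazard * exp(-hazard_scale * (response - mean(response)))
    t_raw <- stats::rexp(n_subjects, rate)
    event <- as.integer(t_raw <= censor_time)
    time <- pmin(t_raw, censor_time)
    list(
      expression = x,
      response = stats::setNames(response, rownames(x)),
      survival = data.frame(subject_id = rownames(x), time_days = time,
                            event = event, stringsAsFactors = FALSE)
    )
  })
}
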