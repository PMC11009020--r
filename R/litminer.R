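#' Train a naive Bayes topic classifier over abstracts
#'
#' Fits a Bernoulli naive Bayes model on token presence with Laplace
#' smoothing `s`. With smoothed per-class presence rates
#' `p_t = (n_pos(t) + s) / (N_pos + 2s)` and
#' `q_t = (n_bg(t) + s) / (N_bg + 2s)`, the stored per-token presence
#' log-odds is `log(p_t) - log(q_t)` and the absence log-odds is
#' `log(1 - p_t) - log(1 - q_t)`. A document's posterior log-odds of topic
#' relevance is the class prior log-odds plus `sum_t log(p_t/q_t)` over
#' present tokens plus `sum_t log((1-p_t)/(1-q_t))` over absent vocabulary
#' tokens. Collecting the absence terms into an intercept (`bias`) makes
#' the classifier a linear function of token-presence indicators with
#' effective weights `log(p_t/q_t) - log((1-p_t)/(1-q_t))`. Tokens unseen
#' in either training class carry no evidence.
#'
#' @param positives,background Lists of abstract records (each a list with
#'   at least a `tokens` character vector); both nonempty.
#' @param smoothing Laplace pseudo-count `s` (> 0).
#' @param prior_log_odds Prior log-odds of the topic class; 0 = equal priors.
#' @param decision_threshold Posterior probability at or above which an
#'   abstract is called relevant; in `[0, 1]`.
#' @return An object of class `topic_classifier` with elements
#'   `token_log_odds` and `absence_log_odds` (named numeric over the
#'   training vocabulary), `prior_log_odds`, `bias` (prior plus total
#'   absence term), and `decision_threshold`.
#' @export
train_topic_classifier <- function(positives, background, smoothing = 1,
                                   prior_log_odds = 0,
                                   decision_threshold = 0.5) {
  if (!length(positives) || !length(background)) {
    stop_bad_arg("both training classes must be nonempty")
  }
  if (smoothing <= 0) stop_bad_arg("smoothing must be > 0")
  if (decision_threshold < 0 || decision_threshold > 1) {
    stop_bad_arg("decision_threshold must lie in [0, 1]")
  }
  doc_tokens <- function(a) unique(a$tokens)
  pos_counts <- table(unlist(lapply(positives, doc_tokens), use.names = FALSE))
  bg_counts <- table(unlist(lapply(background, doc_tokens), use.names = FALSE))
  vocab <- sort(union(names(pos_counts), names(bg_counts)))
  np <- length(positives); nb <- length(background)
  cp <- as.numeric(pos_counts[vocab]); cp[is.na(cp)] <- 0
  cb <- as.numeric(bg_counts[vocab]); cb[is.na(cb)] <- 0
  p <- (cp + smoothing) / (np + 2 * smoothing)
  q <- (cb + smoothing) / (nb + 2 * smoothing)
  structure(list(token_log_odds = stats::setNames(log(p) - log(q), vocab),
                 absence_log_odds = stats::setNames(log1p(-p) - log1p(-q), vocab),
                 prior_log_odds = prior_log_odds,
                 bias = prior_log_odds + sum(log1p(-p) - log1p(-q)),
                 decision_threshold = decision_threshold),
            class = "topic_classifier")
}

#' Posterior topic log-odds of abstracts
#'
#' Linear-form Bernoulli naive Bayes score: `bias` plus, for each present
#' vocabulary token, `token_log_odds - absence_log_odds`.
#'
#' @param clf A [train_topic_classifier()] model.
#' @param abstracts List of abstract records.
#' @return Numeric vector (named by abstract id when available).
#' @export
posterior_log_odds <- function(clf, abstracts) {
  stopifnot(inherits(clf, "topic_classifier"))
  w_eff <- clf$token_log_odds - clf$absence_log_odds
  lo <- vapply(abstracts, function(a) {
    toks <- intersect(unique(a$tokens), names(w_eff))
    clf$bias + sum(w_eff[toks])
  }, numeric(1))
  ids <- vapply(abstracts, function(a) if (is.null(a$id)) NA_character_ else a$id,
                character(1))
  if (!anyNA(ids)) names(lo) <- ids
  lo
}

#' Classify every abstract of a corpus as relevant or irrelevant
#'
#' An abstract is relevant iff its posterior topic probability is at least
#' the classifier's decision threshold.
#'
#' @param clf A `topic_classifier`.
#' @param corpus A `lit_corpus`.
#' @return Named character vector over abstract ids with values
#'   `"relevant"` / `"irrelevant"`.
#' @export
classify_abstracts <- function(clf, corpus) {
  stopifnot(inherits(corpus, "lit_corpus"))
  post <- stats::plogis(posterior_log_odds(clf, corpus$abstracts))
  ifelse(post >= clf$decision_threshold, "relevant", "irrelevant")
}

# One-sided (enrichment) Fisher exact p for table (a, b; c, d):
# P(X >= a) with X hypergeometric over the fixed margins.
fisher_p_greater <- function(a, b, c, d) {
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Score one gene for enrichment among relevant abstracts
#'
#' Builds the 2x2 table over the full classified universe — a: linked to the
#' gene and relevant; b: linked and irrelevant; c: not linked and relevant;
#' d: not linked and irrelevant — and computes the one-sided (enrichment)
#' Fisher exact p-value.
#'
#' @param gene_id Gene id present in the corpus gene index.
#' @param classifications Named relevance vector from [classify_abstracts()].
#' @param corpus The classified `lit_corpus`.
#' @return An object of class `gene_score`: list with `gene_id`, counts
#'   `a`, `b`, `c`, `d`, and `p_value` (`q_value` is filled by
#'   [rank_and_select()]).
#' @export
score_gene <- function(gene_id, classifications, corpus) {
  stopifnot(inherits(corpus, "lit_corpus"))
  linked <- corpus$gene_index[[gene_id]]
  if (is.null(linked) || !length(linked)) {
    stop_bad_arg("gene ", gene_id, " has no linked abstracts")
  }
  rel <- classifications == "relevant"
  is_linked <- names(classifications) %in% linked
  a <- sum(is_linked & rel)
  b <- sum(is_linked & !rel)
  c_ <- sum(!is_linked & rel)
  d <- sum(!is_linked & !rel)
  structure(list(gene_id = gene_id, a = a, b = b, c = c_, d = d,
                 p_value = fisher_p_greater(a, b, c_, d),
                 q_value = NA_real_),
            class = "gene_score")
}

#' Score every linked gene of a corpus
#'
#' @inheritParams score_gene
#' @return data.frame with one row per gene: gene_id, a, b, c, d, p_value.
#' @export
score_genes <- function(classifications, corpus) {
  genes <- names(corpus$gene_index)
  rel <- classifications == "relevant"
  n_rel <- sum(rel); n_tot <- length(rel)
  rel_ids <- names(classifications)[rel]
  a <- vapply(corpus$gene_index, function(ids) sum(ids %in% rel_ids), integer(1))
  nl <- lengths(corpus$gene_index)
  b <- nl - a
  c_ <- n_rel - a
  d <- (n_tot - n_rel) - b
  data.frame(gene_id = genes, a = a, b = b, c = c_, d = d,
             p_value = fisher_p_greater(a, b, c_, d),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank scored genes by FDR and select at a p-value cutoff
#'
#' Computes Benjamini-Hochberg q-values over all scored genes, keeps genes
#' with `p_value < p_cutoff`, and orders them by ascending q-value, breaking
#' ties by ascending p-value and then lexical gene id.
#'
#' @param scores data.frame from [score_genes()] (or a list of
#'   `gene_score` objects).
#' @param p_cutoff Retention cutoff on the raw p-value (default 0.01).
#' @param drug_id Label recorded on the resulting feature set.
#' @return A [feature_set()] with `method = "text-mining"`; the score table
#'   with q-values is attached as attribute `"scores"`.
#' @export
rank_and_select <- function(scores, p_cutoff = 0.01, drug_id = "drug") {
  if (inherits(scores, "gene_score")) scores <- list(scores)
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(s) {
      data.frame(gene_id = s$gene_id, a = s$a, b = s$b, c = s$c, d = s$d,
                 p_value = s$p_value, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(scores) || !nrow(scores)) {
    return(feature_set(drug_id, "text-mining", character()))
  }
  scores$q_value <- stats::p.adjust(scores$p_value, method = "BH")
  keep <- scores[scores$p_value < p_cutoff, , drop = FALSE]
  ord <- order(keep$q_value, keep$p_value, keep$gene_id)
  fs <- feature_set(drug_id, "text-mining", keep$gene_id[ord])
  attr(fs, "scores") <- scores[order(scores$q_value, scores$p_value, scores$gene_id), ]
  fs
}

#' Mine a drug's gene feature set from a literature corpus
#'
#' End-to-end literature scoring: sample a balanced training set from the
#' labeled abstracts (`n_train` topic and `n_train` background), train the
#' naive Bayes topic classifier, classify the whole corpus, score every
#' linked gene with the one-sided Fisher test, and return the FDR-ranked
#' gene list at the p-value cutoff.
#'
#' @param corpus A labeled `lit_corpus`.
#' @param drug_id Label for the resulting feature set.
#' @param n_train Training abstracts per class (the classifier is trained on
#'   `2 * n_train` abstracts).
#' @param p_cutoff Raw p-value retention cutoff.
#' @param smoothing,decision_threshold Passed to
#'   [train_topic_classifier()].
#' @param seed Seed for the training-set draw.
#' @return A [feature_set()]; attributes `"scores"` (full score table) and
#'   `"classifier"` are attached.
#' @export
mine_features <- function(corpus, drug_id = "drug", n_train = 1000,
                          p_cutoff = 0.01, smoothing = 1,
                          decision_threshold = 0.5, seed = 1L) {
  stopifnot(inherits(corpus, "lit_corpus"))
  labs <- vapply(corpus$abstracts, `[[`, character(1), "label")
  pos_idx <- which(labs == "topic")
  bg_idx <- which(labs == "background")
  if (length(pos_idx) < n_train || length(bg_idx) < n_train) {
    stop_bad_arg("corpus has fewer than n_train labeled abstracts per class")
  }
  with_seed(seed, {
    tr_pos <- sample(pos_idx, n_train)
    tr_bg <- sample(bg_idx, n_train)
    clf <- train_topic_classifier(corpus$abstracts[tr_pos],
                                  corpus$abstracts[tr_bg],
                                  smoothing = smoothing,
                                  decision_threshold = decision_threshold)
    cls <- classify_abstracts(clf, corpus)
    scores <- score_genes(cls, corpus)
    fs <- rank_and_select(scores, p_cutoff = p_cutoff, drug_id = drug_id)
    attr(fs, "classifier") <- clf
    attr(fs, "training_idx") <- sort(c(tr_pos, tr_bg))
    fs
  })
}

#' Write a mined score table as TSV
#'
#' Columns: gene, a, b, c, d, p, q.
#'
#' @param fs A [rank_and_select()] / [mine_features()] result carrying a
#'   `"scores"` attribute.
#' @param path Output path.
#' @export
write_score_table <- function(fs, path) {
  sc <- attr(fs, "scores")
  if (is.null(sc)) stop_bad_arg("feature set carries no score table")
  out <- data.frame(gene = sc$gene_id, a = sc$a, b = sc$b, c = sc$c, d = sc$d,
                    p = sc$p_value, q = sc$q_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
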