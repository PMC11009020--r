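#' Specification for a synthetic literature corpus
#'
#' Describes a corpus of drug-topic and background abstracts in which a
#' planted subset of genes is preferentially linked to topic abstracts.
#' The corpus emulates the substrate of literature-based gene-drug scoring:
#' each abstract carries a bag of word tokens drawn from class-conditional
#' Bernoulli presence rates, and a short list of linked genes. Abstracts
#' linked to at least one planted gene have their odds of carrying the topic
#' label multiplied by `link_enrichment`.
#'
#' The vocabulary is split into a topic-informative stratum (the first
#' `ceiling(informative_frac * vocab_size)` tokens, present at
#' `topic_token_rate` in topic abstracts and `background_token_rate`
#' otherwise) and a neutral stratum present at `background_token_rate` in
#' both classes. Each abstract links to `Pois(link_lambda)` genes truncated
#' to `[1, 10]`, drawn uniformly from the gene universe.
#'
#' @param n_genes Number of genes in the universe (ids `g1..g<n>`).
#' @param planted_genes Character vector of planted gene ids; must lie in
#'   the universe.
#' @param n_abstracts_topic,n_abstracts_background Expected numbers of
#'   topic and background abstracts; their ratio fixes the base topic odds
#'   for abstracts not linked to planted genes.
#' @param vocab_size Vocabulary size (tokens `w1..w<V>`).
#' @param topic_token_rate,background_token_rate Per-token Bernoulli
#'   presence rates; the topic rate must exceed the background rate.
#' @param link_enrichment Odds multiplier (>= 1) applied to the topic label
#'   for abstracts linked to a planted gene.
#' @param link_lambda Mean of the (truncated) Poisson number of gene links
#'   per abstract.
#' @param informative_frac Fraction of the vocabulary that is
#'   topic-informative.
#' @param seed Integer seed; the corpus is fully determined by it.
#' @return An object of class `corpus_spec`.
#' @seealso [generate_corpus()]
#' @export
corpus_spec <- function(n_genes = 1000,
                        planted_genes = paste0("g", 1:50),
                        n_abstracts_topic = 1250,
                        n_abstracts_background = 3750,
                        vocab_size = 2000,
                        topic_token_rate = 0.10,
                        background_token_rate = 0.02,
                        link_enrichment = 8,
                        link_lambda = 7,
                        informative_frac = 0.1,
                        seed = 1L) {
  universe <- paste0("g", seq_len(n_genes))
  if (!all(planted_genes %in% universe)) {
    stop_bad_arg("planted_genes must be a subset of the gene universe g1..g", n_genes)
  }
  if (!(topic_token_rate > 0 && topic_token_rate < 1 &&
        background_token_rate > 0 && background_token_rate < 1)) {
    stop_bad_arg("token rates must lie strictly in (0, 1)")
  }
  if (topic_token_rate <= background_token_rate) {
    stop_bad_arg("topic_token_rate must exceed background_token_rate")
  }
  if (link_enrichment < 1) stop_bad_arg("link_enrichment must be >= 1")
  if (n_abstracts_topic < 1 || n_abstracts_background < 1) {
    stop_bad_arg("abstract counts must be positive")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    planted_genes = planted_genes,
    n_abstracts_topic = as.integer(n_abstracts_topic),
    n_abstracts_background = as.integer(n_abstracts_background),
    vocab_size = as.integer(vocab_size),
    topic_token_rate = topic_token_rate,
    background_token_rate = background_token_rate,
    link_enrichment = link_enrichment,
    link_lambda = link_lambda,
    informative_frac = informative_frac,
    seed = as.integer(seed)
  ), class = "corpus_spec")
}

# Truncated-Poisson gene-link counts, one draw per abstract.
rtrunc_pois <- function(n, lambda, lo = 1L, hi = 10L) {
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    k <- stats::rpois(length(todo), lambda)
    ok <- k >= lo & k <= hi
    out[todo[ok]] <- k[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic literature corpus
#'
#' Draws a labeled corpus from a [corpus_spec()]: gene links first, then the
#' topic/background label (base odds `n_abstracts_topic /
#' n_abstracts_background`, multiplied by `link_enrichment` for abstracts
#' linked to a planted gene), then class-conditional tokens. The output is
#' bit-identical for a fixed spec.
#'
#' @param spec A [corpus_spec()].
#' @return An object of class `lit_corpus`: a list with `abstracts` (each a
#'   list with `id`, `tokens`, `gene_ids`, `label`), `gene_index` (gene id ->
#'   abstract ids), and the generating `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    n <- spec$n_abstracts_topic + spec$n_abstracts_background
    universe <- paste0("g", seq_len(spec$n_genes))
    vocab <- paste0("w", seq_len(spec$vocab_size))
    n_inf <- as.integer(ceiling(spec$informative_frac * spec$vocab_size))
    inf_tokens <- vocab[seq_len(n_inf)]
    neutral_tokens <- vocab[-seq_len(n_inf)]

    n_links <- rtrunc_pois(n, spec$link_lambda)
    gene_ids <- lapply(n_links, function(k) sort(sample(universe, k)))
    planted_linked <- vapply(gene_ids, function(g) any(g %in% spec$planted_genes), logical(1))

    base_odds <- spec$n_abstracts_topic / spec$n_abstracts_background
    odds <- base_odds * ifelse(planted_linked, spec$link_enrichment, 1)
    is_topic <- stats::runif(n) < odds / (1 + odds)

    rate_inf <- ifelse(is_topic, spec$topic_token_rate, spec$background_token_rate)
    k_inf <- stats::rbinom(n, n_inf, rate_inf)
    k_neu <- stats::rbinom(n, length(neutral_tokens), spec$background_token_rate)

    abstracts <- vector("list", n)
    ids <- sprintf("a%05d", seq_len(n))
    for (i in seq_len(n)) {
      toks <- c(
        if (k_inf[i] > 0) sample(inf_tokens, k_inf[i]) else character(),
        if (k_neu[i] > 0) sample(neutral_tokens, k_neu[i]) else character()
      )
      if (!length(toks)) toks <- sample(neutral_tokens, 1L)  # tokens must be nonempty
      abstracts[[i]] <- list(
        id = ids[i],
        tokens = sort(toks),
        gene_ids = gene_ids[[i]],
        label = if (is_topic[i]) "topic" else "background"
      )
    }
    new_corpus(abstracts, spec = spec)
  })
}

new_corpus <- function(abstracts, spec = NULL) {
  ids <- vapply(abstracts, `[[`, character(1), "id")
  pairs_gene <- unlist(lapply(abstracts, `[[`, "gene_ids"), use.names = FALSE)
  pairs_id <- rep(ids, times = vapply(abstracts, function(a) length(a$gene_ids), integer(1)))
  gene_index <- split(pairs_id, pairs_gene)
  structure(list(abstracts = abstracts, gene_index = gene_index, spec = spec),
            class = "lit_corpus")
}

#' @export
print.lit_corpus <- function(x, ...) {
  labs <- vapply(x$abstracts, `[[`, character(1), "label")
  cat("Literature corpus:", length(x$abstracts), "abstracts (",
      sum(labs == "topic"), "topic /", sum(labs == "background"), "background ),",
      length(x$gene_index), "linked genes\n")
  invisible(x)
}

#' Write / read a corpus as JSON lines
#'
#' One abstract per line with fields `id`, `tokens`, `gene_ids`, `label`.
#'
#' @param corpus A `lit_corpus`.
#' @param path Output (or input) file path.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns a `lit_corpus`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "lit_corpus"))
  lines <- vapply(corpus$abstracts, function(a) {
    jsonlite::toJSON(list(id = a$id, tokens = a$tokens,
                          gene_ids = a$gene_ids, label = a$label),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path)
  abstracts <- lapply(lines, function(l) {
    a <- jsonlite::fromJSON(l)
    list(id = a$id, tokens = as.character(a$tokens),
         gene_ids = as.character(a$gene_ids), label = a$label)
  })
  new_corpus(abstracts)
}
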