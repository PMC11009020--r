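# litsel

Literature-mined feature selection for anticancer drug response prediction.

## The problem

Predicting a tumor's drug sensitivity from baseline gene expression is a
core task in pharmacogenomics. Expression profiles carry ~20,000 genes but
cohorts rarely exceed a few hundred samples, so feature selection decides
whether a model learns biology or noise — and whether it transfers from the
cell-line panel it was trained on to an independent dataset or an in-vivo
model. `litsel` implements, and makes testable end to end, a
literature-based alternative to purely data-driven selection: genes that
the scientific literature statistically associates with a drug are used as
the model's input features, benchmarked against eight classical selection
strategies.

The package is aimed at computational pharmacogenomics researchers who
want a transparent, fully seeded reimplementation of this pipeline that
runs on synthetic data with known ground truth, so every stage can be
validated before being pointed at real cell-line / xenograft cohorts.

## What it implements

**Literature scorer** (Génie-style). Given a corpus of abstracts with gene
links, a Bernoulli naive Bayes topic classifier is trained on token
presence with Laplace smoothing *s*; with per-class presence rates
*p_t* (topic) and *q_t* (background), a document's posterior log-odds is

    bias + Σ_{t present} [ log(p_t/q_t) − log((1−p_t)/(1−q_t)) ]

a linear function of token-presence indicators. Each gene *g* is then
tested for enrichment of relevant abstracts with a one-sided Fisher exact
test on the 2×2 table (linked × relevant) over the classified universe,
and genes with *p* < .01 are returned ranked by Benjamini–Hochberg false
discovery rate.

**Nine feature-selection strategies**: text-mining, top-100/500 by
variance, top-500 by |Pearson r| with response, the L1000 landmark list,
L1000 minus text-mining genes, MRMR (MID scheme), a genetic algorithm, and
recursive feature elimination with a ridge base model.

**Benchmark**: elastic net, random forest and a small MLP (SGD with
momentum 0.9, learning rate 0.01, dropout 0.2, ReLU hidden layers, sigmoid
output, MSE loss, 15 epochs, 6 restarts) evaluated by 4-fold
cross-validation repeated 20 times within domain, and by training-domain-only
fitting applied once to an independent shifted domain (cross-domain).
Metrics: Pearson, Spearman, Kendall tau-b, RMSE, MSE, MAE; selectors are
compared by paired t-tests over drugs.

**Validation**: per-drug univariate |r| contrast between text-mining and
remaining genes (Welch t-test), and xenograft-style survival validation —
train a random forest on text-mining features, predict a cohort's
response, dichotomize at the median, compare groups by Kaplan–Meier
curves and the log-rank test.

**Synthetic generators**: a literature corpus with a planted gene subset
whose linkage multiplies an abstract's topic odds (so the planted signal
is recoverable by the scorer), and paired pharmacogenomic domains sharing
a sparse linear expression→AAC signal (AAC = area above the dose-response
curve, in [0,1]) under additive per-gene domain shift, plus a survival
cohort whose hazard decreases with true drug sensitivity. All generators
are bit-reproducible given a seed.

## Worked example

```r
library(litsel)

# 1. Mine a drug's gene features from a synthetic literature corpus
corpus <- generate_corpus(corpus_spec(seed = 42))
#> Literature corpus: 5000 abstracts ( 1917 topic / 3083 background ), 1000 linked genes
tm <- mine_features(corpus, drug_id = "drugA", seed = 7)
#> <feature_set> drugA / text-mining: 49 genes
head(attr(tm, "scores")[, c("gene_id", "a", "b", "p_value", "q_value")], 3)
#>     gene_id  a b      p_value      q_value
#> 335      g4 32 4 3.808915e-10 3.808915e-07
#> 313     g38 29 4 4.860421e-09 2.033461e-06
#> 102     g19 32 6 7.145781e-09 2.033461e-06
```

Of the 50 genes planted in the corpus, 49 mined genes recover the set at
~0.94 precision: the score table shows, per gene, its linked-relevant (`a`)
and linked-irrelevant (`b`) abstract counts and the Fisher/BH statistics.

```r
# 2. Paired pharmacogenomic domains with known sparse signal
pair <- generate_pharmaco_pair(pharmaco_spec(n_drugs = 20, seed = 2024))
drug <- dataset_drugs(pair$train)[1]

# 3. Cross-domain benchmark: mined features vs variance features
en <- model_spec("elastic_net", grid = list(alpha = c(0.25, 0.75)), seed = 3)
rbind(
  run_cross_domain(pair$train, pair$test,
                   selector_config("text-mining", genes = tm$genes), en,
                   drugs = drug),
  run_cross_domain(pair$train, pair$test, selector_config("var_100"), en,
                   drugs = drug)
)[, c("drug", "selector", "split_kind", "pearson", "spearman", "rmse")]
#>     drug    selector split_kind   pearson  spearman      rmse
#> 1 drug01 text-mining      cross 0.9173279 0.9880279 0.1275781
#> 2 drug01     var_100      cross        NA        NA 0.3688928
```

Models fitted on mined features transfer to the shifted test domain
(r = 0.92); on the top-100-variance features the elastic net finds nothing
to fit — its predictions are flat, and the correlation is reported as a
flagged `NA` rather than a spurious number (the error metrics still show
the threefold larger RMSE).

```r
# 4. Survival validation on a synthetic xenograft cohort
cohort <- generate_pdx_cohort(pair, drug, n_subjects = 24, seed = 19)
val <- pdx_style_validation(pair$train, drug, tm$genes,
                            cohort$expression, cohort$survival,
                            ntree = 200, seed = 5)
c(chi_square = round(val$chi_square, 2), p = signif(val$p_value, 3))
#> chi_square          p
#>     7.5200     0.0061
```

Median-dichotomized predicted responders and non-responders of the
24-subject cohort differ in survival (log-rank p = 0.006), as they should:
the cohort's hazard was generated to decrease with true sensitivity.

## Package layout

- `R/corpus-sim.R`, `R/pharmaco-sim.R` — seeded synthetic-data generators
- `R/litminer.R` — topic classifier, Fisher enrichment, FDR ranking
- `R/pharmodata.R` — dataset container, TSV I/O, filtering, scaling
- `R/featsel.R` — the nine selectors
- `R/models.R`, `R/bench.R` — regressors, repeated CV, cross-domain runs,
  metrics, paired comparisons
- `R/validate.R` — univariate analysis, Kaplan–Meier, log-rank, xenograft
  validation
- `vignettes/text-mining-features.Rmd` — methods and design notes
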