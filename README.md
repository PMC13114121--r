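# priorvae

Predicting immunotherapy response from gene-level gut-microbiome
abundance with a prior-conditioned variational autoencoder.

## What problem this solves, and for whom

Response to immune-checkpoint inhibition (ICI) in cancer patients
correlates with gut-microbiome composition. Instead of taxonomic
relative-abundance profiles, this package works with *gene-level*
microbial abundance: each feature is an assembled contig, valued by its
RPKM (reads per kilobase per million mapped reads) in each sample. These
tables are wide, sparse, non-negative and heavy-tailed, and models built
on them must generalize across study cohorts. `priorvae` is aimed at
computational microbiome researchers who have such tables (plus,
optionally, protein-embedding summaries of the same assembly) and want a
classifier that is screened, cross-validated, transferable and
interpretable.

## The model

For a z-scored profile $x \in \mathbb{R}^M$ and a fixed protein-embedding
prior $R \in \mathbb{R}^{P\times 320}$:

- encoder $M \to 512 \to d$ ($d = 256$) gives the latent mean $\mu$;
  reparameterization $z = \mu + \epsilon$, $\epsilon \sim N(0, I)$;
- multi-head attention (4 heads) with query $\mu$ and the projected prior
  $R' \in \mathbb{R}^{P \times d}$ as keys and values yields a
  biology-aware embedding $a$ (layer-normalized); $R$ itself is never
  updated;
- fusion $\tilde z = \lambda z + (1 - \lambda)a$, $\lambda = 0.7$, feeds a
  decoder $d \to 512 \to M$ ending in a sigmoid;
- a classifier head $d \to 128 \to 64 \to 1$ predicts the response
  probability from $\mu$;
- loss $L = \lambda_\mathrm{rec} L_\mathrm{rec} + \lambda_\mathrm{KL}
  L_\mathrm{KL} + L_\mathrm{cls}$ with $\lambda_\mathrm{rec} = 0.1$,
  $\lambda_\mathrm{KL} = 0.2$, trained with Adam (lr $10^{-3}$), batch 8,
  seed 42.

Around the model the package provides mutual-information feature
screening, stratified five-fold evaluation (accuracy / AUC / AUPR,
bootstrap confidence intervals, a paired bootstrap AUC test), an
L1-logistic baseline, train-on-one/test-on-others cross-cohort
evaluation, integrated-gradients attribution with GTDB-style labels and
genus/family aggregation, reference-set construction rules (500 bp length
filter, top-k contigs per bin) with the RPKM formula, and a synthetic
cohort generator so everything is testable without external data. The
network — including backpropagation through attention and the
normalization layers — is implemented in the package as explicit matrix
algebra and verified against finite differences in the test suite.

## Worked example

```r
library(priorvae)

spec   <- synthetic_spec(n = 120, m = 120, k_inf = 12, delta = 2, pi0 = 0.6,
                         p_prior = 16, e_dim = 32, seed = 42)
cohort <- generate_cohort(spec)   # abundance + labels + annotations
prior  <- generate_prior(spec)    # fixed P x E embedding stand-in

cfg <- pvae_config(latent_dim = 64, hidden_dim = 96, prior_dim = 32,
                   n_heads = 4, classifier_dims = c(32, 16))
cv  <- run_cv(cohort$abundance, cohort$labels, prior, config = cfg,
              settings = pvae_train_settings(epochs = 30, seed = 42))
cv
#> <pvae_cv> 5 folds | accuracy 0.717 +/- 0.090 | AUC 0.804 +/- 0.052 | AUPR 0.822 +/- 0.047

bootstrap_ci(cv$predictions, "auc", n_rep = 1000, seed = 42)
#> # A tibble: 1 × 6
#>   metric estimate   low  high n_rep n_skipped
#>   <chr>     <dbl> <dbl> <dbl> <dbl>     <int>
#> 1 auc       0.804 0.719 0.872  1000         0

at  <- attribute_cv(cv, cohort$abundance, steps = 50)
top <- top_k_by_attribution(at, "responder", k = 5)
top$label <- format_feature_label(top$feature_id, cohort$annotations)
top
#> # A tibble: 5 × 3
#>   feature_id  mean_ig label
#>   <chr>         <dbl> <chr>
#> 1 contig_0010  0.0429 Family01-0.93 > Genus02-0.72
#> 2 contig_0009  0.0338 Family01-0.73 > Genus01-0.72
#> 3 contig_0007  0.0301 Family01-0.73 > Genus01-0.73
#> 4 contig_0059  0.0298 Family03-0.76 > Genus05-0.72
#> 5 contig_0002  0.0281 Family01-0.78 > Genus02-0.78
```

Reading the output: the cross-validated AUC of 0.80 (95% bootstrap CI
0.72–0.87) says the model separates responders from non-responders well
above chance on this small simulated cohort; the attribution table ranks
contigs by their mean integrated-gradients score among correctly
predicted responders — here 4 of the top 5 are genuinely planted signal
features, and the labels show the synthetic family/genus annotation with
its confidence, `"null"` standing for unclassified.

`tidy(cv)` gives per-fold metrics, `glance(cv)` the means and SDs,
`autoplot(cv)` the ROC curves, `autoplot(at, annotations)` the
attribution bars. A thin command-line front end over the same functions
lives at `inst/cli/priorvae.R` (subcommands `simulate`, `refset`, `rpkm`,
`select-features`, `train`, `evaluate`, `cross-evaluate`, `attribute`,
`aggregate`).

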