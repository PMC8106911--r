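# phagelife

Classify bacteriophage genomes as **temperate** or **virulent** from
nucleotide sequence alone.

Temperate phages can enter a latent (lysogenic) phase inside their host;
virulent phages replicate and lyse the host immediately. Knowing which is
which matters for phage ecology, host evolution studies and phage therapy,
but experimental determination does not scale to the tens of thousands of
sequenced phage genomes. `phagelife` implements a domain-presence
classifier for this task, aimed at microbial genomicists who have assembled
(complete) phage genomes in FASTA and want fast, probabilistic lifestyle
calls — plus the full model-development machinery for anyone who wants to
retrain or interrogate the classifier.

## The method

For an input genome the pipeline computes:

1. **Six-frame translation.** Every maximal stop-free run of ≥ 40 amino
   acids, in all three reading frames of both strands (stop-to-stop
   products, not ORFs).
2. **Domain detection.** The products are searched for a fixed ordered set
   of lysogeny-associated conserved protein domains (integrases,
   excisionases, recombinases, transposases, lysogeny-control and
   partitioning proteins), via HMMER 3 profile HMMs or a built-in motif
   backend. A domain *d_j* is *present* if any product has a full-sequence
   E-value ≤ 10⁻⁵ against its profile.
3. **Presence vector.** The genome becomes x ∈ {0,1}^p with
   x_j = 1 iff domain j was detected.
4. **Random forest.** A probability forest f(x) returns
   P(temperate | x); the call is temperate iff P > 0.5 (the prior is that
   a complete genome is virulent until domain evidence overrides it) and
   flagged *confident* when max(P, 1−P) ≥ 0.95.

Model development follows a fixed protocol: 60:40 train/test split;
hyperparameter grid (bootstrap × class weighting × leaf size × trees ×
depth) evaluated on 20 random train/validation resplits of the training
partition; selection by **highest minimum validation accuracy**; refit of
the winner on the full training partition. Evaluation reports the
confusion matrix, accuracy, adjusted balanced accuracy
((mean recall − 0.5)/0.5), Matthews correlation coefficient and F1
(temperate as positive class), plus confidence-stratified error rates.
A k-mer containment estimator builds phylogenetically independent test
subsets (no training relative with > 80 % identity over > 80 % of the
genome).

## Worked example

The package ships a synthetic fixture generator so the whole pipeline runs
offline (see `vignettes/phage-lifestyle-classification.Rmd` for what the
fixtures do and do not emulate):

```r
library(phagelife)

fx       <- generate_fixture(seed = 1)          # 30 temperate + 30 virulent toy genomes
products <- translate_six_frames(fx$genomes)    # 3,961 products >= 40 aa
hits     <- search_products(products, fx$domain_set, motif_backend(fx$motif_table))
presence <- build_presence_matrix(fx$genomes$genome_id, hits, fx$domain_set)
dataset  <- assemble_dataset(presence, fx$labels)

parts <- train_test_split(dataset, train_fraction = 0.6, seed = 1)
model <- finalize_model(parts$train, lifestyle_hyperparameters(), seed = 1)
model
#> <lifestyle_model> 10 domains, trained on 36 genomes (20 virulent, 16 temperate)
#>   trees=80 depth<=40 min_leaf=1 bootstrap=FALSE class_weight=balanced_subsample seed=1
#>   fingerprint eebb324ffdaa88f4ba2178e200173231

preds <- predict(model, parts$test)
head(preds, 4)
#> # A tibble: 4 × 5
#>   genome_id    p_virulent p_temperate call      confident
#>   <chr>             <dbl>       <dbl> <chr>     <lgl>
#> 1 temperate_02     0.0815       0.918 temperate FALSE
#> 2 temperate_05     0.121        0.879 temperate FALSE
#> 3 temperate_08     0.142        0.858 temperate FALSE
#> 4 temperate_11     0.135        0.865 temperate FALSE

cm <- confusion_matrix(parts$test$lifestyle, preds$call)
classification_metrics(cm)
#> # A tibble: 1 × 5
#>   accuracy balanced_accuracy   mcc    f1     n
#>      <dbl>             <dbl> <dbl> <dbl> <int>
#> 1        1                 1     1     1    24
```

Every held-out genome is recovered (the fixtures are noise-free by
default; `p_temperate` stays below 0.95 here because 36 training genomes
only support so much certainty). `tidy(model)` ranks domains by
importance with cumulative shares, `glance(model)` summarizes the fit,
and `autoplot(model)` / `autoplot(cm)` / `plot_confidence(preds)` draw
the standard figures.

For shell use, `inst/scripts/phagelife` wraps prediction and evaluation:

```sh
Rscript inst/scripts/phagelife predict --input genomes.fasta \
    --model model.rds --hmm-db domains.hmm
```

which writes `genomes.fasta.predictions.tsv` with per-genome
probabilities, calls and confidence flags.

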