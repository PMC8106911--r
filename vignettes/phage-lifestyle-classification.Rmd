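---
title: "Phage lifestyle classification from lysogeny-associated domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phage lifestyle classification from lysogeny-associated domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagelife)
```

## The model

`phagelife` treats lifestyle prediction as binary classification on a
presence/absence representation of a genome's protein-domain content. The
biological premise is asymmetric: lysogeny requires machinery — integrases,
excisionases, recombinases, transposases, repressors, partitioning
proteins — that a strictly lytic phage has no use for. A complete genome
with none of these domains is therefore presumed virulent; detected
domains, in patterns a random forest has learned from labeled genomes,
override that presumption. The probability the forest reports is a vote
share across trees, not a calibrated posterior, which is why downstream
use of the ≥ 0.95 "confident" stratum is recommended rather than treating
0.6 and 0.99 alike.

Three assumptions matter in practice:

* **Completeness.** Absence of a domain is only evidence of lifestyle if
  the genome is complete; on fragments, absence may just mean the domain
  is on a missing segment. `run_predict()` warns about this on every run.
  (Temperate calls on fragments remain informative; virulent calls do
  not.)
* **Annotated diversity.** The classifier can only see lysogeny machinery
  that resembles the profiles in its domain set; novel or highly diverged
  integrases are invisible and will push errors toward
  temperate-called-virulent.
* **Label quality.** Training labels are taken as ground truth; the
  pipeline has no mechanism to detect mislabeled training genomes.

## Pipeline stages and their parameters

**Six-frame translation** (`translate_six_frames()`) emits every maximal
stop-free codon run of at least `min_len = 40` amino acids, in all six
frames, under the standard genetic code. Products are stop-to-stop runs
rather than ORFs by design: requiring start codons would make recall
depend on gene-calling heuristics, while domain search only needs the
domain's residues to appear in some product. For the internal codons that
make up these runs the standard code coincides with the bacterial/phage
code (table 11); start-codon differences are irrelevant because no start
is modeled. Codons containing any non-ACGT base translate to `X` and never
terminate a product — an ambiguity can therefore mask a true stop, but it
can never fabricate a split, which is the conservative direction for
presence detection. Coordinates are 0-based on the strand of the frame;
the round-trip property (re-translating every product from its reported
coordinates) is tested rather than documented informally.

**Domain search** (`search_products()`) decides presence on the
full-sequence E-value with an inclusive threshold of `1e-5`. No threshold
is inherent to the method, and the original significance cutoff is not
something the package can derive, so a conservative common-practice value
is the default and the knob is exposed (`evalue_threshold`). Presence uses
the full-sequence rather than per-domain conditional E-value because
presence/absence is a whole-product question; hit multiplicity and order
are collapsed by construction (`build_presence_vector()` is idempotent).
Two backends satisfy one contract: `hmmer_backend()` shells out to
`hmmsearch` and parses its per-target tabular output; `motif_backend()`
does exact substring matching against diagnostic motifs and exists so the
entire pipeline, including tests, runs with no external binary. Their
agreement on the synthetic fixtures is itself a test (see below).

**Domain selection** (`keyword_select()`, `prevalence_filter()`) encodes
the curation strategy: six case-insensitive substring terms (integrase,
excisionase, recombinase, transposase, lysogen, temperate) plus a
case-sensitive `parA |ParA |parB |ParB` term whose trailing spaces keep it
from matching words like "separate" or "apparatus". The prevalence filter
then drops domains present in two or fewer training genomes (counting both
classes — the rule is about estimability, not class evidence) and domains
more prevalent among virulent than temperate training genomes. Prevalence
is compared as class-conditional *fractions*, not raw counts, because the
classes are unbalanced and only fractions make "more prevalent in the
virulent genomes" scale-free; ties retain the domain (a domain equally
common in both classes is merely useless, and the forest will discard it).
The two rules commute, which is asserted as a property test against a
brute-force oracle.

**Classification** (`fit_lifestyle_model()`, `predict()`) uses a
probability random forest (ranger) with the final published
configuration as defaults: 80 trees, depth ≤ 40, minimum leaf size 1, no
bootstrap, balanced class weighting. Two mappings deserve a note. First,
with bootstrap disabled every tree sees the full training sample, so
"balanced_subsample" weighting (per-tree subsample frequencies) reduces
exactly to "balanced" weighting (full-sample frequencies); both enum
values are accepted and both are implemented as class weights inversely
proportional to class frequency. Second, forests are trained
single-threaded with an explicit seed, so fitting is bit-reproducible;
the seed, hyperparameters, ordered domain set and a hash of the training
matrix travel inside the model artifact, and prediction refuses any input
whose feature columns do not match the stored contract. The decision rule
is `temperate iff P(temperate) > 0.5`: an exact tie goes to virulent,
consistent with the virulent-until-evidence prior. The confidence flag is
inclusive (`max(P, 1−P) ≥ 0.95`).

**Model development** (`train_test_split()`, `evaluate_grid()`,
`select_best()`, `finalize_model()`) reproduces the training protocol.
The 60:40 split is uniform random, not class-stratified (the protocol
says randomly split; stratification is available only by splitting
upstream), and the two partitions carry `"train"`/`"test"` tags:
every model-development entry point refuses the test partition outright,
so test-set leakage is a raised error, not a convention. The grid spans
bootstrap {on, off} × class weight {balanced, balanced_subsample} ×
minimum leaf {1, 2} × trees {10, 15, …, 100} × depth {10, 12, …, 40} —
2,432 combinations, enumerated with depth varying fastest. Each
combination is scored on the same 20 train/validation resplits of the
training partition (seeds derived from the protocol seed, so combinations
face identical validation sets, as a fixed cross-validation splitter
would arrange). The inner resplit ratio is not dictated by the protocol;
75:25 is the default and it is configurable. Selection is by highest
minimum validation accuracy — the operative published rule — with ties
broken by mean accuracy and then enumeration order; per-resplit F1 values
are recorded alongside for inspection, since grid scoring by F1 and
selection by min-accuracy coexist in the protocol's description and the
selection sentence is the one that defines the chosen model.

**Metrics** (`classification_metrics()`, `confidence_strata()`) are
authored in the package rather than delegated, because the reported
tables hinge on conventions: temperate is the F1 positive class (the only
convention that reproduces the published F1 values from their confusion
matrices), balanced accuracy is *adjusted* ((mean recall − 0.5)/0.5, so
random guessing scores 0), and MCC is defined as 0 whenever a marginal is
zero. A brute-force per-sample oracle recomputation over randomized
instances guards the implementation. One published value is knowingly
not reproduced: the domain-rule comparator's printed F1 (0.939) does not
follow from its own confusion matrix under either positive-class
convention (that matrix yields 0.959 with temperate positive); the
package reports what the matrix implies and leaves the discrepancy
documented here.

**Independence screening** (`estimate_similarity()`, `related()`,
`independent_test_subset()`) re-implements the >80 % identity over >80 %
of the genome criterion with a k-mer containment estimator (k = 16):
coverage is the contained fraction of the smaller genome's distinct
k-mer set, identity the standard transform `containment^(1/k)`. This is
deliberately *not* an alignment-tool reimplementation — the criterion is
the contract, the estimator is pluggable, and a `similarities=` table of
externally computed ANI values can be substituted. Both threshold
comparisons are strict; relatedness is single-linkage (one close training
relative excludes a test genome). Two properties are worth knowing: for
point-mutated pairs the containment coverage falls faster than aligned
coverage would (at 2 % divergence only ~72 % of 16-mers survive), so the
estimator is more stringent than alignment-based screening near the
threshold — acceptable for building a *conservative* independent subset —
and agreement with exact pairwise alignment is tested only away from the
threshold, where both are unambiguous.

## The synthetic data generator

`generate_fixture()` stands in for a labeled phage collection so that
every stage is testable offline. Each synthetic domain is a unique random
45-aa motif reverse-translated into a 135-nt stop-free insert; temperate
genomes receive a fixed number of distinct markers at random
non-overlapping positions, random frame offset, random strand; virulent
genomes receive markers only at `leak_rate` (default 0). Generation
verifies itself: the pipeline (translation + motif search) must recover
exactly the planted presence pattern, otherwise the fixture is
regenerated — so a chance background collision cannot silently corrupt
expectations. Defaults are 30 + 30 genomes of 5,000 nt with 10 domains
and 3 markers per temperate genome: large enough that a 60:40 split
trains a forest with class balance intact, small enough that the full
pipeline runs in seconds. Three markers (not fewer) reflect how the real
feature space behaves — with very few domains a held-out genome can carry
a marker pair no training genome exhibits, and no classifier could be
expected to generalize to it.

What the fixtures deliberately do **not** emulate: realistic phage genome
composition, gene structure, codon usage, domain sequence divergence
(motifs are matched exactly or by near-perfect single-sequence profiles),
overlapping or nested domains, incomplete genomes, or phylogenetic
structure between genomes. Passing the synthetic end-to-end test
demonstrates that the plumbing — translation, search, feature assembly,
training, selection, evaluation — is correct and leak-free; it says
nothing about real-data accuracy, which depends on curated profile
databases and labeled genomes the package consumes but does not ship.
`golden_pipeline_case()` freezes one 10-genome fixture with its
construction-derived expectations as the human-inspectable oracle; it is
also the surface on which the motif and HMMER backends are required to
agree, which works because markers are in-frame and stop-free by
construction.

## Numerical and degenerate-input choices

* Empty or all-ambiguous genomes yield empty product tables, empty hit
  lists, all-zero presence vectors and (under any trained model) a
  virulent call — degenerate inputs flow through, only malformed inputs
  (non-IUPAC characters, unlabeled genomes, non-binary features) raise.
* Probabilities are reported in full precision in R and printed to 4
  decimals in TSV outputs; published-table comparisons are made at the
  tables' own printing precision (3 decimals; percentages at 1 decimal).
* `round(train_fraction * n)` defines the training-set size (so 1,057
  genomes split 634/423 at 60:40).
* Forest fits and fixture generation consume a single explicit seed each;
  derived seeds (resplit r uses `seed + r`) keep repeated draws
  independent but reproducible.
* Problem sizes used by the test-suite and acceptance runs — fixtures of
  10–60 genomes of 1.5–5 kb, grids of 1–2 combinations for fitting (the
  full 2,432-row grid is enumerated, not fitted), 50-instance randomized
  property suites — were chosen so each check isolates one property at
  the smallest scale that exercises it.

## Known limitations

Real profile databases and labeled genome collections are inputs, not
contents: the package implements the method and its development protocol,
and reproduces published evaluation arithmetic from printed confusion
matrices, but cannot re-derive the published real-data accuracies without
the external training corpus. The probability forest is uncalibrated, as
noted above. The k-mer independence estimator is conservative near its
thresholds. And the keyword-driven domain selection inherits the biases
of its description text — domains whose annotations omit the seven terms
are invisible to the whole approach.
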