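# missdriver

Cancer genomes carry thousands of somatic missense mutations, but only a
small fraction — the *drivers* — confer a selective growth advantage; the
rest are neutral *passengers*. Separating the two per cancer type is a core
problem in cancer genomics, and the separation is known to depend not only
on the substituted residue pair but on its sequence neighbourhood,
evolutionary conservation and structural context. `missdriver` is an R
toolkit for building cancer-type-specific driver/passenger classifiers
from protein sequences, predicted structures and amino-acid contact
networks. It is aimed at computational biologists who have mutation tables
(e.g. recurrence-annotated somatic variants), protein sequences and
AlphaFold-style predicted models, and want a reproducible
feature-engineering plus classification pipeline that runs entirely
offline.

## What it computes

**Mutation-preference statistics.** For substitution *i → j* with counts
*n<sub>ijD</sub>* among *N<sub>D</sub>* drivers and *n<sub>ijP</sub>* among
*N<sub>P</sub>* passengers,

```
odds ratio = (n_ijD / N_D) / (n_ijP / N_P)
```

with driver-unique / passenger-unique zero cells reported as flags, motif
preference calls at the inclusive cutoffs ≥ 1.2 (driver) and ≤ 0.8
(passenger), Wilson 95 % confidence intervals for per-type driver
frequencies, and Fisher exact tests for residue-composition differences.

**Per-mutation features.**

- *Sequence*: property changes ΔP = P(mut) − P(wt) over configurable
  AAindex1 property tables; AAindex2 substitution-matrix values; AAindex3
  neighbour contact-potential differences; six-class physicochemical
  composition of the 13-residue window; odds ratios of seven gapped
  di-/tri-peptide motif families; PSSM window mean, mutant−wild-type score
  difference and site score; conservation and disorder track features.
- *Structure* (AlphaFold-style models, pLDDT in the B-factor column):
  per-residue pLDDT, Shrake–Rupley solvent-accessible surface area,
  relative ASA, residue depth below the accessible surface,
  secondary-structure one-hot (from DSSP files), inter-residue contact
  counts, averaged across models when several are available.
- *Network*: weighted amino-acid contact networks at a 7 Å atom–atom
  cutoff; normalised closeness, betweenness, eigenvector centrality and
  weighted degree of the mutated residue.

**Classifier.** Min-max normalisation fitted on training data,
select-K-best univariate feature selection (ANOVA F, mutual information or
chi-squared) with a K sweep, and a feed-forward neural network
(1–5 ReLU hidden layers, He-normal initialisation, single sigmoid output)
trained with mini-batch SGD + momentum, L2 weight decay, binary
cross-entropy and early stopping with best-weight restore. Evaluation uses
stratified 80:20 splits, protein-grouped splits (no protein on both sides
— the leakage guard) and stratified 10-fold cross-validation reporting
sensitivity, specificity, accuracy, balanced accuracy, MCC, ROC-AUC and
PR-AUC.

All readers for the external formats (FASTA, PDB/mmCIF, PSI-BLAST ASCII
PSSM, classic DSSP, AAindex1/2/3 flat files, mutation CSV, track TSV) are
included, as is a deterministic synthetic-fixture generator
(`write_fixture_tree()`) that emits all of these formats with planted
signal, so the whole pipeline is testable without downloads.

## Worked example

```r
library(missdriver)

# deterministic synthetic corpus written in the real file formats
cfg  <- synth_config(n_proteins = 10, n_driver = 400, n_passenger = 200,
                     effect_size = 2, seed = 1)
tree <- file.path(tempdir(), "corpus")
write_fixture_tree(cfg, tree)

seqs <- read_fasta(file.path(tree, "fasta", "proteins.fasta"))
rec  <- label_by_recurrence(read_mutation_table(file.path(tree, "mutations.csv")))
rec$label[rec$label == "unknown"] <- "passenger"

sc <- substitution_counts(rec)
head(odds_ratio_table(sc), 3)
#>   wt mut n_driver n_passenger odds          flag
#> 1  C   A        1           1  0.5            ok
#> 2  D   A        2           0   NA driver_unique
#> 3  E   A        3           0   NA driver_unique

# features -> normalised matrix -> selected K -> MLP -> 10-fold CV
fm <- gen_feature_matrix(n = 2000, p = 40, n_planted = 5, d = 2, seed = 1)
cv <- kfold_cv(fm, mlp_config(seed = 1), k_folds = 10, seed = 1,
               n_features = 10)
round(unlist(cv$mean), 3)
#>       sensitivity       specificity          accuracy balanced_accuracy
#>             0.993             0.974             0.986             0.983
#>               mcc           auc_roc            auc_pr
#>             0.970             0.999             1.000
```

The balanced accuracy of about 0.98 reflects the planted effect size
(d = 2 on 5 of 40 features); the same pipeline on label-shuffled data
stays at chance (≈ 0.50), confirming that no information leaks through
normalisation, selection or training.

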