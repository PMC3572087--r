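---
title: "Predicting S-glutathionylation sites from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting S-glutathionylation sites from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

S-glutathionylation is the reversible formation of a mixed disulfide between
glutathione (GSH) and the thiol of a protein cysteine. It regulates signal
transduction, redox homeostasis and metabolism, and its dysregulation is
implicated in cardiovascular, pulmonary and neurodegenerative disease.
Experimentally mapping which cysteines are modified is slow; `glutapred`
predicts susceptible cysteines *in silico* from sequence alone, treating the
flanking residues of a cysteine as a proxy for its (usually unknown)
structural context.

The unit of prediction is a **window**: the peptide of fixed odd width `w`
centered on a cysteine, with `(w - 1)/2` residues on each side (default
`w = 15`, i.e. seven residues per side — the width that performs best in our
window sweep harness and is standard in the PTM-prediction literature).
Windows that would cross a protein terminus are **discarded, never padded**:
every encoder assumes a full-length window, and imputing flanks would
inject fabricated sequence into the features. The same rule is applied to
positive and negative sites. Windows containing non-standard letters
(B, J, O, U, X, Z) are likewise excluded with a warning rather than guessing
a substitution.

Negative examples are unannotated cysteines from the *same* proteins as the
positives, drawn uniformly without replacement, capped at three negatives
per positive per protein. The cap bounds the class imbalance while keeping
negatives biologically comparable to positives.

## Feature encodings

Eight descriptor schemes turn a window into a fixed-length vector
(`scheme_dimensions(15)`):

| scheme              | D    | description |
|---------------------|------|-------------|
| `single_aa`         | 20   | amino acid frequencies |
| `reduced_comp`      | 10   | 3-class + 7-class reduced-alphabet frequencies |
| `pair_aa`           | 400  | contiguous dipeptide frequencies |
| `triplet_aa`        | 8000 | contiguous tripeptide counts |
| `reduced_triplet_aa`| 4200 | tripeptide counts, reversal-merged |
| `binary_profile`    | 300  | one-hot residue per position (20·w) |
| `biprofile_bayes`   | 30   | per-position class frequencies (2·w) |
| `physchem`          | 10   | summed physicochemical properties |

Composition-style "occurrence frequency of each pair/triplet within the
sample" is read as **contiguous** k-mers, the standard interpretation. The
single, pair and reduced-alphabet encoders are normalized to frequencies;
the two triplet encoders keep raw counts (a window of width 15 holds exactly
13 tripeptides, and preserving that budget makes the count-conservation
invariant testable; after per-feature min-max scaling the choice is
immaterial to the classifiers).

The **reversal merge** treats a tripeptide and its reversal as the same
feature ("ABD" = "DBA"): the local neighborhood is read without a preferred
direction. Canonicalization is by lexicographic minimum of the pair — any
consistent canonical form yields the same model, this one is reproducible.
The class count is derived by enumeration, `(8000 − 400)/2 + 400 = 4200`
(the 400 triplets whose first and last residue coincide are their own
reversal).

The **bi-profile Bayes** encoder first tabulates, separately in positive and
negative training windows, the frequency of each residue at each position
(the 20 × 2w posterior matrix); a window is then encoded by looking up its
own residues in both tables (2w dimensions). The default pseudocount is 0 —
plain occurrence frequencies; a positive pseudocount is available for very
small training sets where zero cells would otherwise pin features at 0. The
profile is part of the model, so it must be (and, inside
`crossvalidate()`, is) fitted per training fold.

The **physicochemical** encoder sums ten per-residue properties over the
window: number of atoms, net charge, hydrogen-bonding capacity,
hydrophobicity, hydrophilicity, burial propensity, isoelectric point, mass,
expected contacts within a 14 Å sphere, and electron-ion interaction
potential. The packaged TSV (`inst/extdata/physchem_properties.tsv`) is the
source of truth; its header names the AAIndex accession behind each column,
and any same-shaped table can be substituted. Fixed alphabet order
`ACDEFGHIKLMNPQRSTVWY` indexes all encoders and profiles.

## Normalization, feature ranking, classification

Features are min-max scaled to [0, 1] with training-set minima and maxima
(the standard LIBSVM preprocessing); held-out values are clipped into
[0, 1], and constant training features map to 0.

Features are ranked by the classic **pooled-variance two-sample Student's
t** statistic between classes (|t| descending, ties broken by column index;
zero pooled variance gives t = 0 — such a feature carries no usable
signal). The top `k` features feed the classifier. `k` is a tunable depth;
`default_selected_k()` packages per-scheme reference defaults (3, 6, 21,
76, 71, 12, 18, 3). No multiple-testing correction is applied: the t-test
ranks, it does not certify significance.

Classifiers: SVM (linear / polynomial / RBF kernels, via LIBSVM through
e1071), k-nearest-neighbor (k = 1 by default, Euclidean distance on the
normalized features), and random forest (500 trees). All expose decision
scores for ROC analysis (SVM decision values, kNN positive-vote fraction,
forest class probability) and are seeded for reproducibility.

**Leakage control is the central design rule**: inside `crossvalidate()`
the bi-profile matrix, the normalizer, the t ranking and the classifier are
all fitted on each training fold only. Folds are stratified (per-fold class
counts within one sample of proportionality) and seeded. Pooled metrics —
computed from the concatenated out-of-fold predictions — are the headline
numbers; per-fold metrics are also reported, since with only ~75 positives
the per-fold estimates are noisy and the pooled/averaged distinction
matters. Optional nested SVM tuning (`tune = TRUE`) selects cost and gamma
by an inner 3-fold CV over a coarse log2 grid
(cost 2^{−5,0,5,10,15} × gamma 2^{−15,−11,−7,−3,1}) before each outer fold
is scored, so tuning never sees held-out data. It defaults to off: on the
dataset sizes this package targets the untuned RBF defaults are already
well calibrated, and a full LIBSVM grid in every fold would multiply the
runtime roughly a hundredfold for marginal gain.

The metric suite is sensitivity, specificity, precision, accuracy, F1 and
the Matthews correlation coefficient from the pooled confusion matrix, with
any 0/0 defined as 0, plus the ROC curve swept over all score thresholds
and its trapezoidal AUC (equal to the Mann–Whitney U probability with ties
half-credited — the suite asserts this equivalence against a brute-force
pairwise oracle).

## Motif scanning

`parse_prosite()` implements the core PROSITE pattern dialect:
dash-separated elements that are exact residues, `x` wildcards, `[..]`
allowed sets or `{..}` forbidden sets, each with optional `(n)` / `(n,m)`
repetition. Anchors (`<`, `>`) are rejected explicitly rather than
mis-parsed. `scan_prosite()` backtracks over variable repetitions and
reports every distinct matching start; at each start the shortest
satisfying span is shown (match existence, the quantity motif reports
count, does not depend on the span choice). The scanner is validated
against a mechanical regex translation on random sequences.
`worked_example_patterns()` bundles four active-site signatures (PS00112,
PS00071, PS01204, PS00139) that `worked_example_windows()`'s five positive
windows reproduce.

## The synthetic-data generator

Real curated S-glutathionylation data is small and not redistributable, so
the generator (`generate_dataset()`) emulates its *structure*: 39 proteins
of length ~N(300, 60²) drawn residue-wise from a uniform background, 75
positive cysteines planted at interior positions (every protein gets at
least one), negatives sampled from the remaining cysteines at ≤3 per
positive per protein. All randomness is seeded; the same seed reproduces
the FASTA and site table byte for byte.

The learnable signal is a set of single-residue enrichments at fixed
offsets from the positive cysteine. The calibration signal
(`strong_signal()`) places K at offset −2, E at −1 and W at +1, each with
probability 0.9. The offsets are deliberately **contiguous** with the
center: the enriched residues then form near-deterministic tripeptides
(KEC, ECW) that contiguous k-mer features see directly. Signal planted at
isolated offsets is spread over a wildcard position — twenty tripeptide
classes share it, the per-feature effect drops below the extreme order
statistics of ~4000 null features at n ≈ 300, and univariate t-selection
can no longer find it reliably. With the contiguous signal, the
reduced-triplet + RBF-SVM pipeline recovers pooled AUC ≈ 0.90–0.95 at
these sample sizes; with no signal it sits at chance, and permuting labels
on signal-bearing data collapses it back to chance (the mean over several
permutations is used, since a single permutation's pooled AUC has null
standard deviation ≈ 0.05 at n ≈ 300).

What the generator does **not** emulate: real amino-acid background
composition, homology between proteins, multi-residue or structural motifs,
ASA/pKa-type structural correlates. Passing calibration on this synthetic
family therefore demonstrates that the pipeline is correct and leakage-free
— not that any particular AUC will be attained on real proteomes.

## Numerical and degenerate-input conventions

* 1-based coordinates in every file and report.
* 0/0 metrics are 0; zero-variance features get t = 0; constant features
  normalize to 0; held-out feature values are clipped to [0, 1].
* Fold assignment deals shuffled class members round-robin, continuing
  across classes, so fold sizes as well as per-class counts differ by at
  most one.
* Ranking ties break by feature index; canonical triplets by lexicographic
  minimum; all stochastic steps (sampling, folds, forests) take explicit
  seeds.
* Problem sizes used by the test-suite calibrations: 39 proteins / 75
  positives per dataset (~290–300 windows), five generator seeds for the
  signal and null conditions, three to five label permutations — sizes at
  which the pooled-AUC estimates are stable to within a few hundredths.

## Known limitations

Sequence windows ignore structural context (solvent accessibility, thiol
pKa, 3-D neighbors), which is known to matter for this modification; the
t-test ranks features marginally and will miss purely interactive signal;
PROSITE profile (matrix) entries are out of scope for the motif scanner;
and reported synthetic-data metrics characterize the pipeline, not
biological attainability.
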