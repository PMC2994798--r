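---
title: "Pan-specific MHC class II binding prediction by concurrent core alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-specific MHC class II binding prediction by concurrent core alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

MHC class II molecules present peptides from the extracellular space to CD4+
T helper cells.  Their binding groove is open at both ends, so bound
peptides are typically 13–25 residues long while only a 9-residue *binding
core* occupies the groove; the register of that core within the peptide is
not observable in a binding assay.  On top of the register problem, the MHC
class II genes are enormously polymorphic: hundreds of HLA-DR molecules
exist, each with its own binding preferences, and only a minority have
enough measured binding data to train an allele-specific predictor.

`mhc2align` addresses both problems at once:

* **Concurrent core alignment.**  A feed-forward network is trained by a
  two-step procedure: at every visit of a training peptide, the current
  network first scores all 9-mer windows of the peptide and the
  highest-scoring window is taken as the peptide's core; one
  backpropagation step is then applied at that core against the peptide's
  measured affinity.  Alignment and regression are estimated
  simultaneously — no pre-alignment of the training data is required.
* **Pan-specific input.**  The allele enters the model only through its
  *pseudo sequence* — the 21 groove-lining residue positions in potential
  contact with the peptide.  All alleles are trained in a single model, so
  information flows between alleles with similar groove chemistry, and
  predictions can be made for any allele whose protein sequence (hence
  pseudo sequence) is known, including alleles with no binding data.

## The model

### Regression target

IC50 values (nM) are mapped to the network's output range by

$$t = \max\!\big(0, \min\!\big(1,\; 1 - \log(\mathrm{IC50}) / \log(15{,}000)\big)\big),$$

so 1 nM maps to 1 and 15,000 nM maps to 0.  The base is configurable
(50,000 reproduces the older convention).  Affinities weaker than the base
are clamped to 0 rather than allowed to go negative; this matches the
output range of a logistic unit, and is this package's choice — how such
affinities were handled originally is not documented.

### Input encoding (646 values)

For a candidate core at a given offset the network input concatenates, in a
frozen order:

| block | length |
|---|---|
| core residues (9 × 20) | 180 |
| pseudo-sequence residues (21 × 20) | 420 |
| N-terminal flank (PFR) summary | 20 |
| C-terminal flank (PFR) summary | 20 |
| peptide length pair | 2 |
| N-/C-flank length pairs | 4 |

Residues are encoded either *sparse* (0.9 at the residue's own position,
0.05 elsewhere) or *blosum* (the residue's BLOSUM50 row divided by 5) —
the conventions of the method family this package reimplements; both are
configurable.  The wildcard `X` encodes as the zero vector, so benchmark
proteins containing `X` remain scorable while training peptides with
non-standard residues are rejected at load.

Each flanking-region summary is the arithmetic mean of the encodings of up
to 3 residues immediately adjacent to the core (zero vector when the flank
is empty).  The cap of 3 follows the allele-specific ancestor of this
method and is configurable.

Lengths enter as complementary logistic pairs
$(\sigma((x - h)/s),\, 1-\sigma((x - h)/s))$ with half-point 15 / slope 2
for the peptide length and half-point 2 / slope 1 for the flank lengths.
Only the *number* of these inputs is documented for the original method;
the logistic-pair functional form is this package's design choice — it is
bounded like every other input, strictly monotone in the length, and
centered where the data are densest (15-mers dominate class II data, flanks
of 2–3 are typical).  Flank-length features use the uncapped lengths.

### Network and training

A single hidden layer of 40 logistic units and one logistic output is
trained by online gradient descent on squared error, 500 cycles over the
training data, visiting records in a fresh random order each cycle.
Initial weights are uniform in [−0.1, 0.1].  Learning rate 0.05, no
momentum, no weight decay, no early stopping: the cycle count is fixed.
Learning rate, weight range and activation were not printed for the
original method; these defaults are declared in `train_config()` and
exposed, not claimed as historical fact.  Training is deterministic given
(records, seed, config): all randomness — initial weights and all visit
orders — is drawn up front from seeded generators, and the inner loop
(written in C++ for speed) consumes no random numbers of its own.

Within a cycle the core of each record is re-identified immediately before
that record's weight update (rather than once per cycle for all records);
the original description alternates the two steps per cycle without fixing
the within-cycle order, so this is pinned here and documented.

### Ensembles

Cross-validation uses 5 folds; peptides sharing any identical 9-mer are
forced into the same fold by single-linkage clustering, and clusters are
dealt largest-first onto the smallest fold.  This is a documented
approximation of the "common motif" partitioning used with the published
data sets (that procedure lives in a cited paper, not the one this package
follows).  Per training/test configuration, 2 encodings × 10 random
restarts = 20 networks are trained.  The ensemble score of a peptide is
the mean of the per-network scores on the [0, 1] scale (averaging in nM
would overweight weak predictions), converted to nM at the end; the
reported core is the majority vote of per-network best cores, ties broken
by the higher mean score among tied offsets, then the smaller offset.
Network seeds derive from the master seed by a fixed spread over
(fold, scheme, restart), so every ensemble is reproducible.  A released
predictor pools all folds' networks (100 at defaults).

### Allele distance

The distance between alleles A, B is
$d = 1 - s(A,B)/\sqrt{s(A,A)\,s(B,B)}$ with $s$ the position-wise BLOSUM50
similarity of the pre-aligned pseudo sequences.  The *nearest-neighbor
distance* of an allele is its minimal distance to any training allele;
small values predict good pan-specific extrapolation.  Distances above 1
are possible for very dissimilar sequences and are reported as-is.

## Benchmark protocols

* **Cross-validated evaluation** reports AUC (binders at IC50 ≤ 500 nM;
  Mann–Whitney with half-ties) and Pearson correlation per allele, plus
  unweighted across-allele means.  Whether the original "average" rows
  weight alleles equally is not fully documented; equal weighting is used
  here.
* **Leave-one-allele-out** (`loo_allele`) removes all records of the
  target allele from training and evaluates on them, keeping only the
  pseudo sequence — extrapolation to an uncharacterized molecule.
* **Leave-one-peptide-out** (`loo_peptide`) additionally removes every
  measurement of each evaluation peptide against *any* allele, since
  peptides measured on several molecules otherwise leak information.
  Above 200 data points for the target allele this runs as an inner 3-fold
  cross-validation over its peptides (partitioned by the same shared-9-mer
  clustering, seeded); at or below 200, one round excludes everything.
* **Ligand benchmark** (`ligand_benchmark`): each ligand's source protein
  is cut into all overlapping windows of the ligand's length; only windows
  identical in sequence to the annotated ligand are positives (repeated
  occurrences included), all others negatives — deliberately stringent,
  since windows sharing the binding core count as negatives.  AUC per
  ligand, aggregated per ligand, per allele (within-allele means first)
  and per ligand length.  Epitopes shorter than 9 (no room for a core) or
  longer than 24 residues are excluded and counted.

## The synthetic world

Everything is testable offline against `generate_alleles()` /
`generate_records()`, which emulate a family of related HLA-DR-like
molecules with *known* ground truth:

* A root allele receives a random 21-mer pseudo sequence and a 9 × 20
  position score matrix (PSSM) with larger score spread (sd 1.5 vs 0.4) at
  anchor positions 1, 4, 6, 9 — mimicking the anchor-driven class II
  motifs.  Rows are mean-centered.
* Each derived allele mutates pseudo positions at rate 0.15 along a random
  tree and, per mutated position, perturbs one random PSSM row
  (sd 0.5, then re-centered).  Coupling the two processes makes
  pseudo-sequence distance track motif distance in expectation — the
  premise of pan-specific prediction, asserted as a property test across
  seeds.
* Peptides are uniform-random (lengths 9–21); the *true core* is the
  PSSM-argmax window; the target is
  $\mathrm{logistic}((s_{\max} - (\mu + 1.2\sigma))/(0.4\sigma))$ —
  standardised against the PSSM's own window-score distribution so targets
  spread over [0, 1] instead of saturating, yielding a realistic
  (~50–65%) binder fraction — plus Gaussian noise (sd 0.05) on the target
  scale, clamped.  IC50 follows by the inverse transform.
* Ligand fixtures implant one optimal-core ligand per random protein.

What the generator does **not** emulate: real residue background
frequencies (uniform background keeps the PSSM oracle exact), assay error
structure, length-dependent binding preferences, and real HLA-DR motif
chemistry.  A green synthetic benchmark therefore establishes that the
algorithm recovers planted structure under its own assumptions — it says
nothing about accuracy on laboratory data, and the published absolute
performance values are not reproducible at this scale by design.

At the scaled-down acceptance setting (6 alleles × 400 peptides, 1
encoding × 2 seeds × 150 cycles) the cross-validated per-allele Pearson
correlations, the majority-vote recovery of planted cores among strong
binders (target ≥ 0.7), and the negative rank-correlation between
leave-one-allele-out AUC and nearest-neighbor distance are computed by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`; the numbers
those runs print are the package's empirical claims.  One observation from
development, kept for honesty: with a *single* allele and only 400
peptides, concurrent alignment reaches high affinity correlation while
recovering few planted registers; register recovery is data-hungry
(supervised-alignment control: 0.9 at n = 400; concurrent: ≈0.99 at
n = 2000 single-allele, ≥0.8 at the 6-allele acceptance scale).

## Numerical choices and degenerate inputs

* Ties in core identification go to the smallest offset everywhere
  (training, prediction, and the majority vote's final tie-break).
* AUC ties count one half; single-class inputs yield `NA` with a warning
  and are excluded from averaged AUCs.  Zero-variance inputs make the
  Pearson correlation `NA` likewise.
* 9-mer peptides have exactly one candidate core; no special casing.
* Non-finite weights during training abort with an error (exploding step
  size) rather than propagating `NaN`s.
* Serialized networks store 17 significant digits, which round-trips IEEE
  doubles exactly; predictions from a reloaded model are bit-identical.
* `partition_data` fails when fewer linkage clusters than folds exist.

## Known limitations

* Training cost grows with (records × candidate offsets × cycles); the
  defaults are sized for data-set scales of a few thousand records on one
  CPU.
* The fold partitioner approximates the original common-motif clustering;
  fold compositions will differ from the published ones.
* No percentile-rank output: scores are transformed affinities and nM.
* Scalar length features are a declared functional form, not a
  reconstruction of the original encoding.
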