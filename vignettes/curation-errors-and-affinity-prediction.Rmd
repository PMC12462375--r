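---
title: "Curation errors and structure-based affinity prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation errors and structure-based affinity prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdcurate)
```

# The problem

Databases that pair experimental protein–protein complex structures with
equilibrium dissociation constants (KD) are the raw material for
structure-based affinity prediction. Every KD in such a database was at
some point transcribed by a curator from a publication, and transcription
can go wrong: the value may belong to a different construct or a
different complex, the units may be slipped by a factor of a thousand, a
rounded figure value may replace the precise table value, or a single
number may stand in for a two-site binding model. `kdcurate` provides the
machinery to (i) audit such a dataset against literature-extracted
values, (ii) quantify how each class of curation error degrades
machine-learning prediction of log10(KD) from 3D structure, and (iii)
exercise the entire analysis on synthetic heterodimers so that every
computation is reproducible without any database download.

# The curation taxonomy

Each database record is compared against the KD records extracted from
its primary publication and assigned one of six categories: `Match`,
`NoKD`, `DifferentHeterodimer`, `Approximate`, `Units`, `MultisiteKD`
(see `?curation_categories`). The classifier is a deterministic rule
cascade, ordered from most to least specific:

1. **NoKD** — no literature KD exists for the construct that was actually
   deposited (mismatching constructs are the dominant real-world cause).
2. **MultisiteKD** — the matching-construct record carries a second KD
   from a two-site model.
3. **Match** — the database value exactly equals (relative tolerance
   1e-9) the *primary* matching-construct value, where "primary" means
   the most precise one on record.
4. **Units** — significands agree to a relative 1e-6 and the values
   differ by exactly 3, 6 or 9 decades; a slipped unit prefix (mM / µM /
   nM) produces precisely this signature.
5. **Approximate** — the database value equals the primary value rounded
   to the database's own printed precision, or equals a lower-precision
   alternative reported for the same construct.
6. **DifferentHeterodimer** — the database value equals a value measured
   for a different construct; anything that falls through every rule is
   also placed here, flagged `unresolved`, mirroring the catch-all
   nature of the category.

Printed precision matters throughout (8 × 10⁻⁷ is a different claim from
7.4 × 10⁻⁷), so KD values travel as text until parsed by
`parse_molar_value()` / `parse_kd_token()`, which record significand,
exponent and significant figures.

Whether `Approximate` counts toward the headline error rate is
configurable (`error_rate(include_approximate = )`). The default counts
it, since an approximate value is not the value the literature prints;
under this convention the itemized category counts and the headline
error rate of the motivating study are mutually consistent.

# Evaluation subsets

`build_subsets()` materializes five dataset variants: `FullCorrection`
(errors corrected, uncorrectable `NoKD`/`MultisiteKD` records dropped),
`NoKDOnly` (only the drop), `UnitsOnly` and `DifferentHeterodimerOnly`
(only the named correction) and `PDBBind` (untouched). Training targets
differ by subset; evaluation targets are *always* the literature
(corrected) values, falling back to the database value only where no
literature value exists. This is the only convention under which subsets
of different sizes remain comparable, and it matches the definition of
the measured axis in the study this package reproduces: correlations are
against literature-extracted values.

# Features

**Element-pair counts.** `rfscore_features()` counts every cross-chain
heavy-atom pair within 12 Å (inclusive; squared distances internally),
binned by the unordered element pair. The element vocabulary is frozen
per experiment (`rfscore_vocabulary()`) as the sorted union of elements
over the dataset, so train and test vectors always align.

**Contacts and %NIS.** `prodigy_contacts()` bins cross-chain residue
contacts (any heavy-atom pair within a threshold, one count per residue
pair) into the six unordered class pairs over {charged, polar, apolar}.
The class membership table (`residue_class_table()`) is a
reimplementation choice: charged = {ASP, GLU, LYS, ARG, HIS}, polar =
{ASN, GLN, SER, THR, TYR, CYS}, apolar = the rest including TRP. Other
contact-based predictors make slightly different choices (TRP, TYR, CYS
and HIS are the contentious ones); the table is exported data and every
consumer accepts an override. `nis_percentages()` computes the percent
non-interacting surface per class: residues of the *complex* with
relative solvent accessibility ≥ 5% (configurable) are surface residues,
and the three class shares sum to 100. Accessibility is Shrake–Rupley
SASA (own compiled implementation, 960 golden-spiral points per atom,
probe 1.4 Å, standard van der Waals radii) normalized by
extended-tripeptide reference areas; class fractions are residue-level.

# Sequence distance and cluster-respecting cross-validation

The distance between two heterodimers {a, b} and {α, β} is

> ½ · min( d(a, α) + d(b, β), d(a, β) + d(b, α) )

with d(i, j) = 1 − SW(i, j) / √(SW(i, i) · SW(j, j)), where SW is the
Smith–Waterman local alignment score under BLOSUM62 with affine gaps
(open 11, extend 1 — the standard pairing for this matrix; the values are
configurable and recorded). The construction is symmetric in pair order
and in within-pair chain order, zero for identical pairs, and bounded in
[0, 1]; it is *not* a metric (no triangle inequality is claimed or
relied upon). Scores are computed by a compiled Gotoh recursion; the
test suite pins it against a textbook dynamic-programming oracle and
against an independent aligner.

Single-linkage clustering (`single_linkage()`) records every merge
height. Membership at a minimum-separation threshold `t` applies all
merges strictly below `t`, which makes the clusters exactly the
connected components of the graph joining items at distance < t — the
property the tests exploit as an independent oracle. Tie-breaks among
equal-height merges follow the underlying agglomeration order; they can
permute the dendrogram but never change threshold memberships, precisely
because of the components characterization.

`assign_folds()` shuffles clusters with a seed and assigns each whole
cluster to the currently smallest fold. No cluster ever spans folds, so
a test record never has a near-duplicate in training; fold sizes are
balanced up to the largest cluster size.

# Models

The random-forest regressor (`train_forest()`) uses 100
variance-reduction trees, each grown on a seeded random 50% subset of
training records drawn *without* replacement (a subset, not a
bootstrap), with all features available at every split (configurable to
p/3). The linear model (`stepwise_linear()`) runs forward-and-backward
stepwise selection under AIC (n·ln(RSS/n) + 2(k+1), intercept counted)
over the nine contact/%NIS descriptors, separately for every contact
threshold on the 3.5–20 Å grid (step 0.5), and keeps the
threshold/feature set with the lowest training AIC — the threshold is
chosen by training data only, never by the test fold.

`run_experiment()` pools, per trial, the held-out predictions of all
five folds into a single Pearson correlation, yielding one r per trial;
repeated trials redraw the fold assignment from trial-specific seeds
derived from the master seed, and every stochastic component (fold
shuffles, tree subsamples) derives from that one seed, making runs
bit-reproducible. Fold seeds deliberately do not depend on the subset
name, so two subsets containing identical records are split identically
and their comparison is fully paired. Subset comparisons use the
one-tailed Welch t-test over per-trial correlations.

A note on AIC's selection behaviour: with ~nine candidate descriptors
AIC admits a spurious feature with probability ≈ 0.16 each, and taking
the minimum over a 34-point threshold grid compounds this. On pure noise
the selected model is therefore rarely *literally* empty; it is,
reliably, a small model explaining almost none of the variance, and that
is the property the tests assert. On planted data the planted
descriptors and threshold are recovered, possibly alongside a weak extra
term.

# The synthetic benchmark

`generate_dataset()` builds a dataset with the statistical structure the
analysis assumes, at desk scale:

* **Families.** 262 records in families whose sizes follow a geometric
  distribution with mean 3 — mimicking the redundancy (homologs,
  mutants) that motivates cluster-respecting cross-validation. Members
  are per-site mutants (rate 0.05) of a founder pair of random
  sequences, 40–70 residues per chain. Chain lengths are a deliberate
  desk-scale choice; real heterodimer chains are often longer, which
  changes absolute feature magnitudes but none of the mechanisms under
  study.
* **Structures.** Each chain is a self-avoiding Cα walk (3.8 Å steps,
  non-adjacent residues ≥ 4.2 Å) carrying the residue's true heavy-atom
  element multiset in a shell around each Cα; chains are rotated and
  slid together until the cross-chain pair count within 12 Å approaches
  500, with all heavy atoms kept ≥ 1.5 Å apart. Family members reuse the
  founder geometry with mutated side groups re-placed and a bounded
  0.2 Å coordinate jitter, so structural (and hence feature) similarity
  tracks sequence similarity as it does for real homologs. These are
  geometric fictions, not physical proteins — defensible here because
  every downstream computation (pair counts, contacts, SASA) is purely
  geometric. Passing tests therefore demonstrate the *mechanisms*
  (leakage, error dose–response), not prediction accuracy on real
  complexes; absolute correlations on this benchmark are far higher than
  on real data, where the affinity is not a planted function of the
  features.
* **Affinities.** log10(KD) = −7.5 + Σ wⱼ·zⱼ + N(0, 0.3), a sparse
  linear form over at most eight standardized element-pair bins
  (defaults: the highest-variance bins with fixed alternating weights,
  giving a realistic ~1.4 log-unit spread around a typical −7.5).
* **Curation errors.** `inject_errors()` perturbs exact per-category
  counts (`round(rate × n)`), at default rates 24 NoKD, 12
  DifferentHeterodimer, 3 Units, 2 MultisiteKD and 10 Approximate per
  262 — the category structure of the real Open Access heterodimer
  audit. Each perturbation is the real-world mechanism in miniature:
  unit slips multiply by 10^±3, borrowed values come from another
  record's literature entry and are recorded as non-matching-construct
  measurements, approximate values are 1-significant-figure roundings
  (only records actually changed by rounding are eligible, so the
  classifier can always separate them from `Match`). The classifier and
  the injector close the loop exactly on the default configuration.

# Numerical and design choices

* Exact-match tolerance 1e-9 (relative), loose comparisons 1e-6;
  significand comparison for unit slips at 1e-6 with decade offsets
  {3, 6, 9}.
* Heteroatom groups are retained when covalently attached: any heavy
  atom of the connected group (components over a 1.9 Å bond graph)
  within 1.9 Å of a protein heavy atom of the same chain.
* Altloc records other than `' '`/`'A'` are dropped; occupancy is
  ignored. Whether deduplication should be occupancy-weighted is
  genuinely open; the simple rule is documented as a guess.
* Sequences for alignment are derived from the filtered coordinate
  records (not from SEQRES-style headers), so alignment sees exactly the
  residues the features see.
* Separation thresholds default to {0.1, …, 0.6}; 0.6 is the named
  operating point, the rest are a configurable reconstruction.
* Degenerate inputs fail loudly: constant targets, empty chains,
  zero-variance correlation inputs, fewer clusters than folds (the
  affected cell is skipped with a message rather than silently pooled).

# Problem sizes used by the tests and the acceptance script

The shipped checks run the full pipeline at the default 262-record scale
once (generation ≈ 1 min, distance matrix ≈ 2 s) and evaluate
mechanism-level claims with 20 redrawn trials per condition. For the
dose–response and correction comparisons each trial redraws *both* the
injected errors and the folds: in a synthetic benchmark the injection is
part of the data-generating process, and conditioning on a single
corruption draw would make the comparison hostage to that draw's luck
rather than to the mechanism. Parameter-recovery checks use n = 400–500
records with tabular simulators (`simulate_feature_table()`,
`simulate_contact_tables()`) rather than 3D structures; independence of
the simulated bins keeps the planted models identifiable.

# Known limitations

* The synthetic structures carry no physics: no packing, no secondary
  structure, no solvation, no structural waters, no protonation states.
* The residue-class table may diverge from any particular contact-based
  reference implementation; it is data, not code, for exactly this
  reason.
* The %NIS class shares are residue-level; an atom-level variant would
  differ slightly.
* Real curation tables contain free-text ambiguity that the structured
  schema used here cannot represent; extracting KD records from
  publication text is out of scope.
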