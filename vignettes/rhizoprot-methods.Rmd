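---
title: "Methods: seasonal differential abundance, cross-species convergence and LEA3 profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal differential abundance, cross-species convergence and LEA3 profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoprot)
```

This vignette is the package's own account of the statistics and sequence
analysis it implements, the assumptions behind them, and the design choices
made where more than one reasonable implementation existed.

## Seasonal differential abundance

### Model

Reporter-ion intensities from isobaric (TMT-style) quantification are
treated as log-normal: on the log2 scale, a protein's intensity in sample
$j$ is

$$y_{j} = \mu + \beta\, I[\text{winter}_j] + \gamma_{b(j)} + \delta_{y(j)} + \varepsilon_j,$$

with protein baseline $\mu$, season effect $\beta$ (the quantity of
interest: $\beta = \log_2(\text{winter}/\text{summer})$), optional additive
batch and year offsets, and i.i.d. Gaussian noise. Zeros denote
non-detection, not zero abundance, and are treated as missing; missing
values are omitted per protein (pairwise deletion, no imputation).

Before testing, intensities are normalized by the total-peptide-amount
method: each sample column is multiplied by a single factor so every
column's sum over non-missing entries equals the mean of the input column
sums. A single multiplicative factor preserves within-sample ratios
exactly. This normalization assumes the differential signal is a minor
share of total intensity; when a large fraction of the proteome is
regulated in one direction it shifts all fold changes by the log-ratio of
seasonal totals, which is why validation scenarios keep the regulated
fraction realistic (around 10–20% of proteins).

### Testing

With no adjustment factors, each protein is tested by one-way ANOVA on the
season groups and the winter–summer contrast p-value is taken from Tukey's
honest significant difference, i.e. the studentized-range distribution with
$k$ equal to the number of season groups. Seasons here are exactly two, and
at $k = 2$ the Tukey contrast p, the pooled-variance two-sample t-test p
and the ANOVA omnibus p coincide ($q = \sqrt{2}\,|t|$, $F = t^2$); the
implementation is vectorized through this identity and the test suite
checks it numerically. Because which of the two p-values entered multiple
testing in comparable published workflows is ambiguous, `seasonal_test()`
exposes `p_source = "tukey"` (default) or `"anova"` — at two seasons the
choice is immaterial, and the option exists to make that explicit.

With `adjust_for = c("batch", "year")`, an additive fixed-effects linear
model (season + factors, no interactions) is fitted per protein and the
season coefficient is tested on the residual degrees of freedom; the
reported log2 fold change is then the season coefficient, i.e. adjusted for
the fitted factor effects. Proteins with complete data share one design
matrix and are solved in a single multi-response least-squares fit;
proteins with missing values are fitted individually on their complete
cases. A factor whose levels never span both seasons is confounded with
season and is refused with an error naming the factor; single-level
factors are dropped (nothing to adjust). The additive model is the simplest
structure consistent with "accounting for" batch and year without an
interaction claim; the unadjusted path remains the plain ANOVA + Tukey
procedure.

P-values are Benjamini–Hochberg adjusted within each species over tested
proteins only — each species group is analyzed as a separate family, since
DAP counts are reported per species. A protein is `up` when
`log2fc >= lfc_min` (default 1, i.e. two-fold) and `p_adj < alpha` (default
0.05), `down` symmetrically; proteins lacking two quantified replicates in
either season are `untested`, never silently dropped. Thresholds are
deliberate boundary-inclusive on the fold change (≥) and exclusive on the
p-value (<).

## Orthogroup-level convergence

Protein log2 fold changes are averaged within (orthogroup, species group)
— an unweighted arithmetic mean over member proteins, excluding proteins
without orthogroup assignment and untested proteins, whose fold change is
undefined. Averaging before correlation avoids letting large gene families
dominate cross-species comparisons. Species sampled in different years can
be kept as distinct species groups (e.g. a 2019 and a 2022 cohort), which
is why the category homogeneity test below naturally has
(6 − 1)(9 − 1) = 40 degrees of freedom with six groups.

Spearman correlations are computed over all orthogroups quantified in both
groups of a pair — not only DAP orthogroups — with average-rank tie
handling; fewer than three shared orthogroups is an error rather than a
meaningless coefficient. An orthogroup counts as a DAP orthogroup in a
species group if *any* member protein is a DAP in the relevant direction;
a mean-based criterion would undercount multi-member families in which one
strongly regulated protein is diluted by stable paralogs. Co-occurrence is
summarized by exclusive classes: each flagged orthogroup contributes to
exactly one subset of species groups (its exact membership), so class
counts sum to the total — a conservation property the tests enforce by
exhaustive subset enumeration. Sharing fractions are the proportion of DAP
orthogroups flagged in at least two (and at least three) species groups.

Top-N selection (default 50) orders up-DAPs by descending log2 fold
change, breaking ties by smaller adjusted p and then lexicographic protein
ID, so output is total-ordered and reproducible.

## Cold-related functional categories

The nine categories (membrane stability, chaperones,
metabolism/osmoregulation, ROS scavenging, lipid metabolism,
antifreeze/cell wall, cold signaling, cytoskeleton, other) are assigned by
a keyword/regular-expression map over protein descriptions and GO-term
text, shipped as an editable TSV
(`system.file("extdata", "cold_categories.tsv", package = "rhizoprot")`).
The map's row order is the match priority and the first match wins, which
makes assignment deterministic and auditable. The shipped map is a
documented approximation: the original binning of such datasets is manual
curation, and no keyword list can claim to recover a curator's judgment —
the point is reproducibility of whatever map is used.

The species-group × category table is tested with a Pearson chi-square
test of independence, no continuity correction, df = (r−1)(c−1), with a
warning when more than 20% of expected counts fall below 5. Zero row or
column margins are an error (the statistic is undefined there).

## Tiered peptide reassignment

When samples are searched against a related species' reference proteome,
peptide evidence can be re-aggregated to re-home each originally-assigned
protein in the correct proteome. Candidate targets for a source protein
are ranked by a strict ladder:

1. number of **distinct peptides** hitting the target (unique peptide IDs,
   not alignment positions), descending;
2. **sum of bitscores** over those hits, descending;
3. **median percent identity**, descending;
4. lexicographically smallest target ID.

Tier 4 is a deterministic fallback added so the ranking is a total order —
without it, ties at tier 3 would make output depend on input order. The
result records `decided_at_tier`, the first level that uniquely ranked the
winner, which the simulator uses to verify every tier is exercised.
Optional `min_pident` / `max_evalue` pre-filters are off by default, since
sensible cut-offs depend on the aligner settings used upstream.

Regenerating protein-level tables re-keys intensity rows to chosen
targets; sources that collapse onto one target are **summed** per sample
(intensities are additive evidence for the same protein; collisions are
flagged in an `n_sources` column for audit), missing + value = value, and
rows whose source found no target go to a separate `unassigned` table so
total intensity is conserved exactly. An exact-substring peptide mapper
(`map_peptides_exact()`, pident 100, surrogate bitscore 2 × length) stands
in for an external aligner in tests and simulations.

## LEA3 motifs and hydropathy

### Motif grammar

The group-3 LEA 11-mer is modelled as: positions 1, 2, 5, 9 from an apolar
set, positions 6–8 matching "+ − +" or "+ Q +", positions 3, 4, 10, 11
unconstrained. Two residue-set choices were genuinely open and are
configurable:

* **Apolar set** defaults to {A, T, V, L, I, M, F}. The motif description
  says "apolar (hydrophobic)" and explicitly admits threonine in place of
  alanine but never enumerates the set; this default is the standard
  hydrophobic alphabet plus T, documented as an interpretation.
* **Charge sets** default to {K, R} positive and {D, E} negative, with
  histidine excluded because its protonation state near neutral pH is
  ambiguous; users can add H to either set.

`detect_motifs()` reports every window satisfying the grammar, resolving
overlaps by a greedy left-to-right non-overlapping scan (an accepted motif
suppresses candidate starts within the next 10 residues). Runs of
consecutive motifs (gap 0) and inter-motif gap lengths follow from the
accepted starts; coordinates are 1-based inclusive throughout, matching
residue numbering conventions. The `figure6` preset tolerates one grammar
violation at motif position 1 only — reference LEA3 architectures include
a first motif that deviates from the strict grammar at exactly that
position, and the preset exists to call such chains without loosening the
grammar elsewhere. The detector is verified against a brute-force
all-windows oracle on randomized sequences up to 200 residues.

### Hydropathy profiles and comparison

Profiles are sliding-window means of per-residue scale values
(Kyte–Doolittle by default, Eisenberg available, custom named vectors
accepted), window 11 by default to match the motif length, undefined where
the window does not fit; residues absent from the scale (e.g. X) error by
default or can be skipped from window means. Position-class statistics
average the profile over residues congruent to a chosen motif position
modulo 11 within a region, recovering the periodic amphipathic signature.
Profile comparison over an aligned ortholog pair reports
`delta_hydro` (mean paired difference) and `pattern_r` (Pearson
correlation of paired scores) over a stated region; fewer than three
pairs, or zero variance, are errors rather than NaNs.

Published per-position hydropathy values for LEA3 orthologs (e.g. values
near −1.1 at apolar positions) depend on an unstated combination of scale
and normalization — raw Kyte–Doolittle is positive at hydrophobic
residues — so recovering any particular printed value is treated as an
external-validation exercise with the scale and window exposed, not a unit
test of this package.

Pairwise alignment for profile comparison uses Needleman–Wunsch global
alignment with BLOSUM62, gap opening 10 and gap extension 1 (a gap run of
length $L$ costs $10 + L$), via Biostrings; the suite checks the score
against exhaustive alignment enumeration on short sequences. An externally
produced aligned-FASTA pair is accepted as an alternative pairing source.

## The simulators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed once and the tests are written against
them.

* `gen_abundance_dataset()` draws protein baselines N(20, 2) on the log2
  scale (typical reporter-intensity magnitudes), plants ±`effect_size_log2`
  on proteins of regulated orthogroups, adds per-batch offsets shared by
  all proteins of a batch (batches balanced across seasons, so adjustment
  is identified), Gaussian log2 noise, and missingness at a flat rate.
  Regulation is planted at the orthogroup level: a `shared_frac` subset of
  regulated orthogroups is regulated with the same sign in **all** species,
  the rest in exactly one species. Reference validation conditions:
  effect 3 log2 units, noise sd 0.3, 4 replicates/season, 2,000 proteins,
  20 replicate datasets — at these settings the suite requires sensitivity
  ≥ 0.95 and empirical FDR ≤ 0.10, and the all-species co-occurrence class
  must recover `shared_frac` within binomial error. With zero noise and
  zero batch sd the log2 fold-change estimator is exact to machine
  precision, which the suite asserts literally.
* `gen_motif_proteome()` plants chains of grammar-valid 11-mers; filler
  residues (lead/tail, unconstrained motif positions, insertions) are
  drawn from {G, S, N, P, W, C, H} — letters outside the apolar and charge
  alphabets and not Q — so non-motif regions cannot satisfy the grammar at
  any offset, giving negative controls by construction rather than by
  rejection sampling. Planted coordinates must equal detector output
  exactly.
* `gen_peptide_scenario()` gives every source protein a true target and,
  when `decoy_similarity > 0`, one decoy built to tie the ladder up to a
  planted tier (cycling 1–4) and then strictly win with probability
  `decoy_similarity` or strictly lose. Recovery is therefore 100% without
  competition and decreases in expectation as decoys strengthen, and
  `decided_at_tier` must equal the planted tier — both asserted in tests.

What the simulators do **not** emulate: peptide detectability and missing-
not-at-random structure, isotopic interference and ratio compression in
isobaric quantification, correlated noise between co-eluting proteins,
orthogroup assignment errors, and annotation noise. Passing tests
demonstrate the estimators and algorithms are correct under the stated
generative model, not that real acquisitions meet that model.

## Numerical choices and degenerate inputs

* Zeros in intensity matrices are missing (avoids −∞ under log2).
* Identical values in both seasons: F = 0 and p = 1, not NaN.
* Zero within-group variance with unequal means: the contrast p is 0
  (infinite t), which makes zero-noise simulations behave correctly.
* `p.adjust(..., "BH")`, `stats::cor(method = "spearman")`,
  `stats::chisq.test(correct = FALSE)`, `stats::ptukey` and
  `Biostrings::pairwiseAlignment` supply the standard statistical
  primitives; the package's own code is the orchestration and the
  domain-specific algorithms (tie-break ladder, motif grammar,
  co-occurrence classes, simulators).
* All orderings that affect output (top-N, tier 4, class labels) are
  total orders, so results are invariant to input row/column order; the
  suite permutes inputs to check this.
* Pipeline stage seeds are derived deterministically from one master seed,
  so partial re-runs reproduce.

## Validation problem sizes

The shipped suite runs the motif oracle on 1,000 random sequences ≤ 200
residues, the reassignment oracle on 500 source proteins, the
F = t² identity on 200 proteins, parameter recovery on twenty
2,000-protein datasets, batch-bias estimation on fifty 50-protein
datasets, and the five-species convergence study on 400 orthogroups —
sizes chosen to give stable empirical rates while keeping a full run in
tens of seconds on one CPU.

## Known limitations

* The unadjusted test assumes equal group variances (pooled); no
  empirical-Bayes moderation is applied, by design — with few replicates a
  moderated test would be more powerful but is a different procedure.
* Keyword-based category assignment is only as good as the map; the
  default map is a starting point meant to be edited per study.
* The greedy motif scan is the documented convention for overlapping
  candidates; a different tiling convention would shift reported starts
  for dense overlaps (not observed in planted architectures).
* Orthogroup averaging weights all member proteins equally; quantification
  precision differences between members are ignored.
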