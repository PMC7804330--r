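---
title: "seedmir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seedmir: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmir)
```

`seedmir` turns the miRNA-calling and expression-dynamics analysis of a
developing-seed small-RNA study into explicit, individually testable
functions. This vignette explains the underlying models, every tunable
parameter with its default and rationale, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the procedure left room.

## The pipeline at a glance

Reads from twelve libraries (four timepoints — 10, 20, 30 and 40 days
after anthesis — times three biological replicates) are collapsed to
unique tags, windowed to 15–32 nt (inclusive at both ends), screened
against contaminant blocklists, and normalised to reads per million
mappable reads (RPM). Tags are then (1) assigned to known miRNAs under
position-constrained mismatch rules, or (2) folded in their genomic
context and called as novel miRNAs when eight structural criteria hold.
Expressed miRNAs (mean RPM ≥ 100 at some timepoint) enter differential
expression, clustering, PCA and co-expression networks, and finally
complementarity-based target prediction with degradome validation.

## Known-miRNA assignment

A tag matches a reference mature under an ungapped comparison after end
shifts of at most 2 nt on either end, with

* ≤ 2 mismatches in total,
* ≤ 1 mismatch in the 5′ region (mature positions 1–9),
* no mismatch at positions 10–11,
* ≤ 2 mismatches from position 12 on.

Positions are counted 1-based from the mature 5′ end. The region
boundaries are a design choice: the procedure names a 5′ and a 3′ region
without fixing their limits, and positions 10–11 are the canonical
cleavage-pairing core, so the 5′ region ends at position 9. The published
phrasing "one mismatch in the 5′ region, or 2 in the 3′ region" could
also be read as a disjunction of alternatives; `seedmir` implements the
conjunction of all four rules above, which is the stricter and, in our
reading, intended interpretation. Indels are not permitted inside the
alignment — the rules speak of mismatches and end overhangs only.

Known status additionally requires genome presence: the tag itself occurs
exactly in the genome (same-species case) or the matched reference
precursor does (cross-species case), on either strand. Ties between
equally good matures are broken by mismatch count, then total end shift,
then lexicographic mature id, making assignments reproducible. Multi-locus
tags keep all loci; counts are never apportioned between loci because each
tag is one expression unit.

## The folding model

Structural criteria need a deterministic, exactly reproducible notion of
"the fold". `seedmir` bundles a maximum-weight non-crossing pairing model
solved exactly by dynamic programming in C++:

* pair weights G:C = −3, A:U = −2, G:U = −1 kcal/mol,
* hairpin loops enclose at least 3 unpaired nucleotides,
* lonely pairs are disallowed: every helix has ≥ 2 stacked pairs (the
  convention thermodynamic folders expose as "no lonely pairs").

The no-lonely-pairs rule matters for discrimination: under a pure
weight-maximising model, random sequence pairs promiscuously through
isolated single pairs, which both buries genuine precursor stems under
spurious alternatives and lets background loci imitate hairpins. The
reported "MFE" is the negated total weight; it is *not* a thermodynamic
free energy, but it ranks structures consistently and makes every
criterion value exact and machine-independent. A thermodynamic backend can
be swapped in through `fold(engine = )` for real-data work; all bundled
tests and contracts use the reference model.

## Hairpin decomposition and the eight criteria

For a candidate (a tag plus a folded window) the stem-loop unit carrying
the mature is identified: starting from a hairpin loop, the stem is grown
outward through stacked pairs, bulges and interior loops, stopping at a
multiloop junction, the exterior, an interior loop wider than 8 nt per
side, or a helix of fewer than 3 stacked pairs beyond a loop. The caps
encode what a contiguous precursor stem looks like; without them,
unrelated short helices of a random fold chain into arbitrarily long
"stems". Branched (cloverleaf-like) structures and matures sitting in the
terminal loop are rejected.

Discovery excises the candidate precursor iteratively: each tag-anchored
window (±80 nt flanks; three windows per locus) is folded, trimmed to the
mature-bearing unit, and refolded until it is a single clean hairpin. One
final ±10 nt extension is then attempted, because a stem-closing helix can
lose its pairing partner to an equal-weight tie in the window-level fold
and end up just outside the excision. Criteria are measured on the
converged candidate, so MFE, MFEI and GC% describe the precursor hairpin
itself rather than an arbitrary extraction window — which is also how the
published precursor statistics (MFE between −17 and −94 kcal/mol for
roughly 60–100 nt hairpins) are defined.

The eight criteria, all inclusive: stem ≥ 22 bp; dG ≤ −17 kcal/mol;
hairpin ≥ 56 nt; terminal loop ≤ 82 nt; ≤ 2 biased bulges in the mature;
≥ 14 pairs in the mature *or* star region (the published criterion names
"mature or mature\* region", so either arm may satisfy it); pm ≥ 80;
MFEI ≥ 0.80. A biased bulge is a maximal unpaired run within the mature
whose opposite strand has no unpaired partner run. MFEI = AMFE / GC% with
AMFE = (−dG/length) × 100 and GC% on the 0–100 scale — the established
definition behind the published 0.8–2.2 range. A zero-GC candidate has no
defined MFEI and fails criterion 8 explicitly. The best candidate per tag
maximises criteria passed, then stem size, then the 5′-most window; novel
ids `miR_1, miR_2, …` follow first genome coordinate.

## Expression dynamics

*Normalisation.* The study reports "normalized read numbers" without a
formula; `seedmir` uses reads per million mappable reads per library, the
standard sRNA-seq unit and the one consistent with expression thresholds
in the hundreds. Normalisation is scale-equivariant and tested as such.

*Expression filter.* Mean normalized reads ≥ 100 at one or more
timepoints, inclusive. (The results text says "higher than 100" while the
procedure says "≥ 100"; the inclusive reading is implemented.)

*Differential expression.* One-way fixed-effects ANOVA over the four
timepoints on normalized values, BH-corrected across miRNAs, then pairwise
pooled-variance Student t-tests (df = 4 with triplicates) for consecutive
timepoints plus 10-vs-40, BH-corrected within each comparison. Degenerate
inputs follow explicit conventions: no variance at all, or no
between-group variance, gives p = 1; perfect separation with zero
within-group variance gives p = 0. Log2 fold changes use a pseudocount of
1 on mean normalized reads to avoid infinities at zero.

*Clustering.* Per-miRNA z-scored timepoint means, 1 − Pearson distance,
complete linkage, tree cut at k = 6 to mirror the six published abundance
archetypes, letters assigned in dendrogram order. Zero-variance profiles
cannot be z-scored and receive the sentinel label `"-"`.

*PCA.* Libraries are observations, miRNAs variables, z-scored; scores come
from the singular value decomposition with each component's sign fixed so
its largest-magnitude loading is positive.

*Co-expression network.* Pairwise Pearson r over the twelve per-library
values, two-sided p from t = r·sqrt((n−2)/(1−r²)) on n − 2 df, edges kept
at |r| ≥ 0.75 and p ≤ 0.05. (The source phrases the threshold in "R²"
notation with a negative bound; a squared quantity cannot be negative, so
it is read as signed r.) At n = 12 the |r| ≥ 0.75 threshold corresponds to
p ≈ 0.005, so the correlation bound is the binding constraint.

## Targets and degradome

The expectation score E sums penalties over miRNA positions read against
the reverse complement of the transcript window: mismatch 1, G:U 0.5,
gap 2, all doubled in the seed (positions 2–13); perfect complementarity
scores 0 and sites are reported at E ≤ 2. This is the penalty scheme
underlying the tool family the threshold comes from; only the cutoff is
fixed by the source. The implementation scores ungapped windows: a seed
gap alone (2 × 2 = 4) exceeds the cutoff and a 3′ gap leaves almost no
budget, so gapped sites within E ≤ 2 are a negligible class.

Cleavage is predicted opposite miRNA position 10, the plant-AGO slicing
register. Degradome support is categorised per transcript: with c the
count at the predicted position, M the maximum and med the median over
positions with non-zero counts — category 0 (c > 1, unique maximum),
1 (c > 1, shared maximum), 2 (1 < c < M, c > med), 3 (1 < c ≤ med),
4 (c = 1); zero counts are no hit. The T-plot p-value is an explicit
seeded shuffle test: the empirical probability, over 100
dinucleotide-preserving shuffles of the miRNA, of achieving anywhere on
the transcript an alignment at least as good (E ≤ observed) with a site
at least as well supported (category ≤ observed), with the standard
(1 + k)/(1 + n) estimator. It is deterministic given a seed and is not
claimed to equal any particular tool's analytic p-value; planted-truth
recovery, not p-value equality, is the tested contract. Hits are retained
when category ≤ 2, p < 0.05 (strict) and the miRNA is expressed.

## The synthetic-data generator

`simulate_dataset()` emulates the study design with complete ground
truth:

* **Genome and hairpins.** A uniform-composition toy genome (default
  60 kb) with 10 planted precursors: 6 nt of extra stem + a 20–22 nt
  mature + a 15 nt A/C-only terminal loop (A/C cannot self-pair, keeping
  the loop a loop) + the reverse-complement star carrying 2 single-C
  bulge insertions + the closing stem. The generator asserts that every
  planted precursor passes all eight criteria under the bundled folding
  model and regenerates failing draws.
* **Reference.** A configurable fraction (default 0.5) of planted matures
  is copied into the miRBase-like reference; the rest must be
  rediscovered as novel. Five decoy reference entries absent from the
  genome probe the genome-presence rule.
* **Libraries.** 4 × 3 libraries at 10⁵ background reads each. miRNA
  counts are negative binomial (variance = μ + 0.1 μ²; the study gives no
  noise model, and NB is the standard overdispersed choice — dispersion
  configurable down to Poisson) around six archetype RPM templates:
  A (2000, 200, 200, 2000), B (3000, 800, 250, 150),
  C (900, 1000, 1100, 40), D (200, 200, 2500, 200),
  E (2000, 100, 1500, 100), F (100, 200, 1500, 2600). The templates are
  fixed numeric encodings of the six verbal archetype shapes (high at 10
  and 40; declining; lowest at 40; peaking at 30; high at 10 and 30; high
  at 30/40), chosen once for mutual separation so cluster-recovery tests
  are deterministic in expectation. Ten high-abundance decoy tags at
  non-hairpin loci (500 RPM) probe the discovery specificity.
* **Background.** Reads drawn from non-planted genome positions with a
  fixed length mixture putting 29.9% of reads at 24 nt and 13.5% at
  21 nt, the dominant modes of plant seed sRNA libraries.
* **Degradome.** One 1-kb transcript per planted miRNA with a
  reverse-complement target site (one mismatch planted at miRNA position
  ≥ 14, keeping E ≤ 2), a count spike of 10 at the position opposite
  miRNA position 10 over a 0/1 background — a category-0 peak by
  construction — plus decoy transcripts without sites.

Everything is a pure function of the configuration: each generator stage
draws from a seed derived from `config$seed`, so a dataset is reproduced
exactly from its config.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: sequencing errors and adapters, multi-locus
miRNA families and isomiRs, genome repeats, thermodynamically realistic
folding landscapes, degradome background structure beyond uniform noise,
and library-to-library depth variation. Recovery contracts on synthetic
data validate the pipeline's logic, not its sensitivity on real tissue.

## Problem sizes and reproducibility checks

The bundled checks run at deliberately compact sizes: ten planted
hairpins and ten decoys per discovery run at depth 10⁵ per library;
cluster recovery measured on a 60-miRNA cohort (10 per archetype), since
partition agreement over ten items split six ways is dominated by
single-draw noise; the null-network calibration on 200 independent
profiles (19,900 pairs); folding verified against exhaustive enumeration
up to 18 nt; mature-matching against a literal rule checker on 10⁴ random
pairs. `scripts/acceptance.R` reruns the full set from scratch under a
caller-supplied seed and writes the resulting quantities as JSON; two runs
with the same seed produce byte-identical pipeline outputs.

## Known limitations

* The bundled fold model ranks structures by pair weight, not free
  energy; its MFE and MFEI values are internally consistent but not
  comparable to thermodynamic folders numerically.
* Ungapped target scoring cannot represent bulged target sites; at the
  E ≤ 2 cutoff this excludes only a marginal class, but looser cutoffs
  would need a gapped aligner.
* Chance hairpins in random sequence can genuinely satisfy all eight
  criteria (observed at roughly 0.3% per decoy locus in simulation);
  the criteria bound, but cannot eliminate, structural false positives.
* The known/novel classifier assumes a single canonical reference; it
  does not reconcile reference versions beyond the mismatch re-check
  rules.
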