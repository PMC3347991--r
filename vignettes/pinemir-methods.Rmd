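---
title: "pinemir: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pinemir: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinemir)
```

# The problem

Conserved plant miRNAs can be recovered from an mRNA/EST assembly without a
genome: pri-miRNAs are Pol II transcripts with caps and poly(A) tails, so
fragments of them are present in transcriptome libraries. The pipeline
finds transcripts harboring near-exact copies of known mature miRNAs,
folds the surrounding sequence, and keeps only loci whose structure looks
like a genuine pre-miRNA hairpin. Structure is the decisive gate: mature
homology alone is common among repeats and fragments, and surveys of this
kind routinely discard homologous sequences that cannot fold — which is
exactly what the packaged decoy tests emulate.

# Homology model

Each known mature (18–26 nt) is placed ungapped at every offset of every
transcript, on the + strand and on the reverse complement (precursors do
occur on the antisense strand of an assembled contig, and the synthetic
world plants some there). A placement is a hit when its Hamming distance
is at most `max_mismatch = 2`. The original surveys ran BLASTN, whose
exact scoring is not recoverable; the decisive filter in practice is the
2-mismatch bound, which is implemented exactly. Score and E-value are
provided for the conventional triage (`E < 1e-2` OR `score > 32`, both
strict) under a megablast-like model: `score = 2*matches - 3*mismatches`,
`E = K*m*n*exp(-lambda*score)` with packaged constants `K = 0.71`,
`lambda = 1.33`. With these constants a full-length 2-mismatch hit of a
21-mer always passes, so the filter is deliberately non-binding at
defaults; it becomes active only if the user tightens it.

# Folding model

`fold_mfe()` is a Zuker-style dynamic program over fully nested structures
with canonical pairs (A:U, G:C, G:U), minimum hairpin loop 3 nt, lonely
pairs allowed, and interior loops capped at 30 unpaired nt. The energy
model is a simplified Turner-style nearest-neighbor table packaged as
`inst/extdata/energy_params.tsv`:

* stacking free energies for all pair-over-pair stacks (Watson–Crick
  values close to the published 37 °C set; G:U-containing stacks
  approximated by class), constructed to satisfy the rotational symmetry
  `E(p1/p2) = E(rev(p2)/rev(p1))`;
* hairpin, bulge and internal loop length penalties tabulated to 30 nt
  and extrapolated as `X(n) = X(30) + 1.08 * ln(n/30)` kcal/mol;
* an affine multiloop term `3.4 + 0.4/branch + 0.1/unpaired nt`;
* no dangles, coaxial stacking, special tetraloops, or asymmetry terms.

Numerical choices: all energies are integer tenths of kcal/mol, so the
dynamic program, the standalone structure scorer (`energy_of()`) and the
exhaustive enumeration oracle (`enumerate_mfe()`, ≤ 40 nt) agree exactly
with no floating-point tolerance. The traceback is deterministic,
resolving ties by preferring to pair the leftmost undecided position and
then by a fixed case order (interior before multiloop before hairpin);
this realizes the "prefer paired, then smallest structure" convention
without a full lexicographic search.

Two consequences worth knowing:

* **Absolute energies are model-dependent.** The packaged table is not
  MFOLD's, so refolded MFE values differ from energies printed in
  historical catalogs. Catalog-level statistics therefore treat printed
  MFEI values as given inputs; the folding engine is validated against its
  own enumeration oracle instead.
* **The reverse-complement mirror property holds only where G:U cannot
  pair.** Complementing a sequence maps a G:U pair onto A:C, which does
  not pair, so MFE equality under reverse complement is asserted (and
  true) only on two-letter {G,C} or {A,U} test hairpins.

`parse_external_fold()` accepts `sequence\nstructure (energy)` Vienna
text, validates all structure invariants, and lets any external folder be
substituted for the internal engine.

# Hairpin criteria

A candidate window passes when all of the following hold (strictness read
literally from the standard criteria sentence, all configurable through
`criteria_config()`):

| criterion | rule | boundary |
|---|---|---|
| folding energy | `MFE <= -15` kcal/mol | −15 passes |
| MFEI | `AMFE / (100 - AU%) > 0.5` | 0.50 fails |
| A+U content | `30 <= AU% <= 70`, computed on the precursor window | 30 and 70 pass |
| duplex | mature:star mismatches `< 6` | 6 fails |
| arm | mature wholly within one arm | loop overlap rejects |

`AMFE = |MFE| * 100 / length` normalizes energy per 100 nt; dividing by
the G+C percentage gives the MFEI, which separates miRNA precursors
(typically ≈ 0.9) from tRNA/rRNA/mRNA folds (≈ 0.6–0.7). A+U is computed
on the window, not the mature: printed per-record A+U values in the
worked-example catalog are consistent only with precursor-level content.

Duplex conventions: G:U counts as *paired* here (it is a structural pair),
unlike in target scoring; the star is the partner stretch extended by the
2-nt 3′ overhang of Dicer processing; each bulged nucleotide on either
strand counts 1 mismatch. Candidate windows come from a flank grid
(20–280 nt in 20-nt steps on each side of the hit, clipped to the
transcript and deduplicated) — the historical pipelines never documented
their windowing, so the grid is exposed in the configuration, and the
best passing window per hit is chosen by highest MFEI, then shorter
window, then leftmost start.

# Catalog

Families are inherited from the nearest reference mature (best ungapped
sliding alignment, overhanging positions counting as mismatches, at most
4) rather than by de novo clustering: reference catalogs keep
near-identical matures in distinct families when their precursors differ,
so clustering cannot reproduce accepted family structure. Members get
letter suffixes in order of precursor id and coordinate. Percentages in
summaries are rounded half-up to integers to match the conventional
presentation; MFEI moments to 2 decimals. Note the worked-example catalog
reports its 5′-U fraction as 56% (= 19/34 rounded); the historical figure
of "58%" for the same count is not reproducible from any stated
denominator, so the count (19) is the authoritative statistic.

# Target prediction

The penalizing score aligns the miRNA 5′→3′ against the site read 3′→5′:
Watson–Crick 0, G:U wobble 0.5, mismatch 1.0, gap 2.0, all doubled at
miRNA positions 2–7 (the seed, where cleavage-competent pairing is
obligatory). At most one bulge (`max_gaps = 1`) is allowed — more gaps
make the ≤ 3 acceptance cut meaningless. A gap is "in seed" when it falls
between/at miRNA positions 2–7. Scanning evaluates every window of length
`k-1`, `k`, `k+1`; overlapping acceptable windows collapse to the
minimum-score placement. The predicted cleavage position is the
transcript coordinate 5′ of the bond between the nucleotides pairing
miRNA positions 10 and 11; a bulge between those positions flags the site
instead of guessing. Alignments render as three lines (target 5′→3′,
match symbols, miRNA 3′→5′) with `|` for Watson–Crick, `o` for wobble,
and spaces for mismatches, and re-score to the identical penalty.

# Expression

`relative_quant()` implements plain 2^−ΔΔCt: replicate Ct values are
averaged per gene and sample, normalized against the reference gene's
mean Ct in the same sample, and expressed relative to the calibrator
sample (fold ≡ 1 there by construction). Amplification efficiency is
fixed at 2 — no efficiency correction, matching standard comparative-Ct
usage. Replicate dispersion is the sd of replicate-level ΔCt propagated
through the exponent, reported as `fold * (2^sd - 2^-sd)/2`.

# The synthetic world

`default_sim_spec()` states the world used by the end-to-end tests:

* 20 planted precursors built from the worked-example matures, with
  duplex mismatches cycling 0–3 and every fourth planting on the minus
  strand; 20 decoys; 20 background transcripts.
* Transcript lengths 220–320 nt — short assembly fragments typical of
  early short-read transcriptome assemblies (the same regime that
  produced 76–526 nt precursor records), which also keeps a full
  fold-everything run at desk scale.
* Background composition uniform over {A,C,G,U} (a configurable A+U bias
  exists); real transcriptome composition is unavailable and uniform
  background makes planted hairpins the dominant folding signal.
* Decoys carry the intact mature inside a dinucleotide-shuffled
  (Altschul–Erikson) hairpin context: homology is preserved, local
  composition is preserved, the stem is destroyed. A green decoy test
  therefore establishes that the *structural* criteria, not homology,
  gate acceptance — it does not establish specificity against real
  genomic repeat families, which the generator does not model.

`make_hairpin()` realizes a requested duplex-mismatch count `m` as
`mature + loop + modified star`: each pair of mismatches is a star
substitution (a 1×1 internal loop, counting one bulged nucleotide on each
strand), and an odd count drops the star nucleotide opposite the mature
5′ terminus, leaving it dangling (counting exactly 1). This construction
is MFE-stable: a mid-stem single bulge is *not* (the optimizer absorbs it
into a cheaper 2×1 loop, which is why naive "delete one star base"
constructions do not round-trip), and the property suite verifies exact
recovery of `m` ∈ 0–5 across the full mature panel. The loop alternates
C/A so it cannot extend the stem. A discovery run on perfect plantings
also catalogs the star arm as a second locus — the star of a perfect
hairpin is itself a full-length homolog on the opposite strand — which is
faithful to how both arms of real precursors surface in surveys.

Engineered target sites place wobbles/mismatches only at weight-1
positions outside the seed and away from positions 10/11, so intended
penalties in multiples of 0.5 are met exactly and cleavage mapping stays
defined; a penalty not reachable from {0.5, 1.0} units raises an error
rather than approximating.

# Degenerate inputs and edge policies

* `N` is tolerated on input only when explicitly allowed; N-containing
  transcripts are excluded from homology search by default, and an N
  never matches or pairs anything.
* Coordinates are 0-based half-open on the + strand internally;
  conversion to 1-based inclusive happens only in the GFF3 writer.
* Fragment merging along a guide precursor requires exact agreement over
  ≥ 20 nt of projected overlap; any disagreement leaves fragments
  unmerged (assembly errors argue for conservatism).
* A+U of exactly 100% makes MFEI undefined and is an error, not a 0.

# Known limitations

* The folding engine reports a single MFE structure: no suboptimals,
  partition function, or pair probabilities.
* Energy parameters are simplified; absolute MFEs should not be compared
  against other folders, only within runs of this package.
* The homology E-value/score model is a stand-in for an unrecorded BLASTN
  configuration; only the mismatch bound is faithful by construction.
* Family assignment requires a labeled reference; unassignable matures
  are reported as `unassigned` rather than clustered into new families.
* The expression module assumes a single reference gene and equal
  amplification efficiency of 2 for all assays.
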