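---
title: "Gene-sharing taxonomy of tailed archaeal viruses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-sharing taxonomy of tailed archaeal viruses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `viratax`, the defaults and why
they were chosen, what the synthetic generators do and do not emulate, and
the numerical decisions a user auditing results will want to know. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The problem and the approach

Tailed archaeal viruses diverge so fast at the nucleotide level that
alignment-based taxonomy stops working well above the species rank. What
is conserved is (a) which proteins a genome encodes and (b) the order
they appear in. `viratax` therefore classifies genomes by gene sharing:
exact protein alignment defines homology, homology defines protein
clusters (PCs), PCs define per-genome signatures, and a composite
generalized Jaccard (CGJ) distance over those signatures defines the
dendrogram that family demarcation cuts.

## 2. Alignment and homology thresholds

Protein pairs are aligned by exact Smith–Waterman (no heuristic seeding;
proteomes of tailed viruses are small enough that exactness is
affordable). Scoring is BLOSUM62 with gap open 11 / extend 1, the default
of the BLAST family of tools with which the demarcation thresholds were
originally established; a gap of length L costs `11 + L`. Unknown
residues (X) score 0. E-values use the Karlin–Altschul form
`E = K·m·n·exp(−λS)` with the published gapped BLOSUM62 parameters
λ = 0.267, K = 0.041.

Two search-space policies exist:

* `pairwise_mn` — `m × n` of the two sequences. Used by `all_vs_all()`:
  homology there is a statement about a *pair* of genomes ("is this gene
  shared between A and B?"), and a pairwise search space keeps the call
  independent of how many other genomes happen to be in the collection.
  A database-scale space would make the same protein pair homologous in a
  small study and non-homologous in a large one, which is the wrong
  semantics for demarcation statistics.
* `database_mN` — `m × Σ subject lengths`. Used by the provirus screen,
  which genuinely is a database search (every host ORF against all
  reference proteomes), where collection-size-dependent stringency is the
  correct behaviour.

Homology for gene-sharing statistics requires identity > 30% **and**
E < 1e−25 (both strict, matching the "over 30%" / "< 1e−25" wording the
thresholds come from). Identity is computed over all alignment columns,
gaps included in the denominator — the convention the 30% figure
presupposes.

The batch all-vs-all score matrix is computed by a striped SSE2 16-bit
score-only kernel (Farrar's scheme); the scalar three-state kernel with
full traceback serves the exported single-pair operations. The test suite
cross-validates the striped kernel against the scalar one and both
against a brute-force DP oracle written independently in R.

## 3. Signatures, CGJ distance, demarcation

PCs are single-linkage connected components of the thresholded homology
graph — the transitive closure of the pairwise "homologous" relation.
This is deterministic and parameter-free, unlike MCL-style clustering,
and matches a demarcation criterion that is itself a pairwise threshold.

A genome's **content** vector holds, for every PC, the bit score of its
best member gene aligned to the PC representative (longest member, ties
by id), 0 when absent. Its **order** is the PC sequence along the genome.
For two genomes:

* `J_content` = generalized Jaccard `Σ min / Σ max` over content vectors;
* `J_org` = LCS of the two shared-PC orders / number of shared PCs, where
  the LCS is taken over both orientations and (for circular replicons)
  all rotations — gene order has no canonical strand or origin;
* `CGJ = 1 − sqrt(J_content × J_org)`.

The geometric mean is a deliberate design choice where the source method
defers to its own references: it forces distance 1 when *either* signal
is absent, so gene content alone can never make two organizationally
unrelated genomes look close, and vice versa. Families are leaves joined
below 0.8 in a UPGMA dendrogram (average linkage mirrors the heat-map
dendrograms this style of analysis publishes; ties broken by smallest
member id for determinism). Genera are single-linkage components over
pairs with symmetric shared-gene fraction > 60%, computed within
families, so the genus partition refines the family partition by
construction. The "typically share more than 60%" hedge in the source
description is preserved as a parameter (`genus_min_shared`), not as
hard-coded exceptions.

The directed shared fraction (fraction of A's proteins with a homolog in
B; paralogs counted once) is reported alongside the symmetric mean;
genus demarcation uses the symmetric form to avoid artifacts from
unequal proteome sizes.

## 4. Host range

Raw plating titers below the 10³ pfu/mL detection limit are recorded as
0. Each virus row is normalized by its isolation-host titer (set to 1); a
per-virus substitute reference titer is supported for the case where the
isolation host forms no lawn (the reference value 2×10⁸ pfu/mL then
stands in for EOP 1). Normalization is idempotent. Log10 categories
round half away from zero — the binning rule is not stated in the source,
so the choice is documented here and only affects boundary values.

`hs` of two viruses is shared sensitive hosts over the *union* of
sensitive hosts ("shared/total" read as Jaccard: bounded in [0, 1] and 1
exactly for identical host ranges). Sensitivity means any detectable
plaque formation after normalization, not a normalized-EOP cutoff. The
association between hs and adhesin identity is summarized by Spearman
rank correlation with a Mantel-style permutation test (virus labels
permuted, one-sided for positive association). The permutation test is an
extension: the original analysis presents heat maps without a test.

Adhesin groups are single-linkage clusters at ≥ 45% global identity. The
45% default is a free parameter: the original groups were delimited
visually on a phylogeny, which has no programmatic equivalent.
Neighbor joining substitutes for maximum-likelihood trees here — the
groups in question are deep, well-separated clades for which distance
methods recover the same grouping; ML is out of scope.

## 5. Motif analysis

Motif counting is overlap-inclusive; palindromic motifs (GATC) count once
per site on a single strand, non-palindromic motifs add reverse-strand
occurrences — per-kbp site frequencies for palindromic Dam sites are
therefore directly comparable to published per-kbp figures. N never
matches. Circular sequences are scanned as doubled-minus-one so
origin-spanning sites count exactly once.

The depletion diagnostic compares the observed count to its expectation
under a Markov chain (order 0–2, default 1) fitted to the same sequence:
`E[count] = Σ_w P(w) · positions` over motif-compatible words w. The
null model and the observed/expected ratio are an added diagnostic — the
source analysis reports raw frequencies only.

The MTase-carriage comparison is an in-repo Mann–Whitney U (exact by
complete enumeration for groups of ≤ 8, normal approximation with tie
correction otherwise; U counts first-group-greater pairs, matching
`wilcox.test`'s statistic, which the tests use as an oracle).

## 6. Provirus detection

The blastx screen is replaced by naive ORF calling (start ATG/GTG/TTG,
table 11, ≥ 50 aa) followed by protein–protein Smith–Waterman — one
alignment engine for the whole package, with equivalent sensitivity for
intact proviruses at E < 1e−5. Hits are chained (≥ 10 hits, inter-hit
gaps ≤ 15 kb; invented, configurable defaults).

Attachment sites are direct repeats flanking the integrated region. Two
random 2-kb windows contain ~12–14 bp direct repeats by chance alone
(expected count ≈ `nL·nR·(3L+1)·p₂^L` with p₂ the sum of squared base
frequencies), so a plain "longest repeat ≥ 12 bp with ≤ 1 mismatch" rule
would report an attachment site almost everywhere. Candidates are
therefore ranked by a mismatch-penalized score (length − 4 × mismatches;
a mismatch must "buy" about four extra matched positions, the
log-odds-scale cost of the ≈ 3L-fold larger candidate space) and reported
only when the score exceeds the chance threshold computed from the actual
window sizes and the host's base composition (default tolerated
expectation 0.005). The 12-bp minimum remains a hard floor. Search
windows straddle the region edges because detected boundaries are fuzzy
(ORFs can extend a few hundred bp beyond the integrated sequence).

Family assignment of a provirus region uses the same demarcation
statistic as the reference taxonomy: symmetric shared fraction against
one representative per family, accepted at ≥ 20% (the lower bound of the
within-family sharing range). Integration targets are classified from
host annotations overlapping attL (tRNA / CDS / intergenic), "unknown"
without annotations.

## 7. Synthetic data: what it emulates, what it does not

`gen_taxonomy_set()` plants a three-level hierarchy (defaults 3 families
× 2 genera × 4 genomes): 15 family-core proteins diverged to 45%
expected identity between genera, 20 genus-core proteins at 75% identity
between genomes, 10 private random proteins per genome. Protein evolution
is per-site uniform substitution (a site moves to one of the 19 other
residues); branch error rates are solved in closed form from the
semigroup of the uniform-substitution channel so the *pairwise* leaf
identities hit the stated targets. Genes are back-translated with
GC-weighted synonymous codons (default GC 0.62 — haloarchaeal genomes
are GC-rich) into genomes with 50–150 bp spacers, all on the forward
strand in conserved order.

Ancestral protein lengths default to 160–240 aa. This is the one free
parameter that interacts with the E-value threshold: a 45%-identity
homolog pair must clear E < 1e−25, and at ~150 aa that is marginal
(pass probability ≈ 0.9 per pair), which pushed the realized
within-family shared fraction below the stated 20–50% calibration band.
At 160–240 aa the threshold is cleared essentially always and the
realized band is ≈ 25–35%. The generator does **not** emulate: indels,
rate heterogeneity, paralogy, strand mixing, rearrangements, or
horizontal transfer. A green taxonomy-recovery test therefore
establishes that the demarcation machinery recovers a planted
gene-sharing structure at the stated separations — not that real genome
collections are this clean.

`gen_eop_matrix()` draws block-structured titers (base 2×10⁸ pfu/mL —
the published reference-titer scale — with lognormal σ = 0.5 noise), a
2% off-target "leak" at 10⁻³–10⁻⁶ relative EOP, and the 10³ pfu/mL
floor. `gen_motif_genomes()` adjusts an i.i.d. GC-weighted background
(an order-1 chain with identical rows) by destroying or planting motif
occurrences until observed/expected is within 10% of the target factor.
`plant_provirus()` inserts att + virus + att into an i.i.d. host contig
and forces the bases flanking the planted repeats to differ — without
that guard, chance single-base extensions would make exact att recovery
impossible for roughly half of all seeds, for any detector.

All generators are deterministic given a seed (byte-identical outputs).

## 8. Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based inclusive in
  GenBank/tabular output. Origin-spanning features carry a wraparound
  flag with `end > length`.
* Ambiguity codes other than N are rejected at genome construction.
* Ties: UPGMA and NJ pick the pair whose lexicographically smallest
  member sorts first; PC ids order clusters by smallest member;
  co-optimal alignments resolve by traceback preference (diagonal first).
* Generalized Jaccard of two all-zero vectors is 0 with a warning, as is
  hs of two empty host ranges.
* `classify()` refuses < 2 genomes; stage errors carry the stage name.
* Mann–Whitney p-values use a 0.5 continuity correction in the normal
  branch; exact enumeration is `choose(n+m, n)` assignments.
* The NJ negative-branch rule clamps to 0 and moves the deficit to the
  sister branch, preserving the pair distance.

## 9. Testing strategy and limitations

The suite runs offline in roughly 12 minutes on one CPU; the heavy item
is the 20-seed taxonomy-recovery criterion (each seed is a full 24-genome
all-vs-all of ~1,080 proteins). Oracles are independent routes: an R DP
oracle for alignment scores, `hclust`/`ape::nj` for tree construction,
`wilcox.test` for the U statistic, a regex scanner for motif counts, and
generator truth labels for recovery tests.

Known limitations: no HMM-profile signatures (PC bit scores stand in for
profile scores); genus assignment uses shared-fraction components only;
no ML phylogenetics or bootstrap supports; the provirus scan targets
intact, recent integrations (degraded proviruses with few intact ORFs
fall below the hit-chain threshold); and the quantitative acceptance
targets tied to the original isolate collection are not recomputable
offline, so the property-based suite is the binding acceptance surface.
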