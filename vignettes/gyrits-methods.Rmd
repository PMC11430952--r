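---
title: "Methods: motif-anchored ITS annotation and partitioned distances"
author: "gyrits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-anchored ITS annotation and partitioned distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyrits)
```

## The marker and the problem

The nuclear ribosomal ITS region (ITS1–5.8S–ITS2) is the standard marker
for species identification and phylogeny in the viviparous flatworm family
Gyrodactylidae. Public submissions of this marker are of very uneven
quality: the flanking 18S/28S tails are trimmed inconsistently, some
records carry sequencing artefacts in the conserved ends, and 5.8S genes
that deviate from the family's invariant length are a red flag for
sequence quality. `gyrits` packages the checks and computations a careful
analyst performs on this marker:

1. **Motif-anchored QC and partitioning** — locate the conserved boundary
   motifs, excise flanks, split the record into ITS1 / 5.8S / ITS2, and
   flag deviations.
2. **Partitioned genetic distances** — uncorrected p-distances and
   pairwise maximum-likelihood (ML) distances under per-region
   GTR-family models with discrete-gamma rate heterogeneity.
3. **Group summaries and taxonomy support** — mean intra/inter-group
   distances, monophyly and support of proposed genera on input trees
   (trees are consumed, never inferred), and threshold-based species
   delimitation.
4. **A synthetic-data generator** with exact ground truth, so that every
   stage is testable end to end without network access.

## Boundary motifs and the annotation model

Four short motifs pin the region boundaries in viviparous gyrodactylids:

| motif | canonical | location |
|---|---|---|
| M18S | `ATCATTA` | 3' end of the 18S gene (end of the 5' flank) |
| M58S_5p | `CAACTC` | 5' end of the 5.8S gene |
| M58S_3p | `GTCGGCT` | 3' end of the 5.8S gene |
| M28S | `CCTGACC` | 5' end of the 28S gene (start of the 3' flank) |

The 5.8S gene is exactly **157 bp** in this family; deviations indicate
indel artefacts and are flagged, not silently accepted.

The search tolerates at most **one substitution** per motif (documented
natural variants are all single transitions or transversions, e.g.
`ATCACTA`, `CAACTT`, `TAACTC`, `GTCGGCA`, and the longer 28S variants are
single-error derivatives of `CCTGACC`). Search windows default to the
first/last **120 nt** for the 18S/28S motifs — GenBank submissions retain
variable flank lengths and 120 nt comfortably covers them while limiting
the chance of random interior matches; the window is configurable. The
5.8S motifs are searched in the interior between the outer motif hits.

Decisions the data sources leave open, resolved here as package policy:

* **Coordinates** are 1-based inclusive everywhere a user sees them.
* **Tie-breaking** in `find_motif()`: fewest mismatches first, then the
  hit closest to the bounded flank (head: rightmost; tail: leftmost),
  because the motifs bound the excisable flanks.
* **5.8S pairing**: among candidate 5'/3' motif pairs, the pair whose
  implied 5.8S length is closest to 157 wins, then fewest total
  mismatches, then leftmost. The 157-bp rule is the strongest prior
  available.
* **Missing outer motifs**: a missing M18S leaves ITS1 *incomplete*
  starting at position 1; a missing M28S leaves ITS2 *incomplete* ending
  at the last position. A region is *complete* iff both of its bounding
  motifs were located — motif presence is the only evidence used.
* **IUPAC codes** inside a motif count as a match when the code includes
  the canonical base (recorded, not flagged) and as a mismatch otherwise
  — conservative QC.
* **Disposition**: any missing motif &rArr; `review`; any variant or
  length flag &rArr; `pass_with_warnings`; else `pass`. Records with
  aberrant ends are retained with caveats rather than discarded, matching
  curation practice for this marker.
* **Totals are sums of parts.** Published diagnosis totals occasionally
  disagree with the sum of the printed region lengths (e.g. a 343+157+289
  record printed as 788 bp). `diagnose(reported_total=)` logs such
  discrepancies and always reports the arithmetic sum.

## Substitution models and distances

`substitution_model()` builds reversible GTR-family models. The two
families relevant for this marker are **TVM+F+Γ4** (spacers: transition
exchangeabilities constrained equal, empirical base frequencies) and
**SYM+Γ4** (5.8S: six free exchangeabilities, uniform frequencies). The
rate matrix is `q_ij = s_ij π_j`, normalized to one expected substitution
per site at stationarity, so distances are in substitutions/site.
Rate heterogeneity uses **category means** of the discrete gamma
distribution (equal-probability categories, C = 4 by default): the
simulator and the likelihood machinery share this single discretization,
and the category means are computed in closed form from incomplete-gamma
differences (validated against numerical quadrature at 1e-8).

**p-distances** use pairwise deletion: a site is compared when both rows
carry an unambiguous base. The deletion policy for published matrices of
this marker is typically unstated; pairwise deletion maximizes usable
sites in ragged ITS alignments, and complete-set deletion is available at
the matrix level.

**ML distances** maximize the two-sequence likelihood
$\ell(t) = \sum_{\text{partitions}} \sum_{x,y} n_{xy} \log \sum_c
\tfrac1C \pi_x P_{xy}(t r_c)$ with **one shared branch length across
partitions** (a single likelihood distance per pair is the reported
quantity; per-partition rate multipliers are deliberately not fitted, and
published matrices may therefore differ by a scale factor — a known
caveat). Optimization is bounded scalar search on `[1e-6, 10]` with
tolerance 1e-8; estimates against the upper bound are flagged
`saturated` rather than silently truncated. Model parameters are
estimated **once per partition** from the whole alignment and then fixed
for all pairs, the standard distance-matrix practice.

`estimate_model_params()` maximizes the sum of all pairwise two-sequence
log-likelihoods (a composite likelihood). Branch lengths are profiled
out — re-optimized inside every objective evaluation — because the
per-pair lengths, the transition exchangeabilities and the gamma shape
share a likelihood ridge along which plain coordinate alternation crawls.
Initialization is deterministic (all exchangeabilities 1, α = 1, branch
lengths from the Jukes–Cantor formula), so results are independent of
input order. Degenerate partitions (a single distinct row) fall back to
JC defaults with a warning.

## Taxonomy operations

**Monophyly** uses unrooted bipartition semantics: a group is
monophyletic iff some edge splits the tips exactly into the group versus
its complement. With a designated outgroup, groups containing the
outgroup are rejected, which reproduces rooted-tree readings. When both
the group side and its complement side match (the two child edges of a
root), support is reported from the edge subtending the group itself.
Polytomies require an exactly matching bipartition. Support labels parse
`bp/pp` compound node labels (e.g. `"99/1.0"`) and single values
(values within [0, 1] read as posterior probabilities); the customary
display thresholds bp ≥ 75 and pp ≥ 0.95 are the configurable defaults
for "well supported".

**Species delimitation** is single-linkage clustering at a p-distance
threshold, default **1.3 %**, the customary species-level cutoff for this
marker in this literature. The split is strictly greater-than — a pair at
0.014 separates, a pair at 0.013 stays together — because distances
"slightly above 1.3 %" are read as evidence for distinct species. The
threshold applies to p-distances; ML-scale matrices are rejected by a
unit guard unless forced. Whether the 1.3 % rule was originally stated on
a corrected distance is not re-derivable from the secondary sources; the
p-distance default plus the guard makes the choice explicit.

## The synthetic-data generator

`make_reference_its()` emits the *pre-excision* form of a submission: an
18S tail ending in `ATCATTA`, ITS1, a 157-nt 5.8S bounded by
`CAACTC`/`GTCGGCT`, ITS2, and a 28S head starting with `CCTGACC`, with
exact truth coordinates. Design choices:

* **Background composition** is i.i.d. from a configurable base-frequency
  vector, default uniform — no empirical composition for gyrodactylid
  ITS is established, so the default is neutral and configurable rather
  than calibrated.
* **Motif-clean backgrounds.** Random background can contain spurious
  near-matches of the canonical motifs; the generator redraws background
  positions inside any window that could confuse a single-mismatch
  search, so truth coordinates are unambiguous by construction. Windows
  that can never outrank the true hit (strictly more mismatches under a
  fewest-mismatches rule) are left alone; for the interior 5.8S motifs,
  whose pairing is scored by implied length before mismatches, all stray
  candidates are removed.
* **Mutations** (`apply_mutations()`) cover the artefact classes seen in
  real submissions: single transitions/transversions in a motif, 1–2 nt
  indels in the 5.8S, and truncations that remove a boundary motif plus
  adjacent spacer bases (emulating submissions trimmed before
  deposition). Each mutated record carries the exact flags and region
  lengths a single-mismatch annotator must report, which makes the
  round-trip test (`200` records, every flag and length exact) a sharp
  end-to-end check.
* `simulate_pair()` and `simulate_alignment_on_tree()` are
  substitution-only (no indels, no alignment-process simulation — both
  out of scope); per-site gamma categories are drawn once per site and
  shared across the tree.
* All randomness flows through explicit seeds; identical seeds give
  identical output, and the generator restores the caller's RNG state.

### Synthetic hologenotype reconstructions

`synthetic_hologenotypes()` rebuilds the *structure* of published
reference (hologenotype) diagnoses — region lengths, boundary heptamers
and motif variants — over random backgrounds. They are labelled
synthetic (`_syn` ids) and are **not** the real GenBank records; what
they validate is that the annotator recovers the printed region
architecture (e.g. 345/157/332 = 834 bp with `TGTATTG…TAATTTT` ITS1
boundaries) from a full-length record, including the tolerated motif
variants (`CAACTT`, `CCCGACC`, `ATCACTA`-style ends). For two published
records only the trimmed total is available (751 and 1095 bp); their
ITS1/ITS2 split is a synthetic choice (297/157/297 and 500/157/438) and
only the totals are treated as checkable.

What passing on synthetic data does **not** show: robustness to real
chromatogram noise, chimeras, alignment ambiguity in the ITS1
repeat-rich stretch, or taxon sampling effects. Published genus-level
mean distances additionally depend on the original alignment and the
tree software's likelihood conventions, neither of which is recomputable
from the data shipped here; the distance machinery is therefore
validated by properties (closed-form equivalence, parameter recovery,
oracle agreement) rather than by reproducing those table values.

## Numerical choices

* Transition probabilities use the symmetrized eigendecomposition of the
  reversible rate matrix (exact, no truncation); tiny negative entries
  from roundoff are clamped and rows renormalized.
* Likelihood cells are floored at 1e-300 before `log`.
* ML distance: bounded search on `[1e-6, 10]`, tolerance 1e-8; estimates
  within 10 tolerances of the lower bound snap to it.
* Composite-likelihood fits: Nelder–Mead (maxit 500, reltol 1e-10) on
  log-scale parameters, outer loop to 1e-6, inner profiled branch
  lengths to 1e-6.
* Reports round distances to 2 decimals (matching published tables);
  full precision is retained internally and in TSV/JSON outputs.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script experiments use: 200 mutated
records for the annotation round trip; 1000 random pairs for the
p-distance oracle; 50 replicates × 10 000 sites at t ∈ {0.05, 0.2, 0.5}
for distance recovery (mean bias < 5 %); a 6-tip, 20 000-site SYM+Γ4
alignment for gamma-shape recovery (α̂ ∈ [0.6, 1.0] around a true 0.8);
100 random 8-tip trees × all 2–4-tip subsets for the monophyly oracle;
and 100 random 12-id matrices for the delimitation oracle. These sizes
give tight Monte-Carlo error at interactive runtimes.

## Known limitations

* Alignment is an explicit external step; the pipeline writes trimmed
  FASTA and resumes from a user-provided MSA.
* Tree inference, bootstrap and Bayesian sampling are out of scope;
  trees are inputs.
* The single-shared-t convention for partitioned ML distances can differ
  from tree-software "likelihood distances" by a scale factor.
* The generator does not simulate indel evolution or the alignment
  process; gapped-alignment behaviour is exercised only through the
  deletion policies of the distance functions.
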