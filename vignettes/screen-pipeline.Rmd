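---
title: "Methods: the reporter-screen analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reporter-screen analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtarscreen)
```

`mirtarscreen` implements the desk half of a library-based miRNA targetome
screen: the computational steps that surround a high-throughput
dual-luciferase reporter assay of miRNA--3'UTR interactions (MTIs). This
vignette explains the models and conventions behind each stage, the
parameters that matter, and what the synthetic-data generator does and does
not emulate.

## Library design: UTR tiling

Reporter constructs cannot hold arbitrarily long inserts, so full-length
3'UTRs are tiled into fragments of at most `target_len` nt (default 675)
with a fixed `overlap` (default 30 nt) between consecutive tiles, so no
binding site at an internal cut is lost from both fragments.
"Approximately 675 nt" is resolved into a deterministic rule: the minimal
number of fragments none of which exceeds 675 nt, with lengths as equal as
possible (difference at most 1 nt; the extra nucleotide goes to earlier
fragments). This minimizes construct count and makes the plan testable; it
is a stated convention, not a claim that any particular vendor tiling is
reproduced bit for bit.

```{r}
plan_fragments(1320)$intervals
```

## Canonical seed sites

A mature miRNA recognizes targets primarily through its seed, nucleotides
2--7 (extended seed 2--8). The four canonical site types on the target
strand are:

* **6mer** -- the reverse complement of seed 2--7;
* **7mer-m8** -- additionally complementary to miRNA position 8;
* **7mer-A1** -- the 6mer followed by an adenine opposite miRNA position 1;
* **8mer** -- both extensions.

`find_seed_sites()` performs exact Watson--Crick matching (no G:U wobble:
the screen's site definition is an exact hit). Every 6mer-core occurrence
is reported once, labelled with the maximal type its flanks support, which
avoids counting one physical site as several types; overlapping cores are
each reported. The position-1 adenine is required as a literal target `A`
regardless of the miRNA's first nucleotide -- the standard convention, which
we adopt because the assay's site lists were built that way. Coordinates
are 1-based inclusive on the fragment; BED conversion happens only in the
writer.

## Secondary structure

Site accessibility is scored on a single (MFE-style) secondary structure
per fragment. Two routes provide that structure:

1. **Ingestion** (primary): Vienna dot-bracket files or GML layouts
   produced by an external thermodynamic folder are read verbatim
   (`read_vienna()`, `import_gml()`).
2. **`fold_baseline()`** (self-contained): a maximum-weight nested pairing
   by dynamic programming with pair weights G-C = 3, A-U = 2, G-U = 1 and a
   minimum hairpin loop of 3 unpaired bases, post-filtered to remove
   isolated base pairs and G-U pairs terminating a helix. The weights rank
   pair stabilities by hydrogen-bond count; the two filters mirror common
   folding constraints against implausible lone pairs and weak helix ends.
   Ties in the DP resolve deterministically (3' base unpaired preferred,
   then the 5'-most partner), so the fold is a pure function of the
   sequence. This baseline is a light-weight structural model, not a
   thermodynamic one: it keeps the pipeline and its tests self-contained,
   while real analyses can ingest externally folded structures.

Pseudoknots are not representable; hairpin loops must enclose at least 3
unpaired bases (enforced at parse time).

### Paired-base fraction

`paired_fraction()` reports the percentage of bases marked `(` or `)` over
the site extended by a window of 0, 5 or 50 nt on each side (clipped at the
sequence ends). Window 0 asks whether the site itself is base-paired;
wider windows probe whether the surrounding region folds onto the site.

### 2D layout and the coverage score

Pairedness alone ignores geometry: a site in a dense multiloop is less
approachable than one on a long open strand even at equal pairing. The
coverage score works on a planar drawing of the structure graph
(vertices = bases; edges = backbone bonds plus base pairs).
`layout_2d()` uses the classic radial-loop drawing -- each loop on a
circle, helices as parallel strands, exterior bases on a line -- and then
rescales so that the mean backbone-adjacent distance is exactly 1. That
rescaled spacing defines the **length unit** in which all radii are
expressed, which also makes externally produced layouts (whatever their
native scale) comparable after `import_gml()`.

For a site \(S\) and radius \(r\), the score counts the bases inside a
closed Euclidean ball around each site base and averages:

\[
\mathrm{cov}(S, r) \;=\; \frac{1}{|S|}\sum_{s \in S}
\#\{\, v \in V : \lVert v - s \rVert_2 \le r \,\}.
\]

The ball is closed, so each base counts itself and every score is at least
1; boundary membership is decided with a 1e-9 tolerance so that exact
unit distances survive floating-point rescaling. When a fragment carries
several sites, the site with the *smallest* coverage -- the most
accessible -- represents the fragment (`min_coverage_over_sites()`), with
ties resolved to the 5'-most site. The default radius sweep
`r default_radii()` spans nearest-neighbour contact (0.8, below unit
backbone spacing) to a broad neighbourhood (6 units).

## Reporter statistics

Measurements arrive as firefly/renilla luminescence pairs for 4 biological
replicates in technical duplicates, for each construct co-transfected with
a miRNA expression plasmid or with the empty vector. The technical
duplicates share a lysate, so they are averaged *within* each replicate
before any testing; the per-replicate normalized RLU is the test ratio
divided by the same replicate's control ratio (ratio of ratios, n = 4 per
group). The alternative reading -- treating all 8 wells as independent --
would overstate the degrees of freedom.

An MTI is **validated** when its mean normalized RLU is below 0.90 *and*
the two-sided Welch test of test-versus-control replicate ratios gives
p < 0.05. The p values are nominal by design -- the screen's validation
rule is per-construct -- but a Benjamini--Hochberg column is emitted
alongside for readers who want it. Effect categories bin the mean RLU:
strong (< 0.70), moderate (0.70--0.90), none (0.90--1.10), and upregulated
(> 1.10 with p < 0.05); the up-regulation threshold is chosen symmetric to
the repression cutoff since occasional activation does occur in such
screens but no separate criterion is conventional.

Gene-level results take, over all fragments of a gene, the maximal
reduction (minimum mean RLU) and the maximal significance (minimum p)
independently -- they may come from different fragments -- and a gene is
validated if any fragment is. `build_network()` then places the gene-level
MTIs in the complete bipartite gene x miRNA graph with per-edge
`predicted` / `tested` / `validated` flags and summary rates.

## Structure--repression association

`structure_rlu_scan()` computes Pearson correlations (with the usual
t-based two-sided p) between each accessibility metric and the mean
normalized RLU, per miRNA and per radius. Cells with fewer than 3 MTIs or
a constant metric are flagged rather than silently dropped. The site that
feeds the window metrics when a fragment has several is, by default, the
one selected by minimum coverage at radius 2 (`site_selection =
"min_coverage"`); radius 2 sits mid-sweep, large enough to see past
immediate backbone neighbours and small enough to stay local. A
`"five_prime_most"` alternative is available since the choice is a
convention, not a measurement.

## The synthetic-data generator

Real per-construct luminescence data are wet-lab measurements; the
generator stands in for them so that every stage is testable end to end
against a known truth.

* **Sequences**: uniform random background with exact site patterns
  written at chosen positions; a background that spuriously creates
  additional sites for any panel miRNA, or flanks that would upgrade a
  planted site's type, is rejected and re-rolled (capped at 1000 attempts
  for bounded runtime). Planted sites are kept strictly inside one
  fragment and clear of the 30-nt overlap zones so the fragment-level
  truth table is exact.
* **Effects**: each tested MTI draws a class -- repressed (probability
  0.60, true mean uniform on 0.40--0.88), upregulated (0.02, true mean
  1.30), otherwise null (1.00). The repressed share sits in the middle of
  per-miRNA validation rates such screens report (roughly 50--80%); the
  effect range runs from strong repression to just below the validation
  cutoff; the upregulated mean mirrors the occasional activation seen in
  real screens.
* **Noise**: per-replicate normalized RLU is Normal(true mean, sd 0.05)
  truncated at 0, modelled directly on the ratio scale because the
  pipeline consumes ratios and no raw-luminescence distribution is
  specified anywhere; duplicates share their replicate's ratio and differ
  only in absolute scale. Control ratios have true mean 1.0.
* **Determinism**: the entire bundle is a pure function of the
  `study_config()`, whose seed is recorded in every output header.

What the generator does *not* emulate: plate positional effects,
transfection-efficiency drift, control-well QC, heteroscedastic or heavy-
tailed noise, and correlated effects across fragments of one gene. A green
test suite therefore demonstrates that the pipeline's arithmetic and
inference behave as specified under the stated noise model -- not that the
model captures every failure mode of real plates.

## Numerical choices and degenerate inputs

* Fragment plans: extra nucleotides go to earlier fragments (deterministic
  tie-break); a UTR not exceeding `target_len` is a single fragment.
* `fold_baseline()` accepts 10--2000 nt (fold fragments, not full UTRs);
  an all-unpaired result is valid.
* Layout: loop circles use exact unit chords between adjacent slots;
  the loop-centre offset is clamped to keep centres finite for the
  smallest loops. Degenerate all-unpaired sequences lay out on a line.
* Coverage: closed-ball membership with 1e-9 slack; `r` must be positive.
* Welch test: an error is raised only when *both* samples have zero
  variance; Pearson correlation requires n >= 3 and nonzero variance on
  both sides.
* Zero-noise plates (`noise_sd = 0`) reproduce true means exactly and make
  the Welch test undefined for null effects -- by construction, not a bug.

## Problem sizes in the shipped tests

The test suite exercises: scan-versus-oracle equivalence on 1000 random
fragment/miRNA pairs up to 500 nt; coverage-versus-brute-force equality on
200 folded structures of 40--160 nt across the full radius sweep; type-I
error on 2000 null constructs and power on 500 repressed constructs at the
default noise model; effect-mean recovery on 2000 constructs; and tiling
invariants for every UTR length from 1 to 10,000 nt. These sizes were
chosen so the whole suite completes in well under two minutes while the
Monte-Carlo margins stay comfortable.

## Known limitations

* The folding baseline is combinatorial, not thermodynamic; near-degenerate
  optima fold to one deterministic choice that can differ from an MFE
  structure. Partition-function or ensemble accessibility (pairing
  probabilities) is out of scope -- ingest external structures where that
  matters.
* The radial layout does not prevent overlaps of distant branches in very
  ramified structures; the coverage score is defined on the drawing, as
  intended, so layout style is part of the metric's definition.
* Validation rests on nominal p values by design; the emitted BH column is
  supplementary.
* `pairwise_site_overlap()` enumerates pairs and triples only.
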