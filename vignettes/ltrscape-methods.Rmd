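---
title: "Methods: annotating and dating an LTR-retrotransposon complement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and dating an LTR-retrotransposon complement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ltrscape` reconstructs, as a tested pipeline, the classic in-silico
census of a Ty3/gypsy LTR-retrotransposon (LTRr) complement: detect every
copy of a set of family consensus sequences in an assembled genome,
classify each insertion structurally, date it by divergence from its
consensus, and stratify the complement by chromatin compartment, cluster
membership and gene context. This vignette explains the model behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design decisions taken where the procedure
was genuinely open.

## The biological model

A freshly transposed LTRr is a provirus `LTR5 – internal (gag/pol) – LTR3`
with both LTRs identical, flanked by a 4–6 bp target-site duplication
(TSD) created at integration. Afterwards three clocks run:

* **substitutions** accumulate roughly uniformly, so the proportion of
  nucleotide differences from the family consensus estimates insertion
  age;
* **indels** fragment the copy; deletions outnumber insertions roughly
  2:1, and both span tens of bp to several kb;
* **intra-element recombination** between the two LTRs excises the
  internal region and one LTR, leaving a solo-LTR (still TSD-flanked).

The census therefore needs, per copy: family, condition (proviral /
solo-LTR / unknown), divergence, the list of structural-variation (SV)
events, a fragmentation grade, and genomic context.

## Detection: seed-and-extend scanning

The scanner replaces a BLAST step with an internal implementation so the
whole pipeline is self-contained and deterministic. Parameters
(`scan_params()`):

| parameter | default | role |
|---|---|---|
| `k` | 11 | exact seed word size; k-mers containing N are never indexed |
| `match`/`mismatch` | +1 / −2 | column scores; N columns score 0 |
| `gap_open`/`gap_ext` | −5 / −2 | affine gaps; a gap of length L costs open + L·ext |
| `x_drop` | 20 | extension stops when the running score falls this far below its maximum |
| `min_score` | 30 | reporting floor for a local alignment |
| `chain_gap` | 3500 bp | maximum genome- and consensus-axis gap bridged when chaining |

The scoring approximates contemporary BLASTN defaults. A consequence
worth stating: crossing any indel of ≥ 8 bp costs more than the x-drop
allowance, so **every structural indel terminates the extension**. Copies
with indels are recovered as chains of collinear segments; `chain_gap`
must therefore exceed the largest deletion the analysis should bridge. We
set it to 3.5 kb, above the upper bound of the simulated deletion-size
classes; tandem copies are never fused because chaining also requires
consensus collinearity (a second copy restarts at consensus position 1,
which is a backward jump). Both strands are searched by scanning with the
reverse complement of the consensus; coordinates are always reported on
the forward strand, 1-based inclusive (internally and in all tables; only
BED output is 0-based half-open, per that format).

## Classification

**Family rules.** A candidate is accepted if (1) it aligns a contiguous
stretch of ≥ 400 bp of the internal region at ≥ 90% identity, or (2) it
reaches ≥ 90% identity over at least half of the LTR length. Because
per-gene coordinates inside the internal region are not part of the
family model, "gag/pol" is operationalized as the whole internal segment
— a conservative superset. When candidates of different families overlap
the same locus, the one maximizing identity × aligned length wins, ties
broken by family name.

**Condition.** Solo-LTR if the aligned consensus positions fall only in
LTR segments; proviral if the internal region shows real aligned sequence
— at least 30 non-N aligned internal columns, a floor needed because
x-drop trimming can let a handful of chance columns leak past the
LTR/internal junction of a true solo-LTR; unknown when N tracks
(unsequenced assembly gaps) cover at least half of the span where internal
sequence would lie.

**Copy–consensus alignment.** The end-to-end alignment used for SV and
divergence is assembled as a *composite of the chained extension
segments*: each segment contributes its base-level alignment, and the
inter-segment gaps become explicit deletion/insertion blocks. We
deliberately do not re-align globally: when a copy carries both a large
insertion and a large deletion, the optimal affine-gap path at these
scores "smears" the alien insertion across the deleted consensus
(aligning unrelated sequence costs ≈ −1.25 per column, double-gapping
−4), which scrambles the event calls — the same pathology that forced the
original census to align copies by hand.

**Reliability.** A copy is excluded from SV/divergence analysis
("unreliable alignment") when the per-column score of the composite —
matches and mismatches, penalizing only sub-structural gap wiggles
(< 10 bp) — falls below 0.4 × match over ≥ 50 base-base columns, or when
more than 45% of the copy's sequence cannot be aligned to the consensus
at all. The second criterion is what catches mosaic copies spliced from
different families: their alien half is unalignable, while genuine copies
at ≤ 10% divergence keep per-column scores ≈ 0.7 and low unaligned
fractions. (A single large insertion raises the unaligned fraction to at
most ~0.37 for the simulated size classes, safely below the cap.)

**SV events.** Gap runs ≥ 10 bp in the copy row are deletions, in the
consensus row insertions; an insertion whose sequence matches the
consensus within 500 bp of the insertion point (≥ 90% identity over
≥ 90% of its length) is re-typed as a duplication. Events overlapping an
LTR segment carry a 5′/3′ flag, serialized in the published table dialect
(`del120(5′), ins45`; `No`; `ND`). Fragmentation: ≥ 3 events → highly
fragmented, 1–2 → moderately, none → complete if the copy contains no N
track, else unknown. The "partial" flag is true when summed deletions
exceed 3% of the consensus length (strict inequality); consensus sequence
missing beyond the copy ends counts toward that sum only when the genomic
flank is sequenced (non-N), i.e. when the loss is a real truncation rather
than an assembly gap — whether the original census counted terminal
truncations is unstated, so this reading is a documented choice, and
solo-LTRs are partial by construction.

**Divergence** is the proportion of differing sites over alignment
columns where both rows carry a determined base (pairwise deletion: gap
and N columns excluded), undetermined below 50 comparable columns and
reported to one decimal in percent. The same pairwise-deletion convention
is extended to every identity computation for consistency, since the
original procedure does not state its denominator.

## Genomic context

* **Compartments**: each copy takes the label of the interval containing
  its midpoint (straddlers take the midpoint's side), keeping counts
  additive across regions; base-pair tallies truncate at region borders.
* **Pericentromeric euchromatin (PE)**: euchromatic base pairs are walked
  from the pericentric-heterochromatin boundary toward the telomere,
  skipping intercalary islands, until 3 Mb accumulate (the census's
  definition); an explicit coordinate list can override the derivation.
  On the 1.5-Mb simulated arms the same definition is applied at 300 kb —
  a scaled version of "the euchromatin proximal to the PH", stated
  wherever used.
* **Clustering**: single linkage at ≤ 10 kb, *edge-to-edge* and inclusive
  at exactly 10,000 bp — the most permissive reading of "within 10 kb of
  each other"; a `method = "start"` switch measures start-to-start
  instead, since the original criterion is ambiguous.
* **Gene associations**: a copy associates with a gene when inside its
  transcription borders (exon if it overlaps any exon, else intron;
  proximity 0) or within 1 kb of a border. 5′/3′ assignment is
  strand-aware with 5′ = upstream of the transcription start; the
  published table legend words it the other way around, which contradicts
  its own examples and convention, so it is treated as an erratum, not
  followed.
* **Windows and breakpoints**: densities are tiled from position 1 in
  fixed windows (counts by midpoint, base pairs split proportionally, the
  final short window normalized by its true length); inversion-breakpoint
  neighborhoods report the rearranged interval, both remainders, the
  50-kb flank pairs and a 1-Mb window centered on the proximal breakpoint.

## Statistics

Enrichment uses Pearson goodness-of-fit chi-squares with expectations
proportional to region size in base pairs, and 2×2 contingency
chi-squares **without continuity correction** — the published statistics
(36.39, 5.08, 87.13, 18.66) are recovered from the table counts only
under exactly these conventions. The heterochromatin-versus-NPE
divergence contrast is a pooled-variance Student t on per-arm mean
divergences, which reproduces the printed t = 5.91; a copy-level and a
Welch variant are available. Divergence histograms use
0.5-percentage-point bins over 0–10% (the natural reading of "windows of
0.05" on a percent axis), exposed as a parameter. The published
X-euchromatin chi-square of 8.635 is not recoverable from the printed
table counts and sizes under any of these conventions and is therefore
not targeted. No multiple-testing correction is applied, matching the
original analysis.

## The synthetic-genome generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline is validated under:

* two 1.5-Mb arms, each with a proximal PH block (15%), a mid-arm DIH
  island (3%) and euchromatin elsewhere; genes at ~55/Mb (euchromatin)
  and ~14/Mb (heterochromatin) with 1–4 exons;
* 8 families, consensus 5–8 kb, LTRs 150–400 bp, GC 0.45;
* 200 insertions; compartments receive insertions proportionally to
  multipliers PH 8 : DIH 5 : CIH 5 : EU 1 — chosen to reproduce the
  *qualitative* heterochromatic enrichment, since per-compartment
  insertion rates are not published quantities;
* conditions 40% solo-LTR / 35% complete / 25% fragmented provirals
  (from ≈ 55:45 proviral:solo with 42% of classifiable provirals
  fragmented); divergence uniform on [0, 10%] with half the copies young
  (≤ 1%); substitutions uniform across sites and bases (Jukes–Cantor-like
  — the simplest model consistent with "proportion of nucleotide
  differences"), with the realized count fixed to round(d·L);
* deletion:insertion events 2:1; sizes from the 10–100 / 100–1000 /
  1000–3000 bp classes at weights 47/30/23 (deletions) and 38/37/25
  (insertions), log-uniform within class; event type and size are drawn
  first and only the offset is resampled on placement failure, so the
  ratio is not biased by the tighter placement constraints of large
  deletions;
* TSDs of 4–6 bp copied verbatim to both flanks; 5% of copies carry one
  N-gap track of 0.1–1 kb that *replaces* sequence (lengths stay
  predictable); half the copies are planted on the minus strand.

All coordinates in the truth manifest address the emitted genome exactly;
compartment and gene intervals are remapped through the insertions so the
maps still tile each arm. A single master seed drives everything through
derived sub-seeds (one per arm, one per planted copy), so arms are
independently reproducible and identical configurations give
byte-identical output files.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: nested insertions, mosaic recombinant
copies (they are constructed explicitly in tests, never sampled),
population-level polymorphism (every planted copy has occupancy 1),
non-uniform substitution processes (CpG effects, rate heterogeneity),
segmental duplications or low-complexity background that a real assembly
would contribute, and genuinely unknown family membership (simulated
families are unrelated random sequences, so cross-family homology is
absent while real lineages share domains).

## Numerical choices and degenerate inputs

Sub-seeds are derived as `(seed · 48271 + index) mod (2³¹ − 19)` to stay
within R's integer range. Ties: overlapping same-family candidates keep
the higher-scoring chain (LTR cross-matches of one locus); cross-family
overlaps keep the larger identity × length, then lexicographic family
name. Zero-divergence copies align gap-free and return divergence 0
exactly. Empty plan lists produce a clean genome on which the scanner
reports nothing. Arms without a PH anchor derive no PE (all euchromatin
becomes NPE, with a warning); arms with less than the requested PE size
assign all walked euchromatin to PE, with a warning. Genes without exon
rows are treated as single-exon, with a warning. Regions of zero size are
an error, as are 2×2 tables with a zero marginal and goodness-of-fit
tests with a zero expected cell; two constant equal samples give t = 0,
p = 1 by convention.

## Problem sizes

The validation suite and the acceptance script run the full pipeline on
the default conditions above (two 1.5-Mb arms, 200 planted copies, 8
families) — sizes chosen so a complete simulate–scan–annotate–summarize
cycle takes on the order of a minute while every accuracy estimate rests
on ≥ 50–150 qualifying copies; oracle-equivalence checks for the aligner
use sequence pairs ≤ 200 bp where exhaustive dynamic programming is
exact, and negative controls use hundreds of kb of copy-free sequence.

## Known limitations

Family consensus reconstruction from copies is out of scope (consensus
models are inputs); lineage is accepted as family metadata rather than
inferred from reverse-transcriptase domains; cytological band assignment
and cross-species synteny are not implemented. Detection sensitivity
degrades by design beyond ~10% divergence (the family rules' 90% identity
floor), so the pipeline characterizes a recent-to-middle-aged complement,
as the original census did.
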