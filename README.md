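# ltrscape

Annotation and evolutionary analysis of Ty3/gypsy-style LTR-retrotransposon
complements in assembled genomes.

LTR retrotransposons (LTRrs) transpose through an RNA intermediate: a fresh
insertion is a full-length *provirus* — 5′ LTR, internal gag/pol region,
3′ LTR identical to the 5′ one — flanked by a 4–6 bp target-site duplication
(TSD). Over time copies accumulate substitutions and indels, and
recombination between the two LTRs deletes the internal region, leaving a
*solo-LTR*. The census of such copies — how many, how degraded, how old,
and where they sit relative to heterochromatin, pericentromeric euchromatin
and genes — is the raw material for inferences about transposition
activity, purifying selection and genetic drift.

`ltrscape` implements that census as a reusable, tested pipeline:

* **Detection** — a seed-and-extend gapped aligner (exact 11-mer seeds,
  affine-gap x-drop extension at BlastN-like scoring: match +1, mismatch
  −2, gap open −5, gap extend −2) scans both strands of a genome with each
  family consensus; collinear local alignments are chained across
  structural indels into candidate copies.
* **Classification** — family assignment by the published rules (a
  contiguous ≥ 400 bp stretch of the internal region at ≥ 90% identity, or
  ≥ 90% identity over at least half the LTR length); condition
  (proviral / solo-LTR / unknown when unsequenced N tracks mask the
  decision); TSD detection at the junctions.
* **Structural variation** — the copy–consensus alignment is assembled
  from the chained extension segments; gap runs ≥ 10 bp become deletion /
  insertion / duplication events; copies are graded complete,
  moderately-fragmented (1–2 indels ≥ 10 bp) or highly-fragmented (≥ 3),
  and "partial" when summed deletions exceed 3% of the consensus length.
* **Dating** — divergence from consensus as the proportion of nucleotide
  differences under pairwise deletion (gap and N columns excluded), the
  standard proxy for insertion age.
* **Context** — chromatin-compartment assignment (pericentric PH, diffuse
  and compact intercalary DIH/CIH, pericentromeric euchromatin PE derived
  as the euchromatin proximal to the PH, remaining NPE), 10-kb
  single-linkage clustering, gene associations within 1 kb flanks,
  windowed densities and inversion-breakpoint neighborhoods.
* **Statistics** — chi-square enrichment against size-proportional
  expectations, 2×2 condition contrasts (no continuity correction),
  pooled-variance t tests on divergences, divergence histograms and
  condition-ratio-by-age summaries, e.g.

  χ² = Σ (Oᵢ − Eᵢ)²/Eᵢ,  Eᵢ = n · sizeᵢ / Σ size,  df = 1.

* **Simulation** — a synthetic-genome generator plants copies of known
  family, divergence, structure, strand and location (with TSDs, N-gap
  tracks, a 2:1 deletion:insertion event ratio and heterochromatic
  enrichment) and emits a ground-truth manifest, so every stage is
  verifiable without a real assembly.

## Worked example

The `analysis/` scripts run the whole study on a simulated genome; the
same calls work interactively:

```r
library(ltrscape)

lib   <- build_family_library(8, seed = 101)          # 8 consensus models, 5-8 kb
bps   <- default_blueprints(2, 1500000, seed = 102)   # two 1.5-Mb arms
plans <- sample_insertion_plans(bps, lib, 200, seed = 103)
sim   <- synthesize_genome(bps, lib, plans, seed = 104)

cands  <- scan_genome(lib, sim$genome)
copies <- annotate_copies(cands, lib, sim$genome)
attr(copies, "counts")
#> candidates rejected_family overlap_dropped unreliable annotated
#>        199               2               1          0       196
table(copies$condition)
#> proviral solo-LTR
#>      126       70
```

Placing the copies in context and testing heterochromatic enrichment
(`Rscript analysis/01_simulate.R` … `05_truth_evaluation.R` prints the
full narrative):

```
insertions in clusters (<= 10 kb apart): 159 of 196
simulated het enrichment: 123 het vs 73 eu copies, chi2 = 134.3 (p = 4.8e-31)
                  metric     value   n
       recall_500bp_5pct  1.000000  88
               precision  1.000000 196
      condition_accuracy  0.993421 152
  fragmentation_accuracy  1.000000  88
      divergence_bias_pp -0.001419  65
```

The last block is the evaluation against the planted truth: every copy
≥ 500 bp at ≤ 5% divergence was recovered, fragmentation classes were all
correct, one condition call in 152 differed from truth, and the divergence
estimator is unbiased to about a thousandth of a percentage point on
indel-free kilobase copies.

Re-deriving the published census statistics from the overview tables
shipped with the package (`published_tables()`):

```
X overrepresentation: chi2 = 36.36 (p = 1.64e-09)
PE enrichment:        chi2 = 86.85 (p = 1.17e-20)
proviral/solo PHxNPE: chi2 = 18.66 (p = 1.56e-05)
het vs NPE divergence: t = 5.91 (p = 0.00036)
```

## Repository layout

```
R/, src/            the package: generator, scanner (Rcpp), annotation,
                    context, statistics, pipeline orchestration
analysis/01..05     the numbered study workflow over the package
inst/extdata/       published overview tables (plain text)
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R
vignettes/          the methods vignette
```
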