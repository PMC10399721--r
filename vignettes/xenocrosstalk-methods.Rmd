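---
title: "Cross-species ligand-receptor crosstalk inference: methods and design"
author: "xenocrosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species ligand-receptor crosstalk inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenocrosstalk)
```

# The problem

A human tumor growing in an immunodeficient mouse is a two-compartment
transcriptome: probes matching human transcripts report the cancer cells,
probes matching mouse transcripts report the stroma (vasculature,
fibroblasts, infiltrating myeloid cells). Profiling both compartments on a
dual-species microarray lets one ask a question neither compartment can
answer alone: *which tumor-derived ligands could be signaling to receptors
on the stroma, and which of those signals appear only under a particular
therapy?* In BRAF-mutant melanoma xenografts, combining a BRAF inhibitor
with VEGFA blockade recruits antitumor (M1-like) macrophages, and GM-CSF
(*CSF2*) is the kind of tumor-derived, combination-specific cytokine such an
analysis is designed to surface.

`xenocrosstalk` implements that analysis as a reusable pipeline, together
with the preclinical response layer used to quantify therapy outcomes in
mouse cohorts (caliper tumor volumes, CR/DR/SR/NR response classes,
Kaplan-Meier and log-rank support, ΔΔCt qPCR quantification) and seeded
synthetic-data generators that plant a known ground truth so the whole
chain can be tested end to end.

# The expression pipeline

Input is a probe-level log2 expression matrix over four arms — `control`,
`brafi` (BRAF inhibitor), `anti_vegfa` (VEGFA-neutralizing antibody) and
`combo` — with a probe annotation (`probe_id`, `species`, `gene`) and a
sample sheet. `runCrosstalk()` executes:

1. **Cross-hybridizing probe removal.** Probes that bind transcripts of
   both species contaminate compartment assignment; they are removed by a
   user-supplied blacklist (plus any probe flagged `cross_hyb` in the
   annotation). Pure row deletion: no value is modified.
2. **Significance prefilter.** A probe is kept iff its raw two-group
   p-value against control is *strictly* below `alpha` (default 0.05) in
   at least one treated arm. The strict `<` at the boundary is deliberate:
   a probe exactly at the threshold in every arm is dropped.
3. **Probe-to-gene collapse.** For each (species, gene) the probe with the
   largest mean expression across *all* samples is retained; its values
   are copied unchanged. Ties break to the lexicographically smallest
   probe id, so the collapse is deterministic.
4. **Expression calls.** A gene is called expressed iff its mean within at
   least one condition reaches the floor. The default floor is the
   per-species *median* of gene-level mean intensities — a relative
   cutoff that travels across platforms; an absolute floor can be given
   instead (`floor = 6`, say), and the scanned conditions are
   configurable (`scope`).
5. **Contrasts.** Every gene is tested per treated arm against control
   with a two-sided t-test on log2 values (pooled variance by default,
   Welch optional). The effect estimate is the log2 ratio
   (mean treated − mean control). BH adjustment is applied within each
   species × condition family, mirroring one supplementary table per
   compartment and contrast.
6. **Intersection.** Candidate crosstalk = tumor-expressed (human) ligand
   whose compendium receptor set intersects the stroma-expressed (mouse)
   genes. The report's headline counts are the number of candidate
   ligands and of distinct receptors.
7. **Condition-specific detection.** A candidate is combination-specific
   iff it is significant in `combo` and *not* significant (p ≥ alpha) in
   either monotherapy.
8. **Ranking.** Combination-specific ligands are ordered by descending
   combo log2 ratio, ties by symbol; the first entry is the headline
   ligand.

## Where the prefilter acts

The three filtering rules answer different questions. "Is this gene
*modulated*?" (prefilter) is not "is this gene *expressed*?" (step 4) —
and a receptor can be constitutively expressed on stroma while being
modulated by nothing. Running the prefilter ahead of the expression calls
would therefore delete every unmodulated receptor and empty the candidate
list. The default, `prefilter = "detection"`, computes expression calls
and contrasts on all blacklist-cleaned genes and lets the prefilter gate
only eligibility for the condition-specific call. The literal
filter-first ordering remains available as `prefilter = "global"` for
users who want every downstream stage restricted to significant probes,
and `"off"` disables it.

## Raw versus adjusted p in the condition-specific call

`pMode = "raw"` matches the threshold style of the probe prefilter and is
the default. At genome scale, however, raw p has an ~`1 − 0.95² ≈ 10%`
chance per ligand of *chance* significance in one of the two monotherapy
arms, which would knock true combination-specific ligands off the list.
`pMode = "bh"` uses the BH-adjusted p on both sides of the rule and is
the setting used in the package's own recovery experiments; with hundreds
of genes per family it keeps both false monotherapy hits and false combo
hits rare.

## The ligand-receptor compendium

`LRCompendium` is an ordered, deduplicated set of *directional*
ligand → receptor gene pairs with source provenance, assembled by
`mergeSources()` from one or more tables (e.g. IUPHAR-style and
DLRP-style exports; the original analysis this mirrors pooled two such
resources into a 356-pair compendium whose exact content is not
recoverable, so the package ships a toy fixture and parsers for
user-supplied tables instead). Duplicate pairs collapse with source-tag
union; A→B and B→A are distinct because the analysis is directional.
Symbols are harmonized by a total mapping: explicit
(raw, species) overrides first, else uppercase — human/mouse ortholog
pairs that differ only by case (mouse *Csf2* / human *CSF2*) need no
entry. The packaged `symbol_map.tsv` also maps the transposed spelling
"Csfr2a", which appears in the literature, onto CSF2RA rather than
resolving the discrepancy silently.

# The preclinical layer

* **Volume.** `tumorVolume()` implements the modified ellipsoid formula
  `length × width² / 2` (mm, mm³); width > length is swapped with a
  warning, per caliper convention.
* **Response classes.** With baseline = volume at treatment start:
  CR iff final ≤ `crThreshold` (default 0 mm³ — no palpable tumor; the
  class is narrative in the literature, so the threshold is an explicit,
  documented interpretation and is configurable to a detection floor);
  else DR iff final < baseline; else SR iff the nadir dipped below
  `responseFraction × baseline` (default 0.8, again an interpretation of
  "responded, then progressed") but the tumor returned to ≥ baseline;
  else NR. All but the CR cutoff are ratio rules, so classification is
  invariant to uniform rescaling of volumes.
* **Summaries.** Percentages are rendered at nearest-integer and
  one-decimal precision with half-away-from-zero rounding — the two
  precisions conventionally printed in arm summaries (e.g. 10 of 21 →
  48%; 1 of 7 → 14.3%).
* **Survival.** `kmEstimator()` and `logrankTest()` delegate to the
  `survival` package (product-limit estimate; Mantel-Cox one-df
  chi-square), with the convention (statistic 0, p 1) when neither arm
  has an event. The test suite checks both against independent
  hand-computed oracles (empirical survivor function; explicit
  observed-minus-expected tables).
* **qPCR.** `ddctLog2fc()` returns −ΔΔCt, the log2 fold change after
  normalizing target Ct against a housekeeping gene (Tbp in this
  pipeline) and a reference sample.

# The synthetic-data generators

All generators are pure functions of a `simConfig()` and its seed, and
return machine-readable ground truth alongside the data, so every
recovery test reads generator output — never a hard-coded answer.

**Expression.** Each probe value is gene baseline + probe offset +
per-arm gene effect + independent N(0, `noiseSd`) on the log2 scale.
Defaults: 200 human and 150 mouse genes, 1–3 probes per gene, n = 3 per
arm, baseline N(7, 1.5), probe offsets N(0, 0.5), noise sd 0.25; 5
planted ligands shifted +5 log2 in the combo arm only; 3 decoys shifted
in a monotherapy arm (to exercise the "only after dual therapy" rule); 10%
of probes flagged cross-hybridizing and given a spurious +3 combo shift —
which is precisely the artifact the blacklist guards against. The
geometry mirrors the structure of the real analysis (a handful of
combination-specific ligands among ~80 candidates) at a size where the
full pipeline runs in about a second. Planted ligands, decoys and their
designated receptors are given baselines at least two units above the
population centre with non-negative probe offsets: this enforces the
generator's contract that every planted ligand has a stroma-expressed
cognate receptor (real hits are, by construction of the question,
expressed genes). Cross-hybridizing probes never sit on those genes, so
blacklisting can never ablate a planted signal.

**Compendium.** Planted and decoy ligands are paired with their
designated receptors; filler pairs use symbols absent from the expression
data, so they can never create a candidate. Pairs are split across two
source tables and merged, with one pair present in both to exercise
provenance union.

**Growth cohorts.** Pre-treatment, volume grows exponentially to reach
~250 mm³ at treatment start (day 9); afterwards each mouse follows its
planted class: CR decays (rate 0.2/day) below a 5 mm³ detection floor and
is recorded as 0; DR decays to a plateau at 35% of baseline; SR decays to
a nadir at half baseline by day 12 post-start, then regrows at 0.08/day
past baseline; NR and controls keep growing. Observed volumes get
multiplicative lognormal noise (sd 0.1; 0 = noiseless) and are
back-converted to caliper length/width at a fixed 2:1 aspect ratio, which
makes volume inversion exact. Measurement stops when a mouse first
crosses the 1500 mm³ surrogate endpoint, which also defines its survival
record (event; otherwise censored at day 60). Whether real survival
endpoints are deaths or volume surrogates is usually protocol-specific;
the simulator states its choice explicitly. The default cohorts are a
21-mouse treated arm planted 10 CR / 6 DR / 5 SR and a 7-mouse control
arm of NR.

**What the generators do not emulate.** Noise is independent and
homoscedastic; real microarray data have correlated probes, batch
structure and intensity-dependent variance. Cross-hybridization is a flag
plus a planted bias, not sequence physics. Growth curves are smooth
two-phase exponentials. Passing the recovery tests therefore shows the
*pipeline logic* is correct under its stated model — it does not certify
performance on any particular real dataset.

# Numerical choices and degenerate inputs

* Zero within-group variance in both groups: p = 1 if the means are
  equal, p = 0 otherwise (the difference is exact). These conventions are
  shared by the scalar and vectorized engines and covered by tests.
* The BH step (`bhAdjust`) delegates to `stats::p.adjust`; the test suite
  verifies it against a hand-written step-up oracle on all permutations
  of up to six p-values.
* Collapse and ranking tie-breaks are lexicographic, making every output
  deterministic; reports and manifests contain no timestamps, so
  identical runs are byte-identical.
* Empty inputs fail fast with stage-named errors (`[prefilter] ...`);
  an all-blacklisted matrix is valid and yields an empty gene level.
* `roundHalfUp()` rounds half away from zero; base `round()` would
  render 2.5% as 2%.

# Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run the full pipeline on the
default 350-gene geometry across 20 seeds, a 2000-gene null simulation
for type-I error (the fraction of raw p < 0.05 must sit inside the
binomial 99% band around 0.05), 200 random collapse fixtures, random
compendia up to 10³ pairs against a nested-loop enumeration, and
noiseless growth cohorts for exact class recovery. These sizes were
chosen so the complete check runs comfortably on a laptop in about a
minute while keeping every comparison against an independent oracle.

# Optional real-data mode

`readSeriesMatrix()` parses an uncompressed GEO series-matrix file
offline (e.g. accession GSE69754 for the A375 xenograft series,
downloaded separately). The parsed matrix feeds `makeXenoExperiment()`
once the user supplies the three study-specific inputs the pipeline
cannot invent: a dual-species probe annotation, a cross-hybridization
blacklist, and a sample sheet mapping GEO samples to the four arms.
Reproducing the qualitative headline on real data additionally requires
a ligand-receptor compendium of the user's choosing; compendium content
is version-dependent, which is why the package treats it as an input
rather than shipping a frozen copy.

# Known limitations

* The differential-expression engine is a plain t-test; moderated-variance
  (empirical-Bayes) methods are deliberately out of scope, as the target
  statistic triple is (log2 ratio, raw p, BH p).
* Receptor-side differential expression is reported descriptively in the
  candidate table but never used as a filter.
* Multi-subunit receptor complexes are not modeled; each compendium row
  is one ligand and one receptor gene.
* CR/DR/SR thresholds are explicit interpretations of narrative
  definitions; sensitivity to them is the user's to explore via the
  exposed parameters.
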