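---
title: "Methods: methylation-driven silencing analysis with methylmiR"
author: "methylmiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation-driven silencing analysis with methylmiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmiR)
```

## The scientific problem

Many microRNAs are intragenic: they sit inside an intron of a protein-coding
host gene and are transcribed from the host promoter. When a CpG island (CGI)
overlapping that promoter becomes hypermethylated — a common event in cancer
— both the host transcript and the miRNA are silenced together. methylmiR
implements the complete calculation chain used to establish such epigenetic
silencing, modelled on the miR-486-5p / *ANK1* situation in osteosarcoma:

1. **Sequence level** — in-silico bisulfite conversion, methylation-specific
   PCR (MSP) template and primer evaluation, and semi-quantitative calling of
   direct bisulfite-sequencing traces.
2. **Quantitative PCR** — comparative-CT (2^-ddCt) relative expression and
   demethylation-induction scoring after 5-Aza-2'-deoxycytidine treatment.
3. **Quantitative MSP** — gene:ALU ratios, percent of methylated reference
   (PMR), cohort-derived scoring thresholds and increased-methylation calls.
4. **Arrays** — Illumina-style Beta values, quantile normalisation, locus
   profiles, and methylation–expression integration.
5. **Statistics** — Pearson correlation, an exactly enumerated small-sample
   Mann–Whitney U test, and the paired t-test.
6. **Synthetic cohorts** — a seeded generator that emulates the cohort
   structure those analyses assume, so the full pipeline runs and can be
   validated without any external download.

## Models and formulas

**Bisulfite chemistry.** Bisulfite treatment deaminates cytosine to uracil
(read as thymine) unless the cytosine is methylated; methylation occurs at
CpG dinucleotides. `bisulfite_convert()` therefore converts every `C` to `T`
except the `C` of a CpG marked methylated. On the minus strand the same rule
is applied to the reverse complement: the bottom-strand partner of a
plus-strand CpG is itself a CpG (CG is its own reverse complement), and it is
protected exactly when the plus-strand CpG is methylated. The converted
bottom strand is reported 5'→3' of itself, never re-complemented, because
that is the orientation in which bisulfite PCR primers are written. `N`
passes through unchanged and never forms a CpG site.

**MSP.** `make_msp_templates()` produces the four fully methylated / fully
unmethylated converted templates (two strands); for any sequence the two
templates of a strand differ at exactly its CpG-C positions, which is the
sequence basis of MSP specificity. `primer_matches()` is deliberately
exact-match only — no annealing or mismatch model is available to
parameterise anything richer, so specificity statements reduce to perfect
match versus no match. `call_msp()` maps the two band booleans to
methylated / unmethylated / hemimethylated / failed.

**Trace quantification.** The degree of methylation at a CpG after direct
bisulfite sequencing is the cytosine peak height over the sum of cytosine
and thymine peaks, `C/(C+T)` (`quantify_trace()`), classified by
`classify_bs_ratio()` into unmethylated (≤ 0.20), partially methylated
((0.20, 0.80]) and methylated ((0.80, 1]). The published convention states
these bands to two decimals (0–0.2 / 0.21–0.8 / 0.81–1.0); the half-open
generalisation preserves the membership of every two-decimal ratio while
making the classifier total and monotone on [0, 1]. A site with both peaks
zero is undefined and is reported as a no-call, never as 0.

**Comparative CT.** Replicate Cts are averaged on the Ct scale (the
conventional choice; the alternative, averaging on the rq scale, differs
only at second order for replicate sd ~0.2 cycles). dCt is target minus
reference-gene mean Ct; the calibrator is the *arithmetic mean dCt of the
calibrator group*, so the calibrator group's geometric-mean rq is exactly 1.
`induction()` scores fold = rq_treated/rq_untreated against the ≥ 1.3
threshold (a 30 % induction); `induction_cohort()` uses the equivalent
identity fold = 2^-(dCt_treated − dCt_untreated), in which the calibrator
cancels, and keeps the per-line dCt pairs for the paired t-test. Internally
fold is always treated/untreated; a display that sets treated to 1 is a
rendering choice, not a second convention. Undetected reactions are
excluded, never imputed to a maximum cycle, because imputation shifts folds
untraceably.

**qMSP / PMR.** The gene:ALU ratio is the median over paired replicates of
2^-(Ct_gene − Ct_ALU); when replicate counts differ the replicates cannot be
paired and the ratio of per-assay medians is used. The quantification model
(reference-normalised dCt rather than a standard curve) is the
PMR-literature default and requires no curve inputs. PMR is 100 × the
sample ratio over the fully methylated positive control's ratio. The
methylation-scoring threshold is *derived from the supplied bone series*
(its maximum PMR) on every run — a printed instance of that threshold in any
particular cohort is an observation, not a constant. Methods-style scoring
is inclusive (PMR ≥ threshold); because a strict `>` reading also
circulates, `qmsp_cohort()` reports both calls and messages when they
differ (they differ exactly at the arg-max bone sample). "Increased
methylation" is strict: PMR > 2 × bone mean.

**Arrays.** Beta is the plain ratio M/(M+U); the vendor's +100 background
offset is intentionally omitted since the quantity of interest is the
unadjusted ratio, and both-zero signals become missing values.
`quantile_normalize()` replaces each value by the mean of its rank-matched
sorted values across columns (ties get the average of the tied reference
quantiles); rows with missing values are dropped rather than part-imputed.
Beta classes are unmethylated < 0.3 ≤ partial < 0.7 ≤ methylated; the 0.7
boundary is assigned to the methylated class to mirror the strictness of the
lower `< 0.3` bound. Sample dichotomisation at a single probe defaults to a
0.3 cut — the unmethylated-class boundary — because no published cut exists
for this step; it is an exposed parameter. Correlations use
pairwise-complete observations; constant vectors yield no-calls, and
`correlation_with_outlier()` always reports the correlation with *and*
without the designated outlier rather than choosing one.

**Statistics.** `pearson_r` and `paired_t` delegate to base R's `cor.test`
and `t.test` (two-sided). `mann_whitney_u` is implemented in the package
because its small-sample behaviour must be pinned: with combined n ≤ 12 and
no ties the two-sided p is exact by full enumeration of all rank
assignments; otherwise a normal approximation with midranks, tie-corrected
variance and a 0.5 continuity correction is used, and the result records
which path was taken. The switchover at 12 keeps the enumeration (at most
C(12,6) = 924 splits) instantaneous while covering every group size at
which exact and approximate p can differ materially. Base `wilcox.test`
serves as an independent cross-check in the test suite, never as the
implementation.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_cohort()` derives every
draw from one master seed through named substreams (a deterministic hash of
the stream name), so adding a new generator never perturbs existing ones and
identical configurations yield byte-identical bundles.

What it emulates, and the defaults:

* **Cohort structure** — four groups: normal bone (n = 6), methylated
  tumour lines (n = 14), unmethylated tumour lines (n = 7), xenografts
  (n = 41). The 14 + 7 split mirrors a tumour panel in which roughly
  two-thirds of lines carry promoter hypermethylation; the xenograft group
  size matches a typical combined xenograft series.
* **Promoter methylation** — per-sample island methylation fractions are
  normal draws clipped to [0.01, 0.99]: bone 0.15 ± 0.08, methylated
  tumours 0.75 ± 0.10, unmethylated tumours 0.20 ± 0.08. No published
  parameters exist for a xenograft group; 0.45 ± 0.25 was chosen once to
  reproduce a mixed pattern in which under half the xenografts show
  increased methylation. Clipped-normal noise (rather than a Beta
  distribution) keeps direct moment control; the difference is immaterial
  away from the boundaries at these sds.
* **Locus** — a 3109-bp sequence with a central 1109-bp island carrying
  exactly 79 CpGs (a CpG-island name of the "CpG79" style refers to its CpG
  count) over GC-rich filler, flanked by low-CpG sequence; CpGs are planted
  and accidental CGs removed, so the island count is exact. Flank CpGs are
  hypermethylated (0.85) in all groups, reproducing the common pattern in
  which only the island is differentially methylated.
* **Coupling** — latent log2 expression = a − b·Beta + N(0, σ_e), defaults
  a = 8, b = 4, σ_e = 0.5. The mature miRNA, its primary transcript and the
  host-gene transcript share the latent value plus independent N(0, 0.3)
  offsets, inducing the high mutual correlation expected of co-transcribed
  features. Ct values are reference Ct plus a constant minus latent
  expression with N(0, 0.2) replicate noise.
* **Demethylation** — the treated condition re-draws expression with the
  methylation fraction halved (multiplier 0.5), giving methylated lines an
  expected log2 induction of b·Beta/2 (≈ 1.5 at defaults, comfortably over
  the 1.3-fold call) while leaving low-methylation lines mostly below it.
* **Traces** — per CpG, methylated molecules ~ Binomial(depth 500, site
  probability); channel gains are jittered ±10 % to emulate dye response.
* **qMSP** — gene Ct = ALU Ct + constant − log2(fraction + 10⁻⁴); the
  positive control is generated at fraction 1, so PMR ≈ 100 × fraction.

What it does **not** emulate: tumour purity and copy-number effects, probe
cross-reactivity and detection-p filtering, batch effects, PCR efficiency
below 100 %, or read-level bisulfite sequencing. Passing recovery tests on
these cohorts therefore demonstrates correctness of the calculation chain
under its stated assumptions, not robustness to every artefact of real
data.

## Numerical and design choices

* Coordinates are 0-based half-open internally (BED convention); browser
  text is 1-based inclusive; `format_interval()`/`parse_interval()` convert
  losslessly, tolerating thousands separators.
* Classification boundaries (trace 0.2/0.8, Beta 0.3/0.7), the induction
  fold 1.3, the increased-methylation multiplier 2 and the dichotomisation
  cut 0.3 are all carried by `pipeline_config()`; pipeline stages receive
  them only from there.
* Degenerate inputs produce explicit no-calls (zero-signal trace sites,
  fully undetected assays, constant correlation inputs, zero-variance
  paired differences) rather than silent zeros; reference-assay failures
  are errors because they invalidate the sample, not the value.
* Group fold-change recovery is evaluated on the geometric (log2) scale and,
  at the small 6-per-group size, as the mean over 10 independent cohorts:
  a single 6 + 6 cohort at 0.2-cycle replicate noise has a ~7 % sampling sd
  on the fold estimate, so the cohort-mean is the estimator the recovery
  property actually constrains.
* Problem sizes in the validation suite (cohorts of ~20–70 samples, 100
  seeded replicates for sign-recovery and induction power, 2000 null
  simulations for the Mann–Whitney type-I check) were chosen as the
  smallest sizes at which the checked quantities are stable.
* Two validation checks compare against real reference data that cannot be
  redistributed with the package (a deposited HumanMethylation27 cohort and
  an hg19 island sequence); the suite runs them whenever the user has placed
  those files under `inst/extdata/real/` (paths and formats are documented
  in the test file) and reports them as failures otherwise, so their status
  is always visible.
* The package's interface is its R functions; the end-to-end entry point is
  `run_pipeline()`, which writes a plain-TSV report (no plotting
  dependencies) plus a JSON run log recording version, seed and every
  threshold applied. Report files contain no timestamps, so identical
  inputs give checksum-identical reports.

## Worked end-to-end example

```{r example, eval = FALSE}
bundle <- simulate_cohort(sim_config(seed = 1))
report <- run_pipeline(bundle, "report")
read_tsv(file.path(report, "summary.tsv"))
```

The summary table reports the induced fraction, the promoter DeltaBeta
between methylated tumours and bone, the methylation–expression Pearson r,
the bone-derived PMR threshold and the per-group methylated/increased
counts; `scripts/acceptance.R` recomputes the same quantities from scratch
for any seed.

## Known limitations

* MSP evaluation is exact-match; real primer chemistry tolerates some
  mismatches, so in-silico specificity is a necessary, not sufficient,
  condition.
* The Mann–Whitney exact path requires tie-free data; integer-valued inputs
  at small n fall back to the corrected normal approximation, which is
  recorded in the result's method tag.
* The generator's inverse coupling is linear in Beta on the log2 scale;
  threshold-like (sigmoidal) silencing would weaken linear-correlation
  recovery, which is why the association is also always tested as a
  two-group contrast.
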