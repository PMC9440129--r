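---
title: "Calling autophagosomal cargo from proximity-labelling LFQ data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling autophagosomal cargo from proximity-labelling LFQ data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cargocall)
```

## The problem and the design

APEX2 fused to LC3B biotinylates proteins in the immediate neighbourhood of
autophagosomal membranes. After proteinase K digestion of cell homogenates,
membrane-protected (autophagosome-luminal) biotinylated proteins survive and
are enriched and quantified label-free under two treatments: vehicle (DMSO)
and bafilomycin A1 (BafA1), which blocks lysosomal degradation. Genuine
autophagic cargo accumulates under BafA1, so the statistical task is a
differential-abundance screen with three complications specific to LFQ
degradomics:

1. **Left-censored missingness.** LFQ intensity 0 means "not quantified",
   and the probability of dropout rises as abundance falls (missing not at
   random), so naive mean imputation biases fold changes.
2. **A protection artefact.** Proteins intrinsically resistant to
   proteinase K survive even when membranes are dissolved by detergent
   (RAPIGest); candidates also called in that control are artefacts.
3. **Modestly powered single experiments.** With 3–4 biological replicates
   per condition, a single experiment's p < 0.05 calls are suggestive;
   evidence across a repeat experiment must be combined before multiple
   testing correction is meaningful.

`cargocall` addresses each in a fixed stage order per experiment:
decoy/contaminant removal → spectral-count filter → log2 transform →
imputation → observation ("background") filter → per-protein Student's t
tests → artefact exclusion, followed by cross-experiment meta-analysis. The
background filter runs after imputation but uses the pre-imputation observed
mask, which stays authoritative throughout; the result is identical to
filtering first, and the ordering keeps the completed matrix and the mask
together.

## Stage-by-stage model and defaults

### Inclusion filters

* Decoy (`reverse`), contaminant and "only identified by site" rows never
  enter any statistic. MaxQuant emits them and they would otherwise populate
  the volcano's tails.
* **Spectral counts** (`min_msms_total = 3`): a protein is kept when its
  summed MS/MS count over the replicates of *each* condition exceeds two.
  The summed reading ("more than two counts *across* the replicates") is the
  default; the stricter per-replicate reading is available via
  `per_replicate = TRUE`. The threshold is a count, unitless; 3 is the
  smallest integer satisfying "> 2".
* **Observation filter** (`min_observed = 2`): after imputation, proteins
  lacking two genuinely observed values in every condition are dropped. Two
  is the smallest count that makes a within-condition variance estimable
  from real data, and it guarantees no protein is tested on imputed values
  alone.

### Imputation

Missing log2 intensities in sample column j are replaced by independent
draws from Normal(m_j − 1.8 s_j, (0.25 s_j)²), where m_j and s_j are the
observed mean and sample standard deviation (n − 1 denominator) of that
column. The 1.8/0.25 pairing is the established downshifted-Gaussian
convention for left-censored LFQ data: imputed values land in the
low-abundance tail where censored values plausibly live, with a width narrow
enough not to inflate within-group variance. Both constants are expressed in
units of s_j, which makes them scale-free; each column uses its own fit
because sample distributions differ. Draws are made in a documented
sample-major order from a single seeded generator, so runs are
bit-reproducible; draws are not truncated (a draw below zero log2 units is
possible in principle and left as-is). A column with s_j = 0 degenerates to
a point mass at m_j with a warning.

### Differential testing

Each protein gets an unpaired two-tailed **equal-variance** Student's t test
(not Welch) on the completed log2 values; the fold change is
mean(BafA1) − mean(vehicle) in log2 units. Candidates are proteins with
p < `alpha` (default 0.05) *and* positive fold change — the screen is for
upregulation only, so direction is part of the definition. No per-experiment
multiple-testing correction is applied; correction happens once, at the meta
stage, which is where the final inference lives. Volcano y-coordinates are
−log10 p (the conventional orientation, so stronger evidence is higher). A
protein with zero pooled variance and equal means gets t = 0, p = 1; with
unequal means p is floored at 1e-300 rather than reported as 0.

### Artefact exclusion

The RAPIGest control run is analysed by the identical per-experiment path,
and its candidate set is subtracted from every experiment's candidate set.
Exclusion operates on called candidates, not raw rows: the control
identifies proteins whose *survival* is artefactual, not proteins that
should be invisible to testing, and the meta-analysis still sees every
tested protein.

### Meta-analysis

Each experiment's (p, fold-change sign) becomes a signed deviate
z = sign(fc)·Φ⁻¹(1 − p/2), floored at p = 1e-300. Deviates are combined as
z_meta = Σ√n_i·z_i / √Σn_i with n_i the experiment's **total** sample count
(8 for a 4 + 4 design, 6 for 3 + 3) — the weights as conventionally printed,
not per-group n. Signed combination means discordant experiments cancel
rather than reinforce; for two concordant upregulation results the combined
p is the same either way. Benjamini–Hochberg correction is applied across
the intersection set only (proteins detected in every experiment), because
that is the population actually meta-analysed; `significant` flags
q < `fdr_threshold` (default 0.05).

## The synthetic-data generator

`simulate_experiment()`/`simulate_study()` emulate the statistical structure
the pipeline assumes, not mass spectrometry itself. Per protein a mean log2
abundance is drawn from Normal(25, 3²) (arbitrary log2-intensity units in
the range MaxQuant LFQ outputs occupy); per sample, replicate noise has
sd 0.5 log2 units, a realistic between-replicate scatter for well-behaved
LFQ. Dropout is logistic in the true log2 intensity with midpoint 22 and
unit scale — the simplest MNAR mechanism consistent with left-censoring —
yielding roughly 10–20% missingness at defaults. Spectral counts are
Poisson with 0.5 expected counts per log2 unit above the dropout midpoint
plus a 0.1 floor, linked to intensity only so the count filter has realistic
behaviour (when dropout is disabled the anchor falls back to one protein-sd
below the mean abundance so counts stay finite). Two percent of proteins are
cargo, upregulated under BafA1 by log2(4.67) ≈ 2.22 — anchored to the fold
change such screens report for a strong cargo protein. The default study is
a 4 + 4 experiment plus a 3 + 3 repeat (n = 8 and n = 6) over one protein
universe with shared cargo identities.

What the generator does *not* emulate: correlated protein co-regulation,
sample-to-sample normalisation artefacts, peptide-level identification
uncertainty, or heteroscedastic intensity-dependent noise. Passing tests on
this generator therefore demonstrate the pipeline's statistical correctness
and calibration under its stated assumptions, not robustness to every
property of real instrument data.

## Numerical choices and degenerate inputs

* p-values are floored at 1e-300 before Φ⁻¹ and after extreme t statistics,
  keeping every deviate finite.
* BH is `stats::p.adjust(method = "BH")`; the test suite checks it against
  an exhaustive step-up oracle on all short p-vectors over a grid.
* A sample column with fewer than two observed values is a hard error
  (imputation cannot fit a distribution); the message points at the
  observation filter.
* Zero-variance proteins, empty candidate sets, empty meta intersections
  and all-flagged tables are all legal and return empty-but-typed results.
* Ties in BH are handled by the step-up minimum; q-value ordering follows
  p-value ordering.

## Calibration, problem sizes, and limitations

The test suite verifies, on seeded synthetic data: imputation moments at
10⁵ draws (within 3 Monte-Carlo standard errors of the closed form); a
two-sided null significance rate inside the 99% binomial band around α on a
2000-protein two-experiment null study run through the full pipeline; a
meta-analysis significant rate under the null no higher than FDR
expectation (also checked over 50 simulated-deviate repeats at 2000
proteins); and recovery of the spiked log2(4.67) effect within 3 standard
errors across ≥ 40 cargo proteins without dropout. These sizes keep the
default suite under half a minute while leaving the Monte-Carlo bands
tight.

Known limitations: the equal-variance t test inherits its assumptions
(imputed point masses can make small-sample mixtures non-normal; the null
calibration test shows the aggregate rate stays nominal at defaults);
combining more than two experiments is supported by the formulas but the
defaults and tests exercise the two-experiment design; and no between-sample
normalisation is applied — inputs are assumed already LFQ-normalised
upstream, so systematically shifted samples should be handled before entry.
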