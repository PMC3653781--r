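---
title: "Methods: inferring testis/epididymis promoter methylation from cfsDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring testis/epididymis promoter methylation from cfsDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design being modeled

Cell-free seminal DNA (cfsDNA) is a mixture of DNA from testis, epididymis
and the accessory glands. A successful vasectomy removes the
testis/epididymis (TE) component entirely, so two pooled MeDIP promoter
array hybridizations — normozoospermic donors (Nor) and post-vasectomy men
(PV) — differ exactly in the TE contribution. A promoter that is
methylated in the accessory-gland background but unmethylated in the TE
source shows a methylation peak in PV and a diluted, ideally undetectable
signal in Nor ("TE-specific hypomethylated"); the mirror pattern is
"TE-specific hypermethylated".

The cohort contrast quantifies the mixture: with group mean concentrations
`m_Nor` and `m_PV`, the TE fraction is `(m_Nor - m_PV) / m_Nor`. At the
study's means (1.23 and 0.33 µg/ml seminal plasma) this is 73.2%, which is
why the generator's default `fraction_te` is 0.73.

## The synthetic-data generator

`simulation_config()` describes a NimbleGen-style promoter tiling design:
one window per accession from 2200 bp upstream to 500 bp downstream of the
TSS in transcription orientation, tiled by 50 bp probes every 100 bp
(~27 probes per promoter; the real array had ~385,000 probes over 18,028
promoters, ≈129 bp spacing — 100 bp is a round near-match and
configurable). Promoters sit on synthetic chromosomes `chrS1...` with 8 kb
gaps so windows never overlap. Planted classes follow the study's observed
proportions: 9.71% hypo- and 3.53% hypermethylated. A further 9.6% of
promoters are methylated in both sources; this value was fixed so that the
expected fraction of promoters carrying a peak in at least one condition
is 9.71 + 3.53 + 9.6 ≈ 22.8%, the study's identified-promoter rate
(4111/18028). The remaining promoters are unmethylated in both sources.

### The probe signal model

Methylated loci are drawn at mean log2(IP/Input) `mu_methylated = 1.5`,
unmethylated at `mu_unmethylated = 0`, with per-probe Gaussian noise
`sigma_probe = 0.4` — log-ratio scale throughout; no linear-intensity or
dye-bias modeling.

Two mixture semantics are implemented for a condition with TE fraction
`f`:

* **`signal_model = "component"` (default).** Each probe is drawn from the
  TE component `N(mu(state_te), sigma)` with probability `f`, else from the
  background component. Partial methylation of the pooled sample presents
  as probe-level heterogeneity — some probes report near-full enrichment,
  others near background — while the expected probe mean keeps the closed
  form `f*mu(state_te) + (1-f)*mu(state_bg)` (0.405 for a hypomethylated
  promoter in Nor at defaults).
* **`signal_model = "mean"`.** Every probe is drawn from the mean-mixed
  value `N(f*mu_te + (1-f)*mu_bg, sigma)`.

The component model is the default because the mean model has a structural
pathology for this pipeline: it turns 27% residual methylated DNA into a
*uniform* +0.405 shift across all ~27 probes of a promoter, which a
rank-based KS caller correctly detects as a coherent enriched block. Under
the mean model most hypomethylated promoters therefore fail the
"absent in Nor" criterion, and the failure *worsens* as `sigma_probe`
shrinks (the shift becomes more detectable) — recovery degrades exactly
when the data get cleaner, which is not a usable validation target. The
component model keeps the same expected signal while representing partial
methylation as heterogeneity, the way enrichment arrays actually show it,
and its recovery improves (or is stable) as noise falls. Both models
coincide at `f` of 0 or 1.

### Ct-table generator

`simulate_ct_tables()` inverts the assay formulas so zero-noise tables
round-trip exactly: `Ct_IP - Ct_Input = -log2(enrichment /
dilution_factor)` and `ddCt = -log2(methylation)`, with PCR efficiency
fixed at 2. A planted methylation of exactly 0 cannot yield a finite Ct
and is emitted as a censored record. The methylation-specific reaction is
given a 9-cycle margin on unmethylated control DNA, comfortably above the
5-cycle specificity rule.

All generator operations are pure functions of their configuration and
seed (each op offsets the seed by a fixed small constant, so stages can be
re-run in isolation); `run_all()` with one master seed yields
byte-identical TSV outputs.

## Peak calling

One 750 bp window is centered on every probe midpoint; its probes are
tested for being stochastically **greater** than all other probes on the
array with a one-sided two-sample KS statistic
`D = sup_x [F_bg(x) - F_win(x)]`, clipped to [0, 1]. Both ECDFs are
right-continuous with ties sharing steps; the supremum is evaluated just
below each window jump point with strict "less than" counts, and the
permutation null uses the identical statistic.

* **p-values.** When `min(m, n) <= 8` *and* full enumeration is feasible
  (at most `max_exact_combinations = 1e5` assignments, with a total-work
  cap), p is the exhaustive permutation tail — the regime the oracle tests
  exercise. Otherwise p is the one-sided asymptotic tail
  `exp(-2 D² mn/(m+n))`, which by the one-sided
  Dvoretzky–Kiefer–Wolfowitz inequality never understates the null tail,
  so the score is conservative; p is clipped to (1e-300, 1]. On real-sized
  arrays the background holds ~27,000 probes, so the exact path only
  arises for single-probe windows on small profiles.
* **Significance semantics.** Each probe carries the score of the window
  centered on it, and peaks require at least `min_probes_per_peak = 2`
  significant probes (score ≥ 2) within `max_probe_spacing = 500` bp —
  the per-probe-score convention of NimbleScan-style callers. The
  alternative reading, "any probe covered by a significant window is
  significant", is available as `significance = "cover"`; it converts
  every single extreme window into a multi-probe peak and roughly doubles
  the false-present rate at diluted promoters, so it is not the default.
* **Peakscore.** The maximum window score among windows centered on member
  probes — a single `-log10 p` per peak, matching the classification
  thresholds' scale. Null calibration on i.i.d. Gaussian arrays gives a
  per-window rate of score ≥ 2 of about 0.005, versus the 0.01 nominal
  level.

Profiles are centered before scanning (Tukey biweight location by default,
iterated to machine precision; median or none selectable, recorded in
provenance). Because the KS statistic is rank-based, centering does not
change scores; it only makes reported log-ratios comparable across
profiles.

## Classification and summarization

A peak maps to a promoter on ≥ 1 bp interval overlap (GenomicRanges); a
promoter's per-condition score is the max over assigned peaks and 0 when
none — the only reading under which a vasectomy-abolished signal counts
as "absent". Thresholds follow the study: present means score strictly
above 3.0 (p < 0.001), absent strictly below 2.0 (p > 0.01); scores in
[2.0, 3.0] are indeterminate by design. Gene summarization takes the
unique differential class among a gene's promoters; genes with both
classes are flagged as conflicts and left unclassified — a conservative,
label-symmetric rule (the study states only that multiple promoters "were
summarized").

`tabulate_calls()` reports class percentages with a selectable
denominator: all scored promoters (default; comparable to the planted
proportions) or only "identified" promoters (≥ 1 peak in either
condition, the study's peak-bearing denominator). Both counts are always
returned, since the two rates answer different questions and the study's
denominator definition is not recorded.

## Operating characteristics on planted data

At the default conditions (1000 promoters, `fraction_te = 0.73`,
`sigma_probe = 0.4`, seed 1) the classifier recovers planted TE-specific
promoters with sensitivity ≈ 0.86 and precision 1.0, and the recovered
class percentages (8.1% / 3.2%) sit within binomial error of the planted
9.71% / 3.53%. The residual misses are structural, not noise: with 27%
methylated background DNA in Nor, a hypomethylated promoter occasionally
presents a local cluster of background-component probes whose window
clears score 2, violating the strict "absent" criterion. Because those
events are composition fluctuations, they do not shrink with
`sigma_probe`: sensitivity is essentially identical at sigma 0.2 and 0.4.
Sensitivity beyond ~0.9 at `f = 0.73` would require relaxing the absent
threshold or modeling replicate hybridizations, both outside this design.

Problem sizes used throughout the tests and acceptance script — 1000
promoters (27,000 probes per condition), 10 × 5000-window null arrays,
enumeration oracles up to 12-value pools and universes of 60 — were chosen
as the smallest sizes at which the binomial/Monte-Carlo error of each
check is well below its decision margin.

## Known limitations

* One pooled profile per condition, as in the study; no replicate or
  between-array normalization machinery.
* The generator draws i.i.d. Gaussian probe noise on the log-ratio scale;
  real arrays have probe-affinity effects, spatial artifacts and heavier
  tails, so passing planted-truth tests does not certify performance on
  real data.
* The KS background is the whole array (window excluded); no
  promoter-local or GC-matched null.
* Enrichment reports fold enrichment and BH q-values per category; no GO
  graph propagation and no annotation-cluster "enrichment score" (that
  quantity depends on proprietary clustering of terms).
* The real study's specific gene identities and counts (e.g. 367/134
  genes) derive from undeposited array data and are not reproducible
  here; the synthetic study validates the *procedure*, not those numbers.
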