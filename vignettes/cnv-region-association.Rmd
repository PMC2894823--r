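---
title: "Detecting copy-number variable regions and testing them against quantitative phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting copy-number variable regions and testing them against quantitative phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvrkit)
```

`cnvrkit` takes per-subject CNV calls produced by an upstream caller and
carries them through the three steps of a CNV-based genome-wide association
study: locus definition (sub-CNVR detection), per-subject genotype coding
(state assignment), and covariate-adjusted regression with genome-wide
significance control. This vignette documents the model behind each step,
the tunable parameters with their defaults, the numerical choices, the
design decisions that were genuinely open, and what the synthetic-data
validation does and does not demonstrate.

## The detection model

### Coordinates and coverage

All coordinates are 1-based, closed intervals, regardless of the source
dialect (BED catalogs are converted on import). For *counting*, a call
`[s, e]` covers the inter-border segments half-open, `[s, e)`: the sweep
counter increments at the starting SNP and decrements at the ending SNP,
and all events at one physical position are applied before any segment is
evaluated. Two consequences worth knowing:

* a reported region `[a, b]` is *bracketed* by the border positions `a`
  (opening) and `b` (closing); region boundaries are approximations by the
  physical positions of the bracketing SNPs, not variant breakpoints;
* a 1-bp call (`start == end`) covers no segment and contributes nothing
  to detection (it still participates in state assignment).

### Basic algorithm: sub-CNVRs

Per chromosome, the borders of all calls from all subjects form a sorted
event list. Every segment between consecutive distinct border positions
has a constant carrier count; the segment is reported as a **sub-CNVR**
when

$$\frac{\#\{\text{subjects with a CNV covering the segment}\}}{n_\text{subjects}} > t$$

with a *strict* inequality (so at `t = 0.75` a segment carried by exactly
3 of 4 subjects is rejected). Two details make the counter count
*subjects* rather than *calls*:

* each subject's overlapping calls on a chromosome are collapsed into
  maximal covering intervals before the counter runs (a subject with two
  overlapping deletions is one carrier, not two);
* segment boundaries nevertheless remain at the borders of the *raw*
  calls, so a potential sub-CNVR begins wherever any individual CNV begins
  or ends. The deduplication affects counting only.

The denominator is the full cohort size `n_subjects`, which must be
supplied explicitly when some subjects have no calls at all — the number
of subjects appearing in the call file is only a lower bound.

`coverage_profile()` computes the same per-segment carrier counts by
direct enumeration (an intentionally brute-force O(segments × calls)
scan sharing no code with the sweep). It exists as the reference
implementation: the test suite asserts that the one-pass sweep reproduces
it — boundaries, carrier sets and frequencies — on thousands of randomized
cohorts, and it powers the region-distribution summary.

### Extended algorithm: merging and states

With many subjects and interlaced CNVs the basic algorithm yields a
multitude of regions only two SNPs long. The extended algorithm
(`merge_sub_cnvrs()`, or `merge = TRUE` in `detection_config()`) merges
maximal chains of consecutive above-threshold sub-CNVRs — two sub-CNVRs
merge exactly when they share a bracketing border position, i.e. when no
below-threshold segment lies between them on the same chromosome. Merging
is lossless: every input region becomes a member of exactly one merged
region and `split_cnvrs()` restores the basic output bit for bit.

The frequency of a merged region is *recomputed over the merged span*: the
fraction of subjects carrying a CNV anywhere inside it (equivalently, the
union of the member carrier sets — no subject can overlap the span without
overlapping a member). Member frequencies are retained in the `members`
column. Whether a merged region should instead inherit some summary of its
members' frequencies was an open choice; recomputing is the only option
under which `frequency` keeps its plain meaning ("percentage of subjects
with a CNV inside the boundaries") for both algorithms.

In a merged region a subject's copy-number state is no longer unique, so a
second threshold defines it (`assign_states()`): among the subject's calls
overlapping the region take the one with the longest overlap; if

$$\frac{\text{overlap length}}{\text{region length}} > t_\text{state}
\quad (\text{default } 0.5, \text{ strict}),$$

the subject's state is that call's signed dose, otherwise 0. Region length
is `end − start + 1`. Two deliberate choices here:

* **"length" means overlap with the region**, not the call's absolute
  physical length — a percentage of the region length is the only reading
  under which the 50% default is meaningful for calls that extend beyond
  the region. For users who do want an absolute rule, `state_len_bp`
  switches the criterion to `overlap > state_len_bp` base pairs.
* **ties are broken deterministically**: equal longest overlaps prefer the
  larger absolute dose, then the leftmost start. Determinism everywhere is
  a hard requirement (identical inputs in any row order give identical
  outputs; the test suite asserts this).

### State coding

States are coded on one signed numeric scale so that a region enters the
regression as a single additive column: copy numbers 0, 1, 3, 4 map to
−2, −1, +1, +2; direction-only calls map to ∓1. In text formats a bare
value is a copy number and an explicitly signed value is a dose — this
disambiguates `1` (a deletion, CN1) from `+1` (a duplication), which the
one-column `state` vocabulary would otherwise conflate. CN = 2 is the
neutral diploid baseline and is rejected as a call: a CNV is by definition
a gain or a loss.

### Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `freq_threshold` | 0.05 | minimum carrier frequency, strict; raising it can only shrink the number of regions and the covered length (asserted property) |
| `min_snps` | 1 | calls spanning fewer array SNPs are discarded before detection (strict "fewer than"); calls with *missing* SNP counts are kept with a warning — metadata gaps fail open, coordinate errors fail closed |
| `merge` | `FALSE` | run the extended algorithm |
| `state_len_threshold` | 0.5 | overlap fraction a subject's longest CNV must exceed to define their state |
| `pool_states` | `TRUE` | count gains and losses together (a region is "subjects with *a* CNV"); `FALSE` detects loss- and gain-regions separately |

## The association model

Each region `r` is tested separately with ordinary least squares on the
filtered subjects with complete data:

$$y_i = \beta_0 + \beta_1\,\text{state}_{ri} + \mathbf{c}^\top
\mathbf{z}_i + \varepsilon_i .$$

* **Estimation.** The normal equations `X'X b = X'y` are solved by
  Gaussian elimination with partial pivoting (Gauss–Jordan on the
  augmented system, which also yields `(X'X)⁻¹` for the standard errors
  `se_j = sqrt(s² [(X'X)⁻¹]_jj)`, `s² = RSS/(n−k)`). A pivot below
  `1e−10 ×` the largest pivot raises a collinearity error naming the
  offending column. The suite cross-checks coefficients and standard
  errors against R's QR-based `lm()` to 1e−8 relative error on thousands
  of random problems.
* **Inference.** Two-sided Student t-test of β₁ with `df = n − k`, `k`
  counting the intercept. (Whether the historical convention here was
  `n − k` or `n − k − 1` is ambiguous; `n − k` is the standard OLS
  residual df and is fixed throughout.) The degenerate exact-fit case
  `se = 0` maps to p = 0 for a nonzero effect and p = 1 otherwise.
* **Multiplicity.** A region is genome-wide significant when
  `p < alpha / M` where `M` is the number of regions *actually tested* in
  the run — monomorphic regions (state variance zero over the analysed
  subjects) and regions with too few complete observations are excluded
  from `M` and listed with their reason in the `skipped` attribute, never
  silently dropped. Changing `alpha` rescales the flags with no refit.
* **Missing data.** Complete-case per analysis: a subject missing the
  response, the state, or any covariate is excluded from that region's fit
  only. Missing phenotype cells are missing, never zero.
* **Filters.** `subject_filter("sex", "==", 1)` etc. restrict the run to a
  subject subset; subjects missing a filtered column are excluded. Adding
  a filtered-out subject to the inputs changes no statistic (asserted).

### Combined SNP + CNVR analysis

For each region and each genotyped SNP inside its span the model gains the
SNP's additive B-allele dose:

$$y = \beta_0 + \beta_\text{snp}\,d + \beta_\text{state}\,s +
\mathbf{c}^\top \mathbf{z} + \varepsilon,$$

with per-term t-tests and a joint 2-df F-test of `(d, s)` against the
covariate-only model; `M` counts (region, SNP) models. The notion of a
"cumulative effect" of SNPs and CNVs is underdetermined — a joint model, a
sum score, and sequential conditioning are all defensible readings. The
joint model was chosen because it is the only one that yields a
well-defined test for each component while measuring their combined
contribution; treat the other readings as out of scope. When the state is
constant over the analysed subjects the model degrades to SNP-only (state
term absent, 1-df joint test) with a warning.

## Visualization

`manhattan_plot()` draws −log₁₀ p against cumulative genomic position —
chromosomes concatenated in natural order (1..22, X, Y) with fixed 2%
gaps, alternating colors — and a dashed line at `−log₁₀(alpha/M)` computed
from the `M` actually tested. p-values of zero are clipped to a display
ceiling of 10⁻³²⁰ and the caption says how many points were clipped.
`annotate_catalog()` flags results whose span overlaps a catalog region by
at least 1 bp on the same chromosome (the overlap rule had to be fixed
somewhere; ≥1 bp is the most permissive defensible choice and is purely
annotational — no statistic or ordering changes). Each image is
accompanied by a JSON sidecar carrying `alpha`, `M`, the line height and
per-point metadata, so the plotted quantities are machine-checkable — the
file-based replacement for interactive click-to-inspect.

## The synthetic-data generator

`simulate_dataset()` emulates the data a CNV-GWAS consumes, at desk scale:

* **SNP map**: jittered grid, mean spacing 50 kb, 2 chromosomes × 10 Mb
  (≈ 200 markers each).
* **Cohort**: 500 subjects; covariates age ~ N(50, 10²) years and sex
  ∈ {1, 2}.
* **Planted region**: a 1-Mb (21-SNP) deletion region at carrier frequency
  0.2 with additive effect β = 0.5 per dose unit on a phenotype with
  residual SD 1. Carriers are drawn i.i.d.; their call breakpoints are
  jittered by up to 2 SNPs per side, which is what fragments the region
  into many sub-CNVRs and makes the merge step do real work.
* **Background**: Poisson(2) CNVs per subject per chromosome, 3–10 SNPs
  long, random direction — enough to give segments near but mostly below a
  0.1 detection threshold.
* **Genotypes**: per-marker allele frequency uniform on (0.05, 0.5),
  Hardy–Weinberg doses.

These sizes keep a 200-replicate end-to-end power study in tens of
seconds; `cohort_scale = TRUE` switches to a cohort-scale stress preset
(1,650 subjects, thousands of CNVs per subject) for optional heavy runs.
All randomness flows from one integer seed; identical seeds give
byte-identical fixture bundles.

What the generator does **not** model — and hence what passing tests do
not show about real data: linkage disequilibrium between SNPs, correlation
between CNV carriership and genotype, population structure or relatedness,
non-Gaussian phenotypes, batch effects in calling, and systematically
biased (rather than symmetrically jittered) breakpoints. Calibration and
power results transfer to real cohorts only to the extent that the
regression assumptions hold there.

## Validation summary

The test suite asserts, among others:

* sweep-line detection ≡ brute-force coverage enumeration on 1,000
  randomized cohorts (boundaries, carrier sets, exact rational
  frequencies);
* region count and covered length non-increasing in the frequency
  threshold;
* merge → split is the identity; state assignment honours the strict
  overlap rule on constructed boundary cases;
* OLS ≡ reference `lm()` to 1e−8; t p-values ≡ direct quadrature of the
  t density to 1e−8;
* under a null model (200 subjects × 200 regions × 500 replicates) the
  raw p < 0.05 rate lies in [0.035, 0.065] and no region passes Bonferroni
  in ≥ 95% of replicates;
* with the planted effect (500 subjects, frequency 0.2, β = 0.5, 200
  seeds) the planted span is recovered at ≥ 80% reciprocal overlap and the
  95% CI covers the true β in ≥ 90% of seeds;
* every reader/writer pair round-trips (numerics to ≥ 12 significant
  digits; p = 10⁻³⁰⁰ without underflow).

`scripts/acceptance.R --seed N --out f.json` re-runs a condensed version
of all of the above against the installed package and writes the measured
quantities as JSON.

## Known limitations

* Quantitative phenotypes only — no logistic model for case/control
  traits; nominal phenotypes must be numerically encoded upstream.
* No population-structure or relatedness correction (no mixed models), and
  no FDR alternatives to Bonferroni.
* Region boundaries are bracketing-SNP approximations; X/Y dosage is not
  modeled beyond the signed-dose code.
* The segment-summary reader is a tolerant reconstruction of a proprietary
  export whose exact layout is not publicly documented; the generic CSV is
  the canonical, fully specified interchange format.
* The genotypic (factor) coding of states is deliberately not offered:
  the additive signed-dose model is the single coding used.
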