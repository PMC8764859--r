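---
title: "Dual-platform detection of embryo mosaicism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-platform detection of embryo mosaicism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtmosaic)
```

## The problem

In preimplantation genetic testing for aneuploidy (PGT-A), a trophectoderm
biopsy of 5–10 cells is amplified once by multiple displacement
amplification (MDA) and the product can be assayed on more than one
platform. A *mosaic* embryo carries two or more cell lines with different
karyotypes; neither platform observes cells — both infer mosaicism from an
**intermediate copy-number signal**, somewhere between the integer dosages
of monosomy (1), disomy (2) and trisomy (3).

`pgtmosaic` models this measurement chain end to end: it simulates the cell
mixture, the shared amplification bias, and the two platform read-outs
(SNP-array LogR/BAF; low-pass NGS binned read counts); calls per-arm ploidy
under each platform's published-style criteria; classifies the
between-platform concordance of the calls at chromosome-arm resolution; and
aggregates a cohort into stratified contingency comparisons. Because both
synthetic assays consume the *same* simulated MDA product, the package can
separate disagreement caused by platform criteria from disagreement caused
by sampling a different biopsy.

## The simulator

### Cell mixtures

A biopsy truth is a set of cell lines (each a `cell_karyotype`: integer
copy numbers on a disomic baseline) with population fractions. Two
constructors exist deliberately:

* `biopsy_truth()` takes **exact fractions** — the analytic mixture whose
  mean copy number over a region is
  $\bar c = \sum_i f_i \, c_i$ (`expected_copy_number()`). This is the
  quantity depth-based platforms estimate, and it is the oracle every
  noiseless test is checked against.
* `make_biopsy()` draws the **realized cell composition** of a small biopsy:
  the abnormal-cell count is $\mathrm{Binomial}(n_\mathrm{cells}, f)$, so a
  5-cell biopsy quantizes the mosaic fraction to multiples of 0.2. This is
  the honest small-biopsy model; it is tested against the binomial pmf.

The distinction matters for interpretation: detection-performance
statements at "fraction 0.40" refer to the exact mixture (rendering noise
only). With biopsy-size quantization included, a large share of the spread
in recovered levels comes from the binomial draw itself, not the assay —
with 10 cells, the realized fraction lands within ±0.1 of 0.4 only about
two-thirds of the time, which is a property of small biopsies, not of
either platform.

### Complementary errors

Two mixtures with equal mean copy number are indistinguishable to any
depth-based caller. The canonical example: 40% monosomy + 60% trisomy and
80% disomy + 20% trisomy both average $\bar c = 2.2$ and both read as "20%
mosaic gain"; a balanced monosomy/trisomy mixture averages 2.0 and reads as
euploid. The package asserts this equivalence *at matched seeds*: the two
mixtures produce bit-identical NGS signals and therefore identical
diagnoses.

### The shared MDA layer

`simulate_mda()` draws one multiplicative weight per genomic tile,
$w = 2^{\,N(0,\ \sigma_{\log})}$, mean-normalized. The base-2 choice makes a
tile's contribution to LogR exactly $N(0, \sigma_{\log})$, so the
SNP-array QC statistic has a closed-form expectation (below). Both
renderers take the same weight object, mirroring the single-amplification,
dual-assay design.

Defaults (the paper of record for this design gives no noise magnitudes;
these are fixed package choices, stated once):

| parameter | default | reasoning |
|---|---|---|
| `tile_kb` | 100 | MDA amplicon length scale (tens of kb) |
| `sigma_log` | 0.2 | with `sigma_lrr` 0.15, per-marker LogR SD is 0.25, putting the chip QC statistic at $0.6745 \times 0.25 \approx 0.17$, just inside its 0.2 gate — a decent chip on a single-cell-grade sample |
| `sigma_lrr` | 0.15 | typical array LogR scatter |
| `sigma_baf` | 0.03 | BAF bands stay visually distinct up to ~80% mosaicism |
| `het_prob` | 0.3 | common array heterozygosity |
| `nocall_prob` | 0.01 | call rate 0.99, above the 0.98 gate |
| `bin_kb` | 1000 | the 4 Mb segmental floor spans ≥ 4 bins |
| `total_reads` | 750000 | the platform guarantees at least 0.7 M reads; runs deliver a margin above the floor, so the QC gate is meaningful rather than a coin flip on the Poisson total |
| `overdispersion` | 0.1 | counts are negative binomial with $\mathrm{var} = \mu(1+\phi)$ — mild extra-Poisson noise; the MDA layer carries the dominant WGA variability |
| `gc_coeffs` | (1, −10) | log-linear/quadratic GC response around GC = 0.42 |

### Renderers

`render_snp()`: markers are laid evenly; per marker the mixture's mean
total copies $\bar c$ and mean B-allele copies $\bar b$ follow allele-copy
arithmetic (the gained or lost homologue is drawn once per marker and
shared across cell lines), then

$$\mathrm{LogR} = \log_2\!\Big(\frac{\bar c}{2}\, w\Big) + N(0, \sigma_{LRR}),
\qquad \mathrm{BAF} = \frac{\bar b}{\bar c} + N(0, \sigma_{BAF})
\ \text{truncated to } [0,1].$$

So a pure trisomy puts heterozygous BAF at $\{1/3, 2/3\}$, and a 20%
trisomy at $\{1/2.2,\ 1.2/2.2\} \approx \{0.455, 0.545\}$ — the
characteristic narrowing that makes shallow mosaics hard for arrays.

`render_ngs()`: bin expectations are
$\lambda_b \propto \text{width}_b \cdot (\bar c_b/2) \cdot w_b \cdot
g(\mathrm{gc}_b)$, normalized to the configured total; counts are negative
binomial (`exact = TRUE` returns the expectations — the noiseless limit
used by oracle-equivalence tests). Run metadata (map ratio, duplicate
rate, GC content) is drawn so QC gates are exercisable.

What the generator does **not** emulate: allele dropout and chimeric MDA
artifacts, locus-specific (sequence-driven) amplification bias, real
Giemsa band boundaries, chaotic multi-line mosaicism, X/Y dosage (the
baseline is XX), read-level errors, or within-embryo spatial clustering of
abnormal cells (biopsies are binomial, not clustered). Passing tests
therefore demonstrate that the *criteria and pipeline* behave as specified
on signals with realistic first- and second-moment structure — not that
either platform achieves these error rates on real embryos.

## The SNP-array caller

QC (`snp_qc`): median over autosomal markers of |LogR − median LogR| must
be < 0.2, and the call rate > 0.98.

Per arm (`summarize_arms`, `call_snp`):

* **BAF scatter** — the criterion "heterozygous BAF not concentrated at
  0.5" needs an operational statistic; ours is the fraction of
  het-pattern markers (called, BAF ∈ [0.15, 0.85]) with |BAF − 0.5| >
  `tau_baf` (0.1), and an arm with *no* het-pattern markers scores 1,
  because a vanished 0.5 band (full monosomy) is itself maximal
  non-concentration. The trigger threshold `theta_scatter` is 0.5.
* **Dosage** — with scatter triggered, median LogR > 0.2 is a mosaic gain
  and < −0.2 a mosaic loss. Beyond `log2(1.45)` / `log2(0.55)` (dosage
  within 10% of CN 3 or 1) the call is non-mosaic aneuploidy; the source
  criteria never state the mosaic-vs-full boundary, so it is an explicit,
  configurable parameter.
* **Segments** — a changepoint scan (binary segmentation on marker LogR)
  with a 10 Mb minimum span; arrays resolve coarser segments than
  sequencing and no figure is published, so 10 Mb is a conservative,
  documented default. Adjacent segments with the same classification are
  healed; a segment covering ≥ 95% of an arm becomes an arm call; both
  arms agreeing in direction, mosaicism and dosage (|ΔLogR| ≤ 0.15) merge
  into one whole-chromosome event.
* The SNP platform **never** reports a mosaic level.

A consequence worth knowing: at 40% trisomy the het bands sit only ~0.083
from 0.5 — inside `tau_baf` — so the default SNP caller does not call it.
The array's practical window opens around 50–60% mosaicism, consistent
with the field's experience that arrays are reliable mainly for mid-range
mosaic fractions while depth-based NGS reaches lower.

## The NGS caller

QC (`ngs_qc`): total reads ≥ 700,000; Map_Ratio ≥ 80%; GC content within
39–45%; SD < 3.5. The vendor's SD metric is opaque; ours is defined
operationally as the standard deviation of the per-bin copy-number
estimates (2 × GC-normalized ratio) over autosomal bins, and the 3.5 gate
is configurable because the scale correspondence is unknown. At default
noise our SD is ≈ 0.2, far inside the gate.

`gc_normalize()` works on per-bp coverage rates (so partial bins at
chromosome ends are comparable), divides each bin by its GC-decile median
rate, and rescales the autosomal median ratio to 1. A decile without bins
falls back to the global median. This removes the injected log-quadratic
GC curve to within 2% on a disomic genome while leaving true dosage
intact.

`segment_cnv()` runs per-arm binary segmentation on $2 \times$ ratio with
a BIC-style stopping rule (penalty × noise variance × log n; noise
variance estimated robustly from first differences, with a floor so
constant input never splits on float jitter). Boundary bins strictly
closer to a neighboring segment's mean are handed over before the 4 Mb
resolution floor is enforced — this prevents a sub-floor event from
borrowing a neighbor's bin to reach 4 bins — and segments still shorter
than the floor merge into their nearest neighbor. Arms covered by one
segment promote to arm scope; the two arms of a chromosome promote to a
single whole-chromosome segment when their CNV values agree within 0.3
(chosen as ≈ 4 standard errors of an arm-median difference at default
noise, so whole-chromosome events are not split by arm-level jitter while
a genuine one-arm event two classes away never merges).

`classify_cnv()` applies the interval rule on the CNV scale (disomy = 2):

| CNV value | class |
|---|---|
| < 1.20 | pure aneuploid loss |
| [1.20, 1.80] | mosaic loss |
| (1.80, 2.20) | euploid |
| [2.20, 2.80] | mosaic gain |
| > 2.80 | pure aneuploid gain |

The printed source ranges share the endpoints 1.80 and 2.20 between
classes; we resolve the tie as mosaic-closed / euploid-open because the
complementary-error worked example calls a mean CN of exactly 2.2 "20%
mosaicism", not euploidy. The mosaic level is
$|\mathrm{CNV} - 2| \times 100$, rounded — a formula that is implied rather
than stated, adopted because it reproduces the 20% example and puts the
transferability boundary (level 50) exactly at CNV 1.5 / 2.5.

```{r classify}
classify_cnv(2.2)
classify_cnv(1.5)
```

## Concordance classification

`classify_concordance()` reduces each platform's *mosaic* events to type
keys `(chromosome, whole|p|q, direction)` and compares the two sets.
Deletion vs duplication of the same arm are different types; so are
whole-chromosome vs single-arm mosaicism of the same chromosome; segment
coordinates within an arm are ignored entirely. The five categories:
identical key sets → `complete`; overlapping → `partial` (including NGS
detecting a superset); disjoint (both non-empty) → `discordant_mosaic`; no
NGS mosaic key with pure-aneuploid NGS events → `aneuploid_by_ngs`; no NGS
events at all → `euploid_by_ngs`.

Two genuinely open points were resolved as follows:

* **Mixed NGS diagnoses** (mosaic + pure-aneuploid events): the mosaic keys
  drive the category, because the aneuploid/euploid-by-NGS branches are
  defined by the *absence* of NGS mosaicism — the only reading consistent
  with a five-way accounting that sums to the cohort.
* **Whole vs arm, same direction, same chromosome**: scored discordant (the
  type rule), even though the calls physically overlap. Because a
  reasonable analyst might instead score this partial, the result object
  carries `whole_arm_overlap_flag` so a cohort can be re-tallied under
  either convention without re-running the callers.

`is_transferable()`: no pure aneuploid event and every mosaic level ≤ 50
(the boundary is inclusive).

## Cohort statistics

`pearson_chi2()` is the classical statistic **without continuity
correction** — with Yates' correction the whole-vs-segmental stratum would
give p ≈ 0.418 instead of the printed 0.315, so the uncorrected form is
load-bearing and the test suite pins both facts. `fisher_exact()` is the
two-sided exact test (checked against an exhaustive hypergeometric
enumeration oracle); `compare_groups()` applies the fallback rule: any
expected count < 5 → Fisher, else chi-square. `cohort_summary()` emits the
five-way concordance accounting, the NGS outcome split (mosaic levels
dichotomized at 50%), transferability, and the three strata (maternal age
at 35, whole vs segmental SNP mosaicism with "both"-type embryos excluded,
embryo quality).

## Numerical choices and problem sizes

* Every stochastic operation takes an explicit seed and runs on a local
  RNG; the global `.Random.seed` is restored afterwards, so identical
  seeds give byte-identical outputs regardless of call order.
* Changepoint penalties: 4 for NGS bins; 6 for SNP markers, stiffer
  because marker noise is correlated within WGA tiles, which inflates the
  variance of segment means relative to the iid estimate the penalty is
  scaled by. Both are calibrated for specificity on disomic genomes
  (≈ 0.5 spurious events per genome at default noise) while keeping ≥ 4 Mb
  events at moderate mosaic fractions detectable.
* The bundled cytoband table lays an ISCN-style naming scheme
  (regions/bands/sub-bands) over real hg19 arm lengths by equal
  subdivision; it is synthetic (no Giemsa measurement) and is labelled as
  such in its filename and header. Band-range loci resolve by prefix, so
  `16p12.2-q21` spans the centromere and keys both arms.
* Test and verification sizes: noiseless oracle checks run on 2–4
  chromosome subsets with 6,000–30,000 markers and 1 Mb bins;
  the stochastic recovery study uses 200 full-genome replicates at the
  default 300k-marker/750k-read geometry's binned equivalent (~3,100
  bins). These sizes give standard errors comfortably below the margins
  they are checked against.

## Known limitations

* The SNP caller's mosaic-vs-full boundary, its 10 Mb segmental floor, and
  the NGS SD scale are package conventions for under-specified vendor
  behavior; all are exposed as parameters.
* Arm promotion can split a genuine whole-chromosome event into two arm
  events (or vice versa) near the merge threshold; at key level this
  changes `complete` to `partial`-with-flag rather than silently losing
  the chromosome.
* The X and Y chromosomes are rendered on an XX baseline only; sex-
  chromosome dosage calling is out of scope.
* Real supplementary tables vary in column layout; `read_diagnosis_table()`
  takes a per-column dialect mapping and reports unparseable rows rather
  than dropping them, but the dialect must be supplied by the user.
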