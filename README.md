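# pgtmosaic

Dual-platform detection and concordance analysis of embryo mosaicism in
preimplantation genetic testing for aneuploidy (PGT-A).

A mosaic embryo carries two or more cell lines with different karyotypes.
When a 5–10-cell trophectoderm biopsy is amplified once by MDA and assayed
on both an SNP array and low-pass NGS, neither platform sees cells: both
infer mosaicism from an **intermediate copy-number signal**. For a mixture
with abnormal-cell fraction *f* and event copy number *c*ₑ, the measured
dosage is the mixture mean

> c̄ = (1 − f)·2 + f·cₑ,

so a 40% trisomy reads as c̄ = 2.4, and complementary mixtures with equal
means (40% monosomy + 60% trisomy vs 80% disomy + 20% trisomy, both
c̄ = 2.2) are indistinguishable in principle. `pgtmosaic` is for
reproductive-genetics analysts and methods researchers who want to study
how the two platforms' calling criteria behave — separately and against
each other — on exactly this kind of signal.

The package provides:

* a **simulator** for mixed-cell biopsies: binomially quantized cell
  sampling, a shared log-normal MDA amplification-bias layer, and renderers
  for a ~300k-marker SNP signal (LogR = log₂(c̄/2·w) + noise, BAF = b̄/c̄ +
  noise) and ≥0.7M-read binned NGS coverage with GC bias;
* an **SNP-array caller**: chip QC (median LogR deviation < 0.2, call rate
  > 0.98), per-arm mosaic calls when the heterozygous BAF scatter leaves
  0.5 and |median LogR| > 0.2, full-aneuploidy dosage bounds, and a 10 Mb
  segmental scan — never reporting a mosaic level;
* an **NGS caller**: run QC (reads ≥ 0.7M, Map_Ratio ≥ 80%, GC 39–45%,
  SD < 3.5), GC-decile normalization, per-arm binary segmentation with a
  4 Mb resolution floor, and the CNV-value interval rule — mosaic for
  CNV in [1.20, 1.80] ∪ [2.20, 2.80], euploid in (1.80, 2.20), pure
  aneuploid outside [1.20, 2.80] — with mosaic level |CNV − 2| × 100;
* **concordance classification** at chromosome-arm resolution into
  complete / partial / discordant-mosaic / aneuploid-by-NGS /
  euploid-by-NGS, plus the ≤50%-level transferability rule;
* **cohort statistics**: Pearson chi-square without continuity correction,
  Fisher's exact fallback when an expected count is below 5, and stratified
  summary tables.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
`autoplot()` views; a thin command-line wrapper ships in `inst/cli/`.

## Worked example

Simulate a biopsy in which 60% of cells carry a 2q deletion, render both
platform signals from one MDA product, call both platforms, and compare:

```r
library(pgtmosaic)

genome <- genome_model()
dis <- cell_karyotype(genome = genome)
abn <- cell_karyotype(parse_mosaic_notation("-2q", genome), genome = genome)
truth <- biopsy_truth(list(dis, abn), c(0.4, 0.6))
truth
#> <biopsy_truth> 2 cell line(s), 5 cells
#>    40.0%  disomic
#>    60.0%  2q CN1

mda <- simulate_mda(genome, seed = 5)          # one WGA layer, two assays
snp <- render_snp(truth, mda, genome = genome, seed = 6)
ngs <- render_ngs(truth, mda, genome = genome, seed = 7)

d_snp <- call_snp(snp, genome, embryo_id = "E06")
d_ngs <- call_ngs(ngs, genome, embryo_id = "E06")
d_snp
#> <platform_diagnosis> SNP embryo E06
#>   call: -mos(2q)  [mosaic]
#>   qc: pass
d_ngs
#> <platform_diagnosis> NGS embryo E06
#>   call: -mos(2q)  [mosaic]
#>   qc: pass

classify_concordance(d_snp, d_ngs, genome)
#> <concordance_result> complete
#>   SNP keys: 2:q:loss
#>   NGS keys: 2:q:loss

is_transferable(d_ngs)
#> [1] FALSE
```

Both platforms recover the 2q mosaic loss — the arm-level type keys
`(chromosome, arm, direction)` match, so the pair is *complete*
concordance. The NGS call carries a mosaic level near 60%, above the 50%
transferability bound, so the embryo is untransferable. The
complementary-error arithmetic is one line:

```r
classify_cnv(2.2)
#> # A tibble: 1 × 3
#>   class  direction level_percent
#>   <chr>  <chr>             <dbl>
#> 1 mosaic gain                 20
```

Cohort tables (one row per embryo, calls in the `-mos(2q)` /
`+mos(16p12.2-q21)` notation) are ingested with `read_diagnosis_table()`,
classified with `cohort_records()`, and summarized with
`cohort_summary()`, which prints the five-way concordance accounting, the
NGS outcome split at level 50%, transferability, and the stratified
chi-square/Fisher comparisons.

## Layout

```
R/                  genome model & notation, simulator, SNP/NGS callers,
                    concordance, cohort statistics, io, tidiers, plots
inst/extdata/       synthetic cytoband table (hg19 arm lengths)
inst/cli/pgtmosaic  command-line wrapper (simulate | call-snp | call-ngs |
                    concord | stats | report)
tests/testthat/     unit, property and acceptance suites
scripts/            acceptance.R
vignettes/          methods vignette
```
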