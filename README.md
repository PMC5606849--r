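# vertebrome

MicroCT-based phenomics of the adult zebrafish vertebral column.

Adult zebrafish are small enough that a whole spine fits in one microCT
scan, which makes the vertebral column a natural testbed for *deep
phenotyping*: instead of measuring a handful of traits at one bone,
measure morphology and mineralization at every vertebra and ask whether
the *pattern along the column* differs between groups. `vertebrome`
implements that workflow end to end for people running zebrafish skeletal
screens or characterizing mutants of human bone-disease genes:

* **Segmentation.** Reads a DICOM microCT series, thresholds it
  (IsoData with a configurable correction factor, 0.73 by default), and
  separates touching vertebrae from user-supplied seed lines by growing a
  separation plane until the connected components on its two sides have
  distinct plurality labels. Each vertebra is then split into neural
  arch, centrum and haemal arch/rib masks from the seed-line endpoints
  (with a 5-voxel centrum buffer).
* **Morphometry.** 25 measures per vertebra: volume, surface area,
  model-independent local thickness, tissue mineral density
  (`mgHA/cm³ = (x/4096)·slope + intercept`), their intra-specimen SDs,
  for each element and the whole vertebra, plus centrum length.
* **Pattern statistics.** For each feature the per-vertebra values form a
  curve; a two-group difference in the curve is tested with a global
  score test. With group indicator `y` and centred covariate matrix `X`
  (fish × vertebrae), the statistic is the quadratic form

      Q = (y - ȳ)ᵀ X Xᵀ (y - ȳ) / (y - ȳ)ᵀ(y - ȳ)

  whose null distribution is a mixture of chi-squares obtained from the
  eigenvalues of the covariate Gram matrix (numerical inversion by
  Imhof's integral), or an exact permutation distribution for tiny
  designs. Skeletal barcodes (z-scores against the pooled control
  population), pairwise correlation profiling, and Royston's
  multivariate-normality screen complete the toolkit.
* **Power analysis.** A Monte-Carlo engine estimates sensitivity,
  specificity and power of (a) the global test, (b) a single-vertebra
  Welch t-test and (c) a t-test of the vertebra-averaged value, for
  mutant effects `d_i` expressed in WT per-vertebra SDs — uniform
  (`d_i = d`) or ramped (`d_i = (i-1)/(k-1)·d`) — using multivariate
  normal models estimated from control cohorts.
* **Allometry.** Growth follows `y = a·xᵇ` in standard length `x`;
  fitting log–log OLS per feature lets you slide control fish to a
  reference length with `y* = y·(x*/x)ᵇ`, so mutants with altered growth
  can be compared against length-matched "virtual" controls. TMD is
  never rescaled directly: tissue mineral content (TMC = Vol × TMD) and
  volume are normalized independently and TMD is recomputed.
* **Phantoms.** A synthetic spine generator (hourglass centra, neural and
  haemal blades, known intensities and noise, analytic truth tables)
  makes every imaging claim testable without scan data.

## Worked example

Segment a noiseless phantom and read off its phenome:

```r
library(vertebrome)

ph  <- generate_spine_phantom(phantom_spec(noise_sd = 0, seed = 7))
run <- run_pipeline(ph$volume, ph$seeds)
run$threshold
#> [1] 8942.5
run$phenome[, c("vertebra", "Cent.Vol", "Cent.TMD", "Cent.Th",
                "Haem.Vol", "Cent.Le")]
#>  vertebra Cent.Vol Cent.TMD Cent.Th Haem.Vol Cent.Le
#>         1 36747648    698.7    69.8 16299360     588
#>         2 36747648    698.7    69.8 16299360     588
#>         3 36747648    698.7    69.8  7130970     588
#>         4 36747648    698.7    69.8  7130970     588
```

Volumes (µm³) match the phantom's voxel-count truth exactly; TMD
(mgHA/cm³) equals the calibrated design intensity; the anterior
vertebrae carry the larger rib-bearing haemal volumes; centrum length
equals the designed 588 µm pitch.

Estimate a control model and ask how the three test procedures fare
against a mutant whose Tot.TMD is uniformly 4 SD high (n = 3 per group):

```r
wt <- simulate_phenome_cohort(16, seed = 101)
m  <- estimate_mvn(wt, "Tot.TMD", 1:16)
run_power_analysis(m, effect_pattern(4, "uniform", 16), n = 3,
                   alpha = 0.05, n_sims = 2000, seed = 1)
#>  procedure sensitivity specificity
#>     global      0.9760      0.9515
#>   t_single      0.8815      0.9675
#>     t_mean      0.9330      0.9655
estimate_fdr(0.96, 0.05)   # two-urn FDR at that operating point: ~5%
```

The global test over the 16-vertebra pattern detects the shift more
often than either t-test at the same nominal specificity — the core
argument for phenotyping patterns rather than single sites.

A shell front-end wraps the same functions
(`exec/vertebrome phantom|pipeline|compare|power`).

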