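# kaedeFlux

Quantification of local protein synthesis in growing axons from
photoconvertible (Kaede) fluorescence timelapse imaging — for cell and
developmental biologists running photoconversion assays of mRNA
localization, and for methodologists who want the measurement chain as
tested, reusable code rather than a one-off image-analysis macro.

## The assay and the statistic

Kaede switches irreversibly from green to red emission under 405 nm light.
Photoconverting an axon zeroes its green signal while leaving a stable red
reference; green fluorescence that reappears afterwards is newly made
protein. If the reporter mRNA carries the β-actin 3'UTR — with its
bipartite zipcode element (GGACT … ACA) bound by Igf2bp1/ZBP1 — new green
protein appears locally in the growth cone; without it, green can only
arrive from the soma.

From each two-channel z-stack timelapse (10 stacks, 10-minute intervals)
and a per-timepoint retrograde trace, the pipeline computes:

1. a binary mask from the red stack (Otsu), used to restrict the green
   stack to the axon;
2. SUM projections and the green/red **ratio image**
   `ratio(x, y) = ΣzG / ΣzR`, defined only where the red denominator
   reaches a floor;
3. the ratio along the first 150 trace pixels (32 µm), averaged into 15
   ten-pixel bins (bin 1 = growth cone, bin 15 = proximal axon);
4. per timepoint, the **spatial gradient** — the OLS slope `b(t)` of bin
   mean vs bin-center distance from the growth cone;
5. per axon, the **gradient rate** — the OLS slope of `b(t)` vs time
   `t = 0, 10, …, 90` min.

A negative rate means growth-cone enrichment of new protein is increasing
through the timelapse. Rates of +UTR and −UTR axons are compared with an
exact two-sided Mann-Whitney U test (full enumeration for `n_a + n_b ≤ 16`,
so the 6-vs-10 design is always exact), and the four final-timepoint region
groups with one-way ANOVA + Tukey HSD.

Because the original imaging data are not public, the package ships a
ground-truthed simulator: 1-D reaction–diffusion–transport kinetics of the
green and red pools along a growing axon
(`∂tG = D ∂s²G − v ∂sG + k_local·1[tip]`, soma influx `J`, closed tip),
rendered into noisy two-channel z-stacks with PSF blur, Poisson shot noise
and read noise. Satellite tools cover the study's two side computations:
3-D Laplacian-of-Gaussian spot counting with exclusion-region bookkeeping
(apoptotic-cell counts) and the bipartite zipcode motif scanner.

## Worked example

Simulate a small cohort at the default study conditions and quantify it:

```r
library(kaedeFlux)

cohort <- generateCohort(nPlus = 4, nMinus = 3, simulationConfig(), seed = 42)
report <- quantifyCohort(cohort)

report$rates[, c("axon_id", "condition", "rate", "r_squared")]
#>   axon_id condition          rate    r_squared
#> 1  axon01      +UTR -4.576592e-05 9.870711e-01
#> 2  axon02      +UTR -4.509592e-05 9.938290e-01
#> 3  axon03      +UTR -4.549267e-05 9.948879e-01
#> 4  axon04      +UTR -4.508536e-05 9.912279e-01
#> 5  axon05      -UTR  3.387106e-09 6.302250e-06
#> 6  axon06      -UTR -1.824349e-07 2.663177e-02
#> 7  axon07      -UTR  7.356647e-08 3.447352e-03

report$mannWhitney
#> Mann-Whitney U: statistic = 0, p = 0.05714 (exact enumeration)
```

Every +UTR axon has a clearly negative gradient rate (about
−4.5×10⁻⁵ ratio·px⁻¹·min⁻¹ with r² ≈ 0.99): the green/red ratio gradient
steepens toward the growth cone throughout the timelapse. The −UTR rates
sit at zero within noise. U = 0 means complete separation of the two
groups; with only 4 + 3 axons the smallest achievable exact p is
2/C(7,3) ≈ 0.057, which is what is reported — group size, not effect
size, limits significance here. The underlying bin means show the effect
directly (axon 1, growth cone vs proximal bin):

```r
subset(report$profiles, axon_id == "axon01" &
       timepoint_min %in% c(0, 90) & bin_index %in% c(1, 15))
#>     axon_id timepoint_min bin_index ... mean_ratio
#> 1    axon01             0         1        0.10369799
#> 15   axon01             0        15        0.09729425
#> 136  axon01            90         1        0.79707152
#> 150  axon01            90        15        0.08986524
```

The growth-cone ratio climbs from 0.10 to 0.80 over 90 minutes while the
proximal bin stays at the residual level — the signature of
3'UTR-dependent local translation.

The zipcode scanner, on a sequence built as GGACT, seven spacer
nucleotides, then ACA:

```r
scanZipcode(c(utr = "GGACTAAAAAAAACA"))
#>   record_id pos_ggact pos_aca spacer_nt matched_substring
#> 1       utr         0      12         7   GGACTAAAAAAAACA
```

A command-line dispatcher over the same functions is installed at
`inst/scripts/kaede-flux` (subcommands: simulate, ratio, profile, stats,
count-spots, axon-ratio, scan-zipcode, run-all).

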