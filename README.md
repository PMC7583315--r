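# tbpsnp

Regulatory SNPs in the core promoter can change how tightly the
TATA-binding protein (TBP) binds, and — because transcription initiation
scales with TBP–promoter affinity — how strongly the downstream gene is
expressed. `tbpsnp` is an R package for scoring such variants: given
70-bp proximal promoter sequences and a table of single-nucleotide
substitutions, it estimates the TBP–DNA equilibrium dissociation
constant K_D for each allele, calls significant affinity changes, and
aggregates the calls into selection-pressure statistics. It is aimed at
researchers triaging unannotated promoter SNPs into candidate
expression-altering markers before any clinical or experimental
follow-up.

## The model in brief

For a 26-bp window the package estimates the binding free-energy scale
−ln K_D (K_D in molar) as a linear combination of three elementary-step
terms — site recognition (a 15-bp TATA-box weight matrix, the "stop"
step), one-dimensional sliding along AT-rich tracts, and DNA bending at
TA/AT kink steps — plus a 16-entry dinucleotide fine-energy table:

    −ln K_D = c₀ + c_stop·S_stop + c_slide·S_slide + c_bend·S_bend + Σ_d n_d·D_d

The combination coefficients and fine-energy table are calibrated by
minimum-norm least squares against a ten-ODN panel whose predicted and
EMSA-measured affinities are packaged as a fixture (`odn_table2()`); the
calibration interpolates the panel exactly and its out-of-sample
accuracy is reported by leave-one-out refitting (`loo_affinity_model()`).
A promoter is scored by its strongest 26-bp window (minimal K_D).

For an allele pair the effect is Δln K_D = (−ln K_D)_min − (−ln K_D)_wt,
tested with a Fisher Z statistic Z = Δ/√(se²_wt + se²_min) and a
one-sided normal tail; significant negative Δ means predicted
underexpression ("deficiency"), positive Δ overexpression ("excess").
Marker counts are then compared against the genome-wide norm — SNPs
damaging TBP sites are fourfold more frequent than improving ones
(binomial null p₀ = 0.2 for affinity-increasing calls) — and against an
equal-split null for annotated phenotype directions, both with exact
binomial tails. A saturation-kinetics module fits K_D ± SEM from
(concentration, rate) EMSA data via v = Vmax·c/(K_D + c).

## Worked example

```r
library(tbpsnp)

fa    <- system.file("extdata", "table2_synthetic_promoters.fa", package = "tbpsnp")
tsv   <- system.file("extdata", "table2_snps.tsv", package = "tbpsnp")
calls <- scan_snps(read_promoters(fa), read_snps(tsv))
calls[, c("rsid", "gene_id", "delta_ln_kd", "z", "alpha", "decision")]
#> # A tibble: 5 × 6
#>   rsid         gene_id delta_ln_kd      z     alpha decision
#>   <chr>        <chr>         <dbl>  <dbl>     <dbl> <chr>
#> 1 rs1452787381 SHOX         -1.10  -3.89  0.0000503 deficiency_significant
#> 2 rs1393008234 GTPBP6        1.24   4.38  0.00000605 excess_significant
#> 3 rs1402972626 ASMT          0.0827 0.292 0.385     insignificant
#> 4 rs1452787381 ZFY           0.510  1.80  0.0357    excess_significant
#> 5 rs20067072   CDY2A        -0.510 -1.80  0.0357    deficiency_significant
```

Each row is one SNP: a negative `delta_ln_kd` means the minor allele
binds TBP more weakly than the reference allele (expected
underexpression), `alpha` is the one-sided significance of the change,
and `decision` is the qualitative call at the 0.05 threshold.

Validating predictions against the packaged EMSA panel:

```r
validate_predictions()
#> # A tibble: 8 × 5
#>   scale    method   estimate   p_value     n
#>   <chr>    <chr>       <dbl>     <dbl> <int>
#> 1 absolute pearson     0.839 0.00240      10
#> ...
#> 5 delta    pearson     0.983 0.00267       5
```

The predicted and measured −ln K_D correlate at r = 0.84 over the ten
alleles and r = 0.98 over the five per-SNP Δln K_D values, both
significant below 0.025. Selection statistics over the packaged marker
count table:

```r
rep <- selection_report(selection_table1())
rep[rep$class_label == "TOTAL", c("n_res", "n_gt", "n_lt", "p_norm_null", "p_equal_null")]
#> # A tibble: 1 × 5
#>   n_res  n_gt  n_lt p_norm_null p_equal_null
#>   <dbl> <dbl> <dbl>       <dbl>        <dbl>
#> 1   261   176    85    1.13e-61        0.173
```

176 of 261 significant calls increase affinity where the genome-wide
norm predicts 20% — a vanishing probability under neutrality — while the
phenotype-direction split (119 vs 142) is statistically even.

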