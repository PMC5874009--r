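# necropop

Population-structure analysis of Iron Age necropolis assemblages from
three independent lines of evidence, built for bioarchaeologists asking
"who was buried here, where did they grow up, and does culture track
origin?":

1. **Strontium isotope provenance.** Enamel fixes the ⁸⁷Sr/⁸⁶Sr of the
   region where a tooth crown mineralized. Each individual is classified
   local/non-local by testing the earliest-mineralizing sampled tooth
   (mineralization order dm2 < M1 < P4 < M2 < M3) against an inclusive
   local bioavailable range, and intra-individual mobility is typed from
   tooth pairs of different crown age.
2. **Dental biodistance.** Dichotomized ASUDAS trait frequencies give the
   Freeman–Tukey-corrected Mean Measure of Divergence between groups,

   MMD = (1/r) Σᵢ [ (θ_Ai − θ_Bi)² − (1/(n_Ai+0.5) + 1/(n_Bi+0.5)) ],
   SD = √( (2/r²) Σᵢ (1/n_Ai + 1/n_Bi)² ),

   with θ the Freeman–Tukey double arcsine and significance at
   MMD > 2·SD, plus classical MDS and Ward clustering of the matrix.
3. **Mortuary structure.** Binary grave-good matrices are tested for
   structure by sex, age and isotopic origin via Jaccard distances,
   complete-linkage clustering, occurrence chi-square, distance-matrix
   AMOVA with permutation Φ_ST, correspondence analysis, Random-Forest
   Gini importance and stepwise VIF collinearity filtering.

A synthetic-necropolis generator with known ground truth
(`generate_necropolis()`) exercises every stage end to end and supports
power analysis. The package ships the printed source tables it
reproduces as plain-CSV fixtures (`np_extdata()`).

## Worked example

```r
library(necropop)

iso  <- read_isotope_table(np_extdata("table2_isotopes.csv"))
rng  <- local_range(0.7086, 0.7090)          # inclusive local range
summarize_ratios(iso$ratio[iso$material == "bone"])
#> $mean       0.7087272
#> $two_sigma  0.0001165024
#> $n          5

calls <- classify_provenance(iso, rng)
table(calls$status)
#>    local nonlocal
#>       12       11

head(calls[calls$status == "nonlocal", ], 3)
#>   individual_id   status basis_tooth    ratio   direction single_tooth
#> 3         MV 12 nonlocal   RM1-upper 0.709257 above_range        FALSE
#> 4         MV 15 nonlocal   LM1-lower 0.709266 above_range        FALSE
#> 5         MV 19 nonlocal   LM1-lower 0.709070 above_range        FALSE

table(infer_mobility(iso, rng)$category)
#> arrived_in_childhood   distinct_origin   outbound_return
#>                    4                 1                 2
#>         stable_local   stable_nonlocal
#>                    9                 5
```

Eleven of the 23 sampled individuals grew up outside the local strontium
range (MV 19 by just 0.00007 — comparisons are made at full printed
precision), and the tooth pairs resolve four late-childhood immigrants,
two individuals who left and returned, and one arrival from a third,
low-ratio region.

Biodistance from the packaged group-frequency table:

```r
freq <- read_trait_frequencies(np_extdata("table4_frequencies.csv"))
mm   <- mmd_matrix(freq)                      # 10 retained traits
round(mm$mmd[c("MV", "MVL", "MVNL"), c("BRIT", "MunRain", "LAA", "ETC")], 3)
#>       BRIT MunRain    LAA    ETC
#> MV   0.140   0.306 -0.009  0.027
#> MVL  0.223   0.409 -0.011 -0.017
#> MVNL 0.056   0.221 -0.026  0.060
mm$significant["MVNL", c("BRIT", "MunRain", "HalD")]
#>    BRIT MunRain    HalD
#>   FALSE    TRUE    TRUE
```

The pooled sample (MV) and its local subgroup (MVL) diverge sharply from
the Celtic samples (BRIT, MunRain) but not from the Italic ones (LAA,
ETC; negative MMD means "more similar than sampling noise"), while the
non-local subgroup (MVNL) is statistically indistinguishable from the
Yorkshire Celts — the biological signature of the immigration the
isotopes detect.

`run_pipeline()` chains all stages over whichever input tables are
available and writes JSON/TSV/Newick outputs plus a config log.

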