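# fungwas

Genome-wide association mapping of binary traits in haploid fungal
populations, built around the design used to map germling-communication
loci in wild *Neurospora crassa* isolates: replicated germling-fusion
assays are aggregated per strain, binarized by a standard-deviation rule,
tested site-by-site for co-inheritance with Fisher's exact test, and
calibrated with a permutation-based experiment-wise false discovery rate.
A seeded synthetic-data generator emulates the haploid genotype matrices
and fusion-count phenotypes of such studies, so the whole pipeline is
testable end to end with no external data.

**Who it is for:** fungal population geneticists (or anyone with haploid
strains, a biallelic SNP matrix, and a replicated count phenotype) who
want a small, fully tested, scriptable association pipeline rather than a
human-GWAS toolchain.

## The statistics

For each strain $s$, replicate fusion measurements (`fused/total`,
typically 50 germling pairs per replicate) are averaged to $f_s$, and
$s$ is classed **low** iff $f_s < \bar f - \sigma$ (strict; grand mean
and SD across strains). Each SNP that is biallelic-in-sample with minor
allele fraction $> 0.25$ is tested with Fisher's exact test on the
2×2 table (class × minor/major allele) over strains, two-sided by the
minimum-likelihood rule. Shuffling the class vector among strains
(default 1000 permutations) gives the expected chance hit count
$E(p_t)$ at any threshold, from which

    FDR(p_t) = E(p_t) / observed(p_t),   TP(p_t) = max(0, 1 - FDR)

and the largest threshold with $E \le k$ expected chance hits (e.g.
$k = 0.1$) for the Manhattan significance line. Regional linkage
disequilibrium is the haploid $r^2 = D^2 / (p_i q_i p_j q_j)$ over
pairwise-complete strains.

## Worked example

Simulate a 24-strain panel (504 high-frequency SNPs on chromosomes
I–VII, one causal site on IV with penetrance 0.89 vs 0.24), then run the
pipeline:

```r
library(fungwas)

ds <- gen_dataset(sim_spec(causal_site = 217, strain_effect_sd = 0, seed = 7))
write_dataset(ds, "demo")

gm <- filter_maf(filter_biallelic(read_genotype_tsv("demo/genotypes.tsv")),
                 maf_filter_spec(0.25))          # 405 of 504 sites survive
bp <- binarize(read_phenotype_csv("demo/phenotypes.csv"))
bp
#> binary_phenotype: 24 strains (9 low, 15 high); grand mean 0.6397, SD 0.3321 (sample)

res <- assoc_scan(gm, bp)
head(res[order(res$p), ], 3)
#>  chrom    pos a b  c  d            p neglog10_p degenerate
#>     IV  39467 9 0  0 15 7.648160e-07   6.116443      FALSE
#>     IV  76658 0 9 12  3 3.365190e-04   3.472990      FALSE
#>     IV 131752 0 9 11  4 5.889083e-04   3.229952      FALSE
```

The top hit is the simulated causal site (IV:39467): all 9 low strains
carry its minor allele and no high strain does. Permutation calibration
at two operating thresholds, and the "expect 0.1 chance hits" line:

```r
plan <- permutation_plan(n_permutations = 1000, seed = 2)
threshold_summary(gm, bp, plan, c(5.6e-6, 0.015), results = res)
#>  p_thresh observed_count expected_count    fdr fdr_percent tp_fraction tp_percent
#>   5.6e-06              1          0.000 0.0000        0.0%      1.0000       100%
#>   1.5e-02              6          3.591 0.5985         60%      0.4015        40%

thr <- threshold_for_expected(gm, bp, plan, target_expected = 0.1)
thr
#> [1] 0.0005889083
subset(manhattan_table(res, thr), significant)
#>  chrom   pos neglog10_p significant
#>     IV 39467   6.116443        TRUE
#>     IV 76658   3.472990        TRUE
```

So at the stringent threshold the single observed hit has an estimated
FDR of 0.0% (no chance hits in 1000 permutations), while the permissive
threshold admits 6 hits of which ~60% are expected to be false. The
significance line flags two sites; the site whose p equals the threshold
exactly is excluded (counting is strictly `p < threshold`). Regional LD
around the peak:

```r
ld <- r2_matrix(region_query(gm, "IV", 39467 - 2e5, 39467 + 2e5))
ld
#> ld_matrix: 5 sites; mean off-diagonal r2 0.433
ld_long(ld)           # long-format heatmap source: pos_i, pos_j, r2, n_used
```

The same stages are scriptable via the CLI
(`inst/cli/fungwas`): `simulate`, `filter`, `phenotype`, `assoc`,
`permute`, `ld`, and `run` (full pipeline from a flat config file).

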