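# citrinspectrum

Regional mutation-spectrum analysis for citrin deficiency (CD) cohorts.

Citrin deficiency is an autosomal recessive disorder caused by biallelic
mutations of *SLC25A13*; molecular diagnosis means finding a deleterious
mutation on both of a patient's alleles, and efficient screening depends
on knowing which mutations are common in which population. This package
is for clinical geneticists and population geneticists working with such
cohorts. It:

* parses HGVS-style biallelic genotype strings — legacy IVS aliases,
  cis-compound alleles (`[c.851_854del4; c.1452+1G>A]`), undetected
  alleles (`?`) — against a packaged 41-entity variant registry;
* builds region-stratified allele and genotype spectra (north / border /
  south of the Yangtze), including exact reconstruction of integer
  counts from published relative-frequency tables;
* tests every identity for geographic frequency differences with a
  Pearson chi-square or a full-enumeration **Freeman–Halton exact test**
  (two-sided probability method), plus Bonferroni-corrected pairwise
  comparisons (α = 0.05/3);
* quantifies allelic heterogeneity via observed homozygosity and the
  gene identity **J = Σ Xᵢ²** (each undetected allele treated as a
  unique allele of frequency 1/N);
* simulates seeded synthetic cohorts (random mating, homozygosity
  excess, detection failure, siblings, cis compounds) for calibration
  and parameter-recovery experiments.

## Worked example

```r
library(citrinspectrum)

spec  <- build_table2_fixture()   # allele counts: N = 55/81/392 per region
gspec <- build_table4_fixture()   # genotype counts: n = 23/35/187 families
report <- analyze_spectra(spec, gspec)
report
#> <citrin-deficiency spectrum report>
#>   diagnostic efficiency: 98.86%
#>   geographically heterogeneous identities: c.775C>T, c.851_854del4,
#>     c.1078C>T, IVS11+1G>A, c.1364G>T, c.1399C>T, IVS16ins3kb
#>   geographically heterogeneous genotypes:
#>     c.851_854del4/c.851_854del4, c.1399C>T/c.851_854del4

report$homozygosity
#>  region observed_numerator observed_denominator observed_pct theoretical_J_pct
#>   north                  4                   23        17.39             15.24
#>  border                 12                   35        34.29             24.31
#>   south                 99                  187        52.94             44.81
```

Reading: a mutation was identified on 98.86% of the cohort's 528
independent alleles; seven mutations and two genotypes are distributed
significantly unevenly across the three regions; and homozygosity rises
from north to south — i.e. the northern allele pool is the most
heterogeneous (founder effect of `c.851_854del4` in the south). The
four high-frequency mutations cover most alleles:

```r
round_half_up(relative_frequencies(spec, "all")[
  c("c.851_854del4", "c.1638_1660dup", "IVS6+5G>A", "IVS16ins3kb")], 2)
#>  c.851_854del4 c.1638_1660dup      IVS6+5G>A    IVS16ins3kb
#>          58.33           8.52           7.58          10.04
combined_frequency(spec, c("c.851_854del4", "c.1638_1660dup",
                           "IVS6+5G>A", "IVS16ins3kb"))  # -> 84.47 (%)
```

The numbered drivers under `analysis/` run the whole workflow
(count reconstruction → spectrum summary → geographic tests →
homozygosity → simulation calibration) and write their tables under
`results/`:

```sh
Rscript analysis/01_reconstruct_counts.R
# ... through ...
Rscript analysis/05_simulation_calibration.R
```

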