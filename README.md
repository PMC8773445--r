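# founderhap

Did a handful of "unrelated" carriers of a rare disease mutation inherit it
from a single common ancestor? `founderhap` implements the population-genomics
inference chain that answers this question from phased SNP-array data: array
quality control, genome-wide relatedness checks, detection of the haplotype
segment shared by the carriers around the focal mutation, empirical
genome-wide significance of that sharing, and analytic coalescent dating
(tMRCA) of the common ancestor. It is aimed at statistical geneticists and
clinical researchers studying putative founder mutations in circumscribed
populations — the motivating setting is a set of Alzheimer's-disease families
from a single region carrying the same *APP* missense mutation.

Because patient genotypes in such studies are rarely depositable, the package
also ships a first-class synthetic-cohort simulator that plants a founder
event with known ground truth, so the whole pipeline is testable end to end
without any external data.

## The model

**Sharing.** For the haplotypes that carry the risk allele, the focal shared
segment is the maximal run of SNPs, centred on the mutation, over which all
selected haplotypes are identical (a missing call neither breaks a segment
nor counts toward its SNP total). Its significance is assessed two ways:

* *Genome-wide rank*: all breakpoint-delimited segments shared by the same
  haplotype set are enumerated genome-wide, and the focal segment's rank
  yields `p = (1 + #{segments ≥ focal}) / #segments`, in both the SNP-count
  and bp-length metrics.
* *Patient–control null*: each carrier haplotype is compared against every
  control haplotype and segments at least as large as the focal one are
  counted, with a Bonferroni threshold `α / (n_patients × n_controls)`.

**Dating.** Recombination erodes the ancestral haplotype: over `t`
generations, the distance from the focal site to the nearest breakpoint on
one side is Exponential with rate `c·t` per Morgan, where `c` counts the
effective meioses per generation separating the delimiting recombinations
(`c = 2` for the pairwise-lineage convention, `c = n` for a star genealogy
over `n` carriers). The observed two-sided genetic length `ℓ` therefore has
likelihood

    f(ℓ | t) = (c t)² ℓ exp(−c t ℓ),

and with a uniform prior on `(0, t_max]` the posterior of `t` is
Gamma(3, c·ℓ) truncated at `t_max`, with closed-form mean `3/(cℓ)` and mode
`2/(cℓ)`. The posterior mean is the conventional summary; note it is a
Bayesian quantity — as a frequentist point estimator of a fixed true age it
is biased upward (the unbiased moment estimate `1/(cℓ)` is also reported;
see the methods vignette).

**Relatedness guard.** Before any sharing analysis, method-of-moments
genome-wide IBD (`Z0/Z1/Z2`, `PI_HAT = Z1/2 + Z2`) confirms the carriers are
not cryptically related: no patient–patient `PI_HAT` may exceed the top 1%
of the empirical patient–control distribution.

## Worked example

Dating the published five-carrier segment — 300 SNPs spanning 1.72 Mbp of
chromosome 21 around *APP* — with the packaged (synthetic, constant
1.31 cM/Mb) APP-region genetic map:

```r
library(founderhap)

segment <- data.frame(chrom = "21", start_bp = 26400000L, end_bp = 28120000L,
                      n_snps = 300L, length_bp = 1720000L)
map <- read_genetic_map(system.file("extdata", "chr21_app_synthetic_map.tsv",
                                    package = "founderhap"))
tmrca_from_segment(segment, map, n_carriers = 5,
                   model = tmrca_model(convention = "pair"))
#> tMRCA posterior (l = 0.0225 M, c = 2, n = 5, uniform prior):
#>   mean 66.6 generations (mode 44.4), 90% CI [18.1, 139.7]
#>   1931 years (at 29 y/generation)
```

A mean of ~67 generations puts the common ancestor more than 1,300 years
back for any plausible generation time in 20–35 years — consistent with a
medieval founder of the mutation in the region. The credible interval is
wide: a single segment carries limited information about `t`.

The full simulated pipeline (cohort → QC → structure → sharing → dating)
runs in seconds at desk scale:

```r
report <- run_pipeline(list(seed = 7,
                            sim = list(n_controls = 20, n_carriers = 5,
                                       n_snps = 500)))
report
#> founderhap run report (seed 7)
#>   data:  25 samples x 1000 variants (5 carriers) [simulated]
#>   qc:    831 variants post-QC, 78 after LD pruning
#>   structure: PC1 8.9% variance; 0 relatedness flag(s)
#>   share: focal segment 21:1293078-1869266 (94 SNPs, 576188 bp); rank p (snps) = 0.00508
#>   tmrca: mean 260.3 generations (mode 173.6), ~7550 years
```

The narrative analysis scripts under `analysis/` (`01_simulate.R` …
`05_tmrca.R`) run the same chain at the emulated study scale (84 controls,
7 carriers) and write their tables under `results/analysis/`.

## Coordinates and conventions

Positions are 1-based inclusive (VCF convention); a segment's bp length is
`end_bp − start_bp`, measured between its outermost matching SNPs. Alleles
are oriented ref/alt; the focal risk allele is always named explicitly.
Dosages count alt alleles.

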