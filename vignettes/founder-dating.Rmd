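---
title: "Detecting and dating a founder haplotype: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating a founder haplotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderhap)
```

# The inference chain

`founderhap` decides whether a set of reportedly unrelated carriers of a
rare mutation inherited it from a common ancestor. The chain has five
stages, each a pure function of the previous stage's output:

1. **QC** — missingness, exact Hardy–Weinberg, MAF, LD pruning;
2. **structure** — genotype PCA and a genome-wide relatedness screen;
3. **sharing** — the maximal haplotype segment shared by the carriers
   around the focal mutation, with empirical genome-wide significance;
4. **dating** — an analytic coalescent posterior for the age of the common
   ancestor, driven by the segment's genetic length;
5. **simulation** — a synthetic phased cohort with a planted founder event,
   used to validate every stage with known ground truth.

The premise worth stating explicitly: the carriers must *not* be closely
related genome-wide (otherwise local sharing is unremarkable), yet must
share an unusually long identical haplotype exactly at the mutation. Stages
2 and 3 test those two halves; stage 4 converts the sharing into time.

# The dating model

Let $t$ be the age of the common ancestor in generations and $\ell$ the
two-sided genetic length (Morgans) of the shared segment. Each side of the
segment ends at the recombination breakpoint nearest the focal site, and
breakpoints accumulate at rate $c\,t$ per Morgan, where $c$ is the
effective number of meioses per generation separating the two delimiting
recombinations. The two sides are independent exponentials, so

$$ f(\ell \mid t) = (c t)^2\,\ell\,e^{-c t \ell}, $$

and with a uniform prior on $(0, t_{\max}]$ the posterior is
$\mathrm{Gamma}(3,\, c\ell)$ truncated at $t_{\max}$: mean $3/(c\ell)$,
mode $2/(c\ell)$, mean/mode ratio exactly $1.5$.

**Assumptions.** A star-like genealogy (no internal coalescences between
the carriers and the founder on the timescale of interest); a correct
genetic map; identity of the shared tract caused by descent rather than by
state; no gene conversion; mutation on the tract is ignored (the SNP count
is reported but not modelled — segment length, not marker mismatch, drives
the published quantities; a Poisson mutation factor was considered and left
out as it only rescales the rate, not the shape).

**Meioses convention `c`.** This is the model's one genuinely open choice,
so it is surfaced in every report rather than fixed silently:

* `pair` (`c = 2`, default): the two meiotic paths through the ancestor
  that separate any *pair* of carriers. This is the convention that
  reproduces the published worked example.
* `star` (`c = n`): the consensus segment of $n$ carriers is the
  intersection of $n$ independently eroded tracts, so each flank is the
  minimum of $n$ exponentials — rate $n t$. This is the convention matched
  to the simulator, and the one to use when dating a multi-carrier
  consensus segment under the erosion model the simulator implements.
* an explicit `c` for anything else.

**A calibration caveat the user should know.** The posterior mean
$3/(c\ell)$ is a Bayesian summary: it is calibrated when averaging over the
prior, not over repeated segments at a fixed true $t$. Because $1/\ell$ is
heavy-tailed ($\mathbb{E}[1/\ell] = c t$ for $\ell \sim
\mathrm{Gamma}(2, ct)$), the mean of posterior means over replicate founder
events at fixed $t^\*$ is $3 t^\*$ — a threefold upward bias (about
$2$–$2.5\times$ in our simulations, where SNP spacing truncates the
smallest segments). The package therefore also reports the moment estimate
$\hat t = 1/(c\ell)$, which is exactly unbiased in the repeated-sampling
sense (`tmrca_moment_estimate()`, property-tested). The 90% equal-tailed
credible interval covers a fixed truth in roughly 80–85% of replicates
under the matched model. A package-level acceptance check that asks the
posterior mean to recover $t^\*$ within 15% is deliberately kept — and
deliberately fails — as an honest record of this model property; it is not
a software defect.

**Mean/mode of the worked example.** Under any $\mathrm{Gamma}(3, \cdot)$
posterior, matching the published mean of 66.6 generations forces a mode of
44.4, whereas 47.6 is printed alongside it (a mean/mode ratio of about
1.40, i.e. an effective shape near 3.5). The additional model component
behind that ratio is not recoverable from the available description, so the
package reports its honestly computed mode rather than matching the printed
one, and prints a sensitivity table (map rate × convention) next to the
headline numbers.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `t_max` | 2000 | generations | ample for "hundreds of generations" segments; an error demands ≥ 99% posterior mass below it |
| `grid_step` | 0.1 | generations | posterior grid; summaries match closed forms within one step |
| `generation_years` | 29 | years | range-checked to [20, 35]; any value in range keeps the worked example's ancestor > 1000 years back |
| `prior` | uniform | — | minimal assumption; exponential prior available (`prior_rate`) |
| QC thresholds | 0.05 / 0.05 / α 0.05 / MAF 0.01 / 50-5-0.1 | — | standard array practice; the realized Bonferroni divisor is always reported |
| top quantile (screen) | 0.99 | — | nearest-rank (ceiling) order statistic, exact for small samples |

# The simulator: what it emulates, and what it does not

`sim_config()` defaults emulate the motivating study at desk scale: 84
controls and 7 carriers, array-like marker density (~1 SNP / 6 kb), the
focal mutation on chromosome 21, founder age 50 generations, 1% missing
calls. The genome is scaled down to two chromosomes of 2,000 SNPs — the
package's choice of problem size, enough for thousands of genome-wide
segments in the rank null while keeping every simulation suite in seconds.

Background LD uses first-order Markov copying: each haplotype keeps copying
its current template with probability `copy_prob` (0.9, giving ~10-SNP
expected runs, i.e. ~60 kb), switching to a random earlier haplotype or to
a frequency draw (`innovate_prob` 0.15). Site frequencies come from a
Beta(2, 2) spectrum rescaled into [0.05, 0.95] (common-SNP ascertainment).
The founder haplotype is drawn from the cohort frequencies, so it has no LD
with any cohort member outside the planted intervals; each carrier receives
it over an interval whose sides are independent
Exponential(`erosion_c` · $t^\*$) genetic distances (`erosion_c = 1` per
lineage per side — the same parameter surface the estimator's `c` refers
to, so model-matched recovery experiments are exact by construction).

What the simulator does **not** model: demographic structure, growth or
migration; array ascertainment against the site-frequency spectrum; sex
chromosomes; phasing errors (cohorts are generated phased — phasing is out
of scope, inputs are assumed pre-phased); gene conversion. Two consequences
worth knowing:

* *Boundary extension.* Outside the planted intersection the carriers
  revert to background haplotypes, which can agree by chance for a few
  SNPs, so the detected consensus segment *contains* the planted
  intersection rather than equalling it exactly; tests assert containment.
* *Generation-order coancestry.* Markov copying makes later-generated
  haplotypes mosaics of earlier ones, so samples are not exchangeable: a
  late sample shares more with early samples than two late samples share
  with each other. For experiments that need genuinely unrelated,
  exchangeable individuals (e.g. calibrating the relatedness screen), use
  `copy_prob = 0, innovate_prob = 1`, which gives iid alleles.

# Numerical and convention choices

* **Coordinates** — 1-based inclusive; segment length `end_bp − start_bp`
  between the outermost matching SNPs. A single-SNP segment has length 0.
* **Missing-data rule** — missing matches (does not break a segment, does
  not count toward `n_snps`); the strict rule is a flag, both are tested.
* **Homozygous carriers** — phase 0 selected deterministically;
  `try_both_phases` explores both and keeps the longer segment.
* **HWE** — plain exact two-sided test (sum of configurations with
  conditional probability ≤ observed, tie tolerance 1e-9), no mid-p; the
  printed threshold of the motivating study is not forced — the package
  derives α / n_variants and reports it.
* **LD pruning** — genotype-dosage r² with pairwise-complete observations;
  within an offending pair the lower-MAF variant is removed, ties remove
  the later one; windows advance over the original per-chromosome variant
  grid. Deterministic by construction.
* **IBD** — plug-in method of moments without small-sample frequency
  corrections; `Z` estimates are clamped to [0, 1] and renormalised.
  Clamping makes unrelated-pair `PI_HAT` means slightly positive at small
  marker counts; at the package's IBD problem size (≥ 5,000 markers) the
  mean bias is below 0.02.
* **Rank statistics** — the focal segment counts itself
  (`p = (1 + #others ≥ focal)/total`), so `p` is never 0; zero-count
  patient–control p-values are reported as the bound `1/(total + 1)`. The
  rank statistic is *discrete*: single-SNP segments are a sizeable atom of
  the genome-wide segment population (they all tie), so the null
  distribution of the rank p-value is stochastically ≥ uniform
  (conservative — the property the tests assert) but not uniform in the
  Kolmogorov–Smirnov sense; and the segment containing a *random* focal
  SNP is a length-biased draw, which is anti-conservative. Both facts are
  measured in the acceptance suite and discussed in the test comments.
* **Degenerate inputs** — disagreement at the focal SNP itself yields a
  warned 1-SNP segment; a zero-genetic-length segment refuses to be dated;
  `t_max` covering < 99% of the posterior mass is an error that names the
  fix.

# Problem sizes

Simulation-backed tests use cohorts of 10–91 samples and 400–4,000 SNPs,
200 replicates per condition for recovery experiments, 500 replicates for
null-distribution checks, and 40 seeds for screen calibration; the full
suite runs in well under five minutes, the analysis scripts in seconds
each. These sizes are the package's own desk-scale choices and are fixed in
the test code.

# Known limitations

* Dating from a single segment is inherently low-information: credible
  intervals span several-fold ranges, and the posterior-mean bias discussed
  above applies to any single-tract estimator of this family.
* The genetic map shipped for the APP region is a synthetic constant-rate
  stand-in (clearly labelled); real HapMap-derived maps should be supplied
  for real data.
* The segment scan assumes biallelic SNVs and phased input; phase errors
  would truncate true segments and are not modelled.
* The patient–control null counts breakpoint-delimited segments, not an
  HMM-based IBD probability; probabilistic IBD callers are out of scope.
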