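---
title: "SNP-based versus twin-based heritability: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-based versus twin-based heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snptwin)
```

## The two estimators and why they differ

Twin studies estimate heritability by contrasting the phenotypic
resemblance of monozygotic pairs (genetic similarity ≈ 1.00) with that of
dizygotic pairs (≈ .50). SNP-based estimation turns the same logic on a
population of unrelated individuals: across tens of thousands of SNPs,
any two "unrelated" people are slightly more or less similar than average
by chance — the off-diagonal entries of a genetic relationship matrix
(GRM) spread only a few hundredths around zero — and regressing
phenotypic similarity on this chance genomic similarity recovers the
variance tagged by the genotyped SNPs.

The two numbers answer subtly different questions. The SNP-based estimate
is a **lower limit** of the narrow-sense heritability for two reasons this
package makes mechanical and testable:

1. **Incomplete tagging.** Causal variants that are absent from the array
   and not correlated with anything on it contribute to the twin estimate
   but are invisible to the GRM. The simulator implements this directly:
   a `tagged_fraction` of causal SNPs is flagged visible, and
   `array_view()` hands the GRM only those plus the null SNPs.
2. **Additivity.** GREML captures additive effects; the MZ/DZ contrast
   also absorbs non-additive ones. The simulator generates purely
   additive traits, so in these experiments reason 1 is the whole story —
   a deliberate isolation, not an oversight.

The per-trait ratio h²_SNP / a², and its mean over a designated set of
cognitive traits, is the summary statistic the comparison is built
around (`ratio_table()`).

## The generative model

### Founders and effects

`simulate_founders(n, m, maf_low, maf_high, seed)` draws each SNP's
allele frequency uniformly on `[maf_low, maf_high]` (defaults .05–.50,
i.e. common variants) and dosages as two independent allele draws —
Hardy–Weinberg equilibrium, linkage equilibrium between loci.
`assign_effects()` gives a random subset of `n_causal` SNPs normal
effects of equal per-SNP variance ("many genes of small effect") and
rescales them so the realized genetic variance equals `h2_target` on the
unit-variance phenotype scale; `simulate_phenotype()` adds independent
normal noise with variance `1 − h2_target`. With `h2_target = 1` the
phenotype is exactly the centred genetic value.

There is no recombination map, mutation, selection or population
structure: loci are exchangeable, and an untagged causal variant is
modelled by hiding it from the array rather than by simulating the decay
of linkage disequilibrium. That reproduces the lower-limit mechanism
without coalescent machinery. For finer control, `add_tag_proxies()`
appends a visible proxy whose alleles copy a hidden causal SNP's alleles
with probability `sqrt(r2)`, giving dosage correlation ≈ `sqrt(r2)`
(copying *transmission draws* instead would attenuate the realized r² by
1/(1 + r²/2) — the distinction matters and is covered by a test).

### Assortative mating

`mate_and_reproduce()` implements phenotypic assortment by latent rank
matching: couples inherit the joint rank pattern of a bivariate normal
sample with correlation ρ. Rank matching of normal margins realises a
Pearson correlation of (6/π)·asin(ρ/2), so ρ starts at the analytic
de-attenuation 2·sin(π·target/6) and is recalibrated until the realized
spousal correlation is within `max(0.01, 3/√k)` of the target — the floor
acknowledges that a correlation over k couples cannot be pinned down more
tightly than its own sampling noise. Offspring receive one allele per SNP
per parent. Assortment correlates the parents' genetic values
(spousal genetic correlation ≈ spousal phenotypic correlation × h²), which
(a) inflates additive genetic variance generation after generation
(`simulate_generations()` tracks it) and (b) builds positive cross-locus
correlations among causal alleles — including between tagged and hidden
ones, which is why stronger assortment raises the SNP/twin ratio in the
end-to-end experiments.

### Twin cohorts

`simulate_twin_cohort()` draws distinct parental couples; MZ co-twins
share one meiosis draw, DZ co-twins are full siblings (expected additive
relationship .50, which the GRM on the twins verifies empirically). Traits
follow the ACE composition: genetic value (variance a², via effects scaled
in the founder generation so assortment-driven inflation is preserved when
an effect model is passed in), a shared deviate per pair (c²), and a
unique deviate per twin (e²). One random twin per pair is flagged
genotyped; `genotyped_twin_view()` extracts that member for the SNP-based
analysis while both members enter the twin analysis — mirroring designs in
which only one twin per family was genotyped.

## Estimation machinery

### GRM

`compute_grm()` uses the standardized-dosage cross-product
`A_jk = (1/m) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2p_i(1−p_i))` with
sample allele frequencies by default, mean imputation of missing dosages
per SNP (which preserves the exact row-sum-zero identity, tested to
1e-10), and dropping of monomorphic or low-call-rate (< 95%) SNPs.
Accumulation is blocked over SNPs (`block_size`), so memory stays bounded
and the result is bit-identical for any blocking. Off-diagonals of
unrelated samples have standard deviation ≈ 1/√m — the basis of the
concentration display (`similarity_summary()`), where "within 1% of the
mean" is read as ±0.01 absolute on the relationship scale; since that
reading is a convention, the window is an explicit parameter.

`filter_related()` greedily removes the individual with the most
above-cutoff partners (ties: first in id order) until none remain; on
small instances this matches exhaustive search for maximum retained sets.
The conventional cutoff 0.025 presumes hundreds of thousands of markers;
with m array SNPs chance similarity spreads as 1/√m, so the end-to-end
pipeline defaults to `max(0.025, 6/√m)` to avoid discarding genuinely
unrelated individuals in small simulated panels.

### GREML

`fit_greml()` maximises the restricted likelihood of
`y ~ N(Xβ, σ²_g A + σ²_e I)`. One eigendecomposition of A diagonalises
every evaluation, so each iteration is O(n) after an O(n³) setup. The
iteration starts at σ²_g = σ²_e = var(y)/2, takes one EM step, then
average-information updates; an AI step that would decrease the
likelihood (or a singular AI matrix) falls back to EM, whose likelihood
ascent is monotone (tested). Components that go negative are bent to
1e-6·var(y). Convergence is |Δ log L| < 1e-8 or parameter change < 1e-8,
with a cap of 100 iterations — hitting the cap flags the fit rather than
erroring. The SE of h²_SNP comes from the inverse AI matrix via the delta
method; the 95% CI is Wald truncated to [0, 1] (with estimate .35 and SE
.117 this construction yields [.12, .58] after half-up rounding — the
form the printed intervals in this literature are consistent with;
whether those are Wald or profile intervals is not documented, so Wald is
the default and the profile machinery exists on the twin side).

The AI optimum is validated against an independent 200×200 grid search of
a dense, directly coded restricted likelihood on toy instances.

### Twin ACE

`fit_ace_ml()` maximises the ordered-pair bivariate-normal likelihood
with equal means and variances across twin order and zygosity, MZ
covariance a² + c² and DZ covariance a²/2 + c². Internally it works on
per-zygosity sufficient statistics (mean vector and MLE covariance),
through which the likelihood depends only on swap-invariant moments — so
relabelling twin 1/twin 2 provably cannot change the fit. Proportions are
parameterised through squared sines of angles (a smooth square-root
simplex), keeping all components in [0, 1] without constraints; the
optimiser is Nelder–Mead, restarted once, from the Falconer point.
Profile-likelihood CIs bisect the likelihood-ratio statistic at 3.84 to a
tolerance of 1e-4 in a²; Wald CIs via the numerical Hessian are the fast
alternative used inside replicate loops. `falconer()` provides the moment
estimator (a² = 2(r_MZ − r_DZ)) with clipping to [0, 1], renormalisation,
and the raw values preserved.

The no-sex-limitation, single-variance ACE model is deliberate: the twin
summaries being emulated specify nothing beyond standard model fitting,
and the minimal model keeps the comparison interpretable. ADE selection is
likewise out of scope; the simulated traits are purely additive.

### Spouse similarity index

`spouse_similarity_index()` averages GRM-style similarity over spouse
pairs on a chosen SNP set and compares it with random re-pairings of the
same individuals (one-sided upper-tail permutation p, +1-corrected).
Its signal under phenotypic assortment is approximately
ρ_spouse · h² / n_causal per SNP against permutation noise
~ 1/√(n_pairs · n_causal): power grows with √(n_pairs / n_causal). The
package's power demonstration therefore uses an oligogenic architecture
(20 causal SNPs, 2500 couples), a choice made from this calculation, not
by trial. For strongly polygenic traits the index needs very large
spouse samples — a real limitation of the proposed index, worth knowing
before applying it.

## Problem sizes used by the test-suite

The suite favours the smallest sizes at which each property is decisive:
toy instances (n ≤ 80) for oracle equivalence; n = 2,000 × m = 5,000 for
single-shot parameter recovery (2-SE criterion); 150 replicates of
1,000 MZ + 1,000 DZ pairs for CI coverage (a² = .46, c² = .25 — the
shared-environment share is a fixed design choice, as the emulated
summaries report only a²); 40 replicates at n = 500 × m = 2,500 for GREML
calibration; 25 seed-paired replicates per arm for the end-to-end ratio
comparisons (tagging 0.4 vs 0.8; spousal correlation .20 vs .45), seed
pairing cancelling architecture-level noise; and n = 500 × m = 50,000 for
the similarity-concentration display.

## What passing tests do and do not show

The simulator emulates: unrelated cohorts with tightly concentrated
chance similarity, additive polygenic traits, partial tagging, MZ/DZ
structure with shared environment, and calibrated phenotypic assortment.
It does **not** emulate: linkage maps and realistic LD decay, rare or
non-additive variation, population stratification, genotyping error,
age/sex structure, or measurement unreliability. Results here show that
the estimators do what their theory says under the model's assumptions —
they cannot show that real cohorts satisfy those assumptions. In
particular, h²_SNP in real data is sensitive to stratification and QC in
ways no test here exercises, and the twin model's equal-environments
assumption is simply true by construction in the simulator.

## Numerical conventions

* Ratios and mean ratios are displayed with half-up rounding at 2
  decimals (`round_half_up()`); full precision is kept internally.
* Missing phenotypes are `NA` or `-9` on disk, a single `NA` internally.
* GRM archives are 4-byte little-endian reals over the row-major lower
  triangle with a companion id table — the de-facto binary convention of
  the standard tooling, so archives interoperate in both directions.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state, making each a pure function of its arguments.
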