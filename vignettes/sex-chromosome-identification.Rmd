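---
title: "Identifying sex chromosomes in F2 interspecific crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying sex chromosomes in F2 interspecific crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexqtl)
```

## The design

Many fish lineages — haplochromine cichlids being the extreme case — turn
over their sex-determination systems so fast that closely related species
can differ in both the chromosome that carries the determiner and in which
sex is heterogametic. An interspecific F2 cross exposes a dominant
determiner segregating from one grandparent: cross a female of species A
with a male of species B, intercross F1 siblings within families, and
genotype the F2 at SNP markers. Three independent signals then localise a
sex determiner:

1. **Grandpaternal genotype frequencies.** At markers fixed for alternative
   alleles between the species and heterozygous in both F1 parents, an
   autosomal site shows each homozygous genotype at 25% in both sexes. At a
   fully X/Y-linked site, sons always inherit the determiner-linked
   grandpaternal chromosome, so the grandpaternal homozygote appears in 50%
   of males and 0% of females (mirrored under ZW).
2. **Heterozygote-frequency differences.** Any sequence difference between
   the X and Y (or Z and W) inflates heterozygosity in the heterogametic
   sex. The sign of the male−female heterozygote-proportion difference at
   significant sites therefore distinguishes XY from ZW.
3. **QTL mapping of sex as a binary trait**, by single-marker ANOVA and by
   interval mapping on conditional genotype probabilities.

Once a candidate chromosome and heterogamety are established, sites that
are heterozygous in the heterogametic F0/F1 but homozygous in the
homogametic ones carry the Y- or W-linked allele; combining the strongest
such site with the strongest species-diagnostic site assigns each F2 a
composition (`X_A Y_B`, `Z_B W_A`, ...) traced to the grandparental
species. Phenotype–composition discordance then reveals incomplete
penetrance, modifier loci, or viability selection.

## The statistical machinery

**Permutation test.** For each site the statistic is the difference in
heterozygote proportion between the sexes, computed over non-missing
genotypes. Sex labels are permuted 10,000 times; one shuffled label vector
per replicate is shared across all sites, which preserves the genome-wide
correlation structure of the null and makes replicates comparable across
sites (whether the original analyses shared permutations across sites is
not documented; sharing is this package's choice). The observed sign fixes
the one-sided tail per site; permuted values that tie the observed one
count as extreme. The significance flag reproduces the raw printed rule —
at most one permutation as extreme — while the reported `p_emp` adds the
+1/(n+1) correction so ranking never divides by zero. Scaling the
permutation count down loosens the implied per-site alpha (≤1 of 1,000 is
p < 0.002, not p < 1e-4) and measurably admits linked sampling
fluctuations, so the package defaults to the full 10,000 even in
simulation studies.

**LOD and PVE.** The marker regression uses the one-way ANOVA F statistic
of the binary sex response on the genotype factor, converted as
`LOD = (n/2)·log10(F·df/(n − df − 1) + 1)` with `df` the genotype-factor
numerator degrees of freedom — the form that degrades gracefully when a
genotype class is absent — and `PVE = 100·(1 − 10^(−2·LOD/n))`.

**Interval mapping.** Conditional genotype probabilities follow the
standard F2 intercross hidden Markov model: dosage states 0/1/2 with prior
(¼, ½, ¼), transitions from the map function's recombination fraction over
the inter-position distance, symmetric genotyping-error emissions (default
rate 0.05), a 1 cM pseudomarker grid, and the Kosambi map function by
default. The binary single-QTL model is fitted at each position by EM over
the genotype-probability mixture (class penetrances clamped to
[1e-6, 1 − 1e-6]; positions where a penetrance hits the boundary are
flagged as separated). LOD is the log10 likelihood ratio against a common
penetrance; at a fully informative marker this reduces to the marker-level
binary fit, which the tests verify to 1e-3 LOD. Genome-wide thresholds come
from permuting the response and recording the maximum LOD (default 1,000
replicates); 95% credible intervals normalise `10^LOD` along the
chromosome, grow the smallest contiguous span containing the peak to ≥95%
of the mass, and widen pseudomarker endpoints to the flanking genotyped
markers.

**Filters.** Boundary semantics follow the conventional printed rules
exactly: "> 50% missing" strict, "depth < 12" strict, "MAF at least 0.05"
inclusive, "HWE P > 0.1" strict. The depth-IQR repeat guard is read as an
upper bound of mean-of-site-means + 1.5 × IQR(site means) — the phrase
"less than 1.5 times the interquartile range from the mean" admits more
than one reading, so the multiplier and the interpretation are exposed as
configuration. The Hardy–Weinberg filter uses the standard exact test
(two-sided, conditioning on allele counts), computed within F2 only. The
missingness/depth/MAF cascade is idempotent; the depth-IQR step is a
relative threshold and is applied once. Allelic-balance correction of
founder heterozygotes is approximated at the genotype level (heterozygous
F0 calls with minor-read fraction < 0.2 are recoded to the majority
homozygote); read-level correction is out of scope for a genotype-matrix
package and the approximation is labelled as such.

**Tracing.** The Y/W-linked site contrast tolerates missing parental
genotypes as long as a configurable minimum number of individuals per side
is observed and every observed one matches — with six parents and a few
percent missingness, demanding complete data discards most true sites. The
origin (species-diagnostic) site is additionally required to be
heterozygous in the F1 where F1 genotypes exist: an F1 that carries a
recombinant sex chromosome otherwise makes distal sites look maximally
sex-linked while scrambling the species decode — a failure mode the
simulator reproduces. "Most strongly sex-linked" is ranked by permutation
`p_emp`, then absolute heterozygote difference, then position for Y/W
sites; origin sites are ranked by the grandpaternal-frequency contrast
between the sexes, with ties inside one standard error broken toward the
strongest Y/W site. Genotype-run smoothing (runs of ≤3 equal genotypes
replaced when flanked by ≥5 equal, different genotypes on both sides; one
left-to-right pass over the original vector, no cascading) is the
denoiser; individuals missing at the chosen site fall back to the
next-ranked site, which stands in for the imputation/phasing step of
read-level pipelines.

## The simulator

`simulate_cross()` tracks founder-haplotype identity (grandmother's two
haplotypes, grandfather's two) through meiosis at every marker, so sex
assignment, composition truth and haplotype paintings are exact. Crossovers
are placed per adjacent marker interval as independent Bernoulli draws with
probability equal to the map function's recombination fraction for that
interval — adjacent-interval fractions match Haldane or Kosambi exactly,
and longer-range fractions follow no-interference composition of the
intervals. The determiner (and optional modifier) are pseudo-loci inserted
into the map and inherited like markers.

The default configuration mirrors the structure of RAD-sequenced cichlid
crosses: 22 chromosomes, 10,000 markers, two families, 150 F2, a quarter of
markers fixed between the founder species, negative-binomial read depth
with mean 30 (mid-range of a 12–50× design; low-depth genotypes below 10
reads are masked downstream), 2% dropout and 0.5% genotype error. Gametolog
variants — sites where the heterogametic founder is heterozygous because
the Y (or W) differs from the X (or Z) — are placed at rate 0.05 within
±25 cM of the determiner, giving a few dozen Y-linked sites at full marker
density, the order observed in empirical crosses of this design. Founders
are otherwise homozygous; within-species polymorphism is not simulated, so
every polymorphic marker in the cross is informative about grandparental
origin. That idealisation (plus the absence of alignment artifacts,
linked-read errors and segregation-distorted map gaps) is what passing
recovery tests do and do not show about real data: they validate the
statistical machinery, not robustness to upstream artifacts.

Sex is assigned determiner-first: carriers of the determiner allele become
the determined sex with probability `penetrance`, then, in carriers of the
modifier allele, the modifier flips the phenotype to its direction with its
own penetrance. Viability selection is rejection sampling on the
composition × sex survival map, with an explicit error when a family cannot
be filled. The sex chromosome recombines freely by default — the systems
this design targets are young and undegenerate — with an optional
zero-recombination window around the determiner to model crosses whose F1
carry no recombinant sex chromosome. An optional Y-deletion mode halves
carrier depth over a chosen span so the depth-ratio screen has a positive
control.

## Problem sizes and numerical choices

Simulation-based tests use 4–6 chromosomes at 200–450 markers per
chromosome — the per-chromosome marker density typical of RAD-sequenced
cichlid crosses, carried over to a few chromosomes — with 100–200 F2, and 100 seeded pipeline runs
for the recovery suite. The end-to-end recovery criterion uses
1,000 markers on 4 chromosomes, n = 150, full 10,000-permutation testing.
Composition-accuracy checks simulate a ±10 cM non-recombining window around
the determiner, matching the empirical situation where F1 recombinants at
the sex-determination region are absent or removed; with recombination
through the determiner region, accuracy is bounded by the distance of the
nearest surviving Y/W-linked site, and the tests document that behaviour
rather than hide it. Windowed statistics anchor half-open windows at bp 0.
SNP-only input cannot reproduce a per-sequenced-position heterozygosity
denominator, so window functions accept an optional callable-site count per
window; without it, proportions are per genotyped SNP and are labelled as
such.

## Known limitations

- The polarization step requires the grandmother (or her species
  surrogates) to be genotyped; with neither, REF/ALT orientation is kept
  and composition labels lose the species anchoring.
- The two-site composition decode degrades gracefully but measurably when
  the F1 carry recombinant sex chromosomes or when no tightly linked Y/W
  site survives filtering; the recombinant flag and the site lists are
  returned so users can judge.
- The interval scan's EM is fitted independently per position; no multi-QTL
  or covariate-adjusted interval model is provided (the family covariate is
  available on the marker-regression path).
- Sequencing is simulated at the genotype level; read-level artifacts
  (allelic dropout correlated with alleles, reference bias) are represented
  only through the symmetric error and dropout rates.
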