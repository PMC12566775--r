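---
title: "Mapping a binary callus-type trait: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a binary callus-type trait: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`callusmap` maps a binary tissue-culture phenotype — whether a maize
B73×A188 F2 immature embryo forms a compact Type I or a friable Type II
callus — from sparse, error-prone genotyping-by-sequencing (GBS) calls and
from bulked-segregant RNA-seq allele counts. This vignette explains the
statistical models, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
several defensible options existed.

## The genetic model

The phenotype is modeled as a Bernoulli draw from a logistic liability:
for individual $i$ with A188-allele dosage $x_{iq} \in \{0,1,2\}$ at QTL
$q$,

$$\Pr(\text{Type II}) = \operatorname{logit}^{-1}\!\Big(\mu + \sum_q
\beta_q (x_{iq}-1) + \delta_q\,[x_{iq}=1]\Big).$$

$\beta_q$ is the additive effect per A188 allele copy on the log-odds of
Type II (negative $\beta$ means the B73 allele is favorable); $\delta_q$ is
a heterozygote deviation, zero by default because the mapped callus-type
loci behave additively. Meiosis follows the Haldane model — per gamete and
chromosome, a Poisson number of crossovers with mean equal to the genetic
length in Morgans, positions uniform on the length, no interference. The
same no-interference assumption underlies the interval-mapping transition
probabilities, so simulator and estimator agree by construction; real maize
meiosis shows positive interference, which makes double crossovers rarer
than simulated — a conservative direction for the segmentation tests.

## Segment (bin) markers

GBS calls are sparse and error-prone, so per-individual SNP calls are
reduced to chromosomal segments before mapping. The rule is deliberately
transparent rather than model-based: a centered plurality vote of width
`smooth_window` (default 5) over the non-missing calls, run-length encoding
into candidate segments, and absorption of any segment supported by fewer
than `min_snps_per_segment` SNPs (default 3) into its flanks — merged
through when both flanks agree, otherwise into the better-supported flank
(ties to the left). Boundaries sit at the bp midpoint between the flanking
SNPs. An HMM would be statistically sharper, but the plurality rule is
parameter-light, fast, and its behaviour on clean data is provable: with no
degradation (and smoothing disabled) it reproduces the true crossover
segmentation exactly, which the test suite checks against the simulator's
recorded crossovers for 200 individuals. Equivalence with any particular
published bin-marker tool is not claimed.

Two consequences of the absorption rule are worth knowing. True segments
spanning fewer than `min_snps_per_segment` observed SNPs (tight double
crossovers) are invisible — at 10 SNPs/cM this costs roughly 3% of
individuals one transition, at 5 SNPs/cM roughly 7%. And the *discernible*
recombination count (segment transitions) is what the QC filter compares
against its expectation of $2L$ Morgans; the default multiplier 2.0 is
generous relative to Poisson spread, so clean individuals essentially never
trip it while individuals with several-fold inflated genotype error do.

Population bin markers are the union of all retained individuals' segment
boundaries; monomorphic bins are dropped and physically adjacent bins with
identical call vectors collapse. Bins that became non-adjacent after the
monomorphic drop are never merged across the gap — a merged bin must be a
literal sub-interval of every covering segment.

## The two genome scans

**Logistic scan.** At each bin the likelihood-ratio test of
`y ~ genotype` against the intercept-only model. The default coding is a
2-df genotype factor — a direct test of genotype-frequency differences
between phenotype classes — whose maximum-likelihood fit has a closed form
through the 2×3 contingency table (the G-test); it stays finite under
complete separation, which matters at strongly selected markers. The 1-df
additive coding is available for comparison and is fit by `glm`; when that
fit diverges under separation, a ridge penalty of $10^{-4}$ on the
coefficients stabilizes it and the event is flagged. Two genome-wide
thresholds are computed side by side: Benjamini–Hochberg FDR at 1%, and the
5% quantile of the minimum p-value over 1000 phenotype permutations.

**Binary-model interval mapping.** On a pseudomarker grid (default step
1 cM, marker positions always included), the latent QTL genotype
distribution of each individual is
$\Pr(g \mid g_L, g_R) \propto \Pr(g \mid g_L)\Pr(g_R \mid g)$ using the F2
dosage transition matrix under Haldane recombination fractions to the
nearest informative flanking markers; a missing flank falls back to the
marginal 1:2:1 prior on that side, so positions outside marker coverage are
scored from the single available flank. Penetrances
$p_g = \Pr(\text{Type II} \mid g)$ are fit by EM — E-step: posterior
genotype weights; M-step: weighted class means — with convergence at
$\max_g |\Delta p_g| < 10^{-6}$ or 100 iterations, initialized at the
complete-data weighted class means (EM monotonicity then guarantees
LOD ≥ 0, and the LOD is clamped at zero against floating-point noise). At a
fully informative marker the weights are one-hot, EM converges in one step,
and the LOD equals the 2-df single-marker binomial LOD — the suite asserts
agreement within $10^{-6}$, and that LOD $= \mathrm{LRT}/(2\ln 10)$ against
the logistic factor test. Monomorphic bins are excluded from the scan: a
marker without segregation carries no mapping information but would
otherwise distort the flanking-genotype inference, and excluding it makes
the scan invariant to padding with such markers.

Thresholds: the permutation rule (max-LOD over shuffles, 5%) and the fixed
LOD 3 convention are both supported. Peaks are contiguous above-threshold
runs; within a run the maximum (ties to the smaller bp); peaks closer than
`min_separation_cM` (default 30) merge keeping the higher. Support
intervals extend to the outermost contiguous positions within `lod_drop`
(default 1.5 — the conventional choice; the interval is reported, equality
with any specific published interval is not claimed) of the peak.
The joint fit puts every peak bin into one logistic model (factor-coded, no
epistasis, complete cases) and converts its LOD to percent variance
explained via $100(1-10^{-2\,\mathrm{LOD}/n})$.

**Favorable allele and dominance.** At a peak bin the favorable allele is
the parent whose homozygote class shows the higher Type II proportion. The
dominance call places the heterozygote proportion within the homozygote
span: the middle third is `additive`, the sixth nearest either homozygote
(or beyond it) is `dominant`, the bands between are `partial`. The
trichotomy needs three disjoint regions; reading "outer third" literally
would leave `partial` unreachable, so the dominant band was narrowed to the
outer sixth. Note the statistical ceiling of this rule: with $n \approx
200$ (≈100 heterozygotes), the sampling standard error of the normalized
heterozygote position is ~0.13–0.15, so even a truly additive locus lands
in the middle third only ~75–80% of the time — a property of the rule, not
of the estimator.

## BSR-seq association

Bulk allele counts are modeled as binomial draws: per SNP and bulk, depth
is Poisson and the A188 read count is Binomial(depth, bulk allele
frequency). Records pass the fixed filter `AF ≥ 0.2 && QUAL ≥ 30.0 &&
DP ≥ 100 && DP < 10000` (boundaries exactly as written: inclusive lower
bounds, strict upper) and must match the fixed B73/A188 parental allele
pair. The association test is a binomial GLM with logit link of A188-read
proportion on bulk class, p-value from the 1-df deviance test; the default
pools the two replicate bulks per class, because the test is defined
per-SNP between classes and the replicates are exchangeable draws from the
same bulk frequency. A `replicate_term` variant adds the replicate as a
nuisance factor for users who prefer it; no overdispersion correction is
applied by default, matching the plain-binomial model. Genome-wide
significance is Bonferroni at 5%. The deviance test agrees with the
Pearson 2×2 chi-square oracle within |Δlog10 p| ≤ 0.5 at moderate effects
and depth ≥ 100 (asserted over 1000 random tables); at extreme tables the
two statistics diverge, which is expected asymptotic behaviour, not error.

## What the simulator emulates — and what it does not

Defaults mirror the experimental design: 2194 embryos, 100 + 100 selected
extremes (selection is uniform within phenotype class — the phenotype is
binary, so every class member is equally extreme), 10 chromosomes of
105–180 cM at 1 Mb/cM, 5 SNPs/cM, and two 50-callus bulks per class at
mean depth 200. Degradation is per-call: 20% missing, 2% uniform
miscalls, and 10% heterozygote undercall (allele dropout at GBS depths;
at depth-filtered sites 10% is realistic, and it keeps clean-data
recombination counts at their $2L$ expectation, consistent with a QC
filter that retains most genuine individuals). QTL effect sizes default to
$\beta = (-1.9, -2.2, +2.0, -1.9, -1.8)$ on chromosomes 2/5/6/8/9: the
real loci's liability-scale effects are unreported, so the defaults were
chosen by a power calculation to make all five loci detectable at
$n \approx 200$ — with five segregating loci the phenotypic noise from the
other four attenuates each marginal effect by a factor ~1.7–1.9, which is
why the betas are larger than a single-locus intuition suggests. The
resulting joint-fit variance explained (~50–60% in the selected sample) is
in the range reported for the real cross.

Not emulated: read-level sequence data (no FASTQ, alignment or
base-quality model — degradation acts directly on genotype calls),
crossover interference, segregation distortion, linked or epistatic QTLs,
depth-dependent error structure (undercall probability is constant, not a
function of per-site depth), and any transcriptome structure beyond DEG
labels (the gene fixture assigns DE status at random, with half of the
second contrast's DEGs shared with the first). Passing tests therefore
demonstrate that the estimators recover the truth of *this* generative
model at desk scale; they do not validate robustness to interference,
distortion or alignment artifacts in real GBS data.

## Numerical and interface choices

* Coordinates are 1-based closed internally (the R/Bioconductor
  convention) and in TSV outputs; BED writers convert to 0-based
  half-open. Every output table carries a comment line stating its
  convention.
* Genotypes are stored as A188-allele dosage (AA = 2, AB = 1, BB = 0,
  `NA` missing); `AA` always means the A188 homozygote.
* Likelihood computations use the $0\log 0 = 0$ convention; probabilities
  are clamped at $10^{-300}$ before logs; quantiles in the permutation
  thresholds are type-1 (order statistics), so `alpha = 1` degenerates to
  the extreme over permutations.
* The pipeline fans a single global seed into fixed per-stage substreams,
  so stages can be rerun independently and a rerun of the same
  configuration is byte-identical (manifests record file digests, never
  timestamps).
* Permutation scans are vectorized across shuffles (contingency counts by
  matrix multiplication for the logistic scan; EM over a phenotype matrix
  for interval mapping), which is what makes calibration experiments with
  hundreds of null datasets practical.

The test suite runs its heavier properties at reduced scale chosen for
desk-size runtimes: threshold calibration uses 200 null datasets of 60
individuals on a 3×60-cM genome with 200 permutations each; the five-QTL
recovery property uses 20 replicates of the full 2194-embryo design; the
null-genome family-wise error check uses 100 replicates of 10,000 SNPs.

## Known limitations

* The dominance trichotomy is noisy at $n \approx 200$ (see above);
  treat `partial`/`dominant` calls at moderate-effect loci as suggestive.
* Support intervals inherit the grid step (default 1 cM) as their
  position resolution, and with strong linkage a single broad QTL can
  shoulder into secondary above-threshold peaks beyond the merge distance.
* `expected_recombination_count` assumes discernible transitions ≈
  crossovers, slightly over-expecting at sparse SNP coverage where tight
  double crossovers vanish; the generous QC multiplier absorbs this.
* The VCF reader handles the minimal fixed-field + GT (+AD) subset it
  documents, with a required parental-orientation sidecar; it is not a
  general-purpose VCF implementation.
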