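---
title: "Methods: diversity, divergence and LD across site classes"
author: "driftscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, divergence and LD across site classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftscape)
```

# Scope and model

driftscape implements the population-genomic analysis that sits
downstream of read alignment and genotype calling for a multi-sample
diploid resequencing cohort: a post-call filter stack producing an
explicit accessible-site mask, classification of sites by codon
degeneracy and into conserved noncoding element (CNE) sets with matched
neutral flanks, per-class nucleotide diversity ($\pi$), outgroup
divergence ($d$), $\pi/d$, folded site-frequency spectra and Tajima's
$D$, distance-binned diversity profiles around features with a
distance-kernel convolution, genotype-$r^2$ linkage-disequilibrium (LD)
decay with offset plain and stretched exponential fits, and the
$N_e$/$\mu$ estimates implied by neutral diversity and divergence. A
forward Wright–Fisher simulator generates complete synthetic inputs so
that every stage can be validated against known truth.

## Estimators

Per-site heterozygosity uses the unbiased estimator
$\hat\pi = 2j(n-j)/\{n(n-1)\}$ for a site with minor-allele count $j$
among $n$ called alleles; class-level $\pi$ divides the sum over
segregating sites by the number of *accessible* sites of the class, so
monomorphic sites count in the denominator and per-site rates are
comparable across classes. Divergence compares the ingroup major allele
(ties resolved to the reference allele; the source data do not state a
rule, so we fixed one and exposed the major-allele computation) with
the outgroup base per position, dropping positions without a usable
outgroup base from numerator and denominator.

Because calledness varies by site, spectra are projected to a fixed
haploid size $n_{proj}$ by hypergeometric downsampling, folding after
projection, with expected counts accumulated as real numbers; sites
with fewer than $n_{proj}$ called alleles are skipped and counted.
Tajima's $D$ uses the standard 1989 constants; by default it is
computed on the projected spectrum ($n_{proj} = 6$, i.e. twice the
minimum-calledness threshold of 3 samples, configurable up to the full
cohort), since the original handling of variable $n$ is not
determinable from the source analyses.

Confidence intervals are 95% percentile bootstrap over resampling
units: transcripts for exonic classes and nonempty 1 Mb windows
(configurable) for CNE and flank classes, 1,000 replicates by default.
Percentile rather than BCa intervals keep the procedure identical
across statistics, including ones (like $D$) that are nonlinear in the
unit sums.

$\mu = d/(2Tg)$ converts neutral divergence into a per-generation
rate given a split time $T$ in years and $g$ generations per year, and
$N_e = \pi/(4\mu)$ equates neutral diversity to its drift-mutation
expectation. Defaults $T = 12$ Myr and $g = 2$ match the rat–mouse
calibration; the estimate halves $\mu$ and doubles $N_e$ if $g$ is
doubled, leaving $4N_e\mu$ fixed.

## Filter stack

A site passes when: it is biallelic (multi-allelic single-nucleotide
records are excluded outright — the folded-SFS machinery assumes two
alleles); site quality is at least 23; the inbreeding coefficient
$F = 1 - H_{obs}/H_{exp}$ (taken from the VCF INFO field where present,
otherwise computed when at least 10 samples are called) is at least
$-0.8$ — this removes all-heterozygote sites typical of collapsed
paralogs; per-sample depth lies within 25–300% of that sample's modal
coverage, with out-of-bounds samples set missing rather than failing
the site (this keeps sample-level and site-level filtering composable;
the site is then re-checked against the minimum calledness of 3); and
mean depth/modal over *all* samples lies within 50–140%. Modal coverage
is the argmax over positive depths with ties broken toward the smaller
depth, which is conservative against duplications. Separately, indel
neighborhoods (deleted span plus one base each side; inserted length
each side of the insertion point plus the two flanking bases — the
insertion rule is ambiguous in prose, so our reading is documented and
configurable at the parser level), CpG-prone positions (preceded by C
or followed by G in any provided sequence), and the proximity filter
(variant sites closer than $m_d = 5$ bp to another variant site,
evaluated on the original variant set without cascading) are recorded
in the same mask with distinct reasons. The first failing reason per
site is kept, and `#pass + #fail` always equals the number of
positions considered.

## Site classes

A transcript is *complete* when its CDS starts with ATG, ends with a
stop, has length divisible by three, and contains no internal stop.
Only complete transcripts contribute to degeneracy: each CDS position
takes the number of nucleotide substitutions at its codon position that
preserve the amino acid (0, 1 or 3, mapped to 0-, 2- and 4-fold), and a
genomic position keeps a class only when every complete transcript
covering it agrees; disagreements are excluded as inconsistent.
Three-fold degenerate positions (e.g. Ile third positions) fit none of
the reported classes and are excluded — the source analysis reports
only 0/2/4-fold and is silent on them. Positions covered solely by
incomplete transcripts are excluded as `invalid_transcript`.

CNE sets come in three variants: `noOverlap` (exon-overlapping
*segments* trimmed out, possibly splitting an element), `strict`
(elements with any exon overlap dropped entirely) and `noOverlap_lt1kb`
(`noOverlap` restricted to elements under 1 kb, the default for
within-CNE statistics because rare long elements would otherwise
dominate). The neutral flank reference for a CNE of length $L$ places
$\lceil L/2\rceil$ bases ending exactly 500 bp upstream and
$\lfloor L/2\rfloor$ bases starting exactly 500 bp downstream (ceil
upstream by convention; flanks are not slid outward when masked), then
subtracts exons and the full `noOverlap` CNE set and clips at
chromosome bounds — flanks can end up empty, which is allowed.

## Flank profiles and convolution

Each accessible site outside the features, and not itself classified
as a degeneracy class or CNE, is counted once at its distance to the
nearest feature: distance 1 is the adjacent base, and bins are
$(0, w], (w, 2w], \dots$ with $w = 1$ kb up to 100 kb for exon flanks
and 100 bp up to 20 kb for CNE flanks. To ask how much of the CNE-flank
far field is explained by CNEs sitting near exons, the exon-flank
$\pi$ profile (at 100 bp bins) is convolved with the normalized
distribution of CNE-to-nearest-exon edge gaps (100 bp bins, capped at
200 kb): `out[i] = sum_k kernel[k] * in[i + k]`, the input padded on
the right by the kernel width with the site-weighted mean $\pi$ of the
60–100 kb range. Far-field slopes are site-weighted ordinary least
squares of per-bin $\pi$ on bin midpoints over 5–20 kb. Element-to-exon
distance uses the edge-to-edge gap (not midpoints), matching how flank
distances are measured elsewhere in the package.

## LD decay

Genotype $r^2$ is the squared Pearson correlation of dosage vectors
over samples with both calls present; pairs with a zero-variance
member are skipped and counted. Every focal SNP is paired with all
SNPs within the window (40 kb default) and pooled $r^2$ values are
averaged in 20 bp bins; when the focal set is all SNPs each unordered
pair counts once, and for focal subsets a pair of two focal SNPs counts
once. A per-focal-window pair budget (`nMax`) subsamples uniformly with
a fixed seed. The decay is summarized by
$g(x) = (a-c)\,e^{-(x/b)^d} + c$ with $0 < d \le 1$, fitted by
pair-count-weighted Levenberg–Marquardt least squares under box
constraints from a deterministic multistart grid
($b \in \{100, 300, 1000, 3000, 10^4\}$ bp,
$d \in \{0.3, 0.5, 0.7, 0.9, 1\}$) — these fits are genuinely
hard, and the grid plus the nested $d = 1$ solution as an extra start
makes the free-$d$ fit provably no worse than the plain exponential.
The offset $c$ has the finite-sample floor $1/(n-1)$ for $n$ diploids.
Refits with $d$ pinned at 0.5 give characteristic lengths $b$ that are
comparable across cohorts.

# The synthetic-data generator

The generator is a discrete-generation forward Wright–Fisher
simulation over a segregating-site × haplotype indicator matrix:
per-haplotype mutation counts are Poisson($\mu L$) at uniform
positions, with a mutation landing on an already-segregating (or
fixed-derived) position flipping that haplotype's allele so every site
stays biallelic; recombination draws Poisson($rL$) crossovers between
the two parental haplotypes; diploid viability is multiplicative,
$\prod_p (1 - s_p\,\mathrm{dosage}_p/2)$, i.e. fixed semidominance
$h = 0.5$. The population burns in for $10N$ generations at the most
ancient epoch size before the epoch sequence applies — long enough for
$\pi$ and $D$ at the tested $\theta$ to sit within test tolerances of
their equilibrium values. Derived alleles that fix move to a fixed set
and contribute to divergence alongside the outgroup branch, which
substitutes each position independently with probability
$1 - e^{-2\mu t_{split}}$ (uniform among the three alternatives). This
is where weakly deleterious sites acquire $d$ below neutral: their
ingroup fixations are suppressed while the neutral outgroup branch is
shared, so $\pi/\pi_{neutral} < 1$ and $d/d_{neutral} < 1$ hold in
expectation when the ingroup term contributes appreciably.

Annotation synthesis places non-overlapping single-CDS "transcripts"
(lengths a multiple of three; valid open reading frames are imprinted
into the reference on the sampled strand) and CNEs positioned by a gap
drawn from a uniform/exponential mixture relative to a random exon
edge — the mixture weight is the clustering knob, and weight 0 yields
uniform CNE-to-exon gaps, mimicking the observed overrepresentation of
CNEs near exons when positive. Selection maps assign $s$ to exonic
first/second codon positions (mostly nonsynonymous) and to CNE
positions, leaving third positions neutral as a stand-in for the
largely synonymous 4-fold class.

Cohorts are sampled by pairing haplotypes without replacement;
genotypes are masked independently at the missingness rate; per-sample
depths are negative binomial (mean 30, dispersion 5) and site
qualities a two-component mixture (3% uniform on [5, 22], else uniform
on [30, 1000]) — invented defaults chosen so that every filter rejects
something, recorded in the truth list, and not tuned further. The
depth and quality models are independent of genotype, so filtering is
noisy but unbiased with respect to the statistics under test.

What the generator does *not* emulate: alignment and calling artifacts
correlated along the genome, base-composition and mutation-rate
heterogeneity (beyond CpG flagging of the emitted sequences), gene
conversion, overlapping isoforms, and realistic chromosome lengths.
Passing tests therefore demonstrate correctness of the estimators and
plumbing under a clean generative model, not robustness to real-data
pathologies.

# Numerical choices and degenerate inputs

Hypergeometric projection conserves each site's probability mass to
within $10^{-12}$ and is checked against exhaustive subsample
enumeration. Tajima's $D$ errors (rather than returning 0) when no
site segregates. Largest-remainder rounding preserves SFS totals in
the DFE-alpha export. The modal-coverage tie-break, the flank
ceil/floor convention, distance-1-in-bin-0, and the unordered-pair LD
rule are each fixed once and asserted by tests. Bootstrap intervals
error when the statistic is undefined in more than 10% of replicates.
LD fits return `converged = FALSE` with the best point found rather
than failing, and zero-variance partner SNPs are skipped, not
zero-filled.

Test and vignette problem sizes (e.g. 2 kb replicate loci at
$\theta = 0.004$ with 200 replicates; 20 kb selected/neutral blocks at
$N_es \approx 5$ with 100 replicates; 50–60 kb cohorts for LD and the
pipeline) were chosen as the smallest scales at which the coalescent
expectations under test have comfortable margins; they are stated in
the tests themselves.

# Known limitations

Multi-chromosome inputs are analyzed one chromosome at a time (the
simulator emits a single region). The PSMC encoder assumes upstream
genotype-quality filtering has been applied; the package's own VCFs
carry no per-genotype qualities, so the 10/12-calledness condition is
the operative one. The stretched-exponential characteristic length is
ill-determined when the decay scale approaches the pair window — on
single-locus cohorts the offset and length trade off, so only
direction and rough magnitude of between-cohort $b$ contrasts are
meaningful at desk scale. DFE inference, PSMC's HMM, and conservation
scoring are out of scope: the package emits their inputs only.
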