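---
title: "Profiling ovarian cancer from ascites cfDNA: models, parameters and design"
author: "ascitesProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling ovarian cancer from ascites cfDNA: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascitesProfiler)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-cohort generator does and does not
emulate, the numerical choices, and the known limitations. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Setting

Ascites accumulates in most advanced ovarian cancers and is drained at
routine paracentesis; its cell-free DNA (cfDNA) is strongly tumour-enriched.
Targeted panel sequencing of that cfDNA — typically a ~500-gene oncology
panel with a callable coding footprint near 1.94 Mb, without a matched
germline sample — yields per-sample variant tables and bin-level log2 copy
ratios. From these the pipeline derives: likely-somatic variants, tumour
purity, purity-rescaled copy number, large-scale genomic alterations (LGA),
a binned loss-of-heterozygosity percentage (LOH%), tumour mutation burden
(TMB), a 0–3 genomic-instability consensus, and clonal prevalence across
sequential samples from the same person.

## Somatic triage without a germline sample

With no matched normal, a variant is *likely somatic* when it is strictly
below a population-frequency threshold in every database that annotates it:
0.05% (gnomAD exomes), 0.5% (gnomAD genomes) and 2% (1000 Genomes). These
percentages are taken as the operative rule; an allele-*count* bound
(< 100) is applied additionally only when count annotations are supplied,
since frequencies are what annotation files carry. A variant absent from all
three databases passes — absence from population databases is itself the
strongest somatic evidence — and is marked `"no population evidence"` so the
decision is auditable. All boundary comparisons are strict.

A triaged variant is *verifiable* when detected in more than one sample of
its participant or, if unique, when VAF > 0.05 and depth > 150× (strict).
Rows with zero alt reads — placeholders that give a participant's samples a
shared variant universe — are observations of absence and count toward
neither rule.

Artefact-laden libraries (the FFPE failure mode) announce themselves as
outlying total variant counts. The flag excludes the single sample deviating
most from the cohort median (ties broken toward the larger count, since the
concern is inflation), then flags every sample beyond |Z| = 3 of the
remainder's mean and SD. The exclusion step matters: a gross outlier
otherwise inflates the SD enough to hide moderate outliers. With zero SD in
the remainder, any sample differing from that mean is flagged.

TMB is reported as verified likely-somatic variants per callable megabase
(default 1.94 Mb), rounded to one decimal. Replicating a vendor app's exact
variant-eligibility rules is out of scope; consequently absolute TMB from
this triage runs higher than app-reported panel TMB, because each person
genuinely carries rare germline variants (tens per 2 Mb at realistic
rare-variant loads) that population databases cannot remove. The consensus
score below compares samples against cohort medians, which absorbs this
shared offset.

## Tumour purity from the TP53 double hit

High-grade serous ovarian carcinoma almost always initiates with a
deleterious *TP53* point mutation followed by deletion of the wild-type
allele. Under that double hit, tumour cells carry one mutant and zero
wild-type copies while normal cells carry two wild-type copies, so the
mutant VAF *v* reads out tumour fraction *t*:

$$ v = \frac{t}{t + 2(1-t)} \qquad\Longleftrightarrow\qquad t = \frac{2v}{1+v}. $$

The function is monotone, concave, maps [0, 1] onto [0, 1], and satisfies
*t* ≥ *v* (purity always exceeds the VAF because normal cells contribute two
alleles each). When a sample carries several deleterious *TP53* calls, the
highest-VAF call anchors the estimate — under the gatekeeper assumption that
is the clonal one. When *TP53* cannot anchor (e.g. its locus is deleted in a
later sample, driving the VAF to zero), purity falls back to proportional
scaling of a shared deleterious variant against a reference sample with
known purity, `t = t_ref · v/v_ref`, clipped to [0, 1]; failing that, a
supplied manifest hint. The method used is always recorded.

Assumptions worth stating: clonality and hemizygosity of the anchor (CCF 1,
multiplicity 1, local CN 1), and absence of *TP53*-region subclonal copy
gains. Violations bias the estimate in the direction of the violation; the
recorded `method` and `anchor_variant` make audits possible.

## Copy number, segment repair, LGA

A log2 copy ratio against a flat diploid reference measures the
tumour/normal mixture, so rescaling inverts it:

$$ 2 \cdot 2^{\log_2 r} = t \cdot CN + 2(1-t) \quad\Rightarrow\quad
   CN = \max\!\left(0, \frac{2 \cdot 2^{\log_2 r} - 2(1-t)}{t}\right). $$

The generator produces bin log2 values from exactly the forward form of this
equation, so the pair is self-consistent and invertible at zero noise (a
tested property). Integer copy number uses half-up rounding — "disparate
copy number" means a whole-copy difference, which keeps the LGA statistic
robust to log2 noise.

Segments with implausibly *high* read depth (collapsed repeats, capture
artefacts) are repaired: the modified Z-score `0.6745·(d − median)/MAD` is
computed over a sample's segments, and segments above 3.5 (one-sided — only
high depth is suspect) take the mean of their flanking segments' pre-repair
estimates, a single flank at contig ends. When the MAD is zero (more than
half the segments tied at the median depth) the standard fallback divides by
1.253314 × mean absolute deviation instead; only when that is also zero
(all depths equal) is nothing flagged. Segments at or below the cutoff are
never altered (a tested invariant).

An LGA is counted per boundary: on each chromosome, the ordered subsequence
of segments strictly longer than 10 Mb is scanned and every consecutive pair
with differing integer CN contributes one. Sub-10-Mb interveners are skipped
— the reading consistent with "adjacent to other large segments" — and the
alternative per-segment counting is exposed via `counting = "segment"`.
Whole chromosomes are the adjacency universe (targeted panels carry no
centromere annotation); an arm-level BED could be substituted by splitting
segments beforehand. LGA ≥ 20 is annotated as the published HRD threshold.

Gene amplification calls take each gene's length-weighted mean segment CN;
fold = CN/2, amplified strictly above 2-fold. Divergence between two
samples' profiles is the percentage of shared-grid bins whose covering
segments disagree in integer CN — bins were chosen as the "sites" because
they are the common grid independent of either sample's segmentation.
Cohort profiles are clustered by average-linkage on correlation distance
(1 − r) of bin log2 vectors; a constant profile has undefined correlation
and is assigned distance 1 with a warning. The paired region-density test
(reads/Mb in two regions across samples) is a classical two-sided paired
t-test via `stats::t.test`; zero-variance differences are reported as
undefined rather than fabricated.

## Binned LOH percentage

Heterozygous sites sit at VAF 0.5 when alleles are balanced; allelic
imbalance displaces them in proportion to purity. Chromosomes are tiled with
100-kb bins anchored at position 0 and truncated at contig ends
("chromosome-limited"). *All* detected variants feed the statistic — panel
germline SNPs are the signal carriers, so the somatic triage is deliberately
not applied first. "Non-homozygous" is operationalised as VAF within
[0.05, 0.95] (inclusive, configurable): wide enough to keep strongly
imbalanced LOH heterozygotes, tight enough to shed fixed homozygotes. A bin
is occupied with ≥ 1 eligible variant (`minVariantsPerBin` configurable;
single-variant bins are admitted because panel bins are sparse), and shows
LOH when its mean eligible VAF is strictly outside [0.4, 0.6].

Two guards gate interpretation: mean depth ≥ 150× and median VAF ≥ 0.1 over
the eligible variants; failing samples are flagged unreliable with the
failing guard named, and LOH% strictly above 16 sets the published HRD
cut-off flag. For a deletion-LOH tract the two VAF branches are
`1/(2−t)` and `(1−t)/(2−t)`: both leave the [0.4, 0.6] band only for
t > 1/3, which is why the statistic's sensitivity grows with purity (a
tested monotonicity property) and why low-purity samples are guarded.

## Clonal analysis

Somatic VAFs convert to cancer cell fractions through the standard identity

$$ v = \frac{ccf \cdot t \cdot m}{t \cdot CN + 2(1-t)}, $$

with multiplicity estimated per variant by
`m̂ = clip(round(v·(t·CN + 2(1−t))/t), 1, CN)` — panel data cannot phase
alleles, so a rounding rule replaces marginalisation. Exclusions before
clustering: variants on CN-0 loci in *any* matched sample (`"cn0"`; such
observations have no generative model), and — when any sample of the
participant is below 30% purity — variants at VAF ≥ 0.3 in that sample
(`"low-purity-vaf"`; at low purity such VAFs are germline evidence). The
exclusion log partitions the input (a tested invariant). When the purity
anchor itself is cn0-excluded, the participant carries a high-frequency
clone the clustering cannot represent; it is reported as a warning record
rather than silently dropped.

Clustering is a transparent stand-in for Bayesian clonal deconvolution:
k-means on per-variant CCF vectors over k = 1..8, ten restarts each,
selecting k by a pooled-variance spherical-Gaussian BIC. The pooled variance
is floored at 0.075² — the clone-resolution scale. Two facts force the
floor: CCF estimates inherit counting noise (sd ≈ 0.03–0.07 at panel depths
of 500–1000×), and truncal CCFs pile up at the 1.0 clip, creating
degenerate near-zero-variance clusters that would otherwise make ever-larger
k look likelihood-free. Structure finer than ~0.075 CCF is below what these
depths resolve, so treating it as noise is the honest choice. The exporter
`writePycloneInput()` emits the tab-separated input (one row per
variant × sample, `normal_cn` always 2, `major_cn = max(CN−1, 1)` — a
documented unphased approximation) for users who want full variational
inference.

A clone's prevalence shift between consecutive samples is
`Δccf = ccf(later) − ccf(earlier)`, flagged when |Δccf| strictly exceeds
0.10 — absolute CCF points, not relative change, matching how serial-sample
prevalence charts are read.

## Genomic-instability consensus

LGA, LOH% and TMB are three imperfect HRD surrogates; the consensus score
counts, per sample, how many sit strictly above their cohort medians (0–3).
Medians are computed over each participant's *initial* sample only, so
serially sampled participants do not drag the reference; serial samples are
scored against those same fixed medians (recomputation is switchable via
`recomputeMedians`). Ties score 0 for that marker. An unreliable LOH is
excluded from the LOH median and contributes 0 to its sample's score, with
the flag retained.

## The synthetic cohort: what it emulates, and what it does not

`simulateCohort()` generates the study design end to end: participants with
serial cfDNA samples, per-sample purity, a truncal deleterious *TP53*
variant inside a planted 17p deletion (the double-hit anchor; the anchor's
segment is protected from simulated copy-number evolution so the double-hit
relation holds in every sample), subclones with per-sample CCFs,
allele-specific truth segments (deletion LOH, copy-neutral LOH top-ups that
add no LGA boundary, planted >10-Mb boundaries, an optional focal CN-29
amplification), germline het SNPs with population-AF annotations drawn from
a common/rare mixture, (beta-)binomial read counts, and an FFPE-artefact
injection mode that plants excess low-VAF variants with zero population AF.
Everything is recorded in a truth object, and identical seeds produce
byte-identical cohorts (tested).

Defaults are the study conditions the package targets: 15 participants × 2
serial cfDNA samples, purity uniform on 0.23–0.93, mean variant depth 900×,
hg19 autosomes with 100-kb bins and a 1.94-Mb callable footprint, 13 planted
LGA boundaries, 30% of the genome in LOH tracts, clones carrying (4, 3, 2)
somatic variants, bin log2 noise sd 0.1, beta-binomial ρ = 0.01, and 15% of
the genome changing copy number between serial samples.

Deliberate idealisations — and hence the limits of what passing tests show
about real data:

* **Per-bin phase coherence.** Het SNPs within one 100-kb bin are treated as
  a single haplotype block in perfect LD (their alt alleles co-segregate),
  so in an LOH tract a bin's SNPs deviate in a common direction. Real panels
  mix directions when a bin holds several SNPs of independent phase, which
  pulls the bin's *mean* VAF back toward 0.5 and lowers the sensitivity of
  the mean-based LOH statistic. Recovery results under this generator
  therefore demonstrate the statistic under coherent phase — its favourable
  regime, and the sparse-bin regime of real panels (mostly one informative
  SNP per occupied bin) — not under arbitrary phase at high SNP density.
* **Depth channel.** Per-bin depth varies by a lognormal factor independent
  of copy number; the injectable "unreliable" segment (8× depth, corrupted
  log2) exercises the modified-Z repair. Real coverage also tracks CN, GC
  and mappability.
* **Read-count dispersion.** ρ models *between-library* overdispersion.
  Technical-replicate comparisons are simulated at ρ = 0, because duplicate
  sequencing of one library shares its composition and exhibits counting
  noise only.
* **No read-level simulation** (FASTQ/BAM), no trinucleotide signature
  spectra — FFPE artefacts are emulated only as the excess-variant-count
  phenomenon the outlier flag detects — and no germline-resource realism
  beyond the common/rare AF mixture.
* **Tumour-only TMB bias.** The planted rare-germline fraction (2% of 1500
  SNPs) leaks through any database-only filter by construction, so absolute
  simulated TMB sits well above typical app-reported values; comparisons of
  TMB *between* samples remain meaningful.

## Numerical choices

* Strict inequalities everywhere the rules are printed as strict (AF
  thresholds, VAF/depth verification, >10 Mb, the 0.4–0.6 band, >16%, >10%
  shifts, above-median scoring); ≥ for LGA's HRD threshold of 20.
* Integer CN by half-up rounding (never banker's).
* Modified Z: unscaled MAD with the 0.6745 constant; Iglewicz–Hoaglin
  mean-AD fallback at zero MAD; all-equal depths flag nothing, with a
  warning.
* Repair uses pre-repair neighbour values; a flagged neighbour is skipped;
  a segment with no usable flank keeps its estimate.
* Outlier exclusion ties break toward the larger count.
* Coordinates: variants 1-based inclusive, bins/segments 0-based half-open;
  the conversion lives in one helper pair and is tested at the boundaries.
  Tables are kept in lexicographic (chromosome, start) order — the order the
  readers enforce.
* k-means restarts and the BIC scan are seeded; every simulation consumes
  one user-supplied seed, and all randomness flows from R's global RNG.
* Degenerate inputs: zero-depth variant records are dropped and counted;
  occupied-bin count 0 yields an undefined, unreliable LOH; zero-variance
  paired differences yield an undefined t-test; constant profiles get
  correlation distance 1; `t = 1, CN = 0` defines expected VAF 0 with a
  warning.

## Problem sizes in the tests

The suite favours small, fully checked cases: oracle equivalence on 1000
random segment layouts and 1000 random cohorts, planted-boundary recovery
for k = 0..25 at two purities, LOH recovery on a 3-chromosome (287-Mb)
genome at 5 SNPs per occupied bin, clone-count recovery over 100 seeded runs
per K ∈ {1, 2, 3} at depth 800, and a full end-to-end pipeline on 4
participants. The acceptance script additionally runs the complete
15-participant default cohort once. These sizes were chosen so the entire
suite re-derives every expected value from first principles in well under
half an hour on one core.

## Known limitations

* Purity is undefined without a usable anchor, reference, or hint — by
  design; silent guessing would poison every downstream rescaling.
* The LOH statistic measures allelic imbalance, not haplotype-resolved LOH;
  copy-number gains also displace VAFs (e.g. a 2:1 gain sits at
  (1 ± t·…) branches that cross the band at high purity) and legitimately
  contribute to the percentage.
* The k-means/BIC clustering resolves clones separated by ≳ 0.2 CCF at
  panel depths; finer structure needs the exported PyClone-VI route.
* Segmentation itself is consumed as input (`.cns`); the built-in
  `naiveSegments()` is plumbing for users without one, not a principled
  changepoint method.
* No survival or clinical interpretation, no driver annotation, and no
  reversion-mutation scanning are attempted.
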