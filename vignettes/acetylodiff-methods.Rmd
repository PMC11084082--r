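---
title: "Methods: strain- and allele-specific acetylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain- and allele-specific acetylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetylodiff)
```

## The problem

Two inbred mouse strains of different subspecies origin (here called
strain A, the reference carrier, and strain B) differ in their histone
H3K9 acetylation landscapes. Crossing them reciprocally puts both
genomes into a common nucleus, which separates two sources of
regulatory divergence: a *cis* effect is linked to the local sequence
and produces allelic imbalance inside the hybrid, while a *trans*
effect acts through diffusible factors and affects both alleles
equally. A second, structural source of divergence is insertional
polymorphism of retrotransposons — in particular 5'-truncated LINE-1
(L1) copies that retain only the element's 3' end and are associated
with local hypoacetylation of their neighbourhood.

`acetylodiff` implements the complete quantitative workflow around
these questions: fold-enrichment peak classification, allele-bias
calling, split-read insertion detection from long shotgun reads, motif
gain/loss analysis against an outgroup, metaprofiles around short 3' L1
fragments, and the linkage of allelic promoter/enhancer acetylation to
allelic expression — plus a synthetic genome-pair generator that plants
all of these effects with a recorded ground truth.

## Peak classification

Per-peak activity is fold enrichment with a pseudocount,

$$\mathrm{FE} = \frac{(\text{ChIP} + c)/N_\text{ChIP}}
                    {(\text{Input} + c)/N_\text{Input}},\qquad c = 0.5 ,$$

with library-size normalization on by default (`normalize_libsize`);
how the original analysis normalized inside FE is not stated, so the
flag is exposed. Replicates are combined by the arithmetic mean
(configurable to min or max): the source analysis computes FE for all
samples but never states the replicate summary, and the mean is the
simplest symmetric choice. A peak is A-specific iff mean
$\mathrm{FE}_A \ge 2.5$ and $\mathrm{FE}_B \le 1.5$ (boundaries
inclusive), B-specific symmetrically, otherwise conserved.

## Allele-bias calling

For each feature the A-allele frequency is $n_A/(n_A+n_B)$ per hybrid,
averaged over the two reciprocal hybrids. ChIP peaks are called
A-biased at frequency $\ge 0.68$ (B-biased $\le 0.32$), genes at
$\ge 0.8$ / $\le 0.2$. Two wordings coexist in the source ("0.68 or
more" in the operational description, "> 0.68" in the narrative); the
inclusive reading is implemented, with `inclusive = FALSE` available.
Because the narrative requires bias "in both reciprocal hybrids", the
default peak rule demands that the average *and* each hybrid pass
(`both_hybrids`); averaging-only is a switch. Features without a SNP
cannot be assigned and are excluded (`excluded_no_snp`), as are
features where a hybrid has fewer than `min_allelic_reads = 20`
informative reads — the original criterion for "genes whose allelic
bias could be calculated" is unstated, and 20 reads keeps the binomial
standard error of a frequency below about 0.11.

The acetylation-expression linkage uses a one-sided Wilcoxon rank-sum
test on promoter allele frequencies of A- vs B-biased genes (promoter
defined as TSS ± 1 kb, configurable; the original definition is
unstated) and a 2x2 chi-square test (1 df, no continuity correction —
the plain reading of "χ² test") for the presence of a same-direction
allele-specific peak within 50 kb of the TSS, boundary inclusive.

## Permutation association test

Interval-set association (peaks vs CREs; DARs vs insertion points) is
tested by re-placing every query interval uniformly at random on its
own chromosome, preserving its length, and recomputing the overlap (or
boundary-proximity) count. Within-chromosome shuffling preserves
large-scale composition; shuffled queries may overlap each other. The
empirical p-value uses the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_\text{perm}+1)$, so
$p \in [1/(n_\text{perm}+1),\, 1]$ and a maximal observed statistic at
999 permutations reports exactly 0.001.

## Split-read insertion detection

Long (~700 bp) error-tolerant reads from strain B are aligned to the
strain-A reference by exact 15-mer seeding against a sorted k-mer
index, with seeds every 20 bp along the read and both orientations
tried. Seed hits are clustered by diagonal into gapless local segments;
an optimal chain of segments along the read is selected by dynamic
programming in which a colinear same-chromosome junction costs a small
opening charge plus a near-zero per-base extension — long sandwiched
reference gaps are kept cheap deliberately, which is how the
"minimum gap penalty" of the original BLAST-based procedure is
realized here. Junctions between consecutive segments are refined
base-by-base (isolated substitutions tolerated, two consecutive
mismatches stop the extension), making junction coordinates identical
across reads spanning the same event.

Call logic on the refined, uniquely mapping segments:

* reference-side gap `0 < g < 300` with read-adjacent flanks →
  carrier-A insertion (deletion in B) of length `g`;
* read-side gap `0 < g < 300` with reference-adjacent flanks →
  carrier-B insertion, sequence taken from the read;
* reference-side gap `>= 300`, same chromosome and orientation,
  read-coordinate gap `<= 20` → long carrier-A insertion over the
  sandwiched interval.

Long carrier-B insertions are structurally undetectable at this read
length, matching the original asymmetry of the call set. A junction
anchored in a repeat-ambiguous segment (another near-identical
placement covers ≥ 80% of the same read span) is never called: this
replaces the original manual genome-browser curation with an explicit,
reproducible rule, as does the annotation convention (element class =
repeat covering ≥ 50% of the inserted interval). Per-read calls within
20 bp are merged with summed support. `has_3prime_end` is decided by
the best local alignment of the inserted sequence's ends to the L1
consensus tail: the alignment must end within 30 bp of the consensus 3'
terminus and score at least 25 (about a 25-bp exact match), which
rejects micro-alignments.

Segment scores use match +1 / mismatch −2 and equal the optimal local
DP score over the segment span; the test suite verifies this against an
independent affine-gap aligner on ≤ 2-kb windows.

## PWM scanning with an exact null

PWMs are built from count matrices with pseudocount 0.1 per cell
(probabilities $(n+c)/(N+4c)$), log2 odds against the background, and a
finite sentinel of −30 for zero-probability cells. The score null under
an i.i.d. background is computed exactly by convolving per-position
score distributions discretized at $10^{-3}$ bits; a brute-force
enumeration over all $4^w$ sequences reproduces the DP tail exactly
(within the discretization bound) for widths up to 8. The per-scan
p-value cutoff defaults to $10^{-4}$ — a conventional scanning default,
as the original analysis names no threshold.

Allele-specific presence is evaluated on the two allelic versions of
each peak sequence (the reference sequence with SNP alleles
substituted — exactly how the original built its strain-B sequences),
both strands. The association statistic is a 1-df goodness-of-fit
chi-square on (hyper-only, hypo-only) counts, the minimal test
consistent with the printed 14-vs-4 comparison; a 2x2 variant is
provided behind a flag. No multiple-testing correction is applied by
default, and a count-based rather than presence-based comparison (which
the source's scatter axes hint at) is intentionally not the default:
the presence rule is implemented and the discrepancy documented rather
than resolved. Gain/loss polarization compares motif presence in the
hyper allele, hypo allele, and the outgroup sequence (ancestral proxy):
derived-only presence is a gain, outgroup-plus-one-allele presence is a
loss, anything else is ambiguous. Real-mode whole-genome outgroup
alignment is out of scope; in synthetic mode orthology is positional
through the shared ancestor.

## Metaprofiles and the dip statistic

Genome-wide signal is binned fold enrichment. Hyperacetylated regions
are 50-kb bins with FE ≥ 1.5 (inclusive); the selected fraction is
reported so the expected correspondence with "about the top 3%" can be
checked. Profiles around anchors (short 100–400-bp 3' L1 fragments) are
computed from a fine 100-bp-bin FE track — not from the 50-kb track,
which only selects regions, since the dip has sub-2-kb structure —
resampled around each anchor midpoint (minus-strand anchors flipped,
masked bins excluded from means; the anchor reference point is the
midpoint, which for ≤ 400-bp elements differs from the 3' end by less
than half the flank bin). Per-anchor averaging is the default; pooling
counts first is a flag. The dip statistic is the mean FE within ±2 kb
of the anchor divided by the mean FE over the remaining ±10-kb flank;
it is scale-invariant, equals 1 for a flat track, and recovers a
planted dip factor of 0.3 within [0.25, 0.45] at ≥ 200 anchors.

Two fine points about the no-dip expectation. Being a ratio of means,
the statistic is not exactly unbiased under a *heterogeneous*
background: with the 50-kb regional field the anchor-centred window
shares a single regional draw while the flank mixes neighbouring
windows, which leaves a residual of about +0.3% at 200 anchors —
negligible against the planted effect of 0.3, but visible to a sharp
confidence-interval check. The package's no-dip control therefore runs
on a homogeneous background (`region_sdlog = 0`) without peaks; peaks
are also excluded because the generator never places them within 2.5 kb
of an anchor, so with peaks present the flank mean is inflated by a few
percent relative to the centre — a placement artifact of the simulated
world, not a property of the statistic.

## The synthetic genome pair

The generator draws one ancestral genome and assigns derived states to
the two strain lineages, which yields a coherent outgroup (the
ancestor itself) for gain/loss polarization — mirroring the role of an
earlier-diverging species in the original comparison. Its defaults are
the study conditions:

* SNP divergence 6.3 per kb, alleles assigned to either lineage with
  probability 1/2; the outgroup keeps the ancestral base.
* L1 insertions are 3'-anchored truncations: the inserted sequence is
  always a suffix of the consensus, with length bins < 0.4 / 0.4–1 /
  1–2 / 2–5.8 kb / full at fractions 0.60 / 0.26 / 0.09 / 0.03 / 0.02.
* An acetylation dip of factor 0.3 within 2 kb of any 3' L1 fragment
  present on that allele.
* Shotgun reads of 700 bp (Sanger-like), uniform over either strand,
  with a configurable substitution error rate.
* ChIP counts are negative-binomial around
  $\text{input} \times \lambda \times \text{cis} \times \text{trans}
  \times \text{dip}$; dispersion 0.02 and an input depth of 100
  reads/kb emulate the deep (tens of millions of reads) libraries of
  the study — at desk-scale depths the input noise, which is shared
  between replicate FEs, would dominate the classifier margins. The
  negative binomial is the standard overdispersion model for ChIP
  counts (Poisson as the dispersion→0 limit); the original data's
  dispersion is unknown, so both knobs sit in `sim_config()` and are
  recorded in every run summary.
* Reciprocal hybrids are two independent draws from identical allelic
  expectations: the original analysis averages the reciprocal crosses,
  implying no expected parent-of-origin asymmetry (an imprinting effect
  could be added by giving the two hybrids different cis multipliers,
  but is deliberately off).
* The regional 50-kb fold-enrichment field is lognormal with
  $\sigma_{\log} = \log(1.5)/z_{0.97}$, chosen so that about 3% of
  windows exceed FE 1.5 before library normalization — the study's
  stated calibration of its hyperacetylation cutoff. The realized
  selected fraction is somewhat below 3% because library normalization
  and dip/peak modulation shift the measured FE; the fraction is
  reported, not asserted.
* Shared anchor fragments are placed on a jittered lattice with a
  minimum spacing (default 24 kb) so each anchor has uncontaminated
  ±10-kb flanks; strain-specific insertions and peaks are placed
  uniformly in the remaining space (insertions keep a clearance of two
  read lengths plus the longest element so junction-spanning reads are
  unambiguous; planted elements never nest or overlap, keeping the
  truth table unambiguous for recovery scoring).
* Motif gains and losses are realized *through SNP records*: a gain
  writes the consensus into the hyper allele as substitutions recorded
  in the SNP table, a loss writes the consensus into the ancestor and
  disrupts two informative positions on the hypo lineage. Downstream
  motif analysis therefore sees them exactly the way real data would —
  via allelic sequence reconstruction from reference plus SNPs.

What the generator does *not* emulate: nested or fragmented repeats,
CpG islands and regional mutation-rate variation, recombination, read
quality scores, mapping bias, and parent-of-origin effects. Passing the
recovery tests therefore shows that the estimators are correct under
the stated generative model, not that real-data preprocessing
(mapping, SNP masking, peak calling) is reproduced — those steps are
consumed as inputs in real-data mode.

## Numerical choices and degenerate inputs

Pseudocount 0.5 in FE (finite FE at zero input); PWM discretization
$10^{-3}$ bits and log-odds sentinel −30; round-half-up for reported
percentages at the printed precision (R's banker's rounding would
print 12.5% as 12); merge tolerance 20 bp; zero-total allele counts
are undefined frequencies and become exclusions rather than NaNs; a
(0, 0) motif-association table reports NA rather than a statistic;
empty rank-sum groups are errors. Interval conventions are 0-based
half-open everywhere internally; 1-based inputs (SNP tables) are
converted exactly once on read, and strand "." is treated as "+" where
orientation matters.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
the whole suite completes in minutes on one CPU: genomes of 0.4–6 Mb,
hundreds of peaks, 60 planted insertions at 5x read coverage for the
indel-recovery checks, 200 anchors for dip recovery, and 100–200
replicates for power and calibration checks. These sizes are the
package's own validation choices; all of them are configuration, not
constants.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(chrom_length = 2e6, n_peaks = 150, seed = 11,
                  n_shared_l1_short = 40, n_shared_l1_other = 8,
                  n_insertions = list(A = c(L1 = 12, SINE = 6, LTR = 3),
                                      B = c(L1 = 2, SINE = 4, LTR = 0)),
                  n_genes = 60)
res <- run_pipeline(cfg, out_dir = "acetylodiff_run")
str(res$summary)
```

The summary reports peak counts per class, allele-bias counts, indel
calls per element class, the motif association table with its
chi-square, gain/loss counts, expression-association p-values, the dip
ratio, and every derived percentage — each recomputable from the stage
output files written next to it.

## Known limitations

Real-data mode consumes peak BEDs, count tables, SNP tables and repeat
annotations; it does not map reads, call peaks (MACS2's job), split
reads by allele (SNPsplit's job), or align whole genomes for outgroup
orthology. The indel caller targets clean insertional polymorphism:
inversions, translocations and heavily nested repeats are out of
scope. The motif association follows a single bundled or user-supplied
PWM set and applies no multiple-testing correction by default.
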