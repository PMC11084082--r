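# acetylodiff

Comparative analysis of histone H3K9 acetylation between two diverged
inbred mouse strains and their reciprocal F1 hybrids, with detection of
polymorphic retroelement insertions and their local effect on the
acetylation landscape.

Two subspecies-derived strains (a reference-like strain "A" and an
alternative strain "B", diverged by roughly one SNP per 160 bp) differ
in where H3K9ac — a mark of active promoters and enhancers — is
deposited. In an F1 hybrid both genomes share one nucleus, so a
sequence-linked (*cis*) regulatory difference shows up as allelic
imbalance of ChIP reads, while a diffusible (*trans*) difference
affects both alleles equally. A further source of divergence is
insertional polymorphism of retrotransposons: 5'-truncated LINE-1
copies that retain only the element's 3' end are associated with
hypoacetylation of their immediate neighbourhood.

`acetylodiff` implements the full workflow for users with per-region
ChIP/input count tables, SNP tables, peak/CRE/repeat annotations and
long shotgun reads — and a synthetic genome-pair generator with planted
ground truth for validating every stage.

## Core quantities

* **Fold enrichment** per peak and sample:
  `FE = ((ChIP + c)/N_ChIP) / ((Input + c)/N_Input)`, pseudocount
  `c = 0.5`. A peak is A-specific iff mean replicate `FE_A >= 2.5` and
  `FE_B <= 1.5` (inclusive); B-specific symmetrically.
* **Allele bias** per feature: A-allele frequency `n_A/(n_A + n_B)`,
  averaged over the two reciprocal hybrids; ChIP peaks are allele-biased
  at `>= 0.68` / `<= 0.32` (each hybrid must also pass), genes at
  `>= 0.8` / `<= 0.2`.
* **Split-read insertion calls**: k-mer seeded local segments, chain
  selection with a near-zero per-base gap cost, base-wise junction
  refinement; a reference interval of `>= 300` bp sandwiched between
  read-adjacent, uniquely mapping segments on the same chromosome and
  strand is a strain-A insertion; read-side gaps `< 300` bp are strain-B
  insertions (longer ones are undecidable at ~700-bp reads).
* **PWM scanning** with an exact, DP-computed score null
  (`P(score >= s)` under an i.i.d. background, discretized at 1e-3
  bits), per-scan p-value cutoff 1e-4; motif gains/losses polarized
  against an outgroup.
* **Permutation association**: query intervals re-placed uniformly
  within their chromosomes; `p = (1 + #{null >= obs})/(n_perm + 1)`.
* **Dip statistic**: mean FE within 2 kb of short (100-400 bp) 3' L1
  fragments divided by the mean over the remaining 10-kb flanks; values
  below 1 quantify insertion-associated hypoacetylation.

## Worked example

Simulate a 2-Mb genome pair with planted effects and run the full
pipeline:

```r
library(acetylodiff)

cfg <- sim_config(chrom_length = 2e6, n_peaks = 150, seed = 11,
                  n_shared_l1_short = 40, n_shared_l1_other = 8,
                  n_insertions = list(A = c(L1 = 12, SINE = 6, LTR = 3),
                                      B = c(L1 = 2, SINE = 4, LTR = 0)),
                  n_genes = 60)
res <- run_pipeline(cfg, out_dir = "acetylodiff_run")
str(res$summary[c("n_peaks", "n_a_specific", "n_b_specific",
                  "cre_overlap_pct", "n_consistent_cis",
                  "n_indel_calls", "motif_hyper_only", "motif_chisq",
                  "motif_gain_in_hyper", "motif_loss_in_hypo",
                  "dip_ratio")])
#> List of 11
#>  $ n_peaks            : int 150
#>  $ n_a_specific       : int 20
#>  $ n_b_specific       : int 26
#>  $ cre_overlap_pct    : num 91
#>  $ n_consistent_cis   : int 30
#>  $ n_indel_calls      : int 27
#>  $ motif_hyper_only   : int 14
#>  $ motif_chisq        : num 14
#>  $ motif_gain_in_hyper: int 9
#>  $ motif_loss_in_hypo : int 5
#>  $ dip_ratio          : num 0.299
```

Reading the output: of 150 simulated peaks, 20 + 26 are called
strain-specific (the planted cis, trans and insertion-adjacent
effects); 91% of peaks overlap a synthetic candidate regulatory
element; 30 strain-specific peaks show reciprocal-hybrid allele bias
consistent with their strain difference, i.e. a *cis* explanation. The
indel stage recovers the planted insertions from simulated 5x shotgun
reads of strain B. All 14 differential motif carriers have the motif on
the hyperacetylated allele (goodness-of-fit chi-square 14), and the
outgroup polarizes them into the 9 planted gains on hyperacetylated
alleles and 5 planted losses on hypoacetylated ones. The dip ratio of
0.30 around short 3' L1 fragments recovers the planted dip factor 0.3.
Full stage outputs (classified peaks, allele-bias table, indel calls,
`summary.json`) are written to `acetylodiff_run/`.

A thin command-line wrapper is installed with the package
(`inst/exec/acetylodiff`): `acetylodiff simulate|run --config cfg.yaml
--out dir/`.

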