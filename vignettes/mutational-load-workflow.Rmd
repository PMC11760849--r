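---
title: "Quantifying mutational load and inbreeding in paired populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutational load and inbreeding in paired populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohload)
library(data.table)
```

## The scientific question

Farmed and recently derived breeds typically pass through a founder
bottleneck and are then propagated by selective mating. Both processes raise
inbreeding and can let deleterious mutations drift upward in frequency —
the *mutational load*. A standard genomic work-up of this question, for a
derived breed against its source population, runs:

1. joint SNP calling and quality control;
2. functional annotation of coding SNPs, splitting the load into
   small-effect (missense), moderate-effect (missense with a radical
   amino-acid change) and large-effect (loss-of-function) classes;
3. polarization of each SNP into ancestral and derived alleles using
   outgroup genomes, so that burdens count *derived* (mutant) alleles;
4. detection of runs of homozygosity (ROH) and the inbreeding coefficient
   $F_{ROH}$;
5. per-individual load statistics — derived-allele counts, homozygous
   dosage, and *occurrence* ratios (deleterious / synonymous counts in the
   same region), compared between populations and between the inside and
   outside of ROH;
6. supporting diversity statistics: windowed $\pi$, individual
   heterozygosity versus $F_{ROH}$, and LD decay.

This package implements each stage as a tested, reusable function, and
couples it with a synthetic-data generator that produces the whole input
bundle — reference, gene models, genotypes, outgroup alleles — with
machine-readable truth, so that every stage can be validated end to end
against known answers.

## Load classes

Coding SNPs are classified by codon comparison against gene models
(reverse-complemented for minus-strand transcripts), with SnpEff-style
splice windows: acceptor = last 2 intronic bases before an exon, donor =
first 2 intronic bases after, splice region = intronic bases 3–8 or exonic
bases 1–3 from the junction, and 5 kb up/downstream flanks. When a variant
hits several transcripts the most severe call wins, in the order
splice acceptor/donor and stop gained, then start/stop changes, missense,
synonymous, splice region, UTR, intron, up/downstream, ncRNA, intergenic.

Three load classes are tallied:

* **LoF** — splice acceptor, splice donor and stop-gained SNVs;
* **dnsSNP** — missense changes with Grantham distance $\ge 150$
  (threshold inclusive), reported both on their own and inside the missense
  tally, of which they are a subset;
* **missense** — all amino-acid-changing substitutions.

The Grantham distance is recomputed from the published amino-acid
properties (composition $c$, polarity $p$, molecular volume $v$):
$D_{ij} = \rho\left[\alpha(c_i-c_j)^2 + \beta(p_i-p_j)^2 +
\gamma(v_i-v_j)^2\right]^{1/2}$ with $\alpha = 1.833$, $\beta = 0.1018$,
$\gamma = 0.000399$. We fix $\rho$ by the table's defining property — a
mean distance of exactly 100 over the 190 unordered pairs
($\rho = 50.79$) — rather than using the commonly quoted rounded value
50.723. This choice reproduces the printed extremes (Leu–Ile = 5,
Trp–Cys = 215) exactly; the historical printed table itself deviates by
$\pm 1$ from its own formula for a handful of pairs (for example Ser–Arg is
printed as 110 where the formula gives 109.4), so the formula, not the
print, is treated as authoritative.

```{r grantham}
grantham_distance(c("L", "W"), c("I", "C"))
mean(grantham_matrix()[upper.tri(grantham_matrix())])
```

## Variant QC

The cascade is fixed: biallelic-SNP selection, then hard filters
(`QUAL < 30`, `QD < 2`, `FS > 60`, `MQ < 40`, `MQRankSum < -12.5`,
`ReadPosRankSum < -8`, all strict, each applied only when the metric is
present — the GATK convention, since the inequalities are undefined on
missing annotations), then a depth-percentile filter, then a missingness
filter. The depth cut removes the extreme 0.25% per tail using
nearest-rank order statistics (`k = round(n * tail)`; ties at the cut value
are all removed; degenerate distributions and sets smaller than
`1/tail_fraction` are left untouched with a warning). Site depth is the sum
of per-sample DP. Missingness is strict: a site is removed when more than
10% of genotypes are missing, and half-missing diploid calls count as
missing. The depth percentile is computed once on the post-hard-filter set,
so the cascade is order-sensitive by design but per-record pure: permuting
the input never changes the surviving set.

## Ancestral alleles

The ancestral state is the majority allele, requiring at least three
occurrences, in a five-sequence panel: four outgroup species plus the focal
reference base. Including the focal base follows the "five-species
alignment" convention and keeps the $\ge 3$ rule meaningful; a
configuration with outgroups only is available via `include_focal_ref =
FALSE`. Ties (2–2 splits, or 3–3 when six sequences are supplied) and
majorities that are neither REF nor ALT leave the site unresolved;
unresolved sites are excluded from all derived-allele statistics. A
stricter support threshold trades resolution for accuracy; the package
exposes it (`min_support`) and the tests verify that raising it from 3 to 4
lowers the mispolarization rate under outgroup divergence.

## Runs of homozygosity

Detection is the PLINK sliding-window algorithm: windows of 20 SNPs are
homozygous when they contain at most 1 heterozygous and 5 missing calls; a
SNP is eligible when at least 5% of windows containing it are homozygous;
maximal runs of eligible SNPs — split at inter-SNP gaps above 1 Mb and
trimmed to homozygous terminal SNPs — become segments if they hold enough
SNPs, span at least 10 kb and stay below 50 kb per SNP. The window size,
length floor and density cap follow the standard invocation
(`--homozyg-window-snp 20 --homozyg-kb 10 --homozyg-density 50`); the other
knobs default to PLINK's own defaults.

One PLINK default cannot be kept: 100 SNPs per segment is unsatisfiable
together with a 10 kb floor below 10 SNPs/kb (at the simulated density of
1.5 SNPs/kb, 100 SNPs span roughly 67 kb). The pipeline profile therefore
sets `min_snp = 25`; the knob is prominently exposed on `roh_params()`.

$F_{ROH}$ is the summed segment length divided by the total autosome
length. The headline value counts segments of at least 100 kb — the
quantity usually reported — which also screens out the short chance
segments that any window detector emits near its length floor: stretches of
20-odd SNPs that happen to contain at most one heterozygote are common at
realistic heterozygosity, and they produce spurious 10–30 kb segments
exactly as they do in real PLINK output. Length-class decompositions
(`f_roh_by_class()`, classes below/above 100 kb, 1 Mb and 5 Mb) always sum
to the unfiltered total.

## Load statistics

Burdens count derived alleles (a heterozygote contributes 1, a homozygote
2). For each sample, class and region (genome-wide, inside ROH, outside
ROH) the package reports allele counts, carrier-site counts, homozygote and
heterozygote counts, and the homozygosity ratio hom/(hom + het). "Dosage of
homozygous mutations" is deliberately exported in both candidate readings —
the ratio (headline) and the raw homozygote count — since the phrase is
used loosely in the field. Occurrence ratios divide a deleterious count by
the synonymous count from the same region and sample; with per-allele
counts as the headline and per-site counts also emitted. Inside- and
outside-ROH counts add up exactly to the genome-wide counts, and the dnsSNP
tally is a subset of the missense tally at every level — both are invariants
under test.

Population contrasts use the two-sided Wilcoxon rank-sum test across
individuals, and inside-versus-outside-ROH contrasts the Wilcoxon
signed-rank test paired within individuals; with around 13–21 animals per
cohort a non-parametric test is the safe default, and stars follow the
conventional 0.05/0.01/0.001/0.0001 tiers. No multiple-testing correction
is applied across the per-class panels by default (matching per-panel
reporting practice); `population_contrasts(..., p_adjust = "BH")` switches
on Benjamini–Hochberg adjustment and recomputes the tiers from the
adjusted p-values.

The candidate-gene screen reports every missense/dnsSNP/LoF variant within
a configurable flank (default 10 kb, "within and around" being inherently
fuzzy) of a listed gene, with per-population derived-allele frequencies, a
flag for frequencies above 0.5, and a genotype-exclusivity flag (a genotype
value carried by at least one sample of exactly one population).

## Diversity

Windowed $\pi$ follows the VCFtools convention: per site
$2 c_{ref} c_{alt} / (n(n-1))$ over called allele counts, summed per
500 kb non-overlapping window and divided by the full window length (not
callable length; the last window of a chromosome is truncated and divided
by its actual span). The length-weighted window average equals global
per-site $\pi$ exactly. LD decay uses composite genotype $r^2$ — the
squared Pearson correlation of 0/1/2 dosage vectors — appropriate for
unphased genotypes, averaged in distance bins.

## The synthetic study system

`sim_spec()` fixes the study conditions; `generate_reference()` and
`simulate_populations()` realise them:

* **Genome and genes.** Two 2 Mb chromosomes; 40 protein-coding genes with
  three exons, UTRs and both strands represented; every CDS is a clean ORF
  by construction.
* **Cohorts.** 21 wild-type and 13 white-type samples (the unrelated-animal
  counts typical of a two-breed farm study). Haplotypes are mosaics over
  per-population founder pools (40 wild, 12 white founders per chromosome,
  100 kb mosaic scale); the smaller white pool emulates the breed
  bottleneck and yields measurably slower LD decay. An individual's two
  haplotypes draw from disjoint pool halves, so background autozygosity is
  zero and every homozygous tract in the truth table was planted.
* **Load classes.** 400 synonymous, 400 missense, 80 dnsSNP and 100 LoF
  sites are planted on enumerated candidate positions of known consequence,
  with mean derived allele frequencies 0.25 / 0.15 / 0.08 / 0.04 (Beta
  draws, concentration 6) — the canonical ordering where more damaging
  classes segregate at lower frequency. Non-coding filler SNPs (1.5 per kb,
  mean DAF 0.35) complete the panel. In about 10% of sites the reference
  carries the derived allele, exercising polarity flips.
* **Autozygosity.** Planted tracts realise a per-sample target
  $F_{ROH}$ (mean 0.18 wild, 0.19 white, SD 0.05) from 150–200 kb pieces,
  topped up by one shorter remainder tract; within a sample tracts stay at
  least 50 kb apart (nearby tracts are effectively one IBD segment and
  would be merged by any window detector, making the truth ambiguous), and
  remainder lengths avoid the neighbourhood of the 100 kb reporting
  threshold so that truth and detection never disagree about class
  membership. Inside a tract both haplotypes are replaced by one fresh
  haplotype; a configurable het-leak (default 0) lets tests exercise the
  caller's het tolerance.
* **Planted contrasts** (the generator's effect sizes): white-type derived
  AF at LoF sites multiplied by 1.6 (occurrence excess); white-type
  heterozygous missense genotypes converted to homozygous with probability
  0.25 (homozygous-dosage excess); derived-haplotype probability at
  missense sites doubled inside planted tracts (within-ROH enrichment,
  expected inside/outside ratio contrast of about 2). Setting these to
  (1, 0, 1) yields a null generator.
* **QC faults.** Each hard-filter metric fails in 2% of sites (drawn from
  disjoint pass/fail value ranges, so expected survivor counts are exact
  binomials); 2% of sites get a 25% per-genotype missing rate; 2% indels
  and 1% multiallelic records are spiced in for the selection step;
  per-sample depth is Poisson with mean 13.
* **Outgroups.** Four outgroup columns show the true ancestral allele with
  probability 0.95 each (5% divergence), and are missing with probability
  0.05.

What the generator does *not* emulate: realistic site-frequency spectra
(class means are Beta-distributed around fixed targets), recombination and
coalescent genealogy, sequencing errors at the read level, indels, or
selection. Passing tests therefore demonstrate that the pipeline's
*accounting and inference machinery* is correct under known truth — not
that any particular biological effect size in real data would be
recovered.

## Problem sizes and runtime choices

The default system (4 Mb genome, ~7,000 variant records, 34 samples) runs
the full pipeline in a few seconds, which is what makes replicated
validation affordable: the test suite re-runs the whole pipeline 100 times
to confirm that all four planted contrasts are recovered with the correct
sign in at least 95 replicates, runs 100 null-generator cohorts to confirm
the inside/outside contrast stays flat, and calibrates the rank-sum test's
type-I error on 1,000 null draws at the study's 21-versus-13 sample sizes.
The LD scan is restricted to 50 kb pair distances in the bundled
configuration, since the informative contrast sits at 10–50 kb.

## Numerical and degenerate-input choices

* Depth filter: `round()` (banker's rounding) fixes the nearest-rank count;
  all-equal depth distributions are left intact with a warning.
* `detect_roh()` returns segment ends at terminal SNP positions (PLINK
  reporting), lengths as `end - start + 1`; chromosomes with fewer SNPs
  than one window yield no segments; unsorted positions are an error.
* Zero synonymous counts make the occurrence ratio NA with a warning, never
  an error; identical paired vectors short-circuit the signed-rank test to
  p = 1.
* All stage outputs are pure functions of (inputs, parameters, seed); the
  same config and seed give byte-identical reports.

## Known limitations

* The consequence engine handles SNVs only (no indels or MNVs) and one
  transcript model per gene; canonical-transcript selection beyond the
  severity precedence is out of scope.
* The ROH caller is the window heuristic, not an HMM; near its length floor
  it both misses marginal tracts and emits short chance segments, which is
  why headline $F_{ROH}$ uses the 100 kb floor.
* Polarization is parsimony by majority, not probabilistic ancestral
  reconstruction.
* The generator's two populations share one frequency draw per site with
  independent founder realisations; fine-scale population structure,
  admixture and relatedness are not modelled (the study design assumes
  unrelated individuals).
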