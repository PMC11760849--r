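# Simulation specification: the study conditions under which the pipeline is
# exercised. Defaults emulate the structure of a two-population farmed-animal
# resequencing study at desk scale: two populations with shared ancestry
# (one recently bottlenecked), planted autozygous tracts of known extent,
# coding variants in five consequence classes with class-specific
# derived-allele-frequency means, and a four-species outgroup panel.

#' Simulation specification
#'
#' @param seed integer seed; every downstream draw is reproducible from it.
#' @param n_chromosomes number of autosomes to simulate.
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of protein-coding genes across the genome.
#' @param exons_per_gene exons per gene (>= 2 so splice sites exist).
#' @param n_samples named integer vector `c(wild = ..., white = ...)`:
#'   samples per population. Defaults mirror the 21 + 13 unrelated animals of
#'   a two-breed farm study.
#' @param target_f_roh list with per-population `c(mean, sd)` of the fraction
#'   of the genome planted as autozygous tracts per sample.
#' @param roh_length_range bp range `c(min, max)` of individual planted
#'   tracts. The maximum must not exceed `chrom_length / 10`. A shorter
#'   remainder tract tops each sample up to its target coverage; remainders
#'   falling near the 100 kb headline reporting threshold are split in two so
#'   a planted tract is never ambiguous about which reporting class it
#'   belongs to.
#' @param class_daf_means named numeric: mean derived allele frequency per
#'   load class, strictly ordered `synonymous > missense > dnsSNP > LoF`,
#'   plus `noncoding` for filler sites.
#' @param class_n_sites named integer: number of planted segregating sites
#'   per coding load class.
#' @param snp_density non-coding segregating sites per kb.
#' @param daf_concentration concentration of the Beta distribution the
#'   per-site derived allele frequency is drawn from (shape1 = mean * k,
#'   shape2 = (1 - mean) * k).
#' @param n_founders named integer `c(wild, white)`: founder haplotypes per
#'   population per chromosome. The smaller white-type pool emulates the
#'   breed's recent bottleneck and produces slower LD decay.
#' @param founder_segment_bp mean length of founder-haplotype mosaic segments
#'   (controls the distance scale of linkage disequilibrium).
#' @param ancestral_is_alt_frac fraction of sites where the reference genome
#'   carries the derived allele (ancestral = ALT), exercising polarity flips.
#' @param outgroup_divergence per-site probability that an outgroup species
#'   shows a non-ancestral allele.
#' @param outgroup_missing per-site probability an outgroup allele is missing.
#' @param het_leak probability a genotype inside a planted tract is left
#'   heterozygous (exercises the ROH caller's het tolerance).
#' @param effects list of planted population contrasts:
#'   `lof_daf_mult` multiplies the white-type derived AF at LoF sites
#'   (occurrence excess); `hom_missense_boost` is the probability a white-type
#'   heterozygous missense genotype is converted to homozygous-derived
#'   (homozygous-dosage excess); `roh_missense_boost` multiplies the derived
#'   haplotype probability at missense sites inside planted tracts
#'   (within-ROH enrichment). Set all to `1, 0, 1` for a null generator.
#' @param qc list of QC-fault fractions: `fail_frac` per hard-filter metric,
#'   `high_missing_frac` of sites given a high per-genotype missing rate,
#'   `high_missing_rate`, `base_missing_rate`, `indel_frac`,
#'   `multiallelic_frac`, `mean_depth` (per-sample sequencing depth).
#' @param n_candidate_genes number of genes exported as the candidate-gene
#'   list for the coat-colour screen.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     n_chromosomes = 2L,
                     chrom_length = 2e6L,
                     n_genes = 40L,
                     exons_per_gene = 3L,
                     n_samples = c(wild = 21L, white = 13L),
                     target_f_roh = list(wild = c(mean = 0.18, sd = 0.05),
                                         white = c(mean = 0.19, sd = 0.05)),
                     roh_length_range = c(1.5e5, 2e5),
                     class_daf_means = c(synonymous = 0.25, missense = 0.15,
                                         dnsSNP = 0.08, LoF = 0.04,
                                         noncoding = 0.35),
                     class_n_sites = c(synonymous = 400L, missense = 400L,
                                       dnsSNP = 80L, LoF = 100L),
                     snp_density = 1.5,
                     daf_concentration = 6,
                     n_founders = c(wild = 40L, white = 12L),
                     founder_segment_bp = 1e5,
                     ancestral_is_alt_frac = 0.10,
                     outgroup_divergence = 0.05,
                     outgroup_missing = 0.05,
                     het_leak = 0,
                     effects = list(lof_daf_mult = 1.6,
                                    hom_missense_boost = 0.25,
                                    roh_missense_boost = 2),
                     qc = list(fail_frac = c(QUAL = 0.02, QD = 0.02, FS = 0.02,
                                             MQ = 0.02, MQRankSum = 0.02,
                                             ReadPosRankSum = 0.02),
                               high_missing_frac = 0.02,
                               high_missing_rate = 0.25,
                               base_missing_rate = 0.005,
                               indel_frac = 0.02,
                               multiallelic_frac = 0.01,
                               mean_depth = 13),
                     n_candidate_genes = 5L) {
  spec <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
               chrom_length = as.integer(chrom_length),
               n_genes = as.integer(n_genes),
               exons_per_gene = as.integer(exons_per_gene),
               n_samples = n_samples, target_f_roh = target_f_roh,
               roh_length_range = roh_length_range,
               class_daf_means = class_daf_means,
               class_n_sites = class_n_sites,
               snp_density = snp_density,
               daf_concentration = daf_concentration,
               n_founders = n_founders,
               founder_segment_bp = founder_segment_bp,
               ancestral_is_alt_frac = ancestral_is_alt_frac,
               outgroup_divergence = outgroup_divergence,
               outgroup_missing = outgroup_missing,
               het_leak = het_leak, effects = effects, qc = qc,
               n_candidate_genes = as.integer(n_candidate_genes))
  class(spec) <- "sim_spec"
  validate_sim_spec(spec)
  spec
}

#' @noRd
validate_sim_spec <- function(spec) {
  fr <- c(unlist(lapply(spec$target_f_roh, `[[`, "mean")),
          spec$ancestral_is_alt_frac, spec$outgroup_divergence,
          spec$outgroup_missing, spec$het_leak,
          spec$qc$fail_frac, spec$qc$high_missing_frac,
          spec$qc$base_missing_rate)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (spec$chrom_length < 10 * max(spec$roh_length_range))
    stop("chrom_length must be at least 10 x the longest plantable tract")
  m <- spec$class_daf_means
  if (!(m["synonymous"] > m["missense"] &&
        m["missense"] > m["dnsSNP"] && m["dnsSNP"] > m["LoF"]))
    stop("class_daf_means must be strictly ordered ",
         "synonymous > missense > dnsSNP > LoF")
  if (spec$exons_per_gene < 2L && spec$n_genes > 0L)
    stop("genes need at least 2 exons so splice sites exist")
  if (is.null(names(spec$n_samples)) ||
      !all(c("wild", "white") %in% names(spec$n_samples)))
    stop("n_samples must be named c(wild = ..., white = ...)")
  invisible(spec)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("sim_spec:", x$n_chromosomes, "x", x$chrom_length, "bp,",
      x$n_genes, "genes,", paste(names(x$n_samples), x$n_samples,
                                 sep = "=", collapse = " + "),
      "samples, seed", x$seed, "\n")
  invisible(x)
}
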