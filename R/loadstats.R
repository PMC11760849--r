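# Per-individual mutational-load statistics over polarized, annotated
# variants: derived-allele counts, segregating-site counts and homozygous
# dosage per load class, stratified genome-wide and inside/outside ROH;
# occurrence ratios normalised by synonymous counts in the same region;
# population contrasts by non-parametric rank tests; and the candidate-gene
# screen. The dnsSNP tally is a subset of the missense tally at every level.

LOAD_CLASSES <- c("synonymous", "missense", "dnsSNP", "LoF")

#' Which load classes an annotated class contributes to
#'
#' dnsSNPs are missense changes with a high Grantham distance, so a dnsSNP
#' site is tallied under both `missense` and `dnsSNP`.
#' @noRd
.class_members <- function(load_class) {
  list(synonymous = load_class == "synonymous",
       missense = load_class %in% c("missense", "dnsSNP"),
       dnsSNP = load_class == "dnsSNP",
       LoF = load_class == "LoF")
}

#' Per-individual load summary
#'
#' For every sample, load class and region (`genome`, `inside`, `outside`
#' ROH): the derived-allele count (het contributes 1, hom-derived 2), the
#' segregating-site count (genotypes carrying at least one derived allele),
#' the homozygous-derived genotype count, the heterozygous count, and the
#' homozygosity ratio hom / (hom + het) (NA when no carrier genotypes).
#'
#' @param vs a [variant_set()] of QC-passed SNPs.
#' @param anc output of [polarize_variants()] aligned to `vs` rows;
#'   unresolved sites are excluded.
#' @param load_class character vector aligned to `vs` rows (from
#'   [classify_variants()]).
#' @param roh_membership logical matrix from [variant_roh_membership()], or
#'   NULL to report genome-wide only.
#' @return data.table with columns `sample_id`, `population`, `class_`,
#'   `region`, `allele_count`, `site_count`, `hom_count`, `het_count`,
#'   `hom_ratio`.
#' @export
per_individual_load <- function(vs, anc, load_class, roh_membership = NULL) {
  stopifnot(length(load_class) == nrow(vs$variants))
  d <- derived_dosage(vs, anc)
  members <- .class_members(load_class)
  regions <- if (is.null(roh_membership)) "genome" else
    c("genome", "inside", "outside")
  out <- list()
  for (s in vs$samples) {
    ds <- d[, s]
    for (reg in regions) {
      keep <- switch(reg,
        genome = rep(TRUE, length(ds)),
        inside = roh_membership[, s],
        outside = !roh_membership[, s])
      for (cl in LOAD_CLASSES) {
        sel <- members[[cl]] & keep & !is.na(ds)
        x <- ds[sel]
        hom <- sum(x == 2L); het <- sum(x == 1L)
        out[[length(out) + 1L]] <- data.table(
          sample_id = s, population = unname(vs$populations[s]),
          class_ = cl, region = reg,
          allele_count = sum(x), site_count = sum(x >= 1L),
          hom_count = hom, het_count = het,
          hom_ratio = if (hom + het > 0) hom / (hom + het) else NA_real_)
      }
    }
  }
  rbindlist(out)
}

#' Occurrence ratio of a load class
#'
#' The count of deleterious variants divided by the count of synonymous
#' variants in the same region and sample, a normalisation that controls
#' for background variation.
#'
#' @param class_count,synonymous_count non-negative counts.
#' @return `class_count / synonymous_count`; NA with a warning when the
#'   synonymous count is zero.
#' @export
occurrence_ratio <- function(class_count, synonymous_count) {
  out <- ifelse(synonymous_count > 0, class_count / synonymous_count,
                NA_real_)
  if (any(synonymous_count == 0))
    warning("synonymous count of zero: occurrence ratio undefined")
  out
}

#' Occurrence ratios from a load summary
#'
#' @param load output of [per_individual_load()].
#' @param count which count to normalise: `"allele_count"` (headline) or
#'   `"site_count"`.
#' @return the non-synonymous rows of `load` with an added `occurrence`
#'   column.
#' @export
occurrence_table <- function(load, count = c("allele_count", "site_count")) {
  count <- match.arg(count)
  syn <- load[class_ == "synonymous",
              .(sample_id, region, syn_count = get(count))]
  del <- load[class_ != "synonymous"]
  del <- merge(del, syn, by = c("sample_id", "region"), sort = FALSE)
  del[, occurrence := suppressWarnings(
    occurrence_ratio(get(count), syn_count))]
  del[, syn_count := NULL]
  del[]
}

#' Compare a statistic between two populations (or paired regions)
#'
#' Unpaired contrasts use the two-sided Wilcoxon rank-sum test across
#' individuals; paired contrasts (e.g. inside vs outside ROH within
#' individuals) use the Wilcoxon signed-rank test. Significance tiers use
#' the conventional star thresholds 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param values numeric vector of per-individual statistics.
#' @param groups factor/character of length `values` with two levels (group
#'   comparison), or for paired mode the two aligned vectors `values` and
#'   `values2`.
#' @param values2 second member of each pair (switches to signed-rank mode).
#' @param statistic label for the output row.
#' @return one-row data.table: statistic, per-group medians (or median
#'   paired difference), test name, test statistic, p-value, tier.
#' @export
compare_populations <- function(values, groups = NULL, values2 = NULL,
                                statistic = "statistic") {
  if (is.null(values2)) {
    g <- as.character(groups)
    lev <- unique(g)
    if (length(lev) != 2L) stop("need exactly two groups")
    x <- values[g == lev[1]]; y <- values[g == lev[2]]
    if (length(x) < 2L || length(y) < 2L)
      stop("each population needs at least two values")
    wt <- suppressWarnings(wilcox.test(x, y, exact = NULL))
    res <- data.table(statistic = statistic, test = "wilcoxon_rank_sum",
                      group1 = lev[1], group2 = lev[2],
                      median1 = stats::median(x, na.rm = TRUE),
                      median2 = stats::median(y, na.rm = TRUE),
                      W = unname(wt$statistic), p_value = wt$p.value)
  } else {
    ok <- !is.na(values) & !is.na(values2)
    x <- values[ok]; y <- values2[ok]
    if (length(x) < 2L) stop("need at least two pairs")
    if (all(x == y)) {
      res <- data.table(statistic = statistic,
                        test = "wilcoxon_signed_rank",
                        group1 = "first", group2 = "second",
                        median1 = stats::median(x), median2 = stats::median(y),
                        W = 0, p_value = 1)
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = NULL))
      res <- data.table(statistic = statistic, test = "wilcoxon_signed_rank",
                        group1 = "first", group2 = "second",
                        median1 = stats::median(x),
                        median2 = stats::median(y),
                        W = unname(wt$statistic), p_value = wt$p.value)
    }
  }
  res[, tier := significance_tier(p_value)]
  res[]
}

#' Candidate-gene screen for deleterious variants
#'
#' Reports every missense/dnsSNP/LoF variant lying within a candidate gene
#' span extended by `flank_bp`, with per-population derived (or ALT when
#' unresolved) allele frequencies, a high-frequency flag (AF > 0.5), and a
#' genotype-exclusivity flag: TRUE when some genotype value is carried by at
#' least one sample of exactly one population.
#'
#' @param vs a [variant_set()].
#' @param ann annotation from [classify_variants()] aligned to `vs` rows.
#' @param anc polarization from [polarize_variants()] aligned to `vs` rows
#'   (optional; ALT frequencies are reported when NULL).
#' @param models a [gene_models()] object.
#' @param gene_list data.frame with `gene_name`, `gene_id`.
#' @param flank_bp flank around each gene span (default 10000).
#' @return data.table: one row per (variant, candidate gene).
#' @export
screen_candidate_genes <- function(vs, ann, anc = NULL, models, gene_list,
                                   flank_bp = 10000L) {
  gl <- as.data.table(gene_list)
  empty <- data.table(gene_name = character(), gene_id = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      load_class = character(),
                      af_wild = numeric(), af_white = numeric(),
                      af_gt_half = logical(), exclusive_genotype = logical(),
                      exclusive_population = character())
  if (!nrow(gl)) return(empty)
  tx <- models$transcripts
  dose <- if (is.null(anc)) vs$geno else derived_dosage(vs, anc)
  pops <- unique(vs$populations)
  out <- list()
  for (i in seq_len(nrow(gl))) {
    g <- gl[i]
    span <- tx[gene_id == g$gene_id]
    if (!nrow(span)) {
      warning("unknown gene in candidate list: ", g$gene_name, " (",
              g$gene_id, ")")
      next
    }
    rows <- which(vs$variants$chrom == span$chrom[1] &
                    vs$variants$pos >= min(span$start) - flank_bp &
                    vs$variants$pos <= max(span$end) + flank_bp &
                    ann$load_class %in% c("missense", "dnsSNP", "LoF"))
    for (r in rows) {
      af <- vapply(pops, function(pp) {
        cols <- which(vs$populations == pp)
        x <- dose[r, cols]
        if (all(is.na(x))) return(NA_real_)
        sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
      }, numeric(1))
      gvals <- vs$geno[r, ]
      excl_pop <- NA_character_
      for (gv in unique(gvals[!is.na(gvals)])) {
        has <- vapply(pops, function(pp)
          any(gvals[vs$populations == pp] == gv, na.rm = TRUE), logical(1))
        if (sum(has) == 1L) { excl_pop <- pops[has]; break }
      }
      out[[length(out) + 1L]] <- data.table(
        gene_name = g$gene_name, gene_id = g$gene_id,
        chrom = vs$variants$chrom[r], pos = vs$variants$pos[r],
        ref = vs$variants$ref[r], alt = vs$variants$alt[r],
        load_class = ann$load_class[r],
        af_wild = unname(af["wild"]), af_white = unname(af["white"]),
        af_gt_half = any(af > 0.5, na.rm = TRUE),
        exclusive_genotype = !is.na(excl_pop),
        exclusive_population = excl_pop)
    }
  }
  if (!length(out)) return(empty)
  res <- rbindlist(out)
  setorder(res, chrom, pos)
  unique(res)
}
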