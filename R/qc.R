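# Variant quality control: biallelic-SNP selection followed by a three-step
# filter cascade (hard filters on QUAL/INFO metrics, a depth-percentile
# filter, and a per-site missingness filter). The cascade order is fixed and
# each step is pure per record, except the depth percentile, which is
# computed once on the post-hard-filter set.

#' Keep only biallelic single-nucleotide substitutions
#'
#' Indels, multiallelic and symbolic records are dropped.
#'
#' @param vs a [variant_set()].
#' @return filtered [variant_set()].
#' @export
select_biallelic_snps <- function(vs) {
  v <- vs$variants
  keep <- v$ref %in% DNA_BASES & v$alt %in% DNA_BASES & v$ref != v$alt
  subset_variants(vs, which(keep))
}

#' GATK-style hard filter on a variant table
#'
#' A record fails when any of the clauses `QUAL < 30.0`, `QD < 2.0`,
#' `FS > 60.0`, `MQ < 40.0`, `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`
#' holds for a metric that is present; absent metrics never trigger their
#' clause (the inequality is undefined on a missing annotation).
#'
#' @param variants data.frame with `qual` and the INFO metric columns.
#' @return list with `pass` (logical vector) and `reasons` (list of character
#'   vectors naming every violated clause per record).
#' @export
hard_filter <- function(variants) {
  v <- as.data.table(variants)
  clause <- function(x, test) !is.na(x) & test(x)
  fails <- cbind(
    QUAL = clause(v$qual, function(x) x < 30.0),
    QD = clause(v$QD, function(x) x < 2.0),
    FS = clause(v$FS, function(x) x > 60.0),
    MQ = clause(v$MQ, function(x) x < 40.0),
    MQRankSum = clause(v$MQRankSum, function(x) x < -12.5),
    ReadPosRankSum = clause(v$ReadPosRankSum, function(x) x < -8.0))
  pass <- rowSums(fails) == 0L
  reasons <- lapply(seq_len(nrow(v)), function(i)
    colnames(fails)[fails[i, ]])
  list(pass = pass, reasons = reasons)
}

#' Depth-percentile filter
#'
#' Removes records whose summed site depth lies in the extreme
#' `tail_fraction` of the empirical depth distribution on each side.
#' The cut uses nearest-rank order statistics: with `k = round(n *
#' tail_fraction)`, records with depth at or below the k-th smallest, or at
#' or above the k-th largest, are removed (ties at the cut value are all
#' removed). With fewer than `1 / tail_fraction` records, or when the two
#' cut values collide, nothing is removed and a warning is raised.
#'
#' @param vs a [variant_set()] with `site_depth` populated.
#' @param tail_fraction fraction removed per tail (default 0.0025, i.e. the
#'   top and bottom 0.25 percent).
#' @return filtered [variant_set()].
#' @export
depth_percentile_filter <- function(vs, tail_fraction = 0.0025) {
  if (tail_fraction == 0) return(vs)
  depth <- vs$variants$site_depth
  n <- length(depth)
  if (n == 0L) return(vs)
  if (n < 1 / tail_fraction) {
    warning("fewer than 1/tail_fraction records; depth filter skipped")
    return(vs)
  }
  k <- round(n * tail_fraction)
  if (k < 1L) return(vs)
  srt <- sort(depth)
  lo <- srt[k]
  hi <- srt[n - k + 1L]
  if (lo >= hi) {
    warning("degenerate depth distribution; depth filter skipped")
    return(vs)
  }
  subset_variants(vs, which(depth > lo & depth < hi))
}

#' Missingness filter
#'
#' Removes records whose fraction of missing genotypes exceeds
#' `max_missing`. Half-missing diploid calls were already collapsed to
#' missing when the genotype matrix was built.
#'
#' @param vs a [variant_set()].
#' @param max_missing maximum tolerated missing rate (default 0.10).
#' @return filtered [variant_set()].
#' @export
missingness_filter <- function(vs, max_missing = 0.10) {
  ns <- length(vs$samples)
  if (ns == 0L) stop("missingness filter needs at least one sample")
  rate <- rowSums(is.na(vs$geno)) / ns
  subset_variants(vs, which(rate <= max_missing))
}

#' Run the full QC cascade
#'
#' Order: biallelic-SNP selection, hard filter, depth-percentile filter,
#' missingness filter. Counts are reported per stage.
#'
#' @param vs raw [variant_set()].
#' @param tail_fraction passed to [depth_percentile_filter()].
#' @param max_missing passed to [missingness_filter()].
#' @return list with `vs` (the surviving records) and `report` (data.table
#'   with `stage`, `n_in`, `n_out`).
#' @export
qc_cascade <- function(vs, tail_fraction = 0.0025, max_missing = 0.10) {
  stages <- character(); n_in <- integer(); n_out <- integer()
  step <- function(name, before, after) {
    stages <<- c(stages, name)
    n_in <<- c(n_in, n_variants(before))
    n_out <<- c(n_out, n_variants(after))
    after
  }
  v1 <- step("biallelic_snp", vs, select_biallelic_snps(vs))
  hf <- hard_filter(v1$variants)
  v2 <- step("hard_filter", v1, subset_variants(v1, which(hf$pass)))
  v3 <- step("depth_percentile", v2,
             depth_percentile_filter(v2, tail_fraction))
  v4 <- step("missingness", v3, missingness_filter(v3, max_missing))
  list(vs = v4,
       report = data.table(stage = stages, n_in = n_in, n_out = n_out))
}
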