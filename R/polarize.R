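# Ancestral-allele polarization by outgroup majority rule: the ancestral
# state at a site is the allele observed at least `min_support` times in the
# panel of outgroup alleles plus (optionally) the focal reference base.
# Sites with ties, insufficient support, or a majority allele that is
# neither REF nor ALT stay unresolved and are excluded from derived-allele
# analyses.

#' Call the ancestral allele at one or more sites
#'
#' @param alleles character matrix (sites x sequences) of alleles in
#'   `A/C/G/T` or `.` / NA for missing. Typically 4 outgroup columns plus
#'   the focal reference base as a fifth.
#' @param ref,alt the focal species' REF and ALT alleles per site.
#' @param min_support minimum count the majority allele must reach
#'   (default 3).
#' @return data.table with `ancestral` (NA when unresolved), `support`, and
#'   `status` in `c("resolved", "tie", "insufficient")`.
#' @export
call_ancestral <- function(alleles, ref, alt, min_support = 3L) {
  if (is.null(dim(alleles))) alleles <- matrix(alleles, nrow = 1L)
  ok <- alleles %in% c(DNA_BASES, ".", NA)
  if (!all(ok)) stop("invalid outgroup allele: ",
                     paste(unique(alleles[!ok]), collapse = ", "))
  n <- nrow(alleles)
  if (n == 0L) return(data.table(ancestral = character(),
                                 support = integer(), status = character()))
  counts <- vapply(DNA_BASES, function(b)
    rowSums(alleles == b, na.rm = TRUE), numeric(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, DNA_BASES))
  top <- max.col(counts, ties.method = "first")
  support <- as.integer(counts[cbind(seq_len(n), top)])
  major <- DNA_BASES[top]
  tie <- rowSums(counts == support) > 1L & support > 0L
  status <- rep("insufficient", n)
  status[support >= min_support & tie] <- "tie"
  resolved <- support >= min_support & !tie & (major == ref | major == alt)
  status[resolved] <- "resolved"
  anc <- rep(NA_character_, n)
  anc[resolved] <- major[resolved]
  data.table(ancestral = anc, support = support, status = status)
}

#' Polarize a variant set against an outgroup table
#'
#' @param vs a [variant_set()] of QC-passed biallelic SNPs.
#' @param outgroups data.table with `chrom`, `pos` and one column per
#'   outgroup species (alleles, `.` for missing).
#' @param include_focal_ref add the focal reference base as a fifth sequence
#'   (default TRUE; the species panel then counts five sequences, matching a
#'   five-species alignment with the focal genome included).
#' @param min_support minimum majority count (default 3).
#' @return data.table keyed by (`chrom`, `pos`) with the [call_ancestral()]
#'   columns plus `derived` (the non-ancestral member of REF/ALT).
#' @export
polarize_variants <- function(vs, outgroups, include_focal_ref = TRUE,
                              min_support = 3L) {
  v <- vs$variants
  og <- as.data.table(outgroups)
  sp_cols <- setdiff(names(og), c("chrom", "pos"))
  m <- merge(v[, .(chrom, pos, ref, alt)], og, by = c("chrom", "pos"),
             all.x = TRUE, sort = FALSE)
  mat <- as.matrix(m[, ..sp_cols])
  if (include_focal_ref) mat <- cbind(mat, m$ref)
  calls <- call_ancestral(mat, m$ref, m$alt, min_support)
  out <- cbind(m[, .(chrom, pos, ref, alt)], calls)
  out[, derived := ifelse(is.na(ancestral), NA_character_,
                          ifelse(ancestral == ref, alt, ref))]
  out[]
}

#' Derived allele dosage matrix
#'
#' Converts ALT dosages to derived-allele dosages using ancestral calls;
#' rows at unresolved sites are NA.
#'
#' @param vs a [variant_set()].
#' @param anc output of [polarize_variants()] aligned to `vs` rows.
#' @return integer matrix like `vs$geno`.
#' @export
derived_dosage <- function(vs, anc) {
  stopifnot(nrow(anc) == nrow(vs$variants))
  d <- vs$geno
  flip <- which(!is.na(anc$ancestral) & anc$ancestral == vs$variants$alt)
  if (length(flip)) d[flip, ] <- 2L - d[flip, , drop = FALSE]
  d[is.na(anc$ancestral), ] <- NA_integer_
  d
}

#' Derived-allele-frequency spectra per load class
#'
#' @param vs a [variant_set()] (QC-passed, annotated rows).
#' @param anc output of [polarize_variants()] aligned to `vs`.
#' @param load_class character vector of load classes aligned to `vs` rows.
#' @param maf_threshold threshold for the rare-variant fraction
#'   (default 0.05).
#' @return list with `sites` (per-site per-population DAF, long format) and
#'   `summary` (per class x population: mean DAF, fraction with minor allele
#'   frequency below the threshold, fixed-derived count, site count).
#' @export
derived_frequencies <- function(vs, anc, load_class, maf_threshold = 0.05) {
  stopifnot(length(load_class) == nrow(vs$variants))
  d <- derived_dosage(vs, anc)
  pops <- unique(vs$populations)
  res <- list()
  for (pp in pops) {
    cols <- which(vs$populations == pp)
    called <- rowSums(!is.na(d[, cols, drop = FALSE]))
    dc <- rowSums(d[, cols, drop = FALSE], na.rm = TRUE)
    keep <- which(!is.na(anc$ancestral) & called > 0)
    res[[pp]] <- data.table(chrom = vs$variants$chrom[keep],
                            pos = vs$variants$pos[keep],
                            population = pp,
                            class_ = load_class[keep],
                            daf = dc[keep] / (2 * called[keep]))
  }
  sites <- rbindlist(res)
  summary <- sites[, .(
    mean_daf = mean(daf),
    frac_maf_lt = mean(pmin(daf, 1 - daf) < maf_threshold),
    n_fixed_derived = sum(daf == 1),
    n_sites = .N
  ), by = .(class_, population)]
  setorder(summary, class_, population)
  list(sites = sites, summary = summary)
}
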