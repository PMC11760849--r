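# Runs of homozygosity: a PLINK-style sliding-window scan. A window of
# `window_snp` consecutive SNPs is homozygous when it holds at most
# `window_het` heterozygous and `window_missing` missing calls; each SNP's
# hit rate is the fraction of windows containing it that are homozygous,
# and SNPs at or above `hit_threshold` are eligible. Maximal runs of
# eligible SNPs, split at inter-SNP gaps above `max_gap_kb`, trimmed to
# homozygous terminal SNPs, and passing the minimum SNP count, minimum
# length and maximum kb-per-SNP density checks, become segments.

#' ROH detector parameters
#'
#' `window_snp = 20`, `min_kb = 10` and `max_density = 50` follow the PLINK
#' invocation `--homozyg-window-snp 20 --homozyg-kb 10 --homozyg-density 50`;
#' the remaining knobs default to PLINK's own defaults. Note PLINK's
#' `min_snp = 100` conflicts with a 10 kb length floor at realistic SNP
#' densities (a 10 kb run can never hold 100 SNPs below 10 SNPs/kb), so
#' `min_snp` is prominently configurable; the pipeline default is 10.
#'
#' @param window_snp SNPs per sliding window.
#' @param min_kb minimum segment length in kb.
#' @param max_density maximum kb per SNP within a segment.
#' @param window_het maximum heterozygous calls per homozygous window.
#' @param window_missing maximum missing calls per homozygous window.
#' @param hit_threshold minimum fraction of homozygous windows for a SNP to
#'   be eligible.
#' @param min_snp minimum SNPs per segment.
#' @param max_gap_kb maximum gap between consecutive SNPs in a segment (kb).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 20L, min_kb = 10, max_density = 50,
                       window_het = 1L, window_missing = 5L,
                       hit_threshold = 0.05, min_snp = 100L,
                       max_gap_kb = 1000) {
  p <- list(window_snp = as.integer(window_snp), min_kb = min_kb,
            max_density = max_density, window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            hit_threshold = hit_threshold, min_snp = as.integer(min_snp),
            max_gap_kb = max_gap_kb)
  stopifnot(p$window_snp >= 1L, p$min_kb >= 0, p$max_density > 0,
            p$hit_threshold > 0, p$hit_threshold <= 1)
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity for one sample on one chromosome
#'
#' @param genotypes integer vector of ALT dosages (0/1/2, NA missing).
#' @param positions strictly increasing 1-based positions.
#' @param params a [roh_params()].
#' @return data.table with `start`, `end` (positions of the terminal SNPs,
#'   inclusive), `n_snps`, `n_het`, `length_bp`.
#' @export
detect_roh <- function(genotypes, positions, params = roh_params()) {
  n <- length(genotypes)
  stopifnot(length(positions) == n)
  empty <- data.table(start = integer(), end = integer(),
                      n_snps = integer(), n_het = integer(),
                      length_bp = integer())
  if (n == 0L) return(empty)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  W <- params$window_snp
  if (n < W) return(empty)

  het <- !is.na(genotypes) & genotypes == 1L
  mis <- is.na(genotypes)
  csh <- c(0L, cumsum(het))
  csm <- c(0L, cumsum(mis))
  nw <- n - W + 1L
  wh <- csh[(1:nw) + W] - csh[1:nw]
  wm <- csm[(1:nw) + W] - csm[1:nw]
  homwin <- wh <= params$window_het & wm <= params$window_missing
  cshw <- c(0L, cumsum(homwin))
  j <- seq_len(n)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, nw)
  total <- hi - lo + 1L
  hits <- cshw[hi + 1L] - cshw[lo]
  eligible <- total > 0L & hits / pmax(total, 1L) >= params$hit_threshold

  hom <- !het & !mis
  segs <- list()
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    idx <- a:b
    gap_break <- which(diff(positions[idx]) > params$max_gap_kb * 1000)
    sub_start <- c(a, idx[gap_break + 1L])
    sub_end <- c(idx[gap_break], b)
    for (s in seq_along(sub_start)) {
      i1 <- sub_start[s]; i2 <- sub_end[s]
      while (i1 <= i2 && !hom[i1]) i1 <- i1 + 1L
      while (i2 >= i1 && !hom[i2]) i2 <- i2 - 1L
      if (i1 > i2) next
      ns <- i2 - i1 + 1L
      len <- positions[i2] - positions[i1] + 1L
      if (ns < params$min_snp) next
      if (len < params$min_kb * 1000) next
      if (len / ns > params$max_density * 1000) next
      segs[[length(segs) + 1L]] <- data.table(
        start = positions[i1], end = positions[i2], n_snps = ns,
        n_het = sum(het[i1:i2]), length_bp = len)
    }
  }
  if (length(segs)) rbindlist(segs) else empty
}

#' Detect ROHs for every sample across a variant set
#'
#' @param vs a [variant_set()] of QC-passed biallelic SNPs.
#' @param params a [roh_params()].
#' @return data.table with `sample_id`, `chrom` and the [detect_roh()]
#'   columns.
#' @export
detect_roh_all <- function(vs, params = roh_params()) {
  out <- list()
  v <- vs$variants
  for (ch in unique(v$chrom)) {
    rows <- which(v$chrom == ch)
    pp <- v$pos[rows]
    o <- order(pp)
    for (s in vs$samples) {
      segs <- detect_roh(vs$geno[rows[o], s], pp[o], params)
      if (nrow(segs)) {
        segs[, `:=`(sample_id = s, chrom = ch)]
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(data.table(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_snps = integer(), n_het = integer(),
                      length_bp = integer()))
  }
  res <- rbindlist(out)
  setcolorder(res, c("sample_id", "chrom"))
  setorder(res, sample_id, chrom, start)
  res[]
}

#' Inbreeding coefficient F_ROH per sample
#'
#' F_ROH is the summed length of ROH segments (at or above
#' `min_length_filter`) divided by the total autosome length. Per-length-
#' class columns report F_ROH restricted to segments of at least 100 kb,
#' shorter than 1 Mb, at least 1 Mb, and at least 5 Mb.
#'
#' @param segments output of [detect_roh_all()] (or a truth table with
#'   `sample_id` and `length_bp`).
#' @param autosome_lengths named numeric vector of autosome lengths.
#' @param min_length_filter minimum segment length counted (bp, default 0).
#' @param samples optional sample ids to report (zero rows otherwise absent).
#' @return data.table with `sample_id`, `f_roh` and the length-class
#'   decomposition.
#' @export
f_roh <- function(segments, autosome_lengths, min_length_filter = 0,
                  samples = NULL) {
  L <- sum(autosome_lengths)
  if (L <= 0) stop("total autosome length must be positive")
  seg <- as.data.table(segments)
  if (!"length_bp" %in% names(seg) && all(c("start", "end") %in% names(seg)))
    seg[, length_bp := end - start + 1L]
  seg <- seg[length_bp >= min_length_filter]
  agg <- seg[, .(
    f_roh = sum(length_bp) / L,
    f_roh_ge100kb = sum(length_bp[length_bp >= 1e5]) / L,
    f_roh_lt1mb = sum(length_bp[length_bp < 1e6]) / L,
    f_roh_ge1mb = sum(length_bp[length_bp >= 1e6]) / L,
    f_roh_ge5mb = sum(length_bp[length_bp >= 5e6]) / L,
    n_segments = .N
  ), by = sample_id]
  if (!is.null(samples)) {
    base <- data.table(sample_id = samples)
    agg <- merge(base, agg, by = "sample_id", all.x = TRUE)
    for (cc in setdiff(names(agg), "sample_id"))
      agg[is.na(get(cc)), (cc) := 0]
  }
  agg[]
}

#' F_ROH decomposed over disjoint length classes
#'
#' @inheritParams f_roh
#' @param breaks interior class edges in bp; classes are
#'   `[0, b1), [b1, b2), ..., [bk, Inf)`.
#' @return data.table with one row per sample x class plus the class label.
#' @export
f_roh_by_class <- function(segments, autosome_lengths,
                           breaks = c(1e5, 1e6, 5e6)) {
  L <- sum(autosome_lengths)
  if (L <= 0) stop("total autosome length must be positive")
  seg <- as.data.table(segments)
  if (!"length_bp" %in% names(seg))
    seg[, length_bp := end - start + 1L]
  edges <- c(0, breaks, Inf)
  labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  seg[, class_ := cut(length_bp, edges, labels = labs, right = FALSE)]
  out <- seg[, .(f_roh = sum(length_bp) / L, n_segments = .N),
             by = .(sample_id, class_)]
  setorder(out, sample_id, class_)
  out[]
}

#' Flag variants inside a sample's ROH segments
#'
#' @param vs a [variant_set()].
#' @param segments output of [detect_roh_all()].
#' @return logical matrix (variants x samples): TRUE when the variant
#'   position lies within any of that sample's segments (inclusive ends).
#' @export
variant_roh_membership <- function(vs, segments) {
  v <- vs$variants
  inside <- matrix(FALSE, nrow(v), length(vs$samples),
                   dimnames = list(NULL, vs$samples))
  seg <- as.data.table(segments)
  if (!nrow(seg)) return(inside)
  for (s in unique(seg$sample_id)) {
    for (ch in unique(seg[sample_id == s]$chrom)) {
      ss <- seg[sample_id == s & chrom == ch]
      rows <- which(v$chrom == ch)
      if (!length(rows)) next
      setorder(ss, start)
      idx <- findInterval(v$pos[rows], ss$start)
      hit <- idx >= 1L & v$pos[rows] <= ss$end[pmax(idx, 1L)]
      inside[rows[hit], s] <- TRUE
    }
  }
  inside
}

#' Write ROH segments as a BED file
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open.
#'
#' @param segments output of [detect_roh_all()].
#' @param path output path.
#' @export
write_roh_bed <- function(segments, path) {
  seg <- as.data.table(segments)
  bed <- seg[, .(chrom, start = start - 1L, end, name = sample_id)]
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
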