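# Genetic diversity: windowed nucleotide diversity (pi), per-individual
# heterozygosity, and linkage-disequilibrium decay from unphased genotypes.
# pi follows the VCFtools convention: the per-window sum of per-site
# 2 * c_ref * c_alt / (n * (n - 1)) divided by the window length.

#' Windowed nucleotide diversity
#'
#' @param vs a [variant_set()] (typically restricted to one population's
#'   samples via `samples`).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window window size in bp (default 500 kb, non-overlapping).
#' @param samples optional subset of sample ids.
#' @param denominator `"window"` (default, the VCFtools convention: divide
#'   by the full window length) or `"callable"` (divide by the number of
#'   sites in the window with at least two called alleles, giving a
#'   per-variable-site average).
#' @return data.table with `chrom`, `win_start`, `win_end`, `n_sites`
#'   (polymorphic sites used), `pi_sum` (summed per-site pi) and `pi_window`
#'   (per-bp pi over the chosen denominator).
#' @export
windowed_pi <- function(vs, chrom_lengths, window = 500000L, samples = NULL,
                        denominator = c("window", "callable")) {
  denominator <- match.arg(denominator)
  if (window <= 0) stop("window size must be positive")
  cols <- if (is.null(samples)) vs$samples else samples
  g <- vs$geno[, cols, drop = FALSE]
  called <- rowSums(!is.na(g))
  c_alt <- rowSums(g, na.rm = TRUE)
  n_al <- 2L * called
  c_ref <- n_al - c_alt
  pi_site <- ifelse(n_al >= 2L,
                    2 * c_ref * c_alt / (n_al * (n_al - 1)), 0)
  v <- vs$variants
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    rows <- which(v$chrom == ch)
    wi <- findInterval(v$pos[rows], starts)
    agg <- data.table(wi = wi, pi = pi_site[rows],
                      poly = pi_site[rows] > 0,
                      called = n_al[rows] >= 2L)[, .(
                        pi_sum = sum(pi), n_sites = sum(poly),
                        n_called = sum(called)), by = wi]
    full <- data.table(chrom = ch, wi = seq_along(starts),
                       win_start = starts, win_end = ends)
    full <- merge(full, agg, by = "wi", all.x = TRUE)
    full[is.na(pi_sum), `:=`(pi_sum = 0, n_sites = 0L, n_called = 0L)]
    out[[ch]] <- full
  }
  res <- rbindlist(out)
  if (denominator == "window") {
    res[, pi_window := pi_sum / (win_end - win_start + 1)]
  } else {
    res[, pi_window := ifelse(n_called > 0, pi_sum / n_called, 0)]
  }
  res[, wi := NULL]
  setorder(res, chrom, win_start)
  res[]
}

#' Genome-wide per-site pi averaged over a genome
#'
#' The length-weighted mean of windowed pi; equals the global per-site sum
#' divided by the genome length.
#'
#' @param pi_windows output of [windowed_pi()].
#' @return numeric scalar.
#' @export
global_pi <- function(pi_windows) {
  w <- pi_windows$win_end - pi_windows$win_start + 1
  sum(pi_windows$pi_window * w) / sum(w)
}

#' Per-individual heterozygosity
#'
#' @param vs a [variant_set()].
#' @return data.table with `sample_id`, `population`, `n_called`, `n_het`,
#'   `het` (het genotype count / called genotype count).
#' @export
individual_heterozygosity <- function(vs) {
  g <- vs$geno
  called <- colSums(!is.na(g))
  if (any(called == 0))
    stop("sample(s) with zero called genotypes: ",
         paste(colnames(g)[called == 0], collapse = ", "))
  hets <- colSums(g == 1L, na.rm = TRUE)
  data.table(sample_id = colnames(g),
             population = unname(vs$populations[colnames(g)]),
             n_called = called, n_het = hets, het = hets / called)
}

#' LD decay from unphased genotypes
#'
#' Composite genotype r-squared: the squared Pearson correlation of 0/1/2
#' dosage vectors for every site pair within `max_dist`, averaged per
#' distance bin. Pairs involving a monomorphic site are skipped.
#'
#' @param vs a [variant_set()].
#' @param max_dist maximum pair distance in bp (default 300 kb).
#' @param bin_width distance bin width in bp (default 1 kb).
#' @param samples optional subset of sample ids (e.g. one population).
#' @return data.table with `dist_bin` (bin upper edge, bp), `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(vs, max_dist = 300000L, bin_width = 1000L,
                     samples = NULL) {
  cols <- if (is.null(samples)) vs$samples else samples
  v <- vs$variants
  sums <- counts <- numeric(ceiling(max_dist / bin_width))
  for (ch in unique(v$chrom)) {
    rows <- which(v$chrom == ch)
    o <- order(v$pos[rows])
    rows <- rows[o]
    p <- v$pos[rows]
    g <- vs$geno[rows, cols, drop = FALSE]
    sds <- apply(g, 1L, stats::sd, na.rm = TRUE)
    poly <- !is.na(sds) & sds > 0
    rows_i <- which(poly)
    for (ii in seq_along(rows_i)) {
      i <- rows_i[ii]
      jmax <- i
      while (jmax < length(p) && p[jmax + 1L] - p[i] <= max_dist)
        jmax <- jmax + 1L
      if (jmax <= i) next
      js <- (i + 1L):jmax
      js <- js[poly[js]]
      if (!length(js)) next
      r <- suppressWarnings(
        cor(g[i, ], t(g[js, , drop = FALSE]), use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      d <- p[js] - p[i]
      b <- pmin(ceiling(d / bin_width), length(sums))
      ok <- !is.na(r2)
      if (any(ok)) {
        tb <- tapply(r2[ok], b[ok], sum)
        idx <- as.integer(names(tb))
        sums[idx] <- sums[idx] + tb
        tn <- tapply(rep(1, sum(ok)), b[ok], sum)
        counts[idx] <- counts[idx] + tn
      }
    }
  }
  data.table(dist_bin = seq_along(sums) * bin_width,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = as.integer(counts))
}

#' Relationship between heterozygosity and F_ROH
#'
#' @param het output of [individual_heterozygosity()].
#' @param froh output of [f_roh()].
#' @return list with the merged table, the Pearson correlation, and the
#'   slope of the least-squares regression of heterozygosity on F_ROH.
#' @export
het_froh_relationship <- function(het, froh) {
  m <- merge(het, froh, by = "sample_id")
  fit <- stats::lm(het ~ f_roh, data = m)
  list(table = m,
       correlation = suppressWarnings(cor(m$het, m$f_roh)),
       slope = unname(stats::coef(fit)[2]))
}
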