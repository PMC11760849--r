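# Independent brute-force oracles. Each one recomputes a quantity by the
# most literal route available (whole-genome mutation and re-translation,
# naive enumeration, all-pairs scans) and is kept deliberately simple and
# separate from the package's own code paths.

## ---- consequence oracle ---------------------------------------------------
## Re-classifies one SNP against one transcript by mutating the whole genome
## string, re-extracting and re-translating the CDS, and scanning features
## with plain loops.

oracle_severity <- c(
  "splice_acceptor", "splice_donor", "stop_gained",
  "start_lost", "stop_lost", "stop_retained",
  "missense", "synonymous", "splice_region",
  "UTR", "intron", "upstream", "downstream", "ncRNA", "intergenic")

oracle_extract_cds <- function(genome_str, cd, strand) {
  pieces <- character(nrow(cd))
  for (i in seq_len(nrow(cd)))
    pieces[i] <- substr(genome_str, cd$start[i], cd$end[i])
  s <- paste(pieces, collapse = "")
  if (strand == "-") toy_revcomp(s) else s
}

oracle_translate <- function(cds) {
  ct <- toy_codon_table()
  out <- character(nchar(cds) / 3L)
  for (i in seq_along(out)) out[i] <- ct[[substr(cds, 3L * i - 2L, 3L * i)]]
  out
}

oracle_classify_tx <- function(pos, alt, t1, ex, cd, genome_str,
                               flank = 5000L) {
  if (pos < t1$start - flank || pos > t1$end + flank) return(NULL)
  if (pos < t1$start) {
    return(if (t1$strand == "+") "upstream" else "downstream")
  }
  if (pos > t1$end) {
    return(if (t1$strand == "+") "downstream" else "upstream")
  }
  if (!t1$coding) return("ncRNA")
  ## which exon, if any
  exon_idx <- 0L
  for (i in seq_len(nrow(ex)))
    if (pos >= ex$start[i] && pos <= ex$end[i]) exon_idx <- i
  if (exon_idx == 0L) {
    ## intronic: locate intron, measure junction offsets
    for (i in seq_len(nrow(ex) - 1L)) {
      istart <- ex$end[i] + 1L; iend <- ex$start[i + 1L] - 1L
      if (pos >= istart && pos <= iend) {
        if (t1$strand == "+") {
          donor <- pos - istart + 1L; acc <- iend - pos + 1L
        } else {
          donor <- iend - pos + 1L; acc <- pos - istart + 1L
        }
        if (donor <= 2L) return("splice_donor")
        if (acc <= 2L) return("splice_acceptor")
        if (min(donor, acc) <= 8L) return("splice_region")
        return("intron")
      }
    }
    stop("oracle: position lost in transcript")
  }
  in_cds <- FALSE
  for (i in seq_len(nrow(cd)))
    if (pos >= cd$start[i] && pos <= cd$end[i]) in_cds <- TRUE
  if (!in_cds) {
    near_left <- exon_idx > 1L && (pos - ex$start[exon_idx] + 1L) <= 3L
    near_right <- exon_idx < nrow(ex) &&
      (ex$end[exon_idx] - pos + 1L) <= 3L
    if (near_left || near_right) return("splice_region")
    return("UTR")
  }
  ## coding: mutate the genome, re-extract, re-translate
  mut <- genome_str
  substr(mut, pos, pos) <- alt
  cds_ref <- oracle_extract_cds(genome_str, cd, t1$strand)
  cds_alt <- oracle_extract_cds(mut, cd, t1$strand)
  aa_ref <- oracle_translate(cds_ref)
  aa_alt <- oracle_translate(cds_alt)
  changed <- 0L
  for (i in seq_along(aa_ref)) {
    c_r <- substr(cds_ref, 3L * i - 2L, 3L * i)
    c_a <- substr(cds_alt, 3L * i - 2L, 3L * i)
    if (c_r != c_a) changed <- i
  }
  stopifnot(changed > 0L)
  if (aa_ref[changed] == aa_alt[changed]) {
    if (aa_ref[changed] == "*") return("stop_retained")
    return("synonymous")
  }
  if (changed == 1L) return("start_lost")
  if (aa_alt[changed] == "*") return("stop_gained")
  if (aa_ref[changed] == "*") return("stop_lost")
  "missense"
}

oracle_classify <- function(chrom, pos, alt, ref_obj, flank = 5000L) {
  models <- ref_obj$models
  genome_str <- ref_obj$genome[[chrom]]
  cats <- character()
  for (i in seq_len(nrow(models$transcripts))) {
    t1 <- as.list(models$transcripts[i])
    if (t1$chrom != chrom) next
    ex <- as.data.frame(models$exons[models$exons$tx_id == t1$tx_id])
    ex <- ex[order(ex$start), ]
    cd <- as.data.frame(models$cds[models$cds$tx_id == t1$tx_id])
    if (nrow(cd)) cd <- cd[order(cd$start), ]
    cc <- oracle_classify_tx(pos, alt, t1, ex, cd, genome_str, flank)
    if (!is.null(cc)) cats <- c(cats, cc)
  }
  if (!length(cats)) return("intergenic")
  cats[which.min(match(cats, oracle_severity))]
}

## ---- ROH oracle -----------------------------------------------------------
## Maximal runs of homozygous non-missing genotypes, split at large gaps,
## filtered by the segment-level constraints.

oracle_roh <- function(genotypes, positions, min_snp = 1L, min_kb = 0,
                       max_density = Inf, max_gap_kb = Inf) {
  hom <- !is.na(genotypes) & genotypes != 1L
  segs <- list()
  i <- 1L
  n <- length(genotypes)
  while (i <= n) {
    if (!hom[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && hom[j + 1L] &&
           positions[j + 1L] - positions[j] <= max_gap_kb * 1000) j <- j + 1L
    ns <- j - i + 1L
    len <- positions[j] - positions[i] + 1L
    if (ns >= min_snp && len >= min_kb * 1000 &&
        len / ns <= max_density * 1000) {
      segs[[length(segs) + 1L]] <- c(start = positions[i],
                                     end = positions[j], n_snps = ns)
    }
    i <- j + 1L
  }
  if (!length(segs)) {
    return(data.frame(start = integer(), end = integer(),
                      n_snps = integer()))
  }
  as.data.frame(do.call(rbind, segs))
}

## ---- nucleotide-diversity oracle ------------------------------------------
## All-pairs allele differences per site: expand every called genotype into
## two alleles, compare every allele pair, average.

oracle_pi_site <- function(dosages) {
  alleles <- integer()
  for (g in dosages) {
    if (is.na(g)) next
    alleles <- c(alleles, switch(as.character(g),
                                 `0` = c(0L, 0L), `1` = c(0L, 1L),
                                 `2` = c(1L, 1L)))
  }
  n <- length(alleles)
  if (n < 2L) return(0)
  diffs <- 0L; pairs <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    pairs <- pairs + 1L
    if (alleles[i] != alleles[j]) diffs <- diffs + 1L
  }
  diffs / pairs
}
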