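# Reference-genome and gene-model generation. Genes are laid out with
# non-overlapping spans, alternating strands; each coding sequence is built
# from codons (ATG start, a sampled stop, no internal stops) and written into
# the chromosome so that translating the annotated CDS always yields a clean
# open reading frame, on either strand.

#' Generate a miniature reference genome with gene models
#'
#' @param spec a [sim_spec()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `models` (a [gene_models()] object) and `chrom_lengths`.
#' @export
generate_reference <- function(spec) {
  set.seed(spec$seed)
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  genome <- stats::setNames(vapply(chroms, function(ch)
    paste(sample(DNA_BASES, spec$chrom_length, replace = TRUE),
          collapse = ""), character(1)), chroms)

  tx <- ex <- cd <- list()
  if (spec$n_genes > 0L) {
    per_chrom <- diff(round(seq(0, spec$n_genes,
                                length.out = spec$n_chromosomes + 1L)))
    gi <- 0L
    for (ci in seq_along(chroms)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      ## reserve a span budget per gene: UTRs + exons + introns + margin
      max_span <- 30L + 30L + 250L * 3L * spec$exons_per_gene +
        1000L * (spec$exons_per_gene - 1L) + 200L
      gap <- 2000L
      if (ng * (max_span + gap) > spec$chrom_length)
        stop("gene placement impossible: ", ng, " genes of up to ", max_span,
             " bp do not fit on a ", spec$chrom_length, " bp chromosome")
      slot <- spec$chrom_length %/% ng
      for (k in seq_len(ng)) {
        gi <- gi + 1L
        g <- .build_gene(spec, gene_idx = gi, chrom = chroms[ci],
                         slot_start = (k - 1L) * slot + 1L,
                         slot_end = k * slot - gap)
        genome[chroms[ci]] <- .splice_into(genome[[chroms[ci]]], g$writes)
        tx[[gi]] <- g$tx; ex[[gi]] <- g$exons; cd[[gi]] <- g$cds
      }
    }
  }
  models <- gene_models(
    transcripts = if (length(tx)) rbindlist(tx) else
      data.table(tx_id = character(), gene_id = character(),
                 chrom = character(), strand = character(),
                 start = integer(), end = integer(), coding = logical()),
    exons = if (length(ex)) rbindlist(ex) else
      data.table(tx_id = character(), start = integer(), end = integer()),
    cds = if (length(cd)) rbindlist(cd) else
      data.table(tx_id = character(), start = integer(), end = integer()))
  list(genome = genome, models = models,
       chrom_lengths = stats::setNames(rep(spec$chrom_length,
                                           spec$n_chromosomes), chroms))
}

#' Lay out one gene inside [slot_start, slot_end] and design its CDS.
#' @noRd
.build_gene <- function(spec, gene_idx, chrom, slot_start, slot_end) {
  ne <- spec$exons_per_gene
  n_codons <- sample(150:250, 1L)                 # includes start + stop
  cds_len <- 3L * n_codons
  cds_parts <- split_length(cds_len, ne, 30L)
  introns <- sample(200:1000, ne - 1L, replace = TRUE)
  utr5 <- 30L; utr3 <- 30L
  span <- utr5 + sum(cds_parts) + sum(introns) + utr3
  avail <- slot_end - slot_start + 1L - span
  if (avail < 0L) stop("gene placement impossible in slot")
  gstart <- slot_start + sample.int(avail + 1L, 1L) - 1L
  strand <- if (gene_idx %% 2L == 0L) "-" else "+"

  ## genomic exon/CDS intervals (genomic order; UTRs at the two ends)
  exon_starts <- integer(ne); exon_ends <- integer(ne)
  cds_starts <- integer(ne); cds_ends <- integer(ne)
  cur <- gstart
  for (i in seq_len(ne)) {
    e_start <- cur
    c_start <- e_start + if (i == 1L) utr5 else 0L
    c_end <- c_start + cds_parts[i] - 1L
    e_end <- c_end + if (i == ne) utr3 else 0L
    exon_starts[i] <- e_start; exon_ends[i] <- e_end
    cds_starts[i] <- c_start; cds_ends[i] <- c_end
    cur <- e_end + if (i < ne) introns[i] + 1L else 0L
  }
  gend <- exon_ends[ne]

  ## design the coding sequence: ATG + non-stop codons + stop
  ct <- codon_table()
  sense <- names(ct)[ct != "*" & names(ct) != "ATG"]
  coding <- paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
                    sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
  genomic_cds <- if (strand == "-") revcomp(coding) else coding
  ## distribute across CDS intervals in genomic order
  offs <- cumsum(c(0L, cds_parts))
  writes <- lapply(seq_len(ne), function(i)
    list(start = cds_starts[i],
         seq = substr(genomic_cds, offs[i] + 1L, offs[i + 1L])))

  id <- sprintf("gene%03d", gene_idx)
  list(
    tx = data.table(tx_id = paste0(id, ".t1"), gene_id = id, chrom = chrom,
                    strand = strand, start = gstart, end = gend,
                    coding = TRUE),
    exons = data.table(tx_id = paste0(id, ".t1"),
                       start = exon_starts, end = exon_ends),
    cds = data.table(tx_id = paste0(id, ".t1"),
                     start = cds_starts, end = cds_ends),
    writes = writes)
}

#' Overwrite stretches of a chromosome string with designed sequence.
#' @noRd
.splice_into <- function(seq, writes) {
  for (w in writes) substr(seq, w$start, w$start + nchar(w$seq) - 1L) <- w$seq
  seq
}
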