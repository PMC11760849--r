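# Gene models: protein-coding (and optionally non-coding) transcripts with
# exon and CDS intervals. All coordinates are 1-based inclusive genomic
# positions; exons are non-overlapping and stored in genomic order.

#' Construct a gene-model set
#'
#' @param transcripts data.frame with columns `tx_id`, `gene_id`, `chrom`,
#'   `strand` ("+"/"-"), `start`, `end`, `coding` (logical).
#' @param exons data.frame with columns `tx_id`, `start`, `end`.
#' @param cds data.frame with columns `tx_id`, `start`, `end` (empty for a
#'   purely non-coding set).
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(transcripts, exons, cds) {
  tx <- as.data.table(transcripts)
  ex <- as.data.table(exons)
  cd <- as.data.table(cds)
  for (dt in list(tx, ex, cd))
    for (cc in intersect(c("start", "end"), names(dt)))
      set(dt, j = cc, value = as.integer(dt[[cc]]))
  setorder(ex, tx_id, start)
  setorder(cd, tx_id, start)
  for (id in tx$tx_id) {
    e <- ex[tx_id == id]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", id)
    cc <- cd[tx_id == id]
    if (nrow(cc)) {
      if (sum(cc$end - cc$start + 1L) %% 3L != 0L)
        stop("CDS length of ", id, " is not a multiple of 3")
      ok <- vapply(seq_len(nrow(cc)), function(i)
        any(e$start <= cc$start[i] & e$end >= cc$end[i]), logical(1))
      if (!all(ok)) stop("CDS not contained in exons for transcript ", id)
    }
  }
  structure(list(transcripts = tx, exons = ex, cds = cd),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$transcripts), "transcripts (",
      sum(x$transcripts$coding), "coding ) on",
      length(unique(x$transcripts$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Coding sequence of one transcript (transcription orientation)
#'
#' @param models a [gene_models()] object.
#' @param id transcript id.
#' @param genome named character vector of chromosome sequences.
#' @return character scalar: the spliced CDS read 5' to 3' on the coding
#'   strand.
#' @export
transcript_cds_seq <- function(models, id, genome) {
  tx <- models$transcripts[tx_id == id]
  if (nrow(tx) != 1L) stop("unknown transcript: ", id)
  cd <- models$cds[tx_id == id]
  if (!nrow(cd)) stop("transcript ", id, " has no CDS")
  pieces <- substring(genome[[tx$chrom]], cd$start, cd$end)
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") s <- revcomp(s) else s
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA (or ncRNA), exon and CDS features with standard
#' `ID`/`Parent` attributes. CDS phase is computed from the cumulative coding
#' length in transcription order.
#'
#' @param models a [gene_models()] object.
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  tx <- models$transcripts
  setorder(tx, chrom, start)
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i]
    type <- if (t1$coding) "mRNA" else "ncRNA"
    lines <- c(lines,
      sprintf("%s\trohload\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              t1$chrom, t1$start, t1$end, t1$strand, t1$gene_id),
      sprintf("%s\trohload\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              t1$chrom, type, t1$start, t1$end, t1$strand, t1$tx_id, t1$gene_id))
    ex <- models$exons[tx_id == t1$tx_id]
    lines <- c(lines, sprintf(
      "%s\trohload\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      t1$chrom, ex$start, ex$end, t1$strand, t1$tx_id))
    cd <- models$cds[tx_id == t1$tx_id]
    if (nrow(cd)) {
      if (t1$strand == "-") cd <- cd[order(-start)]
      clen <- cumsum(c(0L, cd$end - cd$start + 1L))[seq_len(nrow(cd))]
      phase <- (3L - (clen %% 3L)) %% 3L
      lines <- c(lines, sprintf(
        "%s\trohload\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
        t1$chrom, cd$start, cd$end, t1$strand, phase, t1$tx_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Uses rtracklayer for parsing and rebuilds the internal representation from
#' the mRNA/ncRNA, exon and CDS features.
#'
#' @param path GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.table(as.data.frame(gr))
  df[, chrom := as.character(seqnames)]
  txdf <- df[type %in% c("mRNA", "ncRNA")]
  tx <- data.table(
    tx_id = as.character(txdf$ID),
    gene_id = vapply(txdf$Parent, function(p) as.character(p)[1], character(1)),
    chrom = txdf$chrom, strand = as.character(txdf$strand),
    start = txdf$start, end = txdf$end,
    coding = txdf$type == "mRNA"
  )
  exdf <- df[type == "exon"]
  ex <- data.table(
    tx_id = vapply(exdf$Parent, function(p) as.character(p)[1], character(1)),
    start = exdf$start, end = exdf$end)
  cddf <- df[type == "CDS"]
  cd <- data.table(
    tx_id = vapply(cddf$Parent, function(p) as.character(p)[1], character(1)),
    start = cddf$start, end = cddf$end)
  gene_models(tx, ex, cd)
}

#' Write chromosome sequences as FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read chromosome sequences from FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
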