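# Hand-built toy reference: one 3 kb chromosome carrying two protein-coding
# genes, one per strand, with multi-exon structure, UTRs adjacent to introns
# and known codons at fixed positions. Used by the consequence tests and the
# exhaustive classifier-vs-oracle comparison.
#
# Layout (1-based, inclusive):
#   geneA (+) span 201..1520
#     exon1  201..320   all 5' UTR
#     intron 321..520
#     exon2  521..880   UTR5 521..540, CDS 541..880 (340 bp)
#     intron 881..1080
#     exon3 1081..1520  CDS 1081..1220 (140 bp), UTR3 1221..1520
#     CDS total 480 bp = 160 codons; codon1 = ATG at 541..543,
#     codon2 = CGA at 544..546 (one substitution from the TGA stop).
#   geneB (-) span 1801..2700
#     exon1 1801..2100  UTR3 1801..1860, CDS 1861..2100 (240 bp)
#     intron 2101..2300
#     exon2 2301..2700  CDS 2301..2639 (339 bp), UTR5 2640..2700 (61 bp)
#     CDS total 579 bp = 193 codons.

toy_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

toy_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

make_toy_reference <- function() {
  set.seed(4242)
  L <- 3000L
  genome <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  ct <- toy_codon_table()
  sense <- names(ct)[ct != "*"]

  put <- function(genome, start, seq) {
    substr(genome, start, start + nchar(seq) - 1L) <- seq
    genome
  }

  ## geneA (+): 160 codons, fixed leading codons to hit known cases
  lead <- c("ATG", "CGA", "TGG", "CTT", "ATA", "TCG")
  codA <- c(lead, sample(sense, 160L - length(lead) - 1L, replace = TRUE),
            "TAA")
  cdsA <- paste(codA, collapse = "")
  genome <- put(genome, 541L, substr(cdsA, 1L, 340L))
  genome <- put(genome, 1081L, substr(cdsA, 341L, 480L))

  ## geneB (-): 193 codons, written reverse-complemented in genomic order
  codB <- c("ATG", "TGG", sample(sense, 190L, replace = TRUE), "TGA")
  cdsB <- paste(codB, collapse = "")
  gB <- toy_revcomp(cdsB)            # genomic-strand CDS, genomic order
  genome <- put(genome, 1861L, substr(gB, 1L, 240L))
  genome <- put(genome, 2301L, substr(gB, 241L, 579L))

  models <- gene_models(
    transcripts = data.frame(
      tx_id = c("geneA.t1", "geneB.t1"),
      gene_id = c("geneA", "geneB"),
      chrom = "chrT", strand = c("+", "-"),
      start = c(201L, 1801L), end = c(1520L, 2700L),
      coding = TRUE),
    exons = data.frame(
      tx_id = c("geneA.t1", "geneA.t1", "geneA.t1", "geneB.t1", "geneB.t1"),
      start = c(201L, 521L, 1081L, 1801L, 2301L),
      end = c(320L, 880L, 1520L, 2100L, 2700L)),
    cds = data.frame(
      tx_id = c("geneA.t1", "geneA.t1", "geneB.t1", "geneB.t1"),
      start = c(541L, 1081L, 1861L, 2301L),
      end = c(880L, 1220L, 2100L, 2639L)))

  chrU <- paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE),
                collapse = "")
  list(genome = c(chrT = genome, chrU = chrU), models = models,
       chrom_lengths = c(chrT = L, chrU = 300L))
}

## A tiny variant_set builder for fixtures
make_vs <- function(chrom, pos, ref, alt, geno, populations,
                    qual = 50, QD = 10, FS = 5, MQ = 55,
                    MQRankSum = 0, ReadPosRankSum = 0, site_depth = 400) {
  n <- length(pos)
  v <- data.table::data.table(
    chrom = rep_len(chrom, n), pos = pos, ref = ref, alt = alt,
    qual = rep_len(qual, n), QD = rep_len(QD, n), FS = rep_len(FS, n),
    MQ = rep_len(MQ, n), MQRankSum = rep_len(MQRankSum, n),
    ReadPosRankSum = rep_len(ReadPosRankSum, n),
    site_depth = rep_len(site_depth, n))
  variant_set(v, geno, populations)
}
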