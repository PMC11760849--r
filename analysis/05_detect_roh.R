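#!/usr/bin/env Rscript

## Stage 5: runs of homozygosity. PLINK-style sliding-window detection
## (window 20 SNPs, 10 kb length floor, 50 kb-per-SNP density cap) and the
## per-sample inbreeding coefficient F_ROH, headline value restricted to
## segments of at least 100 kb.

suppressPackageStartupMessages({library(rohload); library(data.table)})

samples <- fread("results/sim/samples.tsv")
vs <- read_vcf("results/variants.filtered.vcf",
               populations = setNames(samples$population,
                                      samples$sample_id))
genome <- read_fasta("results/sim/reference.fa")
chrom_lengths <- setNames(nchar(genome), names(genome))

segments <- detect_roh_all(vs, roh_params(min_snp = 25L))
write_roh_bed(segments, "results/roh.bed")
froh <- f_roh(segments, chrom_lengths, min_length_filter = 1e5,
              samples = vs$samples)
fwrite(froh, "results/froh.tsv", sep = "\t")
fwrite(f_roh_by_class(segments, chrom_lengths),
       "results/froh_by_class.tsv", sep = "\t")

m <- merge(froh, samples, by = "sample_id")
print(m[, .(mean_froh = mean(f_roh)), by = population])
cat(sprintf("%d segments; %.1f%% shorter than 100 kb\n", nrow(segments),
            100 * mean(segments$length_bp < 1e5)))
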