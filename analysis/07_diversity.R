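#!/usr/bin/env Rscript

## Stage 7: genetic diversity. Windowed nucleotide diversity (500 kb
## non-overlapping windows, per population), per-individual heterozygosity
## against F_ROH, and genotype-r^2 LD decay per population.

suppressPackageStartupMessages({library(rohload); library(data.table)})

samples <- fread("results/sim/samples.tsv")
pops <- setNames(samples$population, samples$sample_id)
vs <- read_vcf("results/variants.filtered.vcf", populations = pops)
genome <- read_fasta("results/sim/reference.fa")
chrom_lengths <- setNames(nchar(genome), names(genome))

pi_tabs <- rbindlist(lapply(unique(pops), function(pp)
  cbind(population = pp,
        windowed_pi(vs, chrom_lengths, window = 500000L,
                    samples = names(pops)[pops == pp]))))
fwrite(pi_tabs, "results/pi_windows.tsv", sep = "\t")

het <- individual_heterozygosity(vs)
fwrite(het, "results/heterozygosity.tsv", sep = "\t")
froh <- fread("results/froh.tsv")
hf <- het_froh_relationship(het, froh)
cat(sprintf("heterozygosity ~ F_ROH: r = %.3f, slope = %.4f\n",
            hf$correlation, hf$slope))

ld <- rbindlist(lapply(unique(pops), function(pp)
  cbind(population = pp,
        ld_decay(vs, max_dist = 50000L, bin_width = 5000L,
                 samples = names(pops)[pops == pp]))))
fwrite(ld, "results/ld_decay.tsv", sep = "\t")
print(ld[dist_bin <= 20000,
         .(mean_r2 = mean(mean_r2, na.rm = TRUE)), by = population])
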