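#!/usr/bin/env Rscript

## Stage 6: mutational-load statistics. Per-individual derived-allele
## burdens, homozygous dosage, and occurrence ratios (deleterious count /
## synonymous count in the same region) genome-wide and inside/outside ROH;
## Wilcoxon contrasts between populations and paired inside-vs-outside; and
## the candidate-gene screen.

suppressPackageStartupMessages({library(rohload); library(data.table)})

samples <- fread("results/sim/samples.tsv")
vs <- read_vcf("results/variants.filtered.vcf",
               populations = setNames(samples$population,
                                      samples$sample_id))
ann <- fread("results/annotation.tsv")
anc <- fread("results/ancestral.tsv",
             colClasses = list(character = c("ancestral", "derived")))
segments <- fread("results/roh.bed",
                  col.names = c("chrom", "start0", "end", "sample_id"))
segments[, start := start0 + 1L][, start0 := NULL]

membership <- variant_roh_membership(vs, segments)
load <- per_individual_load(vs, anc, ann$load_class, membership)
occ <- occurrence_table(load)
fwrite(load, "results/load_summary.tsv", sep = "\t")
fwrite(occ, "results/occurrence.tsv", sep = "\t")

contrasts <- rohload:::.population_contrasts(load, occ)
fwrite(contrasts, "results/contrasts.tsv", sep = "\t")
print(contrasts[, .(statistic, median1, median2, p_value, tier)])

models <- read_gene_models("results/sim/genes.gff3")
cand <- fread("results/sim/candidate_genes.tsv")
screen <- screen_candidate_genes(vs, ann, anc, models, cand,
                                 flank_bp = 10000L)
fwrite(screen, "results/candidate_screen.tsv", sep = "\t")
cat("Candidate-gene deleterious variants:", nrow(screen),
    "| with AF > 0.5:", sum(screen$af_gt_half), "\n")
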