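#!/usr/bin/env Rscript

## Stage 3: consequence annotation. Each filtered SNP is classified against
## the gene models (codon comparison on the coding strand, SnpEff-style
## splice windows, 5 kb flanks), missense changes get Grantham distances,
## and load classes are assigned: LoF = splice acceptor/donor + stop gained;
## dnsSNP = missense with Grantham >= 150.

suppressPackageStartupMessages({library(rohload); library(data.table)})

genome <- read_fasta("results/sim/reference.fa")
models <- read_gene_models("results/sim/genes.gff3")
samples <- fread("results/sim/samples.tsv")
vs <- read_vcf("results/variants.filtered.vcf",
               populations = setNames(samples$population,
                                      samples$sample_id))

ann <- classify_variants(vs$variants, models, genome)
fwrite(ann, "results/annotation.tsv", sep = "\t")
print(ann[, .N, by = load_class])
cat("Annotated", nrow(ann), "variants\n")
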