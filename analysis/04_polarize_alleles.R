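#!/usr/bin/env Rscript

## Stage 4: ancestral-allele polarization. The ancestral state is the
## majority allele (>= 3 occurrences) among the four outgroup species plus
## the focal reference base; derived-allele-frequency spectra are then
## summarised per load class and population.

suppressPackageStartupMessages({library(rohload); library(data.table)})

samples <- fread("results/sim/samples.tsv")
vs <- read_vcf("results/variants.filtered.vcf",
               populations = setNames(samples$population,
                                      samples$sample_id))
outgroups <- fread("results/sim/outgroups.tsv",
                   colClasses = list(character = c("og1", "og2", "og3",
                                                   "og4")))
ann <- fread("results/annotation.tsv")

anc <- polarize_variants(vs, outgroups)
fwrite(anc, "results/ancestral.tsv", sep = "\t")
spectra <- derived_frequencies(vs, anc, ann$load_class)
fwrite(spectra$summary, "results/spectra.tsv", sep = "\t")
print(spectra$summary)
cat("Resolved:", sum(anc$status == "resolved"), "of", nrow(anc), "sites\n")
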