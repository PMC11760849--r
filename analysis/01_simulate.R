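#!/usr/bin/env Rscript

## Stage 1: generate the synthetic study system — a miniature reference
## genome with gene models, and two related populations (a diverse wild-type
## cohort and a bottlenecked white-type cohort) carrying planted autozygous
## tracts, class-structured coding variants and a four-species outgroup
## panel. All artefacts plus the machine-readable truth land in results/sim/.

suppressPackageStartupMessages(library(rohload))

seed <- as.integer(Sys.getenv("ROHLOAD_SEED", "1"))
spec <- sim_spec(seed = seed)
print(spec)

reference <- generate_reference(spec)
sim <- simulate_populations(spec, reference)
write_sim_data(sim, reference, "results/sim")

cat("Samples:", length(sim$vs$samples), "|",
    "variant records:", n_variants(sim$vs), "|",
    "planted tracts:", nrow(sim$truth$roh), "\n")
cat("Outputs in results/sim/: reference.fa, genes.gff3, variants.vcf,",
    "outgroups.tsv, samples.tsv, candidate_genes.tsv, truth_*.tsv\n")
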