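#!/usr/bin/env Rscript

## Stage 2: variant QC. Biallelic-SNP selection, then the three-step
## cascade: hard filters on QUAL/QD/FS/MQ/MQRankSum/ReadPosRankSum, a
## 0.25%-per-tail depth-percentile filter, and a 10% missingness filter.

suppressPackageStartupMessages({library(rohload); library(data.table)})

samples <- fread("results/sim/samples.tsv")
pops <- setNames(samples$population, samples$sample_id)
vs <- read_vcf("results/sim/variants.vcf", populations = pops)

qc <- qc_cascade(vs, tail_fraction = 0.0025, max_missing = 0.10)
print(qc$report)
fwrite(qc$report, "results/qc_report.tsv", sep = "\t")
write_vcf(qc$vs, "results/variants.filtered.vcf")
cat("Survivors:", n_variants(qc$vs), "of", n_variants(vs), "records\n")
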