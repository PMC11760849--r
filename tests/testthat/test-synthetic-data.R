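# The synthetic-data generator: reference genomes with clean gene models,
# and two-population cohorts with planted truth.

test_that("a zero-gene spec yields an empty annotation and a valid genome", {
  spec <- spec_with(n_genes = 0L)
  ref <- generate_reference(spec)
  expect_identical(nrow(ref$models$transcripts), 0L)
  expect_identical(nrow(ref$models$exons), 0L)
  expect_true(all(nchar(ref$genome) == spec$chrom_length))
  path <- file.path(withr::local_tempdir(), "ref.fa")
  write_fasta(ref$genome, path)
  back <- read_fasta(path)
  expect_identical(unname(back), unname(ref$genome))
  gff <- file.path(withr::local_tempdir(), "empty.gff3")
  write_gff3(ref$models, gff)
  expect_identical(readLines(gff), "##gff-version 3")
})

test_that("reference generation is deterministic under a fixed seed", {
  spec <- shared_spec()
  r1 <- generate_reference(spec)
  r2 <- generate_reference(spec)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$models$transcripts, r2$models$transcripts)
  d <- withr::local_tempdir()
  write_gff3(r1$models, file.path(d, "a.gff3"))
  write_gff3(r2$models, file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.gff3")),
                   readLines(file.path(d, "b.gff3")))
})

test_that("every generated CDS is a clean ORF on the annotated strand", {
  ref <- shared_reference()
  tx <- ref$models$transcripts
  expect_true(all(c("+", "-") %in% tx$strand))
  for (id in tx$tx_id) {
    cds <- transcript_cds_seq(ref$models, id, ref$genome)
    expect_identical(nchar(cds) %% 3L, 0L)
    prot <- translate_cds(cds)
    expect_identical(substr(prot, 1L, 1L), "M")
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    ## no internal stop
    expect_false(grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)))
    ## at least two exons so splice sites exist
    expect_gte(nrow(ref$models$exons[tx_id == id]), 2L)
  }
})

test_that("impossible gene density fails explicitly", {
  spec <- spec_with(n_chromosomes = 1L, chrom_length = 50000L,
                    n_genes = 30L, roh_length_range = c(1000, 2000))
  expect_error(generate_reference(spec), "placement impossible")
})

test_that("population simulation is deterministic under a fixed seed", {
  ref <- shared_reference()
  s1 <- simulate_populations(shared_spec(), ref,
                             candidates = shared_candidates(), seed = 99L)
  s2 <- simulate_populations(shared_spec(), ref,
                             candidates = shared_candidates(), seed = 99L)
  expect_identical(s1$vs$variants, s2$vs$variants)
  expect_identical(unclass(s1$vs$geno), unclass(s2$vs$geno))
  expect_identical(s1$truth$roh, s2$truth$roh)
  expect_identical(s1$outgroups, s2$outgroups)
})

test_that("zero autozygosity target plants no tracts", {
  spec <- spec_with(target_f_roh = list(wild = c(mean = 0, sd = 0),
                                        white = c(mean = 0, sd = 0)))
  sim <- simulate_populations(spec, shared_reference(),
                              candidates = shared_candidates(), seed = 5L)
  expect_identical(nrow(sim$truth$roh), 0L)
})

test_that("zero outgroup divergence reproduces the ancestral allele", {
  spec <- spec_with(outgroup_divergence = 0, outgroup_missing = 0)
  sim <- simulate_populations(spec, shared_reference(),
                              candidates = shared_candidates(), seed = 7L)
  og <- sim$outgroups
  anc <- sim$truth$variants$ancestral
  for (cc in c("og1", "og2", "og3", "og4"))
    expect_identical(og[[cc]], anc)
})

test_that("planted tracts are homozygous, non-overlapping, on-target", {
  bundle <- shared_bundle()
  sim <- bundle$sim
  spec <- shared_spec()
  G <- sum(bundle$reference$chrom_lengths)
  roh <- sim$truth$roh
  ## non-overlap within sample
  by_s <- split(roh, roh$sample_id)
  for (tr in by_s) {
    for (ch in unique(tr$chrom)) {
      cc <- tr[tr$chrom == ch, ]
      cc <- cc[order(cc$start), ]
      if (nrow(cc) > 1L)
        expect_true(all(cc$start[-1] > cc$end[-nrow(cc)]))
    }
  }
  ## coverage within +-0.01 of the drawn per-sample target
  cov <- roh[, .(f = sum(end - start + 1) / G), by = sample_id]
  cov <- merge(cov, sim$truth$f_targets, by = "sample_id")
  expect_true(all(abs(cov$f - cov$f_target) <= 0.01))
  ## genotypes inside tracts are homozygous (zero het-leak by default)
  v <- sim$vs$variants
  for (s in head(unique(roh$sample_id), 6)) {
    tr <- roh[sample_id == s]
    inside <- rep(FALSE, nrow(v))
    for (j in seq_len(nrow(tr)))
      inside <- inside | (v$chrom == tr$chrom[j] & v$pos >= tr$start[j] &
                            v$pos <= tr$end[j])
    g <- sim$vs$geno[inside, s]
    expect_true(all(g != 1L, na.rm = TRUE))
  }
})

test_that("every coding variant carries exactly one truth class", {
  sim <- shared_bundle()$sim
  tv <- sim$truth$variants
  expect_true(all(tv$truth_class %in%
                    c("synonymous", "missense", "dnsSNP", "LoF",
                      "noncoding")))
  expect_identical(anyDuplicated(tv[, .(chrom, pos)]), 0L)
  counts <- table(tv$truth_class)
  spec <- shared_spec()
  for (cl in names(spec$class_n_sites))
    expect_identical(unname(counts[cl]),
                     as.integer(spec$class_n_sites[[cl]]))
})

test_that("realized derived allele frequencies hit the class means", {
  ## larger per-class site counts tighten the standard error; planted
  ## contrasts and tracts are switched off so every class is a clean draw
  spec <- spec_with(n_genes = 80L, seed = 11L,
                    class_n_sites = c(synonymous = 2000L, missense = 2000L,
                                      dnsSNP = 1200L, LoF = 1200L),
                    effects = null_effects(),
                    target_f_roh = list(wild = c(mean = 0, sd = 0),
                                        white = c(mean = 0, sd = 0)))
  ref <- generate_reference(spec)
  sim <- simulate_populations(spec, ref)
  tv <- sim$truth$variants
  for (cl in c("synonymous", "missense", "dnsSNP", "LoF")) {
    daf <- tv[truth_class == cl & !is.na(daf_wild)]$daf_wild
    se <- sd(daf) / sqrt(length(daf))
    expect_lt(abs(mean(daf) - spec$class_daf_means[[cl]]), 3 * se)
  }
})

test_that("an oversized tract request fails explicitly", {
  spec <- shared_spec()
  spec$roh_length_range <- c(3e6, 3e6)   # longer than any chromosome
  spec$chrom_length <- 4e7L              # bypass the spec-level guard
  expect_error(
    rohload:::.plant_tracts(spec, shared_reference(),
                            c("wild01"), c(wild01 = "wild")),
    "longer than chromosome")
})

test_that("simulation artefacts round-trip through plain files", {
  skip_if_not_installed("vcfR")
  skip_if_not_installed("rtracklayer")
  bundle <- shared_bundle()
  d <- withr::local_tempdir()
  write_sim_data(bundle$sim, bundle$reference, d)
  expect_true(all(file.exists(file.path(d, c(
    "reference.fa", "genes.gff3", "variants.vcf", "outgroups.tsv",
    "samples.tsv", "candidate_genes.tsv", "truth_variants.tsv",
    "truth_roh.tsv")))))
  vs2 <- read_vcf(file.path(d, "variants.vcf"),
                  populations = bundle$sim$vs$populations)
  expect_identical(vs2$variants$pos, bundle$sim$vs$variants$pos)
  expect_identical(vs2$variants$ref, bundle$sim$vs$variants$ref)
  expect_identical(vs2$variants$alt, bundle$sim$vs$variants$alt)
  expect_identical(as.vector(vs2$geno), as.vector(bundle$sim$vs$geno))
  expect_identical(colnames(vs2$geno), colnames(bundle$sim$vs$geno))
  expect_equal(vs2$variants$QD, bundle$sim$vs$variants$QD,
               tolerance = 1e-4)
  models2 <- read_gene_models(file.path(d, "genes.gff3"))
  m1 <- bundle$reference$models
  expect_identical(nrow(models2$transcripts), nrow(m1$transcripts))
  t2 <- models2$transcripts[order(tx_id)]
  t1 <- m1$transcripts[order(tx_id)]
  expect_identical(t2$start, t1$start)
  expect_identical(t2$end, t1$end)
  expect_identical(t2$strand, t1$strand)
  expect_identical(models2$cds[order(tx_id, start)]$start,
                   m1$cds[order(tx_id, start)]$start)
})
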