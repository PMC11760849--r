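# Per-individual load accounting, occurrence ratios, population contrasts
# and the candidate-gene screen.

test_that("derived-allele accounting matches hand arithmetic", {
  pops <- c(s1 = "white", s2 = "white")
  ## s1: 3 het + 2 hom-derived missense sites -> alleles 7, homs 2,
  ## homozygosity ratio 0.4; s2 carries nothing
  g <- cbind(s1 = c(1L, 1L, 1L, 2L, 2L), s2 = rep(0L, 5))
  vs <- make_vs("chr1", pos = c(1:5) * 100L, ref = "A", alt = "G",
                geno = g, populations = pops)
  anc <- data.table::data.table(ancestral = rep("A", 5))
  load <- per_individual_load(vs, anc, rep("missense", 5))
  s1 <- load[sample_id == "s1" & class_ == "missense"]
  expect_identical(s1$allele_count, 7L)
  expect_identical(s1$site_count, 5L)
  expect_identical(s1$hom_count, 2L)
  expect_equal(s1$hom_ratio, 0.4)
  s2 <- load[sample_id == "s2" & class_ == "missense"]
  expect_identical(s2$allele_count, 0L)
  expect_true(is.na(s2$hom_ratio))
})

test_that("inside plus outside ROH counts equal genome-wide counts", {
  load <- shared_bundle()$load$summary
  wide <- data.table::dcast(load, sample_id + class_ ~ region,
                            value.var = c("allele_count", "site_count",
                                          "hom_count", "het_count"))
  expect_identical(wide$allele_count_genome,
                   wide$allele_count_inside + wide$allele_count_outside)
  expect_identical(wide$hom_count_genome,
                   wide$hom_count_inside + wide$hom_count_outside)
  expect_identical(wide$het_count_genome,
                   wide$het_count_inside + wide$het_count_outside)
})

test_that("the dnsSNP tally is a subset of the missense tally", {
  load <- shared_bundle()$load$summary
  m <- merge(load[class_ == "missense",
                  .(sample_id, region, a = allele_count, s = site_count,
                    h = hom_count)],
             load[class_ == "dnsSNP",
                  .(sample_id, region, a2 = allele_count, s2 = site_count,
                    h2 = hom_count)], by = c("sample_id", "region"))
  expect_true(all(m$a2 <= m$a))
  expect_true(all(m$s2 <= m$s))
  expect_true(all(m$h2 <= m$h))
})

test_that("occurrence ratios divide by same-region synonymous counts", {
  expect_equal(occurrence_ratio(100, 200), 0.5)
  expect_equal(occurrence_ratio(0, 50), 0)
  expect_warning(r <- occurrence_ratio(10, 0), "undefined")
  expect_true(is.na(r))
})

test_that("rank tests behave at the degenerate extremes", {
  same <- compare_populations(rep(c(1, 2, 3), 2),
                              rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  expect_identical(same$tier, "ns")

  ## completely separated samples attain the exact permutation p-value
  sep <- compare_populations(c(1:10, 21:30), rep(c("a", "b"), each = 10))
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(sep$tier, "****")

  expect_error(compare_populations(c(1, 2, 3), c("a", "a", "b")),
               "at least two")

  paired_same <- compare_populations(c(1, 2, 3), values2 = c(1, 2, 3))
  expect_equal(paired_same$p_value, 1)
})

test_that("significance tiers follow the star convention", {
  expect_identical(significance_tier(c(0.2, 0.04, 0.009, 5e-4, 5e-5)),
                   c("ns", "*", "**", "***", "****"))
})

test_that("candidate screen respects flanks and exclusivity", {
  toy <- make_toy_reference()
  pops <- c(w1 = "wild", w2 = "wild", h1 = "white", h2 = "white")
  ## geneA span 201..1520; flank 100 -> window 101..1620
  g <- rbind(c(0L, 0L, 2L, 0L),    # pos 1620: white-private hom genotype
             c(1L, 0L, 1L, 0L),    # pos 1621: outside the flank
             c(1L, 1L, 1L, 1L))    # pos 300: shared genotypes
  colnames(g) <- names(pops)
  vs <- make_vs("chrT", pos = c(1620L, 1621L, 300L), ref = "A", alt = "G",
                geno = g, populations = pops)
  ann <- data.table::data.table(load_class = c("missense", "missense",
                                               "LoF"))
  gl <- data.table::data.table(gene_name = "coatA", gene_id = "geneA")
  res <- screen_candidate_genes(vs, ann, anc = NULL, toy$models, gl,
                                flank_bp = 100L)
  expect_identical(sort(res$pos), c(300L, 1620L))
  r1620 <- res[pos == 1620]
  expect_true(r1620$exclusive_genotype)
  expect_identical(r1620$exclusive_population, "white")
  expect_equal(r1620$af_white, 0.5)
  expect_equal(r1620$af_wild, 0)
  expect_false(r1620$af_gt_half)
  expect_false(res[pos == 300]$exclusive_genotype)

  expect_identical(nrow(screen_candidate_genes(
    vs, ann, NULL, toy$models, gl[0], 100L)), 0L)
  expect_warning(screen_candidate_genes(
    vs, ann, NULL, toy$models,
    data.table::data.table(gene_name = "nope", gene_id = "geneZ"), 100L),
    "unknown gene")
})

test_that("multiple-testing adjustment is available but off by default", {
  bundle <- shared_bundle()
  load <- bundle$load$summary
  occ <- bundle$load$occurrence
  raw <- population_contrasts(load, occ)
  bh <- population_contrasts(load, occ, p_adjust = "BH")
  expect_identical(raw$statistic, bh$statistic)
  expect_true(all(bh$p_value >= raw$p_value))
  expect_identical(raw$p_value, bundle$load$contrasts$p_value)
  expect_identical(bh$tier, significance_tier(bh$p_value))
})

test_that("a null generator leaves inside/outside occurrence undisturbed", {
  ## 100 small null cohorts: the paired signed-rank test on the missense
  ## occurrence ratio inside vs outside ROH should stay non-significant in
  ## at least 90 of them
  spec <- spec_with(
    n_chromosomes = 1L, chrom_length = 2000000L, n_genes = 20L,
    n_samples = c(wild = 10L, white = 10L),
    class_n_sites = c(synonymous = 250L, missense = 250L, dnsSNP = 50L,
                      LoF = 50L),
    effects = null_effects(), seed = 303L)
  ref <- generate_reference(spec)
  cand <- enumerate_coding_candidates(ref)
  ok <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    sim <- simulate_populations(spec, ref, candidates = cand,
                                seed = 40000L + r)
    qc <- qc_cascade(sim$vs)
    ann <- classify_variants(qc$vs$variants, ref$models, ref$genome)
    anc <- polarize_variants(qc$vs, sim$outgroups)
    segs <- detect_roh_all(qc$vs, roh_params(min_snp = 25L))
    memb <- variant_roh_membership(qc$vs, segs)
    load <- per_individual_load(qc$vs, anc, ann$load_class, memb)
    occ <- occurrence_table(load)
    oi <- occ[region == "inside" & class_ == "missense"][order(sample_id)]
    oo <- occ[region == "outside" & class_ == "missense"][order(sample_id)]
    p <- compare_populations(oi$occurrence, values2 = oo$occurrence)$p_value
    if (p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 0.9 * n_rep)
})
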