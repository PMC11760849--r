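# Consequence classification on the hand-built toy reference. The layout
# (fixed codons at known positions) is documented in helper-toy.R.

toy <- make_toy_reference()

test_that("known codon changes classify on the plus strand", {
  ## codon2 of geneA is CGA at 544..546; C->T makes the TGA stop
  expect_identical(
    classify_site("chrT", 544L, "C", "T", toy$models, toy$genome)$category,
    "stop_gained")
  ## codon1 ATG at 541..543: any change loses the start
  expect_identical(
    classify_site("chrT", 541L, "A", "G", toy$models, toy$genome)$category,
    "start_lost")
  ## codon3 TGG at 547..549: G->T at the third base gives TGT (Trp->Cys),
  ## the most radical substitution in the matrix, hence a dnsSNP
  call <- classify_site("chrT", 549L, "G", "T", toy$models, toy$genome)
  expect_identical(call$category, "missense")
  expect_identical(call$aa_ref, "W")
  expect_identical(call$aa_alt, "C")
  expect_identical(call$grantham, 215L)
  expect_identical(call$load_class, "dnsSNP")
  ## terminal stop TAA at 1218..1220: A->G at the third base keeps a stop
  expect_identical(
    classify_site("chrT", 1220L, "A", "G", toy$models, toy$genome)$category,
    "stop_retained")
  ## A->C at the second base gives TCA (Ser): the stop is lost
  expect_identical(
    classify_site("chrT", 1219L, "A", "C", toy$models, toy$genome)$category,
    "stop_lost")
})

test_that("splice windows follow the 2/8-intronic, 3-exonic convention", {
  g <- toy$genome
  m <- toy$models
  ref_at <- function(p) substring(g[["chrT"]], p, p)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), ref_at(p))[1]
  cat_at <- function(p) classify_site("chrT", p, ref_at(p), alt_of(p),
                                      m, g)$category
  ## geneA (+): intron1 = 321..520
  expect_identical(cat_at(321L), "splice_donor")
  expect_identical(cat_at(322L), "splice_donor")
  expect_identical(cat_at(323L), "splice_region")
  expect_identical(cat_at(328L), "splice_region")
  expect_identical(cat_at(420L), "intron")
  expect_identical(cat_at(513L), "splice_region")
  expect_identical(cat_at(519L), "splice_acceptor")
  expect_identical(cat_at(520L), "splice_acceptor")
  ## exonic splice region: last 3 bases of the all-UTR exon1 (318..320)
  expect_identical(cat_at(318L), "splice_region")
  expect_identical(cat_at(320L), "splice_region")
  expect_identical(cat_at(250L), "UTR")
  ## geneB (-): intron = 2101..2300; transcription runs right to left
  expect_identical(cat_at(2300L), "splice_donor")
  expect_identical(cat_at(2299L), "splice_donor")
  expect_identical(cat_at(2101L), "splice_acceptor")
  expect_identical(cat_at(2102L), "splice_acceptor")
  expect_identical(cat_at(2200L), "intron")
})

test_that("flanks, intergenic and precedence resolve as specified", {
  g <- toy$genome
  m <- toy$models
  ## pos 100: upstream of geneA (+), downstream of geneB (-): upstream wins
  expect_identical(
    classify_site("chrT", 100L, substring(g[["chrT"]], 100, 100),
                  "A", m, g, check_ref = FALSE)$category, "upstream")
  ## chrU carries no genes and is beyond every flank
  expect_identical(
    classify_site("chrU", 150L, substring(g[["chrU"]], 150, 150),
                  "A", m, g, check_ref = FALSE)$category, "intergenic")
  ## reference mismatch errors with the site name
  ref_base <- substring(g[["chrT"]], 544, 544)
  wrong <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  expect_error(classify_site("chrT", 544L, wrong, ref_base, m, g),
               "reference mismatch at chrT:544")
})

test_that("grantham scores are attached exactly to missense calls", {
  cases <- data.table::data.table(
    chrom = "chrT", pos = rep(521:1520, each = 1L))
  cases[, ref := substring(toy$genome[["chrT"]], pos, pos)]
  cases[, alt := ifelse(ref == "A", "G", "A")]
  ann <- classify_variants(cases, toy$models, toy$genome)
  expect_true(all(!is.na(ann[category == "missense"]$grantham)))
  expect_true(all(is.na(ann[category != "missense"]$grantham)))
})

test_that("the LoF definition equals acceptor + donor + stop-gained", {
  cases <- data.table::data.table(chrom = "chrT",
                                  pos = rep(1:3000, each = 3L))
  refb <- strsplit(toy$genome[["chrT"]], "")[[1]]
  cases[, ref := refb[pos]]
  cases[, alt := unlist(lapply(refb, function(r)
    setdiff(c("A", "C", "G", "T"), r)))]
  ann <- classify_variants(cases, toy$models, toy$genome)
  n_lof_parts <- sum(ann$category %in%
                       c("splice_acceptor", "splice_donor", "stop_gained"))
  expect_identical(sum(ann$load_class == "LoF"), n_lof_parts)
  ## dnsSNP is the high-Grantham subset of missense
  expect_true(all(ann[load_class == "dnsSNP"]$grantham >= 150L))
  expect_true(all(ann[load_class == "missense"]$grantham < 150L))
})

test_that("classification is invariant under reverse-complementing", {
  ## mirror the toy genome: flip sequence, strands and coordinates; every
  ## category must be unchanged
  mirror <- local({
    g <- toy$genome
    L <- nchar(g[["chrT"]])
    m <- toy$models
    tx <- data.table::copy(m$transcripts)
    ex <- data.table::copy(m$exons)
    cd <- data.table::copy(m$cds)
    tx[, `:=`(start2 = L - end + 1L, end2 = L - start + 1L,
              strand = ifelse(strand == "+", "-", "+"))]
    tx[, `:=`(start = start2, end = end2, start2 = NULL, end2 = NULL)]
    ex[, `:=`(start2 = L - end + 1L, end2 = L - start + 1L)]
    ex[, `:=`(start = start2, end = end2, start2 = NULL, end2 = NULL)]
    cd[, `:=`(start2 = L - end + 1L, end2 = L - start + 1L)]
    cd[, `:=`(start = start2, end = end2, start2 = NULL, end2 = NULL)]
    list(genome = c(chrT = toy_revcomp(g[["chrT"]]), chrU = g[["chrU"]]),
         models = gene_models(tx, ex, cd), L = L)
  })
  set.seed(31)
  pos <- sample(3000L, 400L)
  refb <- strsplit(toy$genome[["chrT"]], "")[[1]]
  alts <- vapply(refb[pos], function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  fwd <- classify_variants(
    data.table::data.table(chrom = "chrT", pos = pos, ref = refb[pos],
                           alt = alts), toy$models, toy$genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev <- classify_variants(
    data.table::data.table(chrom = "chrT", pos = mirror$L - pos + 1L,
                           ref = comp[refb[pos]], alt = comp[alts]),
    mirror$models, mirror$genome)
  expect_identical(rev$category, fwd$category)
})

test_that("load categories map as specified", {
  expect_identical(assign_load_category("stop_gained"), "LoF")
  expect_identical(assign_load_category("splice_acceptor"), "LoF")
  expect_identical(assign_load_category("splice_donor"), "LoF")
  expect_identical(assign_load_category("missense", 150L), "dnsSNP")
  expect_identical(assign_load_category("missense", 151L), "dnsSNP")
  expect_identical(assign_load_category("missense", 149L), "missense")
  expect_identical(assign_load_category("synonymous"), "synonymous")
  expect_identical(assign_load_category(c("intron", "UTR", "stop_lost",
                                          "start_lost", "stop_retained")),
                   rep("other", 5))
})
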