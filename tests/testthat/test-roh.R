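# PLINK-style ROH detection, F_ROH and variant membership.

paper_params <- function(...) roh_params(min_snp = 2L, ...)

test_that("an all-heterozygous sample yields no segments", {
  pos <- seq(1000L, by = 1000L, length.out = 50L)
  segs <- detect_roh(rep(1L, 50), pos, roh_params())
  expect_identical(nrow(segs), 0L)
})

test_that("runs shorter than the 10 kb floor are discarded", {
  ## 20 homozygous SNPs spanning 8 kb satisfy every other criterion
  pos <- as.integer(round(seq(1000, 9000, length.out = 20)))
  segs <- detect_roh(rep(0L, 20), pos, paper_params())
  expect_identical(nrow(segs), 0L)
})

test_that("a clean homozygous run is reported end to end", {
  ## 60 homozygous SNPs at 1 kb spacing with the window-20 profile
  pos <- seq(1000L, by = 1000L, length.out = 60L)
  segs <- detect_roh(rep(2L, 60), pos, paper_params())
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$start, 1000L)
  expect_identical(segs$end, 60000L)
  expect_identical(segs$n_snps, 60L)
  expect_identical(segs$n_het, 0L)
})

test_that("unsorted positions are rejected", {
  expect_error(detect_roh(c(0L, 0L), c(200L, 100L), roh_params()),
               "strictly increasing")
})

test_that("degenerate parameters reproduce exhaustive maximal runs", {
  degen <- roh_params(window_snp = 1L, window_het = 0L, window_missing = 0L,
                      hit_threshold = 1, min_snp = 3L, min_kb = 1,
                      max_density = 1e6, max_gap_kb = 50)
  set.seed(42)
  for (r in 1:30) {
    n <- 500L
    pos <- sort(sample.int(5e5, n))
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c(0.45, 0.3, 0.2, 0.05))
    got <- detect_roh(g, pos, degen)
    want <- oracle_roh(g, pos, min_snp = 3L, min_kb = 1,
                       max_density = 1e6, max_gap_kb = 50)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$start, as.integer(want$start))
    expect_identical(got$end, as.integer(want$end))
    expect_identical(got$n_snps, as.integer(want$n_snps))
  }
})

test_that("total ROH length is monotone in min_kb and window_het", {
  set.seed(9)
  pos <- sort(sample.int(2e6, 2000L))
  g <- sample(c(0L, 1L, 2L), 2000L, replace = TRUE,
              prob = c(0.5, 0.15, 0.35))
  total <- function(p) sum(detect_roh(g, pos, p)$length_bp)
  lens <- vapply(c(10, 30, 100), function(kb)
    total(roh_params(min_kb = kb, min_snp = 5L)), numeric(1))
  expect_true(all(diff(lens) <= 0))
  hets <- vapply(c(0L, 1L, 3L), function(h)
    total(roh_params(window_het = h, min_snp = 5L)), numeric(1))
  expect_true(all(diff(hets) >= 0))
})

test_that("F_ROH arithmetic and class decomposition are consistent", {
  empty <- data.table::data.table(sample_id = character(),
                                  chrom = character(), start = integer(),
                                  end = integer(), length_bp = integer())
  expect_identical(nrow(f_roh(empty, c(chr1 = 1e8))), 0L)
  f0 <- f_roh(empty, c(chr1 = 1e8), samples = "s1")
  expect_identical(f0$f_roh, 0)

  one <- data.table::data.table(sample_id = "s1", chrom = "chr1",
                                start = 1L, end = 1e7, length_bp = 1e7)
  expect_equal(f_roh(one, c(chr1 = 1e8))$f_roh, 0.10)
  expect_error(f_roh(one, c(chr1 = 0)), "positive")

  ## disjoint length classes partition the total
  bundle <- shared_bundle()
  segs <- bundle$roh$segments
  lens <- bundle$reference$chrom_lengths
  total <- f_roh(segs, lens)
  parts <- f_roh_by_class(segs, lens)[, .(f = sum(f_roh)), by = sample_id]
  m <- merge(total[, .(sample_id, f_roh)], parts, by = "sample_id")
  expect_equal(m$f_roh, m$f, tolerance = 1e-12)
})

test_that("variant membership is inclusive of segment ends", {
  pops <- c(s1 = "wild")
  g <- matrix(0L, 4, 1, dimnames = list(NULL, "s1"))
  vs <- make_vs("chr1", pos = c(1000L, 5000L, 5001L, 999L),
                ref = "A", alt = "G", geno = g, populations = pops)
  segs <- data.table::data.table(sample_id = "s1", chrom = "chr1",
                                 start = 1000L, end = 5000L)
  inside <- variant_roh_membership(vs, segs)
  expect_identical(unname(inside[, "s1"]), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("membership agrees with a brute-force containment scan", {
  set.seed(13)
  pops <- c(a = "wild", b = "white")
  n <- 1000L
  v_pos <- sort(sample.int(1e6, n))
  g <- matrix(0L, n, 2, dimnames = list(NULL, names(pops)))
  vs <- make_vs("chr1", pos = v_pos, ref = "A", alt = "G", geno = g,
                populations = pops)
  segs <- data.table::data.table(
    sample_id = rep(c("a", "b"), each = 10),
    chrom = "chr1",
    start = as.integer(sort(sample(seq(1, 9.5e5, by = 5e4), 10)) +
                         rep(0, 10)))
  segs[, start := start + sample(0:1000, .N)]
  segs[, end := start + sample(5000:30000, .N)]
  got <- variant_roh_membership(vs, segs)
  for (s in c("a", "b")) {
    ss <- segs[sample_id == s]
    want <- vapply(v_pos, function(p)
      any(p >= ss$start & p <= ss$end), logical(1))
    expect_identical(unname(got[, s]), want)
  }
})

test_that("BED export shifts to 0-based half-open coordinates", {
  segs <- data.table::data.table(sample_id = "s1", chrom = "chr1",
                                 start = 1000L, end = 5000L,
                                 n_snps = 10L, n_het = 0L,
                                 length_bp = 4001L)
  path <- file.path(withr::local_tempdir(), "roh.bed")
  write_roh_bed(segs, path)
  expect_identical(readLines(path), "chr1\t999\t5000\ts1")
})
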