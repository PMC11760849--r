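# Two-population genotype simulation with machine-readable truth.
#
# Haplotypes are mosaics of per-population founder haplotypes (the white-type
# pool is smaller, emulating the breed bottleneck and producing slower LD
# decay); an individual's two haplotypes draw from disjoint halves of the
# founder pool, so background autozygosity is zero and every autozygous
# tract in the truth table was planted deliberately. Tracts are planted by
# replacing both haplotypes with a single sampled haplotype over an interval;
# coding variants are placed on enumerated candidate sites of known
# consequence class, with class-specific derived-allele-frequency means.

#' Simulate two populations over a generated reference
#'
#' @param spec a [sim_spec()].
#' @param reference output of [generate_reference()].
#' @param candidates optional precomputed [enumerate_coding_candidates()]
#'   table (pass it when simulating many replicates over one reference).
#' @param seed seed for the population draw; defaults to `spec$seed + 1`
#'   so the reference and the cohort can be varied independently.
#' @return an object of class `sim_data`: a list with
#'   `vs` (a [variant_set()] including the spiced-in non-SNP records),
#'   `outgroups` (data.table chrom, pos, og1..og4),
#'   `truth` (list: `variants` with true class, ancestral allele and realized
#'   derived AFs; `roh` with planted intervals; `qc` with planted filter
#'   faults), `sample_map`, and `candidate_genes`.
#' @export
simulate_populations <- function(spec, reference, candidates = NULL,
                                 seed = spec$seed + 1L) {
  set.seed(seed)
  genome <- reference$genome
  chroms <- names(genome)
  G <- sum(nchar(genome))

  ## ---- choose coding sites of known class -------------------------------
  if (is.null(candidates)) {
    candidates <- if (spec$n_genes > 0L)
      enumerate_coding_candidates(reference)
    else data.table(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), load_class = character())
  }
  used <- character()
  coding <- list()
  for (cl in names(spec$class_n_sites)) {
    pool <- candidates[load_class == cl]
    pool <- pool[sample.int(nrow(pool))]
    pool <- pool[!duplicated(paste(chrom, pos))]
    pool <- pool[!paste(chrom, pos) %in% used]
    nreq <- spec$class_n_sites[[cl]]
    if (nrow(pool) < nreq)
      stop("not enough candidate sites of class ", cl, ": have ",
           nrow(pool), ", need ", nreq)
    take <- pool[seq_len(nreq), .(chrom, pos, ref, alt)]
    take[, truth_class := cl]
    used <- c(used, paste(take$chrom, take$pos))
    coding[[cl]] <- take
  }
  coding <- if (length(coding)) rbindlist(coding) else
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), truth_class = character())

  ## ---- non-coding filler sites (outside all candidate positions) --------
  n_nc <- round(spec$snp_density * G / 1000)
  blocked <- unique(c(used, paste(candidates$chrom, candidates$pos)))
  nc <- data.table(
    chrom = sample(chroms, n_nc, replace = TRUE,
                   prob = nchar(genome) / G),
    pos = NA_integer_)
  nc[, pos := sample.int(nchar(genome[[chrom[1]]]), .N, replace = FALSE),
     by = chrom]
  nc <- nc[!paste(chrom, pos) %in% blocked]
  nc[, ref := substring(genome[chrom], pos, pos)]
  nc[, alt := vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                     character(1))]
  nc[, truth_class := "noncoding"]

  v <- rbind(coding, nc)
  setorder(v, chrom, pos)
  n <- nrow(v)

  ## ---- per-site derived allele frequencies ------------------------------
  k <- spec$daf_concentration
  m <- spec$class_daf_means[v$truth_class]
  p_base <- rbeta(n, m * k, (1 - m) * k)
  p_wild <- p_base
  p_white <- p_base
  lof <- v$truth_class == "LoF"
  p_white[lof] <- clamp(p_base[lof] * spec$effects$lof_daf_mult, 0, 0.98)
  anc_is_alt <- runif(n) < spec$ancestral_is_alt_frac
  v[, ancestral := ifelse(anc_is_alt, alt, ref)]

  ## ---- samples and planted tracts ---------------------------------------
  samples <- c(sprintf("wild%02d", seq_len(spec$n_samples[["wild"]])),
               sprintf("white%02d", seq_len(spec$n_samples[["white"]])))
  pops <- stats::setNames(rep(c("wild", "white"), spec$n_samples), samples)
  planted <- .plant_tracts(spec, reference, samples, pops)
  truth_roh <- planted$roh

  ## ---- haplotype mosaics, tract overwrite, derived genotypes ------------
  d <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  boost <- spec$effects$roh_missense_boost
  for (ch in chroms) {
    si <- which(v$chrom == ch)
    if (!length(si)) next
    ppos <- v$pos[si]
    qswitch <- 1 - exp(-diff(ppos) / spec$founder_segment_bp)
    for (pp in c("wild", "white")) {
      p_site <- if (pp == "wild") p_wild[si] else p_white[si]
      K <- spec$n_founders[[pp]]
      founders <- matrix(rbinom(K * length(si), 1L, rep(p_site, each = K)),
                         nrow = K)
      halves <- list(seq_len(K %/% 2L), (K %/% 2L + 1L):K)
      for (s in samples[pops == pp]) {
        hap <- lapply(1:2, function(h)
          .mosaic_haplotype(founders, halves[[h]], qswitch))
        ds <- hap[[1]] + hap[[2]]
        ## planted tracts: copy a single fresh haplotype over both
        tr <- truth_roh[sample_id == s & chrom == ch]
        if (nrow(tr)) {
          p_eff <- p_site
          mis <- v$truth_class[si] == "missense"
          p_eff[mis] <- clamp(p_site[mis] * boost, 0, 1)
          for (j in seq_len(nrow(tr))) {
            inside <- which(ppos >= tr$start[j] & ppos <= tr$end[j])
            if (!length(inside)) next
            hcopy <- rbinom(length(inside), 1L, p_eff[inside])
            dd <- 2L * hcopy
            leak <- runif(length(inside)) < spec$het_leak
            dd[leak] <- 1L
            ds[inside] <- dd
          }
        }
        d[si, s] <- ds
      }
    }
  }

  ## ---- excess missense homozygosity in the white-type population --------
  hb <- spec$effects$hom_missense_boost
  if (hb > 0) {
    mis_rows <- which(v$truth_class == "missense")
    white_cols <- which(pops[colnames(d)] == "white")
    if (length(mis_rows) && length(white_cols)) {
      sub <- d[mis_rows, white_cols, drop = FALSE]
      conv <- sub == 1L & matrix(runif(length(sub)) < hb, nrow(sub))
      sub[conv] <- 2L
      d[mis_rows, white_cols] <- sub
    }
  }

  ## ---- ALT-dosage genotypes, missingness, depth -------------------------
  geno <- d
  flip <- which(anc_is_alt)
  if (length(flip)) geno[flip, ] <- 2L - geno[flip, ]
  miss_rate <- rep(spec$qc$base_missing_rate, n)
  high_miss <- runif(n) < spec$qc$high_missing_frac
  miss_rate[high_miss] <- spec$qc$high_missing_rate
  drop <- matrix(runif(n * ncol(geno)) < miss_rate, n)
  geno[drop] <- NA_integer_
  dp <- matrix(rpois(n * ncol(geno), spec$qc$mean_depth), n,
               dimnames = list(NULL, samples))

  ## ---- QUAL / INFO metrics with planted failure fractions ---------------
  met <- .draw_qc_metrics(n, spec$qc$fail_frac)
  v[, `:=`(qual = met$values$QUAL, QD = met$values$QD, FS = met$values$FS,
           MQ = met$values$MQ, MQRankSum = met$values$MQRankSum,
           ReadPosRankSum = met$values$ReadPosRankSum,
           site_depth = rowSums(dp))]

  ## ---- realized derived allele frequencies (truth) ----------------------
  daf_of <- function(cols) {
    sub <- d[, cols, drop = FALSE]
    called <- rowSums(!is.na(geno[, cols, drop = FALSE]))
    num <- rowSums(sub * !is.na(geno[, cols, drop = FALSE]))
    ifelse(called > 0, num / (2 * called), NA_real_)
  }
  truth_variants <- data.table(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    truth_class = v$truth_class, ancestral = v$ancestral,
    p_wild = p_wild, p_white = p_white,
    daf_wild = daf_of(which(pops[samples] == "wild")),
    daf_white = daf_of(which(pops[samples] == "white")),
    high_missing = high_miss)
  truth_variants <- cbind(truth_variants, met$fails)

  ## ---- outgroup alleles --------------------------------------------------
  og <- matrix(v$ancestral, n, 4L)
  for (j in 1:4) {
    div <- runif(n) < spec$outgroup_divergence
    if (any(div)) {
      og[div, j] <- vapply(v$ancestral[div], function(a)
        sample(setdiff(DNA_BASES, a), 1L), character(1))
    }
    gone <- runif(n) < spec$outgroup_missing
    og[gone, j] <- "."
  }
  outgroups <- data.table(chrom = v$chrom, pos = v$pos,
                          og1 = og[, 1], og2 = og[, 2],
                          og3 = og[, 3], og4 = og[, 4])

  ## ---- spice in non-SNP records (dropped by biallelic-SNP selection) ----
  spice <- .spice_records(spec, reference, blocked = c(blocked,
                                                       paste(v$chrom, v$pos)),
                          samples = samples)
  if (nrow(spice$variants)) {
    v_all <- rbind(v[, .(chrom, pos, ref, alt, qual, QD, FS, MQ, MQRankSum,
                         ReadPosRankSum, site_depth)],
                   spice$variants)
    geno_all <- rbind(geno, spice$geno)
    dp_all <- rbind(dp, matrix(rpois(nrow(spice$geno) * ncol(geno),
                                     spec$qc$mean_depth),
                               nrow(spice$geno)))
    ord <- order(v_all$chrom, v_all$pos)
    v_all <- v_all[ord]; geno_all <- geno_all[ord, , drop = FALSE]
    dp_all <- dp_all[ord, , drop = FALSE]
  } else {
    v_all <- v[, .(chrom, pos, ref, alt, qual, QD, FS, MQ, MQRankSum,
                   ReadPosRankSum, site_depth)]
    geno_all <- geno; dp_all <- dp
  }
  attr(geno_all, "dp") <- dp_all
  vs <- variant_set(v_all, geno_all, pops)

  ## ---- candidate-gene list ----------------------------------------------
  genes <- reference$models$transcripts$gene_id
  cand_genes <- data.table(
    gene_name = sprintf("candidate%d",
                        seq_len(min(spec$n_candidate_genes, length(genes)))),
    gene_id = if (length(genes))
      sample(genes, min(spec$n_candidate_genes, length(genes)))
    else character())

  structure(list(vs = vs, outgroups = outgroups,
                 truth = list(variants = truth_variants, roh = truth_roh,
                              f_targets = planted$targets,
                              n_spice = nrow(spice$variants)),
                 sample_map = data.table(sample_id = samples,
                                         population = unname(pops)),
                 candidate_genes = cand_genes, spec = spec, seed = seed),
            class = "sim_data")
}

#' One mosaic haplotype over a founder matrix.
#' @noRd
.mosaic_haplotype <- function(founders, pool, qswitch) {
  S <- ncol(founders)
  if (S == 1L) return(founders[sample(pool, 1L), ])
  sw <- c(TRUE, runif(S - 1L) < qswitch)
  seg <- cumsum(sw)
  fid <- sample(pool, max(seg), replace = TRUE)
  founders[cbind(fid[seg], seq_len(S))]
}

#' Plant non-overlapping autozygous intervals per sample.
#' @noRd
.plant_tracts <- function(spec, reference, samples, pops) {
  G <- sum(reference$chrom_lengths)
  out <- list()
  targets <- data.table(sample_id = samples, f_target = 0)
  for (s in samples) {
    tf <- spec$target_f_roh[[pops[[s]]]]
    ft <- if (tf[["mean"]] == 0 && tf[["sd"]] == 0) 0 else
      clamp(rnorm(1, tf[["mean"]], tf[["sd"]]), 0, 0.45)
    targets[sample_id == s, f_target := ft]
    target_bp <- round(ft * G)
    placed <- data.table(chrom = character(), start = integer(),
                         end = integer())
    total <- 0L
    tries <- 0L
    if (spec$roh_length_range[1] > max(reference$chrom_lengths))
      stop("requested tract longer than chromosome")
    ## tracts are kept >= 50 kb apart within a sample: two nearby autozygous
    ## intervals are effectively one IBD segment, and a sliding-window
    ## detector would merge them, making the planted truth ambiguous
    min_sep <- 5e4
    place_one <- function(len) {
      ch <- sample(names(reference$chrom_lengths), 1L,
                   prob = reference$chrom_lengths)
      if (len > reference$chrom_lengths[[ch]]) return(FALSE)
      st <- sample.int(reference$chrom_lengths[[ch]] - len + 1L, 1L)
      en <- st + len - 1L
      if (nrow(placed[chrom == ch & start <= en + min_sep &
                        end >= st - min_sep])) return(FALSE)
      placed <<- rbind(placed, data.table(chrom = ch, start = st, end = en))
      total <<- total + len
      TRUE
    }
    while (target_bp - total >= 2e4 && tries < 500L) {
      tries <- tries + 1L
      remaining <- target_bp - total
      hi <- min(spec$roh_length_range[2], remaining)
      lo <- min(spec$roh_length_range[1], hi)
      len <- round(runif(1, lo, hi))
      ## keep planted lengths away from the 100 kb reporting threshold so
      ## that truth and detection agree on length-class membership
      if (len >= 8e4 && len <= 1.3e5 && len < spec$roh_length_range[1]) {
        half <- len %/% 2L
        place_one(half)
        place_one(len - half)
      } else {
        place_one(len)
      }
    }
    if (nrow(placed)) {
      placed[, sample_id := s]
      out[[s]] <- placed
    }
  }
  roh <- if (length(out)) {
    res <- rbindlist(out)[, .(sample_id, chrom, start, end)]
    setorder(res, sample_id, chrom, start)
    res
  } else {
    data.table(sample_id = character(), chrom = character(),
               start = integer(), end = integer())
  }
  list(roh = roh, targets = targets)
}

#' Draw QUAL/INFO metrics from pass/fail mixtures.
#' @noRd
.draw_qc_metrics <- function(n, fail_frac) {
  ranges <- list(
    QUAL = list(pass = c(40, 100), fail = c(5, 29.99)),
    QD = list(pass = c(5, 30), fail = c(0, 1.99)),
    FS = list(pass = c(0, 20), fail = c(60.01, 150)),
    MQ = list(pass = c(45, 60), fail = c(10, 39.99)),
    MQRankSum = list(pass = c(-3, 3), fail = c(-20, -12.51)),
    ReadPosRankSum = list(pass = c(-3, 3), fail = c(-15, -8.01)))
  values <- list()
  fails <- data.table(row_id = seq_len(n))
  for (mname in names(ranges)) {
    f <- runif(n) < fail_frac[[mname]]
    x <- runif(n, ranges[[mname]]$pass[1], ranges[[mname]]$pass[2])
    if (any(f)) x[f] <- runif(sum(f), ranges[[mname]]$fail[1],
                              ranges[[mname]]$fail[2])
    values[[mname]] <- x
    fails[[paste0("fail_", mname)]] <- f
  }
  fails[, row_id := NULL]
  list(values = values, fails = fails)
}

#' Non-SNP records that the biallelic-SNP selection must drop.
#' @noRd
.spice_records <- function(spec, reference, blocked, samples) {
  G <- sum(reference$chrom_lengths)
  n_ind <- round(spec$qc$indel_frac * spec$snp_density * G / 1000)
  n_mul <- round(spec$qc$multiallelic_frac * spec$snp_density * G / 1000)
  ntot <- n_ind + n_mul
  if (ntot == 0L) {
    return(list(variants = data.table(chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      qual = numeric(), QD = numeric(),
                                      FS = numeric(), MQ = numeric(),
                                      MQRankSum = numeric(),
                                      ReadPosRankSum = numeric(),
                                      site_depth = numeric()),
                geno = matrix(integer(), 0L, length(samples),
                              dimnames = list(NULL, samples))))
  }
  chroms <- names(reference$chrom_lengths)
  dt <- data.table(chrom = sample(chroms, ntot, replace = TRUE,
                                  prob = reference$chrom_lengths))
  dt[, pos := sample.int(reference$chrom_lengths[[chrom[1]]] - 1L, .N),
     by = chrom]
  dt <- dt[!paste(chrom, pos) %in% blocked]
  dt[, ref := substring(reference$genome[chrom], pos, pos)]
  ntot <- nrow(dt)
  n_ind <- min(n_ind, ntot)
  kind <- c(rep("indel", n_ind), rep("multi", ntot - n_ind))
  dt[, alt := ifelse(kind == "indel",
                     paste0(ref, sample(DNA_BASES, .N, replace = TRUE)),
                     vapply(ref, function(r)
                       paste(sample(setdiff(DNA_BASES, r), 2L),
                             collapse = ","), character(1)))]
  met <- .draw_qc_metrics(nrow(dt), stats::setNames(rep(0, 6),
    c("QUAL", "QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")))
  dt[, `:=`(qual = met$values$QUAL, QD = met$values$QD, FS = met$values$FS,
            MQ = met$values$MQ, MQRankSum = met$values$MQRankSum,
            ReadPosRankSum = met$values$ReadPosRankSum,
            site_depth = rpois(nrow(dt),
                               spec$qc$mean_depth * length(samples)))]
  list(variants = dt[, .(chrom, pos, ref, alt, qual, QD, FS, MQ, MQRankSum,
                         ReadPosRankSum, site_depth)],
       geno = matrix(0L, nrow(dt), length(samples),
                     dimnames = list(NULL, samples)))
}

#' Write every artefact of a simulation to a directory
#'
#' Emits reference FASTA, gene-model GFF3, the multi-sample VCF, the
#' outgroup-allele TSV, the sample map, candidate-gene list and truth tables
#' as plain text files.
#'
#' @param sim a `sim_data` object from [simulate_populations()].
#' @param reference the matching [generate_reference()] output.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_data <- function(sim, reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(reference$genome, file.path(dir, "reference.fa"))
  write_gff3(reference$models, file.path(dir, "genes.gff3"))
  write_vcf(sim$vs, file.path(dir, "variants.vcf"),
            contigs = reference$chrom_lengths)
  fwrite(sim$outgroups, file.path(dir, "outgroups.tsv"), sep = "\t")
  fwrite(sim$sample_map, file.path(dir, "samples.tsv"), sep = "\t")
  fwrite(sim$candidate_genes, file.path(dir, "candidate_genes.tsv"),
         sep = "\t")
  fwrite(sim$truth$variants, file.path(dir, "truth_variants.tsv"), sep = "\t")
  fwrite(sim$truth$roh, file.path(dir, "truth_roh.tsv"), sep = "\t")
  invisible(dir)
}
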