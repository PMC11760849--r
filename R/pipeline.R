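# End-to-end orchestration: simulate -> qc -> annotate -> polarize -> roh ->
# load -> diversity -> report, from a single config and seed. Stages hand
# off plain files (VCF / TSV / BED) under the output directory so each one
# is independently replaceable with real data, but the in-memory bundle is
# also returned for programmatic use.

#' Pipeline configuration
#'
#' @param spec a [sim_spec()] describing the synthetic cohort.
#' @param outdir output directory (NULL: nothing is written).
#' @param roh a [roh_params()]. The pipeline default keeps the detection
#'   profile (window 20 SNPs, 10 kb floor, 50 kb/SNP density) but sets
#'   `min_snp = 25`, since PLINK's 100-SNP minimum cannot co-exist with a
#'   10 kb length floor at the simulated SNP density (100 SNPs span about
#'   67 kb at 1.5 SNPs/kb).
#' @param stages character vector of stages to run, in dependency order.
#' @param qc_tail_fraction,qc_max_missing QC cascade parameters.
#' @param include_focal_ref,min_support polarization parameters.
#' @param pi_window window for nucleotide diversity (bp).
#' @param ld_max_dist,ld_bin_width LD decay parameters (bp).
#' @param candidate_flank_bp flank for the candidate-gene screen.
#' @param froh_min_length minimum segment length entering the headline
#'   F_ROH (bp; the default 1e5 mirrors reporting F_ROH for ROHs above
#'   100 kb, which also screens out the short chance segments a
#'   window-based detector emits at a 10 kb floor).
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(spec = sim_spec(), outdir = NULL,
                            roh = roh_params(min_snp = 25L),
                            stages = c("simulate", "qc", "annotate",
                                       "polarize", "roh", "load",
                                       "diversity", "report"),
                            qc_tail_fraction = 0.0025,
                            qc_max_missing = 0.10,
                            include_focal_ref = TRUE, min_support = 3L,
                            pi_window = 500000L,
                            ld_max_dist = 100000L, ld_bin_width = 5000L,
                            candidate_flank_bp = 10000L,
                            froh_min_length = 1e5) {
  structure(list(spec = spec, outdir = outdir, roh = roh, stages = stages,
                 qc_tail_fraction = qc_tail_fraction,
                 qc_max_missing = qc_max_missing,
                 include_focal_ref = include_focal_ref,
                 min_support = min_support, pi_window = pi_window,
                 ld_max_dist = ld_max_dist, ld_bin_width = ld_bin_width,
                 candidate_flank_bp = candidate_flank_bp,
                 froh_min_length = froh_min_length),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @param reference optional pre-built [generate_reference()] output
#'   (rebuilt from the spec otherwise).
#' @param candidates optional cached [enumerate_coding_candidates()] table.
#' @return a list bundle with one element per executed stage.
#' @export
run_pipeline <- function(config, reference = NULL, candidates = NULL) {
  stopifnot(inherits(config, "run_config"))
  on <- function(s) s %in% config$stages
  out <- list(config = config)
  if (!length(config$stages)) return(structure(out, class = "run_bundle"))
  odir <- config$outdir
  if (!is.null(odir)) dir.create(odir, recursive = TRUE,
                                 showWarnings = FALSE)

  if (on("simulate")) {
    if (is.null(reference)) reference <- generate_reference(config$spec)
    sim <- simulate_populations(config$spec, reference,
                                candidates = candidates)
    out$reference <- reference
    out$sim <- sim
    if (!is.null(odir)) write_sim_data(sim, reference, odir)
  } else {
    stop("this run config disables simulation; construct the bundle ",
         "stage-by-stage from files instead")
  }

  if (on("qc")) {
    qc <- qc_cascade(sim$vs, config$qc_tail_fraction, config$qc_max_missing)
    out$qc <- qc
    if (!is.null(odir)) {
      fwrite(qc$report, file.path(odir, "qc_report.tsv"), sep = "\t")
      write_vcf(qc$vs, file.path(odir, "variants.filtered.vcf"),
                contigs = reference$chrom_lengths)
    }
  }

  if (on("annotate")) {
    ann <- classify_variants(out$qc$vs$variants, reference$models,
                             reference$genome)
    out$annotation <- ann
    if (!is.null(odir))
      fwrite(ann, file.path(odir, "annotation.tsv"), sep = "\t")
  }

  if (on("polarize")) {
    anc <- polarize_variants(out$qc$vs, sim$outgroups,
                             include_focal_ref = config$include_focal_ref,
                             min_support = config$min_support)
    spectra <- derived_frequencies(out$qc$vs, anc,
                                   out$annotation$load_class)
    out$ancestral <- anc
    out$spectra <- spectra
    if (!is.null(odir)) {
      fwrite(anc, file.path(odir, "ancestral.tsv"), sep = "\t")
      fwrite(spectra$summary, file.path(odir, "spectra.tsv"), sep = "\t")
    }
  }

  if (on("roh")) {
    segments <- detect_roh_all(out$qc$vs, config$roh)
    froh <- f_roh(segments, reference$chrom_lengths,
                  min_length_filter = config$froh_min_length,
                  samples = out$qc$vs$samples)
    out$roh <- list(segments = segments, froh = froh)
    if (!is.null(odir)) {
      write_roh_bed(segments, file.path(odir, "roh.bed"))
      fwrite(froh, file.path(odir, "froh.tsv"), sep = "\t")
    }
  }

  if (on("load")) {
    membership <- variant_roh_membership(out$qc$vs, out$roh$segments)
    load <- per_individual_load(out$qc$vs, out$ancestral,
                                out$annotation$load_class, membership)
    occ <- occurrence_table(load)
    contrasts <- population_contrasts(load, occ)
    screen <- screen_candidate_genes(out$qc$vs, out$annotation,
                                     out$ancestral, reference$models,
                                     sim$candidate_genes,
                                     config$candidate_flank_bp)
    out$load <- list(summary = load, occurrence = occ,
                     contrasts = contrasts, candidate_screen = screen,
                     membership = membership)
    if (!is.null(odir)) {
      fwrite(load, file.path(odir, "load_summary.tsv"), sep = "\t")
      fwrite(occ, file.path(odir, "occurrence.tsv"), sep = "\t")
      fwrite(contrasts, file.path(odir, "contrasts.tsv"), sep = "\t")
      fwrite(screen, file.path(odir, "candidate_screen.tsv"), sep = "\t")
    }
  }

  if (on("diversity")) {
    pops <- unique(out$qc$vs$populations)
    pi_tabs <- lapply(pops, function(pp)
      cbind(population = pp,
            windowed_pi(out$qc$vs, reference$chrom_lengths,
                        config$pi_window,
                        samples = names(out$qc$vs$populations)[
                          out$qc$vs$populations == pp])))
    names(pi_tabs) <- pops
    het <- individual_heterozygosity(out$qc$vs)
    ld_tabs <- lapply(pops, function(pp)
      cbind(population = pp,
            ld_decay(out$qc$vs, config$ld_max_dist, config$ld_bin_width,
                     samples = names(out$qc$vs$populations)[
                       out$qc$vs$populations == pp])))
    names(ld_tabs) <- pops
    hf <- het_froh_relationship(het, out$roh$froh)
    out$diversity <- list(pi = rbindlist(pi_tabs), het = het,
                          ld = rbindlist(ld_tabs), het_froh = hf)
    if (!is.null(odir)) {
      fwrite(out$diversity$pi, file.path(odir, "pi_windows.tsv"), sep = "\t")
      fwrite(het, file.path(odir, "heterozygosity.tsv"), sep = "\t")
      fwrite(out$diversity$ld, file.path(odir, "ld_decay.tsv"), sep = "\t")
    }
  }

  if (on("report")) {
    out$report <- build_report(out)
    if (!is.null(odir))
      writeLines(out$report, file.path(odir, "report.md"))
  }
  structure(out, class = "run_bundle")
}

#' Standard between-population and inside/outside-ROH contrasts.
#'
#' @param load,occ tables from [per_individual_load()] /
#'   [occurrence_table()].
#' @param p_adjust multiple-testing correction across the contrast panel:
#'   `"none"` (default, per-panel reporting convention) or any
#'   [stats::p.adjust()] method such as `"BH"`. Tiers are recomputed from
#'   the adjusted p-values.
#' @return data.table of contrasts.
#' @export
population_contrasts <- function(load, occ, p_adjust = "none") {
  res <- .population_contrasts(load, occ)
  if (!identical(p_adjust, "none")) {
    res[, p_value := stats::p.adjust(p_value, method = p_adjust)]
    res[, tier := significance_tier(p_value)]
  }
  res[]
}

#' @noRd
.population_contrasts <- function(load, occ) {
  rows <- list()
  gw <- load[region == "genome"]
  for (cl in setdiff(LOAD_CLASSES, "synonymous")) {
    sub <- gw[class_ == cl]
    rows[[length(rows) + 1L]] <- compare_populations(
      sub$allele_count, sub$population,
      statistic = paste0("total_", cl, "_alleles"))
    rows[[length(rows) + 1L]] <- compare_populations(
      sub$hom_ratio, sub$population,
      statistic = paste0("hom_ratio_", cl))
    og <- occ[region == "genome" & class_ == cl]
    rows[[length(rows) + 1L]] <- compare_populations(
      og$occurrence, og$population,
      statistic = paste0("occurrence_", cl))
    oin <- occ[region == "inside" & class_ == cl]
    oout <- occ[region == "outside" & class_ == cl]
    m <- merge(oin[, .(sample_id, x = occurrence)],
               oout[, .(sample_id, y = occurrence)], by = "sample_id")
    m <- m[complete.cases(m)]
    if (nrow(m) >= 2L) {
      rows[[length(rows) + 1L]] <- compare_populations(
        m$x, values2 = m$y,
        statistic = paste0("occurrence_", cl, "_inside_vs_outside"))
    }
  }
  rbindlist(rows)
}

#' Assemble the markdown report
#'
#' Surfaces per-class consequence counts, derived-allele-frequency spectra,
#' occurrence contrasts, the F_ROH length-class decomposition, and
#' inside/outside-ROH occurrence.
#'
#' @param bundle a run bundle from [run_pipeline()].
#' @return character vector of markdown lines.
#' @export
build_report <- function(bundle) {
  fmt_tab <- function(dt) {
    dt <- as.data.table(dt)
    num <- vapply(dt, is.numeric, logical(1))
    for (cc in names(dt)[num]) dt[[cc]] <- formatC(dt[[cc]], format = "g",
                                                   digits = 5)
    c(paste(names(dt), collapse = " | "),
      paste(rep("---", ncol(dt)), collapse = " | "),
      apply(dt, 1L, paste, collapse = " | "), "")
  }
  lines <- c("# Mutational load analysis report", "")
  if (!is.null(bundle$qc)) {
    lines <- c(lines, "## Variant QC cascade", "",
               fmt_tab(bundle$qc$report))
  }
  if (!is.null(bundle$annotation)) {
    counts <- bundle$annotation[, .N, by = category][order(-N)]
    lc <- bundle$annotation[, .N, by = load_class][order(-N)]
    lines <- c(lines, "## Consequence categories", "", fmt_tab(counts),
               "## Load classes", "", fmt_tab(lc))
  }
  if (!is.null(bundle$spectra)) {
    lines <- c(lines, "## Derived allele frequency spectra", "",
               fmt_tab(bundle$spectra$summary))
  }
  if (!is.null(bundle$roh)) {
    cls <- f_roh_by_class(bundle$roh$segments,
                          bundle$reference$chrom_lengths)
    lines <- c(lines, "## F_ROH per sample", "", fmt_tab(bundle$roh$froh),
               "## F_ROH by length class", "", fmt_tab(cls))
  }
  if (!is.null(bundle$load)) {
    lines <- c(lines, "## Population contrasts", "",
               fmt_tab(bundle$load$contrasts),
               "## Candidate-gene screen", "",
               fmt_tab(bundle$load$candidate_screen))
  }
  if (!is.null(bundle$diversity)) {
    pi_sum <- bundle$diversity$pi[, .(mean_pi = mean(pi_window)),
                                  by = population]
    lines <- c(lines, "## Nucleotide diversity", "", fmt_tab(pi_sum))
  }
  lines
}
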