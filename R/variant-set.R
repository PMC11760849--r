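# A variant set couples a table of site records (position, alleles, QUAL,
# INFO metrics, summed depth) with a genotype matrix of ALT-allele dosages
# (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing), one column per sample,
# and a sample -> population map.

#' Construct a variant set
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual` and optionally `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`,
#'   `site_depth`.
#' @param geno integer matrix (variants x samples) of ALT dosages with NA for
#'   missing genotypes.
#' @param populations named character vector mapping sample id -> population.
#' @return object of class `variant_set`.
#' @export
variant_set <- function(variants, geno, populations) {
  v <- as.data.table(variants)
  stopifnot(nrow(v) == nrow(geno))
  if (ncol(geno) > 0L && is.null(colnames(geno)))
    stop("genotype matrix must have sample names")
  if (!all(colnames(geno) %in% names(populations)))
    stop("every sample needs a population assignment")
  structure(list(variants = v, geno = geno,
                 samples = colnames(geno),
                 populations = populations[colnames(geno)]),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "records x", length(x$samples),
      "samples (", paste(names(table(x$populations)),
                         table(x$populations), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

#' Subset a variant set by record index
#' @param vs a [variant_set()].
#' @param idx integer or logical index over records.
#' @export
subset_variants <- function(vs, idx) {
  variant_set(vs$variants[idx], vs$geno[idx, , drop = FALSE], vs$populations)
}

#' Number of records in a variant set
#' @param vs a [variant_set()].
#' @export
n_variants <- function(vs) nrow(vs$variants)

#' Write a variant set as VCF v4.2
#'
#' QD/FS/MQ/MQRankSum/ReadPosRankSum and summed DP go into INFO; genotypes
#' are emitted as unphased GT (plus per-sample DP when a depth matrix is
#' attached as `attr(vs$geno, "dp")`).
#'
#' @param vs a [variant_set()].
#' @param path output path (plain text; use a .vcf suffix).
#' @param contigs optional named vector of contig lengths for the header.
#' @export
write_vcf <- function(vs, path, contigs = NULL) {
  v <- vs$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohload")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Summed sample depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g",
                                                      digits = 6))
  info_field <- function(name, x) {
    out <- paste0(name, "=", fmt_num(x))
    out[is.na(x)] <- NA
    out
  }
  parts <- cbind(info_field("DP", v$site_depth), info_field("QD", v$QD),
                 info_field("FS", v$FS), info_field("MQ", v$MQ),
                 info_field("MQRankSum", v$MQRankSum),
                 info_field("ReadPosRankSum", v$ReadPosRankSum))
  info <- apply(parts, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else "."
  })
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(v), length(vs$samples))
  ok <- !is.na(vs$geno)
  gt[ok] <- gt_code[as.character(vs$geno[ok])]
  dp <- attr(vs$geno, "dp")
  if (!is.null(dp)) {
    gt <- matrix(paste0(gt, ":", dp), nrow(v))
    fmt <- "GT:DP"
  } else fmt <- "GT"
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt,
                fmt_num(v$qual), "PASS", info, fmt,
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant set
#'
#' Parsing is delegated to vcfR; QD/FS/MQ/MQRankSum/ReadPosRankSum and DP are
#' pulled from INFO, genotypes from GT (half-missing diploid calls count as
#' missing).
#'
#' @param path VCF file (optionally bgzipped).
#' @param populations named character vector sample -> population; samples
#'   missing from it are assigned population "unknown".
#' @return a [variant_set()].
#' @export
read_vcf <- function(path, populations = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(vc))
  num <- function(key) {
    x <- vcfR::extract.info(vc, element = key, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else as.numeric(x)
  }
  v <- data.table(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT,
                  qual = suppressWarnings(as.numeric(fix$QUAL)),
                  QD = num("QD"), FS = num("FS"), MQ = num("MQ"),
                  MQRankSum = num("MQRankSum"),
                  ReadPosRankSum = num("ReadPosRankSum"),
                  site_depth = num("DP"))
  gt <- vcfR::extract.gt(vc, element = "GT")
  geno <- matrix(NA_integer_, nrow(v), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  geno[clean %in% c("0/0")] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean %in% c("1/1")] <- 2L
  if (is.null(populations)) {
    populations <- stats::setNames(rep("unknown", ncol(gt)), colnames(gt))
  } else {
    missing <- setdiff(colnames(gt), names(populations))
    if (length(missing))
      populations <- c(populations,
                       stats::setNames(rep("unknown", length(missing)),
                                       missing))
  }
  variant_set(v, geno, populations)
}
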