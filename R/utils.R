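#' @noRd
DNA_BASES <- c("A", "C", "G", "T")

#' Complement of DNA bases (vectorised, character)
#' @noRd
comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Reverse complement of a DNA string
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Standard genetic code as a named character vector (codon -> one-letter AA,
#' "*" for stop), taken from Biostrings.
#' @noRd
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Translate an in-frame coding sequence to a protein string (stops as "*").
#' @noRd
translate_cds <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3: ", n)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(codon_table()[codons], collapse = "")
}

#' Split a total length into k parts, each at least `min_part`.
#' @noRd
split_length <- function(total, k, min_part) {
  if (total < k * min_part) stop("cannot split ", total, " into ", k,
                                 " parts of at least ", min_part)
  extra <- total - k * min_part
  if (k == 1L) return(total)
  cuts <- sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cuts, extra))
  as.integer(parts + min_part)
}

#' Clamp numeric values into [lo, hi]
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Significance tier from a p-value, using the conventional star thresholds.
#'
#' @param p numeric vector of p-values.
#' @return character vector in `c("ns", "*", "**", "***", "****")`.
#' @export
significance_tier <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05]   <- "*"
  out[p < 0.01]   <- "**"
  out[p < 0.001]  <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)]   <- NA_character_
  out
}
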