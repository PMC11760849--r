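# Grantham (1974) physicochemical distance between amino acids:
#   D(i, j) = rho * [alpha (c_i - c_j)^2 + beta (p_i - p_j)^2
#                    + gamma (v_i - v_j)^2]^(1/2)
# where c is side-chain composition (atomic weight ratio of non-carbon
# elements), p is polarity and v is molecular volume. rho normalises the
# mean distance over the 190 unordered pairs to exactly 100. Note the
# historical printed table deviates by +-1 from its own formula for a few
# pairs; this package treats the formula as authoritative (it reproduces the
# printed minimum 5 for Leu-Ile, the maximum 215 for Trp-Cys, and the mean).

#' Amino-acid property table used by the Grantham distance
#'
#' Side-chain composition (`c`), polarity (`p`) and molecular volume (`v`)
#' for the 20 standard amino acids, plus the weighting constants
#' `alpha`, `beta`, `gamma` and the normalisation factor `rho` that fixes the
#' mean pairwise distance at 100.
#'
#' @return A list with elements `properties` (data.frame with rownames =
#'   one-letter amino-acid codes and columns `c`, `p`, `v`), `alpha`, `beta`,
#'   `gamma`, and `rho`.
#' @export
grantham_tables <- function() {
  aa <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
          "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
  props <- data.frame(
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    row.names = aa
  )
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
  d2 <- function(x) outer(x, x, "-")^2
  raw <- sqrt(alpha * d2(props$c) + beta * d2(props$p) + gamma * d2(props$v))
  rho <- 100 / mean(raw[upper.tri(raw)])
  list(properties = props, alpha = alpha, beta = beta, gamma = gamma, rho = rho)
}

#' Full 20 x 20 Grantham distance matrix
#'
#' Distances are rounded to the nearest integer, symmetric, and zero on the
#' diagonal. Row/column names are one-letter amino-acid codes.
#'
#' @param tables output of [grantham_tables()]; recomputed if missing.
#' @return integer matrix.
#' @export
grantham_matrix <- function(tables = grantham_tables()) {
  props <- tables$properties
  d2 <- function(x) outer(x, x, "-")^2
  raw <- sqrt(tables$alpha * d2(props$c) + tables$beta * d2(props$p) +
                tables$gamma * d2(props$v))
  m <- round(tables$rho * raw)
  mode(m) <- "integer"
  dimnames(m) <- list(rownames(props), rownames(props))
  m
}

#' Grantham distance between two amino acids
#'
#' @param aa_from,aa_to one-letter codes of standard amino acids (vectorised).
#' @param tables output of [grantham_tables()].
#' @return integer vector of distances; 0 for identical amino acids.
#' @examples
#' grantham_distance("L", "I")  # 5, the matrix minimum
#' grantham_distance("W", "C")  # 215, the matrix maximum
#' @export
grantham_distance <- function(aa_from, aa_to, tables = grantham_tables()) {
  m <- grantham_matrix(tables)
  bad <- !(aa_from %in% rownames(m)) | !(aa_to %in% rownames(m))
  if (any(bad)) {
    stop("not a standard amino acid: ",
         paste(unique(c(aa_from[bad], aa_to[bad])), collapse = ", "),
         " (stop codons are not scored)")
  }
  m[cbind(aa_from, aa_to)]
}
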