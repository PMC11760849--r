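# Functional-consequence classification of biallelic SNPs against gene
# models. Region tests (flank / UTR / intron / splice windows) are followed
# by codon comparison on the coding strand; multi-transcript overlaps are
# resolved by a fixed most-severe-first precedence. Splice windows follow
# the SnpEff convention: acceptor = last 2 intronic bases before an exon,
# donor = first 2 intronic bases after an exon (transcription orientation),
# splice region = intronic bases 3-8 or exonic bases 1-3 from the junction.

#' Consequence categories in precedence order (most severe first)
#' @export
CONSEQUENCE_LEVELS <- c(
  "splice_acceptor", "splice_donor", "stop_gained",
  "start_lost", "stop_lost", "stop_retained",
  "missense", "synonymous", "splice_region",
  "UTR", "intron", "upstream", "downstream", "ncRNA", "intergenic")

#' Classify SNP consequences against gene models
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (single upper-case bases).
#' @param models a [gene_models()] object.
#' @param genome named character vector of chromosome sequences.
#' @param flank upstream/downstream flank in bp (default 5000, the SnpEff
#'   convention).
#' @param splice_intronic intronic splice windows: bases 1..`[1]` are
#'   donor/acceptor sites, bases up to `[2]` are splice region.
#' @param splice_exonic exonic splice-region width in bases.
#' @param check_ref verify that the reference base at each position matches
#'   the `ref` allele (error naming the first offending site).
#' @param tables Grantham tables, see [grantham_tables()].
#' @return data.table: one row per variant with the canonical (most severe)
#'   `category`, `tx_id`, `gene_id`, `codon_ref`/`codon_alt`,
#'   `aa_ref`/`aa_alt`, `grantham` (missense only) and `load_class`.
#' @export
classify_variants <- function(variants, models, genome, flank = 5000L,
                              splice_intronic = c(2L, 8L),
                              splice_exonic = 3L,
                              check_ref = TRUE,
                              tables = grantham_tables()) {
  v <- as.data.table(variants)[, .(chrom, pos = as.integer(pos), ref, alt)]
  if (nrow(v) == 0L) {
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), category = character(),
                      tx_id = character(), gene_id = character(),
                      codon_ref = character(), codon_alt = character(),
                      aa_ref = character(), aa_alt = character(),
                      grantham = integer(), load_class = character()))
  }
  if (check_ref) {
    gbase <- substring(genome[v$chrom], v$pos, v$pos)
    bad <- which(gbase != v$ref)
    if (length(bad)) {
      stop(sprintf("reference mismatch at %s:%d (genome %s, record %s)",
                   v$chrom[bad[1]], v$pos[bad[1]], gbase[bad[1]],
                   v$ref[bad[1]]))
    }
  }
  v[, key_ := .I]

  tx <- models$transcripts
  hits <- list()
  for (i in seq_len(nrow(tx))) {
    t1 <- tx[i]
    sel <- v[chrom == t1$chrom & pos >= t1$start - flank &
               pos <= t1$end + flank]
    if (!nrow(sel)) next
    res <- .classify_against_tx(sel, t1, models, genome, flank,
                                splice_intronic, splice_exonic)
    hits[[length(hits) + 1L]] <- res
  }
  ct <- codon_table()
  if (length(hits)) {
    h <- rbindlist(hits)
    h[, prec := match(category, CONSEQUENCE_LEVELS)]
    setorder(h, key_, prec, tx_id)
    best <- h[, .SD[1L], by = key_]
  } else {
    best <- data.table(key_ = integer(), category = character(),
                       tx_id = character(), gene_id = character(),
                       codon_ref = character(), codon_alt = character(),
                       aa_ref = character(), aa_alt = character(),
                       prec = integer())
  }
  out <- merge(v, best, by = "key_", all.x = TRUE, suffixes = c("", ".h"))
  out[is.na(category), category := "intergenic"]
  out[, grantham := NA_integer_]
  mi <- which(out$category == "missense")
  if (length(mi)) {
    out[mi, grantham := grantham_distance(aa_ref, aa_alt, tables)]
  }
  out[, load_class := assign_load_category(category, grantham)]
  setorder(out, key_)
  out[, intersect(c("key_", "prec"), names(out)) := NULL]
  out[]
}

#' Classify a single SNP (scalar convenience wrapper)
#' @inheritParams classify_variants
#' @param chrom,pos,ref,alt the variant.
#' @return one-row data.table, see [classify_variants()].
#' @export
classify_site <- function(chrom, pos, ref, alt, models, genome, ...) {
  classify_variants(data.table(chrom = chrom, pos = pos, ref = ref,
                               alt = alt), models, genome, ...)
}

#' @noRd
.classify_against_tx <- function(sel, t1, models, genome, flank,
                                 splice_intronic, splice_exonic) {
  ex <- models$exons[tx_id == t1$tx_id]
  setorder(ex, start)
  ne <- nrow(ex)
  P <- sel$pos
  n <- length(P)
  cat <- rep(NA_character_, n)
  codon_ref <- codon_alt <- aa_ref <- aa_alt <- rep(NA_character_, n)

  left <- P < t1$start; right <- P > t1$end
  if (t1$strand == "+") {
    cat[left] <- "upstream"; cat[right] <- "downstream"
  } else {
    cat[left] <- "downstream"; cat[right] <- "upstream"
  }
  inspan <- !left & !right

  if (!t1$coding) {
    cat[inspan] <- "ncRNA"
  } else {
    cd <- models$cds[tx_id == t1$tx_id]
    setorder(cd, start)
    cds_cum <- cumsum(c(0L, cd$end - cd$start + 1L))
    L <- cds_cum[length(cds_cum)]
    coding_seq <- transcript_cds_seq(models, t1$tx_id, genome)
    ct <- codon_table()

    ei <- findInterval(P, ex$start)
    in_exon <- inspan & ei >= 1L & P <= ex$end[pmax(ei, 1L)]
    intronic <- inspan & !in_exon

    ## --- introns: splice donor / acceptor / region by junction distance ---
    ii <- which(intronic)
    if (length(ii)) {
      k <- ei[ii]                       # intron follows exon k (genomic)
      istart <- ex$end[k] + 1L
      iend <- ex$start[k + 1L] - 1L
      if (t1$strand == "+") {
        donor_off <- P[ii] - istart + 1L
        acc_off <- iend - P[ii] + 1L
      } else {
        donor_off <- iend - P[ii] + 1L
        acc_off <- P[ii] - istart + 1L
      }
      icat <- rep("intron", length(ii))
      icat[pmin(donor_off, acc_off) <= splice_intronic[2]] <- "splice_region"
      icat[acc_off <= splice_intronic[1]] <- "splice_acceptor"
      icat[donor_off <= splice_intronic[1]] <- "splice_donor"
      cat[ii] <- icat
    }

    ## --- exons: CDS codon comparison, else UTR / exonic splice region ---
    xi <- which(in_exon)
    if (length(xi)) {
      ci <- findInterval(P[xi], cd$start)
      in_cds <- ci >= 1L & P[xi] <= cd$end[pmax(ci, 1L)]

      ui <- xi[!in_cds]                 # exonic, non-coding: UTR
      if (length(ui)) {
        k <- ei[ui]
        dl <- P[ui] - ex$start[k] + 1L
        dr <- ex$end[k] - P[ui] + 1L
        spl <- (dl <= splice_exonic & k > 1L) |
               (dr <= splice_exonic & k < ne)
        cat[ui] <- ifelse(spl, "splice_region", "UTR")
      }

      ki <- xi[in_cds]                  # coding positions
      if (length(ki)) {
        cii <- ci[in_cds]
        g_off <- cds_cum[cii] + P[ki] - cd$start[cii] + 1L
        cpos <- if (t1$strand == "+") g_off else L - g_off + 1L
        codon_i <- (cpos - 1L) %/% 3L + 1L
        off <- (cpos - 1L) %% 3L + 1L
        cref <- substring(coding_seq, codon_i * 3L - 2L, codon_i * 3L)
        altb <- if (t1$strand == "+") sel$alt[ki] else comp_base(sel$alt[ki])
        calt <- mapply(function(cod, o, b) {
          substr(cod, o, o) <- b; cod
        }, cref, off, altb, USE.NAMES = FALSE)
        ar <- unname(ct[cref]); aa <- unname(ct[calt])
        kcat <- ifelse(ar == aa,
                       ifelse(ar == "*", "stop_retained", "synonymous"),
                ifelse(codon_i == 1L, "start_lost",
                ifelse(aa == "*", "stop_gained",
                ifelse(ar == "*", "stop_lost", "missense"))))
        cat[ki] <- kcat
        codon_ref[ki] <- cref; codon_alt[ki] <- calt
        aa_ref[ki] <- ar; aa_alt[ki] <- aa
      }
    }
  }
  data.table(key_ = sel$key_, category = cat, tx_id = t1$tx_id,
             gene_id = t1$gene_id, codon_ref = codon_ref,
             codon_alt = codon_alt, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Assign a load class to consequence calls
#'
#' Loss-of-function (LoF) collects splice acceptor, splice donor and
#' stop-gained variants; missense changes with a Grantham distance at or
#' above `dns_threshold` are flagged as deleterious nonsynonymous SNPs
#' (dnsSNP), a subset of missense counted separately; remaining missense and
#' synonymous calls keep their names; everything else is `other`.
#'
#' @param category character vector of consequence categories.
#' @param grantham integer vector of Grantham distances (NA unless missense).
#' @param dns_threshold inclusive Grantham threshold for dnsSNP (default 150).
#' @return character vector in
#'   `c("synonymous", "missense", "dnsSNP", "LoF", "other")`.
#' @export
assign_load_category <- function(category, grantham = NA_integer_,
                                 dns_threshold = 150L) {
  out <- rep("other", length(category))
  out[category %in% c("splice_acceptor", "splice_donor", "stop_gained")] <- "LoF"
  mis <- category == "missense"
  out[mis] <- ifelse(!is.na(grantham[mis]) & grantham[mis] >= dns_threshold,
                     "dnsSNP", "missense")
  out[category == "synonymous"] <- "synonymous"
  out
}

#' Enumerate every possible coding-relevant SNP of a reference
#'
#' Lists all single-base substitutions at CDS positions and at the intronic
#' splice-site bases of every transcript, classified with
#' [classify_variants()]. Used by the population simulator to plant variants
#' of known load class.
#'
#' @param reference output of [generate_reference()].
#' @param ... passed to [classify_variants()].
#' @return data.table of candidate variants with consequence annotation.
#' @export
enumerate_coding_candidates <- function(reference, ...) {
  models <- reference$models
  pos_list <- list()
  for (i in seq_len(nrow(models$transcripts))) {
    t1 <- models$transcripts[i]
    cd <- models$cds[tx_id == t1$tx_id]
    ex <- models$exons[tx_id == t1$tx_id]
    setorder(ex, start)
    p <- unlist(lapply(seq_len(nrow(cd)), function(j) cd$start[j]:cd$end[j]))
    if (nrow(ex) > 1L) {
      for (j in seq_len(nrow(ex) - 1L)) {
        istart <- ex$end[j] + 1L; iend <- ex$start[j + 1L] - 1L
        if (iend >= istart) {
          w <- min(2L, iend - istart + 1L)
          p <- c(p, istart:(istart + w - 1L), (iend - w + 1L):iend)
        }
      }
    }
    pos_list[[i]] <- data.table(chrom = t1$chrom, pos = unique(p))
  }
  cand <- unique(rbindlist(pos_list))
  cand[, ref := substring(reference$genome[chrom], pos, pos)]
  cand <- cand[rep(seq_len(.N), each = 3L)]
  cand[, alt := unlist(lapply(ref[seq(1L, .N, 3L)],
                              function(r) setdiff(DNA_BASES, r)))]
  classify_variants(cand, models, reference$genome, ...)
}
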