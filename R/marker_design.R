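#' Reverse complement of a DNA string
#'
#' @param seq character vector of ACGT strings.
#' @return Reverse-complemented string(s).
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Load a nearest-neighbor thermodynamic parameter table
#'
#' The default is the unified duplex parameter set: per-dinucleotide
#' stack enthalpies (kcal/mol) and entropies (cal/mol K), duplex
#' initiation terms for G-C and A-T terminal pairs, and the entropic
#' symmetry correction for self-complementary duplexes.  The table is
#' shipped as an editable TSV so alternative parameter sets can be
#' swapped in.
#'
#' @param path optional TSV with columns `type` (`stack`/`init`/`sym`),
#'   `key`, `dH_kcal`, `dS_cal`.
#' @return A list of class `nn_params` with elements `stack_dH`,
#'   `stack_dS` (named length-16 vectors), `init_dH`, `init_dS` (named
#'   by `GC`/`AT`), `sym_dH`, `sym_dS`.
#' @export
nn_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_unified.tsv", package = "mabctools")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  st <- tab[tab$type == "stack", ]
  if (nrow(st) != 16) stop("NN table must define all 16 dinucleotide stacks")
  stack_dH <- stats::setNames(st$dH_kcal, st$key)
  stack_dS <- stats::setNames(st$dS_cal, st$key)
  for (k in st$key) {
    rc <- revcomp(k)
    if (abs(stack_dH[k] - stack_dH[rc]) > 1e-9 ||
        abs(stack_dS[k] - stack_dS[rc]) > 1e-9) {
      stop("NN table violates complementary-stack symmetry at ", k)
    }
  }
  ini <- tab[tab$type == "init", ]
  sym <- tab[tab$type == "sym", ]
  structure(list(stack_dH = stack_dH, stack_dS = stack_dS,
                 init_dH = stats::setNames(ini$dH_kcal, ini$key),
                 init_dS = stats::setNames(ini$dS_cal, ini$key),
                 sym_dH = sym$dH_kcal[1], sym_dS = sym$dS_cal[1]),
            class = "nn_params")
}

#' Predict the duplex melting temperature of an amplicon
#'
#' Nearest-neighbor model: total enthalpy and entropy are sums of
#' dinucleotide stack terms plus initiation terms for the two terminal
#' base pairs (and a symmetry correction for self-complementary
#' sequences); then
#' `Tm = dH / (dS + R ln(C_T / x)) - 273.15`
#' with `R = 1.9872` cal/(mol K).  The entropy is adjusted for sodium
#' concentration by `0.368 (N-1) ln[Na+]`, an identity at the default
#' 1 M Na+.
#'
#' @param seq DNA string (ACGT, length >= 2).
#' @param na_conc sodium concentration, mol/L.
#' @param strand_conc total strand concentration `C_T`, mol/L
#'   (default 0.25 uM, a typical PCR amplicon concentration).
#' @param nn an [nn_params()] table.
#' @return Melting temperature in degrees Celsius.
#' @export
predict_tm <- function(seq, na_conc = 1.0, strand_conc = 0.25e-6,
                       nn = nn_params()) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2) stop("sequence must have length >= 2")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT characters")
  b <- strsplit(seq, "")[[1]]
  stacks <- paste0(b[-n], b[-1])
  dH <- sum(nn$stack_dH[stacks])
  dS <- sum(nn$stack_dS[stacks])
  ends <- ifelse(b[c(1, n)] %in% c("G", "C"), "GC", "AT")
  dH <- dH + sum(nn$init_dH[ends])
  dS <- dS + sum(nn$init_dS[ends])
  x <- 4
  if (seq == revcomp(seq)) {
    dH <- dH + nn$sym_dH
    dS <- dS + nn$sym_dS
    x <- 1
  }
  dS <- dS + 0.368 * (n - 1) * log(na_conc)
  R <- 1.9872
  1000 * dH / (dS + R * log(strand_conc / x)) - 273.15
}

#' Filter parental variants for HRM marker design
#'
#' Retains INDELs called homozygous in the donor with length at or above
#' the minimum; SNPs and heterozygous calls are discarded.
#'
#' @param variants variant data frame from [make_parents()] or
#'   [read_variants_vcf()].
#' @param min_indel_len minimum INDEL length, bp.
#' @return Filtered variant data frame.
#' @export
filter_variants <- function(variants, min_indel_len = 3) {
  variants[variants$kind == "INDEL" &
             variants$donor_zygosity == "hom" &
             variants$indel_len >= min_indel_len, , drop = FALSE]
}

#' Design an allele-discriminating amplicon pair around an INDEL
#'
#' Deterministic first-fit grid search over amplicon extents: primers
#' must lie outside the INDEL interval, primer lengths and both allele
#' products must fall in their permitted ranges.  Extents are tried from
#' the middle of the product range outwards, arms balanced around the
#' variant, so results are reproducible.  On success the two allele
#' products are materialised and their melting temperatures predicted.
#'
#' @param variant one-row variant data frame (kind `INDEL`).
#' @param ref_context reference-allele context sequence; defaults to the
#'   `context` column of the variant.
#' @param ctx_offset 1-based start of the REF allele within
#'   `ref_context`; defaults to the variant's `ctx_offset`.
#' @param product_range allowed amplicon lengths, bp.
#' @param primer_len_range allowed primer lengths, bp.
#' @param nn an [nn_params()] table.
#' @return A list of class `amplicon_pair` with primer and product
#'   sequences, `tm_rec`, `tm_don` and `delta_tm`; or a list with
#'   `rejected = TRUE` and a `reason` string when no design satisfies
#'   the constraints.
#' @export
build_amplicon_pair <- function(variant, ref_context = variant$context,
                                ctx_offset = variant$ctx_offset,
                                product_range = c(130, 260),
                                primer_len_range = c(18, 23),
                                nn = nn_params()) {
  if (variant$kind != "INDEL") {
    stop("HRM amplicons are designed for INDELs; got a ", variant$kind)
  }
  if (is.na(ref_context) || is.na(ctx_offset)) {
    stop("variant has no reference context")
  }
  ref <- variant$ref; alt <- variant$alt
  ctx_len <- nchar(ref_context)
  vstart <- ctx_offset
  vend <- ctx_offset + nchar(ref) - 1L
  if (substr(ref_context, vstart, vend) != ref) {
    stop("ref allele does not match context at ctx_offset")
  }
  len_shift <- nchar(alt) - nchar(ref)
  pmin_ <- primer_len_range[1]; pmax_ <- primer_len_range[2]
  a_max <- vstart - 1L              # upstream arm, primer ends before INDEL
  b_max <- ctx_len - vend           # downstream arm
  if (a_max < pmin_ || b_max < pmin_) {
    return(structure(list(rejected = TRUE, reason = "no_primer_room",
                          variant_id = variant$id), class = "amplicon_pair"))
  }
  varlen <- vend - vstart + 1L
  # shortest feasible product first: melt discrimination between the two
  # allele products is strongest for small amplicons
  for (rec_len in product_range[1]:product_range[2]) {
    don_len <- rec_len + len_shift
    if (don_len < product_range[1] || don_len > product_range[2]) next
    arms <- rec_len - varlen
    a <- arms %/% 2L; b <- arms - a
    # shift arms into the available context if unbalanced room
    if (a > a_max) { b <- b + (a - a_max); a <- a_max }
    if (b > b_max) { a <- a + (b - b_max); b <- b_max }
    if (a < pmin_ || b < pmin_ || a > a_max || b > b_max) next
    fstart <- vstart - a
    rend <- vend + b
    plen_f <- min(pmax_, a)
    plen_r <- min(pmax_, b)
    amp_rec <- substr(ref_context, fstart, rend)
    amp_don <- paste0(substr(ref_context, fstart, vstart - 1L), alt,
                      substr(ref_context, vend + 1L, rend))
    tm_rec <- predict_tm(amp_rec, nn = nn)
    tm_don <- predict_tm(amp_don, nn = nn)
    return(structure(list(
      rejected = FALSE, variant_id = variant$id,
      chrom = variant$chrom, pos = variant$pos,
      primer_fwd = substr(ref_context, fstart, fstart + plen_f - 1L),
      primer_rev = revcomp(substr(ref_context, rend - plen_r + 1L, rend)),
      amp_rec = amp_rec, amp_don = amp_don,
      len_rec = nchar(amp_rec), len_don = nchar(amp_don),
      tm_rec = tm_rec, tm_don = tm_don,
      delta_tm = abs(tm_rec - tm_don)), class = "amplicon_pair"))
  }
  structure(list(rejected = TRUE, reason = "no_feasible_product",
                 variant_id = variant$id), class = "amplicon_pair")
}

#' Retain amplicon pairs discriminable by melt temperature
#'
#' @param pair an `amplicon_pair` from [build_amplicon_pair()].
#' @param threshold minimum melt-temperature difference, degrees C;
#'   pairs are kept only when `delta_tm` strictly exceeds it.
#' @return List with `keep` (logical) and `delta_tm`.
#' @export
score_delta_tm <- function(pair, threshold = 0.5) {
  if (isTRUE(pair$rejected)) return(list(keep = FALSE, delta_tm = NA_real_))
  list(keep = pair$delta_tm > threshold, delta_tm = pair$delta_tm)
}

#' Design HRM candidate markers from a variant set
#'
#' Applies [filter_variants()], [build_amplicon_pair()] and
#' [score_delta_tm()] across the variant table and returns the retained
#' candidates with their genetic positions.
#'
#' @param variants variant data frame from [make_parents()].
#' @param map a [genome_map()].
#' @param min_indel_len minimum INDEL length, bp.
#' @param delta_tm_threshold melt-difference retention threshold, deg C.
#' @param ... passed to [build_amplicon_pair()].
#' @return Data frame of candidate markers: `id`, `chrom`, `pos`,
#'   `pos_cM`, primer sequences, product lengths, `tm_rec`, `tm_don`,
#'   `delta_tm`.
#' @export
design_hrm_candidates <- function(variants, map, min_indel_len = 3,
                                  delta_tm_threshold = 0.5, ...) {
  cand <- filter_variants(variants, min_indel_len)
  nn <- nn_params()
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    pair <- build_amplicon_pair(cand[i, ], nn = nn, ...)
    if (isTRUE(pair$rejected)) next
    if (!score_delta_tm(pair, delta_tm_threshold)$keep) next
    rows[[i]] <- data.frame(
      id = pair$variant_id, chrom = pair$chrom, pos = pair$pos,
      primer_fwd = pair$primer_fwd, primer_rev = pair$primer_rev,
      len_rec = pair$len_rec, len_don = pair$len_don,
      tm_rec = pair$tm_rec, tm_don = pair$tm_don,
      delta_tm = pair$delta_tm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    stop("no candidate markers survived the design filters")
  }
  out$pos_cM <- vapply(seq_len(nrow(out)), function(i) {
    bp_to_cM(map, out$chrom[i], out$pos[i])
  }, numeric(1))
  out[order(match(out$chrom, names(map)), out$pos), ]
}

#' Per-chromosome marker counts of the default background panel
#'
#' @return Named integer vector (A01..A10) summing to 131.
#' @export
brapa_marker_counts <- function() {
  c(A01 = 13L, A02 = 12L, A03 = 17L, A04 = 13L, A05 = 14L,
    A06 = 13L, A07 = 10L, A08 = 10L, A09 = 15L, A10 = 14L)
}

#' Select an evenly spaced marker panel
#'
#' Partitions each chromosome's genetic length into as many equal cM
#' bins as markers requested and picks, per bin, the candidate nearest
#' the bin midpoint (ties: larger delta-Tm, then smaller bp).  An empty
#' bin falls back to the nearest unused candidate on the chromosome,
#' with a warning.
#'
#' @param candidates candidate data frame from [design_hrm_candidates()]
#'   (needs `id`, `chrom`, `pos`, `pos_cM`, `delta_tm`).
#' @param map a [genome_map()].
#' @param per_chrom_counts named integer vector of markers per
#'   chromosome; defaults to [brapa_marker_counts()].
#' @return A `marker_panel` data frame sorted by chromosome and
#'   position, with a `type = "HRM"` column.
#' @export
select_even_panel <- function(candidates, map,
                              per_chrom_counts = brapa_marker_counts()) {
  panels <- list()
  for (chrom in names(per_chrom_counts)) {
    k <- per_chrom_counts[[chrom]]
    cc <- candidates[candidates$chrom == chrom, , drop = FALSE]
    if (nrow(cc) < k) {
      stop("chromosome ", chrom, " has ", nrow(cc),
           " candidates for ", k, " requested markers")
    }
    L <- map[[chrom]]$gen_len
    width <- L / k
    used <- logical(nrow(cc))
    picks <- integer(k)
    for (b in seq_len(k)) {
      lo <- (b - 1) * width; hi <- b * width
      mid2 <- (lo + hi) / 2
      inbin <- which(!used & cc$pos_cM >= lo &
                       (cc$pos_cM < hi | (b == k & cc$pos_cM <= hi)))
      pool <- if (length(inbin)) inbin else which(!used)
      if (!length(inbin)) {
        warning("empty bin ", b, " on ", chrom,
                "; falling back to nearest unused candidate")
      }
      d <- abs(cc$pos_cM[pool] - mid2)
      ord <- order(d, -cc$delta_tm[pool], cc$pos[pool])
      picks[b] <- pool[ord[1]]
      used[picks[b]] <- TRUE
    }
    panels[[chrom]] <- cc[picks, , drop = FALSE]
  }
  panel <- do.call(rbind, panels)
  panel$type <- "HRM"
  panel <- panel[order(match(panel$chrom, names(map)), panel$pos), ]
  rownames(panel) <- NULL
  if (anyDuplicated(panel$id)) stop("marker panel has duplicated ids")
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Marker density report
#'
#' Per chromosome: marker count, average physical density (chromosome
#' length / count, Mb), average genetic density (genetic length / count,
#' cM) and the largest cM gap between adjacent markers.  The genome-wide
#' row is the mean of the ten per-chromosome values.  All values are
#' reported to 2 decimals.
#'
#' @param panel a marker panel data frame (needs `chrom`, `pos_cM`).
#' @param map a [genome_map()].
#' @param counts optional named counts overriding `table(panel$chrom)`
#'   (used to report densities for a nominal design).
#' @return Data frame with rows A01..A10 and `genome`.
#' @export
density_report <- function(panel, map, counts = NULL) {
  chroms <- names(map)
  if (is.null(counts)) {
    counts <- vapply(chroms, function(ch) sum(panel$chrom == ch), integer(1))
  }
  if (any(counts == 0)) stop("chromosome with zero markers")
  avg_phys <- round(vapply(chroms, function(ch) map[[ch]]$phys_len,
                           numeric(1)) / counts / 1e6, 2)
  avg_gen <- round(vapply(chroms, function(ch) map[[ch]]$gen_len,
                          numeric(1)) / counts, 2)
  max_gap <- vapply(chroms, function(ch) {
    p <- sort(panel$pos_cM[panel$chrom == ch])
    if (length(p) < 2) return(NA_real_)
    round(max(diff(p)), 2)
  }, numeric(1))
  out <- data.frame(chrom = chroms, phys_len = vapply(chroms, function(ch)
                      map[[ch]]$phys_len, numeric(1)),
                    gen_len = vapply(chroms, function(ch)
                      map[[ch]]$gen_len, numeric(1)),
                    n_markers = as.integer(counts),
                    avg_phys_mb = avg_phys, avg_gen_cm = avg_gen,
                    max_gap_cm = max_gap, row.names = NULL)
  genome <- data.frame(chrom = "genome", phys_len = sum(out$phys_len),
                       gen_len = sum(out$gen_len),
                       n_markers = sum(out$n_markers),
                       avg_phys_mb = round(mean(out$avg_phys_mb), 2),
                       avg_gen_cm = round(mean(out$avg_gen_cm), 2),
                       max_gap_cm = round(mean(out$max_gap_cm), 2))
  rbind(out, genome)
}

#' Design the allele-specific (KASP-style) target-locus marker
#'
#' Two 3'-anchored allele-specific forward primers whose last base is
#' the dominant (G) and recessive (C) allele respectively, plus one
#' common reverse primer placed so the product falls inside the KASP
#' amplicon range.
#'
#' @param locus a [target_locus()].
#' @param context reference sequence around the SNP (dominant allele at
#'   `ctx_offset`).
#' @param ctx_offset 1-based SNP position within `context`.
#' @param primer_len allele-specific and common primer length, bp.
#' @param product_len target product length, bp.
#' @return List of class `kasp_marker` with `primer_dom`, `primer_rec`,
#'   `primer_common` and the genotype `decode` table.
#' @export
design_target_marker <- function(locus, context, ctx_offset,
                                 primer_len = 20, product_len = 80) {
  base <- substr(context, ctx_offset, ctx_offset)
  if (base != locus$dominant_allele) {
    stop("context does not carry the dominant allele at ctx_offset")
  }
  if (ctx_offset < primer_len ||
      nchar(context) < ctx_offset + product_len - primer_len) {
    stop("context too short for the requested product length")
  }
  stem <- substr(context, ctx_offset - primer_len + 1L, ctx_offset - 1L)
  rend <- ctx_offset + product_len - primer_len
  structure(list(
    id = "SC-TARGET", chrom = locus$chrom, pos = locus$pos, type = "KASP",
    primer_dom = paste0(stem, locus$dominant_allele),
    primer_rec = paste0(stem, locus$recessive_allele),
    primer_common = revcomp(substr(context, rend - primer_len + 1L, rend)),
    product_len = product_len,
    decode = data.frame(dom_signal = c(TRUE, FALSE, TRUE, FALSE),
                        rec_signal = c(FALSE, TRUE, TRUE, FALSE),
                        genotype = c("MM", "mm", "Mm", NA_character_))),
    class = "kasp_marker")
}

#' Decode a KASP fluorescence signal pair to a genotype
#'
#' @param dom_signal,rec_signal logical: amplification of the
#'   dominant-allele (FAM) and recessive-allele (VIC) primer.
#' @return `"MM"`, `"mm"`, `"Mm"`, or `NA` (no call, e.g. no-template
#'   control).
#' @export
kasp_genotype <- function(dom_signal, rec_signal) {
  ifelse(dom_signal & rec_signal, "Mm",
         ifelse(dom_signal, "MM",
                ifelse(rec_signal, "mm", NA_character_)))
}

#' Write a marker panel as TSV
#'
#' @param panel marker panel data frame.
#' @param path output file.
#' @export
write_marker_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
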