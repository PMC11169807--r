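#' Construct a genome map
#'
#' A `genome_map` is the coordinate backbone shared by the simulator, the
#' marker designer and the segment analyses: an ordered set of chromosomes,
#' each with a physical length (bp), a genetic length (cM) and a monotone
#' set of anchor points relating the two coordinate systems.  Positions
#' between anchors are interpolated linearly.
#'
#' @param chrom character vector of chromosome labels (e.g. `"A01"`).
#' @param phys_len integer vector of physical lengths in bp (> 0).
#' @param gen_len numeric vector of genetic lengths in cM (> 0).
#' @param anchors optional data frame with columns `chrom`, `pos_bp`,
#'   `pos_cM` giving additional interior anchor points (for example from a
#'   linkage map).  Terminal anchors (1 bp, 0 cM) and
#'   (`phys_len`, `gen_len`) are always added; interior anchors must be
#'   strictly increasing in both coordinates.
#' @return An object of class `genome_map`: a named list of per-chromosome
#'   lists with elements `name`, `phys_len`, `gen_len` and `anchors`
#'   (two-column matrix `pos_bp`, `pos_cM`).
#' @seealso [brapa_genome_map()] for the default *Brassica rapa* map,
#'   [bp_to_cM()], [cM_to_bp()].
#' @export
genome_map <- function(chrom, phys_len, gen_len, anchors = NULL) {
  stopifnot(length(chrom) == length(phys_len), length(chrom) == length(gen_len))
  if (anyDuplicated(chrom)) stop("duplicated chromosome labels")
  if (any(phys_len <= 0) || any(gen_len <= 0)) {
    stop("phys_len and gen_len must be positive")
  }
  chroms <- lapply(seq_along(chrom), function(i) {
    a <- rbind(c(1, 0), c(phys_len[i], gen_len[i]))
    if (!is.null(anchors)) {
      extra <- anchors[anchors$chrom == chrom[i], , drop = FALSE]
      if (nrow(extra)) {
        a <- rbind(a[1, , drop = FALSE],
                   cbind(extra$pos_bp, extra$pos_cM),
                   a[2, , drop = FALSE])
      }
    }
    colnames(a) <- c("pos_bp", "pos_cM")
    if (any(diff(a[, 1]) <= 0) || any(diff(a[, 2]) <= 0)) {
      stop("anchors for ", chrom[i],
           " are not strictly increasing in both bp and cM")
    }
    list(name = chrom[i], phys_len = as.numeric(phys_len[i]),
         gen_len = as.numeric(gen_len[i]), anchors = a)
  })
  names(chroms) <- chrom
  structure(chroms, class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map with", length(x), "chromosomes\n")
  df <- data.frame(chrom = names(x),
                   phys_len = vapply(x, `[[`, numeric(1), "phys_len"),
                   gen_len = vapply(x, `[[`, numeric(1), "gen_len"),
                   n_anchors = vapply(x, function(ch) nrow(ch$anchors), integer(1)),
                   row.names = NULL)
  print(df, ...)
  invisible(x)
}

#' Default Brassica rapa (Chiifu v3.0) genome map
#'
#' Ten chromosomes A01-A10 with the physical lengths and genetic map
#' lengths used throughout the package examples, and a telomere-to-telomere
#' linear bp/cM anchor pair per chromosome.
#'
#' @return A [genome_map()].
#' @export
brapa_genome_map <- function() {
  tab <- utils::read.table(system.file("extdata", "brapa_chiifu_map.tsv",
                                       package = "mabctools"),
                           header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric"))
  genome_map(tab$chrom, tab$phys_len, tab$gen_len)
}

map_chrom <- function(map, chrom) {
  ch <- map[[chrom]]
  if (is.null(ch)) stop("unknown chromosome label: ", chrom)
  ch
}

#' Convert physical to genetic position
#'
#' Piecewise-linear interpolation between the chromosome's anchor points.
#'
#' @param map a [genome_map()].
#' @param chrom chromosome label.
#' @param pos physical position(s) in bp, `1 <= pos <= phys_len`.
#' @return Genetic position(s) in cM, within `[0, gen_len]`.
#' @export
bp_to_cM <- function(map, chrom, pos) {
  ch <- map_chrom(map, chrom)
  if (any(pos < 1 | pos > ch$phys_len)) {
    stop("bp position out of range for ", chrom)
  }
  stats::approx(ch$anchors[, "pos_bp"], ch$anchors[, "pos_cM"],
                xout = pos, ties = "ordered")$y
}

#' Convert genetic to physical position
#'
#' Inverse of [bp_to_cM()].  The result is a continuous coordinate (not
#' rounded), so `bp_to_cM(cM_to_bp(x)) == x` to interpolation precision;
#' round it when an integer base position is required.
#'
#' @inheritParams bp_to_cM
#' @param pos genetic position(s) in cM, `0 <= pos <= gen_len`.
#' @return Physical position(s) in bp.
#' @export
cM_to_bp <- function(map, chrom, pos) {
  ch <- map_chrom(map, chrom)
  if (any(pos < 0 | pos > ch$gen_len)) {
    stop("cM position out of range for ", chrom)
  }
  bp <- stats::approx(ch$anchors[, "pos_cM"], ch$anchors[, "pos_bp"],
                      xout = pos, ties = "ordered")$y
  pmax(1, bp)
}

#' Map distance to recombination fraction
#'
#' Converts a genetic distance into the probability of an odd number of
#' crossovers between two loci.  The default Haldane map function assumes
#' independent (Poisson) crossovers; Kosambi allows for positive
#' interference.
#'
#' @param d genetic distance(s) in cM, `d >= 0`.
#' @param method `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
recombination_fraction <- function(d, method = c("haldane", "kosambi")) {
  method <- match.arg(method)
  if (any(d < 0)) stop("genetic distance must be non-negative")
  M <- d / 100
  switch(method,
         haldane = (1 - exp(-2 * M)) / 2,
         kosambi = tanh(2 * M) / 2)
}

#' Read a genome map from TSV files
#'
#' @param path TSV with columns `chrom`, `phys_len`, `gen_len`.
#' @param anchor_path optional TSV with columns `chrom`, `pos_bp`, `pos_cM`
#'   of interior linkage-map anchors.
#' @return A [genome_map()].
#' @export
read_genome_map <- function(path, anchor_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "phys_len", "gen_len")
  if (!all(need %in% names(tab))) {
    stop("genome map file must have columns: ", paste(need, collapse = ", "))
  }
  anchors <- NULL
  if (!is.null(anchor_path)) {
    anchors <- utils::read.table(anchor_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos_bp", "pos_cM") %in% names(anchors))) {
      stop("anchor file must have columns: chrom, pos_bp, pos_cM")
    }
  }
  genome_map(tab$chrom, tab$phys_len, tab$gen_len, anchors = anchors)
}

#' Write a genome map to TSV
#'
#' @param map a [genome_map()].
#' @param path output file.
#' @export
write_genome_map <- function(map, path) {
  df <- data.frame(chrom = names(map),
                   phys_len = vapply(map, `[[`, numeric(1), "phys_len"),
                   gen_len = vapply(map, `[[`, numeric(1), "gen_len"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
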