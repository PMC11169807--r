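#' Delineate introgression segments from dense genotype calls
#'
#' Scans a chromosome's per-locus calls (sorted by position, missing
#' calls skipped) for maximal runs of identical state.  Runs supported
#' by fewer than `min_support` informative loci are absorbed into the
#' flanking run with more support (ties to the left), smoothing
#' genotyping errors.  The boundary between adjacent segments is placed
#' at the midpoint between the last locus of one run and the first
#' locus of the next; the outermost segments extend to 1 and to the
#' chromosome's physical end.
#'
#' @param calls data frame with columns `pos` (bp, sorted increasing)
#'   and `state` (`A`/`H`/`B`/`-` or long names).
#' @param chrom chromosome label.
#' @param phys_len chromosome physical length, bp.
#' @param min_support minimum informative loci per emitted segment;
#'   1 disables smoothing.
#' @return Data frame of segments: `chrom`, `start`, `end` (1-based
#'   inclusive), `state`, `n_support`; the segments tile
#'   `[1, phys_len]`.
#' @export
delineate_segments <- function(calls, chrom, phys_len, min_support = 3) {
  if (is.unsorted(calls$pos, strictly = FALSE)) {
    stop("calls must be sorted by position")
  }
  st <- normalize_calls(calls$state)
  keep <- st != "-"
  pos <- calls$pos[keep]
  st <- st[keep]
  if (!length(pos)) stop("no informative (non-missing) calls")
  r <- rle(st)
  runs <- data.frame(state = r$values, support = r$lengths)
  ends <- cumsum(r$lengths)
  runs$first <- pos[c(1L, utils::head(ends, -1L) + 1L)]
  runs$last <- pos[ends]

  merge_adjacent <- function(runs) {
    i <- 1L
    while (i < nrow(runs)) {
      if (runs$state[i] == runs$state[i + 1L]) {
        runs$support[i] <- runs$support[i] + runs$support[i + 1L]
        runs$last[i] <- runs$last[i + 1L]
        runs <- runs[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    runs
  }

  while (nrow(runs) > 1L && min(runs$support) < min_support) {
    w <- which(runs$support == min(runs$support))[1L]
    left <- if (w > 1L) runs$support[w - 1L] else -Inf
    right <- if (w < nrow(runs)) runs$support[w + 1L] else -Inf
    tgt <- if (left >= right) w - 1L else w + 1L
    runs$state[w] <- runs$state[tgt]
    runs <- merge_adjacent(runs)
  }

  k <- nrow(runs)
  start <- numeric(k); end <- numeric(k)
  start[1L] <- 1
  end[k] <- phys_len
  if (k > 1L) {
    mids <- floor((runs$last[-k] + runs$first[-1L]) / 2)
    end[-k] <- mids
    start[-1L] <- mids + 1
  }
  data.frame(chrom = chrom, start = start, end = end,
             state = runs$state, n_support = runs$support,
             stringsAsFactors = FALSE)
}

#' Segment length in Mb
#'
#' Inclusive length `(end - start + 1) / 1e6`, reported to 1 decimal.
#'
#' @param seg data frame (or row) with `start` and `end` columns.
#' @return Length(s) in Mb.
#' @export
segment_length_mb <- function(seg) {
  round((seg$end - seg$start + 1) / 1e6, 1)
}

#' Linkage-drag report at the target locus
#'
#' Returns the segment containing the target position together with its
#' state and flanking recombination boundaries; flags the inconsistency
#' of a homozygous-recurrent segment in an individual genotyped `mm`.
#'
#' @param segments segment data frame tiling the target chromosome
#'   (from [delineate_segments()]).
#' @param target a [target_locus()].
#' @param genotype optional target genotype of the individual
#'   (`"MM"`/`"Mm"`/`"mm"`) for the consistency check.
#' @return One-row data frame: the containing segment plus `length_mb`,
#'   `upstream_boundary` and `downstream_boundary`.
#' @export
drag_report <- function(segments, target = target_locus(), genotype = NULL) {
  seg <- segments[segments$chrom == target$chrom, , drop = FALSE]
  hit <- which(seg$start <= target$pos & target$pos <= seg$end)
  if (!length(hit)) stop("target locus not covered by any segment")
  hit <- hit[1L]
  if (!is.null(genotype) && genotype == "mm" && seg$state[hit] == "A") {
    stop("inconsistency: mm individual with homozygous-recurrent ",
         "segment at the target locus")
  }
  out <- seg[hit, , drop = FALSE]
  out$length_mb <- segment_length_mb(out)
  out$upstream_boundary <- if (hit > 1L) seg$end[hit - 1L] else NA_real_
  out$downstream_boundary <- if (hit < nrow(seg)) seg$start[hit + 1L] else NA_real_
  rownames(out) <- NULL
  out
}

non_rec_ranges <- function(segments, chrom) {
  s <- segments[segments$chrom == chrom & normalize_calls(segments$state) != "A",
                , drop = FALSE]
  IRanges::reduce(IRanges::IRanges(start = s$start, end = s$end))
}

#' Shared donor segments of carriers absent from non-carriers
#'
#' Intersects the non-recurrent (donor or heterozygous) regions of all
#' carrier individuals and removes every region that is non-recurrent in
#' any non-carrier; the result is the candidate interval set private to
#' the carriers.
#'
#' @param carriers list of segment data frames (one per carrier
#'   individual).
#' @param non_carriers list of segment data frames (may be empty).
#' @return Data frame of candidate intervals: `chrom`, `start`, `end`,
#'   `length_mb`; zero rows when nothing is shared.
#' @export
shared_segments <- function(carriers, non_carriers = list()) {
  if (!length(carriers)) stop("at least one carrier is required")
  chroms <- unique(unlist(lapply(carriers, function(s) s$chrom)))
  rows <- list()
  for (chrom in chroms) {
    shared <- Reduce(IRanges::intersect,
                     lapply(carriers, non_rec_ranges, chrom = chrom))
    if (length(non_carriers)) {
      excl <- IRanges::reduce(
        Reduce(c, unname(lapply(non_carriers, non_rec_ranges, chrom = chrom))))
      shared <- IRanges::setdiff(shared, excl)
    }
    if (length(shared)) {
      rows[[chrom]] <- data.frame(chrom = chrom,
                                  start = IRanges::start(shared),
                                  end = IRanges::end(shared),
                                  stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(out) <- NULL
  out$length_mb <- if (nrow(out)) segment_length_mb(out) else numeric(0)
  out
}

#' Length-weighted PR from delineated segments
#'
#' Weighs each segment's physical length by its recurrent allele dose
#' (2 for homozygous recurrent, 1 heterozygous, 0 donor); a cross-check
#' for the locus-count PR on dense calls.
#'
#' @param segments segment data frame(s) tiling one individual's
#'   chromosomes.
#' @return PR in percent.
#' @export
pr_from_segments <- function(segments) {
  w <- c(A = 2, H = 1, B = 0)[normalize_calls(segments$state)]
  len <- segments$end - segments$start + 1
  100 * sum(w * len) / (2 * sum(len))
}

#' Export segments as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention; the segment state is written in the name
#' column.
#'
#' @param segments segment data frame.
#' @param path output file.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1,
                    end = segments$end,
                    name = segments$state)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export segments as TSV (1-based inclusive)
#'
#' @param segments segment data frame.
#' @param path output file.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
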