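# Accept either single-letter file codes or long state names.
normalize_calls <- function(calls) {
  long <- c(HOM_REC = "A", HET = "H", HOM_DON = "B", MISSING = "-")
  calls <- as.character(calls)
  idx <- calls %in% names(long)
  calls[idx] <- long[calls[idx]]
  bad <- !calls %in% c("A", "H", "B", "-")
  if (any(bad)) stop("unknown genotype code(s): ",
                     paste(unique(calls[bad]), collapse = ", "))
  calls
}

count_calls <- function(calls) {
  calls <- normalize_calls(calls)
  c(n_rec = sum(calls == "A"), n_het = sum(calls == "H"),
    n_don = sum(calls == "B"), n_missing = sum(calls == "-"))
}

#' Proportion of recurrent-parent genome (PR)
#'
#' Allele-weighted recovery score:
#' `PR = (2 * recurrent + 1 * heterozygous + 0 * donor) / (2 * total) * 100`,
#' with missing calls excluded from both numerator and denominator.
#'
#' @param calls genotype vector (`A`/`H`/`B`/`-` or
#'   `HOM_REC`/`HET`/`HOM_DON`/`MISSING`).
#' @return PR in percent.
#' @export
compute_pr <- function(calls) {
  n <- count_calls(calls)
  tot <- n["n_rec"] + n["n_het"] + n["n_don"]
  if (tot == 0) stop("all calls missing")
  unname(100 * (2 * n["n_rec"] + n["n_het"]) / (2 * tot))
}

#' Homozygosity of the genetic background (HGB)
#'
#' `HGB = homozygous calls / total calls * 100`, missing excluded.
#'
#' @inheritParams compute_pr
#' @return HGB in percent.
#' @export
compute_hgb <- function(calls) {
  n <- count_calls(calls)
  tot <- n["n_rec"] + n["n_het"] + n["n_don"]
  if (tot == 0) stop("all calls missing")
  unname(100 * (n["n_rec"] + n["n_don"]) / tot)
}

#' Per-individual background report
#'
#' @param calls genotype matrix (rows = individuals, cols = markers).
#' @param source `"marker"` (PRm/HGBm) or `"dense"` (PRs/HGBs),
#'   recorded in the output.
#' @return Data frame with call counts, `pr` and `hgb` per individual.
#' @export
background_report <- function(calls, source = c("marker", "dense")) {
  source <- match.arg(source)
  rows <- lapply(rownames(calls), function(id) {
    v <- calls[id, ]
    n <- count_calls(v)
    data.frame(id = id, n_rec = n[["n_rec"]], n_het = n[["n_het"]],
               n_don = n[["n_don"]], n_missing = n[["n_missing"]],
               pr = compute_pr(v), hgb = compute_hgb(v),
               source = source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-step background marker-assisted selection
#'
#' Step 1 ranks all individuals by PR over a small set of anchor markers
#' and keeps the top `keep_step1`; step 2 re-ranks the survivors by PR
#' over the full marker set.  Ties break on lexicographic individual id
#' for determinism.
#'
#' @param calls genotype matrix (rows = individuals, cols = marker ids).
#' @param step1_markers ids of the preliminary anchor markers.
#' @param keep_step1 number of individuals surviving step 1.
#' @param keep_final number of individuals in the final ranking
#'   (default all survivors).
#' @return List with `step1` and `final` background-report data frames,
#'   each sorted best-first.
#' @export
two_step_mas <- function(calls, step1_markers, keep_step1 = 96,
                         keep_final = NULL) {
  miss <- setdiff(step1_markers, colnames(calls))
  if (length(miss)) stop("marker id(s) absent from call matrix: ",
                         paste(miss, collapse = ", "))
  keep_step1 <- min(keep_step1, nrow(calls))
  pr1 <- vapply(rownames(calls), function(id)
    compute_pr(calls[id, step1_markers]), numeric(1))
  ord1 <- order(-pr1, rownames(calls))
  survivors <- rownames(calls)[ord1][seq_len(keep_step1)]
  rep1 <- background_report(calls[survivors, step1_markers, drop = FALSE],
                            source = "marker")
  rep2 <- background_report(calls[survivors, , drop = FALSE],
                            source = "marker")
  rep2 <- rep2[order(-rep2$pr, rep2$id), ]
  if (!is.null(keep_final)) rep2 <- rep2[seq_len(min(keep_final, nrow(rep2))), ]
  rownames(rep2) <- NULL
  list(step1 = rep1, final = rep2)
}

#' Filter a population on target-locus genotype
#'
#' @param pop a population object or list of individuals.
#' @param map a [genome_map()].
#' @param required `"Mm"` or `"mm"` (or `"MM"`).
#' @param target a [target_locus()].
#' @return Population with only the matching individuals, order
#'   preserved.
#' @export
select_by_target <- function(pop, map, required = c("Mm", "mm", "MM"),
                             target = target_locus()) {
  required <- match.arg(required)
  members <- if (inherits(pop, "mabc_population")) pop$members else pop
  keep <- vapply(members, function(ind)
    target_genotype(ind, map, target) == required, logical(1))
  if (inherits(pop, "mabc_population")) {
    new_population(pop$generation, members[keep], pop$seed)
  } else {
    members[keep]
  }
}

#' Chi-square test of a two-class segregation ratio
#'
#' One-degree-of-freedom goodness-of-fit test without continuity
#' correction.
#'
#' @param n_class1,n_class2 observed counts.
#' @param ratio expected ratio as a length-2 numeric (default 1:1).
#' @return List with `chi2` and `p`.
#' @export
segregation_test <- function(n_class1, n_class2, ratio = c(1, 1)) {
  if (n_class1 < 0 || n_class2 < 0) stop("counts must be non-negative")
  if (n_class1 + n_class2 == 0) stop("total count must be positive")
  ht <- stats::chisq.test(c(n_class1, n_class2), p = ratio / sum(ratio),
                          correct = FALSE)
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Graphical genotype matrix
#'
#' Orders markers by physical position and returns the call matrix in
#' that order, ready for chromosome painting; optionally writes the
#' matrix as TSV.
#'
#' @param calls genotype matrix.
#' @param panel marker panel data frame (`id`, `chrom`, `pos`).
#' @param path optional TSV output path.
#' @return The reordered matrix, with a `panel` attribute.
#' @export
graphical_genotypes <- function(calls, panel, path = NULL) {
  panel <- panel[order(match(panel$chrom, unique(panel$chrom)), panel$pos), ]
  ids <- intersect(panel$id, colnames(calls))
  m <- calls[, ids, drop = FALSE]
  attr(m, "panel") <- panel[panel$id %in% ids, ]
  if (!is.null(path)) write_genotype_matrix(m, path)
  m
}

#' Paint a graphical genotype matrix
#'
#' Renders individuals as rows and markers (in map order) as columns;
#' light blue = homozygous recurrent, dark blue = heterozygous,
#' red = homozygous donor, grey = missing.
#'
#' @param m matrix from [graphical_genotypes()].
#' @param file optional PNG output path.
#' @param main plot title.
#' @export
plot_graphical_genotypes <- function(m, file = NULL, main = "Graphical genotypes") {
  codes <- matrix(match(normalize_calls(m), c("A", "H", "B", "-")),
                  nrow = nrow(m))
  cols <- c("#9ecae1", "#08306b", "#cb181d", "#d9d9d9")
  if (!is.null(file)) grDevices::png(file, width = 1200, height = 400)
  graphics::image(t(codes[rev(seq_len(nrow(codes))), , drop = FALSE]),
                  col = cols, axes = FALSE, main = main,
                  zlim = c(1, 4))
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 2, cex.axis = 0.6)
  if (!is.null(file)) grDevices::dev.off()
  invisible(m)
}
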