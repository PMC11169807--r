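# Shared fixtures and independent oracles.

# a small two-chromosome map for fast simulation tests
small_map <- function() {
  genome_map(c("C1", "C2"), phys_len = c(10e6, 8e6), gen_len = c(100, 80))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Independent nearest-neighbor Tm oracle: accumulates enthalpy/entropy from
# the 10 unique duplex stacks (reverse-complement folding), terminal
# initiation terms, symmetry correction and salt adjustment, by explicit
# per-stack loop.  Kept deliberately separate from the package's
# table-driven implementation.
tm_oracle <- function(seq, na = 1, ct = 0.25e-6) {
  H <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
         CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  S <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
         CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  chars <- strsplit(seq, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(chars) - 1)) {
    st <- paste0(chars[i], chars[i + 1])
    if (!st %in% names(H)) st <- rc_str(st)
    dH <- dH + H[[st]]; dS <- dS + S[[st]]
  }
  for (e in chars[c(1, length(chars))]) {
    if (e %in% c("G", "C")) {
      dH <- dH + 0.1; dS <- dS - 2.8
    } else {
      dH <- dH + 2.3; dS <- dS + 4.1
    }
  }
  x <- 4
  if (seq == rc_str(seq)) { dS <- dS - 1.4; x <- 1 }
  dS <- dS + 0.368 * (length(chars) - 1) * log(na)
  1000 * dH / (dS + 1.9872 * log(ct / x)) - 273.15
}

# brute-force shared-segment oracle: per-position membership scan
shared_oracle <- function(carriers, non_carriers, chrom, max_pos) {
  pos <- seq_len(max_pos)
  inside <- function(segs) {
    s <- segs[segs$chrom == chrom & segs$state != "A", , drop = FALSE]
    out <- rep(FALSE, max_pos)
    for (i in seq_len(nrow(s))) out[s$start[i]:s$end[i]] <- TRUE
    out
  }
  keep <- Reduce(`&`, lapply(carriers, inside))
  if (length(non_carriers)) {
    keep <- keep & !Reduce(`|`, lapply(non_carriers, inside))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  data.frame(start = starts[r$values], end = ends[r$values])
}

# construct an individual with explicit donor segments (cM space)
fixed_individual <- function(map, segs1, segs2, id = "fix", gen = "BC1") {
  dip <- lapply(names(map), function(chrom) {
    mk <- function(s) {
      if (is.null(s[[chrom]])) {
        matrix(numeric(0), ncol = 2)
      } else {
        matrix(s[[chrom]], ncol = 2, byrow = TRUE)
      }
    }
    list(mk(segs1), mk(segs2))
  })
  names(dip) <- names(map)
  mabctools:::new_individual(id, gen, dip)
}
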