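# Interval arithmetic on donor-segment lists.
#
# A haplotype is represented per chromosome as a k x 2 matrix of
# donor-derived intervals on the genetic (cM) axis, sorted and
# non-overlapping; rows are [start, end] with 0 <= start < end <= gen_len.
# An empty matrix means the haplotype is entirely recurrent-parent.

empty_segs <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

full_segs <- function(gen_len) {
  matrix(c(0, gen_len), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

# sort rows, drop zero-length, merge touching/overlapping intervals
seg_normalize <- function(m) {
  if (nrow(m) == 0) return(empty_segs())
  m <- m[order(m[, 1]), , drop = FALSE]
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) <= 1) return(m)
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) {
      out[j, 2] <- max(out[j, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

# restrict segment list to the window [lo, hi]
seg_clip <- function(m, lo, hi) {
  if (nrow(m) == 0 || hi <= lo) return(empty_segs())
  s <- pmax(m[, 1], lo)
  e <- pmin(m[, 2], hi)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

seg_total_length <- function(m) {
  if (nrow(m) == 0) return(0)
  sum(m[, 2] - m[, 1])
}

# donor coverage (0/1) of a sorted segment matrix at positions pos
seg_covers <- function(m, pos) {
  if (nrow(m) == 0) return(rep(0L, length(pos)))
  bounds <- as.vector(t(m))
  idx <- findInterval(pos, bounds, rightmost.closed = TRUE)
  as.integer(idx %% 2L == 1L)
}

seg_valid <- function(m, gen_len) {
  if (nrow(m) == 0) return(TRUE)
  all(m[, 1] < m[, 2]) &&
    all(m[, 1] >= 0) && all(m[, 2] <= gen_len + 1e-9) &&
    (nrow(m) == 1 || all(diff(as.vector(t(m))) >= 0))
}
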