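test_that("segment delineation tiles the chromosome and places midpoints", {
  # uniform state: one whole-chromosome segment
  calls <- data.frame(pos = seq(1e5, 9e5, by = 1e5), state = "A")
  segs <- delineate_segments(calls, "C1", 1e6)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 1)
  expect_equal(segs$end, 1e6)
  expect_equal(segs$state, "A")
  # midpoint rule between runs
  calls2 <- data.frame(pos = c(seq(1000, 10000, by = 1000),
                               seq(11000, 20000, by = 1000)),
                       state = rep(c("A", "B"), each = 10))
  segs2 <- delineate_segments(calls2, "C1", 30000)
  expect_equal(segs2$end[1], 10500)
  expect_equal(segs2$start[2], 10501)
  expect_equal(segs2$state, c("A", "B"))
  # tiling invariant: lengths sum to phys_len
  expect_equal(sum(segs2$end - segs2$start + 1), 30000)
  expect_error(delineate_segments(data.frame(pos = c(5, 1), state = "A"),
                                  "C1", 10), "sorted")
  expect_error(delineate_segments(data.frame(pos = 1:3, state = "-"),
                                  "C1", 10), "informative")
})

test_that("short runs are absorbed and missing calls are skipped", {
  st <- c(rep("A", 10), "B", rep("A", 10))       # lone discordant call
  calls <- data.frame(pos = seq_along(st) * 1000, state = st)
  segs <- delineate_segments(calls, "C1", 25000)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, "A")
  expect_equal(segs$n_support, 21)
  # min_support = 1 disables smoothing
  segs_raw <- delineate_segments(calls, "C1", 25000, min_support = 1)
  expect_equal(nrow(segs_raw), 3)
  # missing calls do not break a run
  st2 <- c(rep("A", 5), "-", rep("A", 5), rep("B", 6))
  calls2 <- data.frame(pos = seq_along(st2) * 1000, state = st2)
  segs2 <- delineate_segments(calls2, "C1", 20000)
  expect_equal(segs2$state, c("A", "B"))
  expect_equal(segs2$n_support, c(10, 6))
})

test_that("delineation is idempotent on its own reconstruction", {
  set.seed(123)
  st <- rep(c("A", "H", "B", "A"), c(30, 20, 25, 25))
  pos <- sort(sample.int(5e6, length(st)))
  segs <- delineate_segments(data.frame(pos = pos, state = st), "C1", 5e6)
  implied <- segs$state[findInterval(pos, segs$start)]
  segs2 <- delineate_segments(data.frame(pos = pos, state = implied),
                              "C1", 5e6)
  expect_equal(segs2$state, segs$state)
  expect_equal(segs2$start, segs$start)
  expect_equal(segs2$end, segs$end)
})

test_that("noisy dense calls recover simulated segment structure", {
  map <- small_map()
  tg <- target_locus("C1", 5e6)
  p <- make_parents(map, target = tg, seed = 246)
  f1 <- make_f1(p$donor, p$recurrent, map)
  bc1 <- backcross(f1, p$recurrent, 1, map, seed = 303)
  ind <- bc1$members[[1]]
  pos <- seq(2e4, map$C1$phys_len - 2e4, by = 2e4)   # ~500 loci
  loci <- data.frame(id = sprintf("d%04d", seq_along(pos)), chrom = "C1",
                     pos = pos)
  truth <- call_genotypes(list(ind), loci, map, 0, 0, seed = 1)
  noisy <- call_genotypes(list(ind), loci, map, 0, 0.02, seed = 2)
  segs_t <- delineate_segments(data.frame(pos = pos, state = truth[1, ]),
                               "C1", map$C1$phys_len, min_support = 1)
  segs_n <- delineate_segments(data.frame(pos = pos, state = noisy[1, ]),
                               "C1", map$C1$phys_len, min_support = 3)
  expect_equal(segs_n$state, segs_t$state)
  # every recovered boundary within one inter-locus spacing of the truth
  if (nrow(segs_t) > 1) {
    expect_true(all(abs(segs_n$end[-nrow(segs_n)] -
                          segs_t$end[-nrow(segs_t)]) <= 2e4))
  }
})

test_that("segment lengths report printed-precision Mb", {
  expect_equal(segment_length_mb(data.frame(start = 12059865,
                                            end = 17244940)), 5.2)
  expect_equal(segment_length_mb(data.frame(start = 8101576,
                                            end = 19449508)), 11.3)
  expect_equal(segment_length_mb(data.frame(start = 5, end = 5)), 0)
})

test_that("the drag report finds the donor segment around the target", {
  tg <- target_locus("A03", 14652371)
  segs <- data.frame(chrom = "A03",
                     start = c(1, 12059865, 17244941),
                     end = c(12059864, 17244940, 38154160),
                     state = c("A", "B", "A"), n_support = c(100, 40, 200))
  d <- drag_report(segs, tg, genotype = "mm")
  expect_equal(d$state, "B")
  expect_equal(d$length_mb, 5.2)
  expect_equal(d$upstream_boundary, 12059864)
  expect_equal(d$downstream_boundary, 17244941)
  # homozygous-recurrent segment in an mm plant is an inconsistency
  segs_bad <- segs; segs_bad$state <- "A"
  expect_error(drag_report(segs_bad, tg, genotype = "mm"), "inconsistency")
  # a fully recurrent MM individual simply reports the recurrent segment
  whole <- data.frame(chrom = "A03", start = 1, end = 38154160,
                      state = "A", n_support = 500)
  expect_equal(drag_report(whole, tg, genotype = "MM")$state, "A")
  expect_error(drag_report(whole[0, ], tg), "not covered")
})

test_that("shared segments equal the brute-force membership scan", {
  mk <- function(...) {
    segs <- rbind(...)
    data.frame(chrom = "C1", start = as.numeric(segs[, 1]),
               end = as.numeric(segs[, 2]), state = segs[, 3], n_support = 5)
  }
  c1 <- mk(c(1, 9e3, "A"), c(9001, 20e3, "B"), c(20001, 3e4, "A"))
  c2 <- mk(c(1, 1e4, "A"), c(10001, 22e3, "H"), c(22001, 3e4, "A"))
  nc <- mk(c(1, 11999, "A"), c(12000, 14000, "B"), c(14001, 3e4, "A"))
  res <- shared_segments(list(c1, c2), list(nc))
  oracle <- shared_oracle(list(c1, c2), list(nc), "C1", 3e4)
  expect_equal(res$start, oracle$start)
  expect_equal(res$end, oracle$end)
  # identical carrier and non-carrier sets leave nothing
  expect_equal(nrow(shared_segments(list(c1), list(c1))), 0)
  # a single carrier with no non-carriers returns its non-recurrent regions
  solo <- shared_segments(list(c1))
  expect_equal(solo$start, 9001)
  expect_equal(solo$end, 20e3)
  # randomized instances against the oracle
  set.seed(515)
  for (i in 1:20) {
    rand_segs <- function() {
      cuts <- sort(sample.int(9999, sample(2:6, 1)))
      b <- c(1, cuts + 1)
      e <- c(cuts, 10000)
      data.frame(chrom = "C1", start = b, end = e,
                 state = sample(c("A", "H", "B"), length(b), replace = TRUE),
                 n_support = 3)
    }
    carriers <- replicate(sample(1:3, 1), rand_segs(), simplify = FALSE)
    ncs <- replicate(sample(0:2, 1), rand_segs(), simplify = FALSE)
    res <- shared_segments(carriers, ncs)
    ora <- shared_oracle(carriers, ncs, "C1", 10000)
    expect_equal(res$start, ora$start)
    expect_equal(res$end, ora$end)
  }
})

test_that("length-weighted segment PR agrees with dense locus-count PR", {
  map <- small_map()
  p <- make_parents(map, target = target_locus("C1", 5e6), seed = 88)
  f1 <- make_f1(p$donor, p$recurrent, map)
  bc1 <- backcross(f1, p$recurrent, 3, map, seed = 89)
  pos <- seq(1e4, map$C1$phys_len - 1e4, by = 1e4)
  loci <- data.frame(id = sprintf("d%05d", seq_along(pos)), chrom = "C1",
                     pos = pos)
  calls <- call_genotypes(bc1, loci, map, 0, 0, seed = 1)
  for (id in rownames(calls)) {
    segs <- delineate_segments(data.frame(pos = pos, state = calls[id, ]),
                               "C1", map$C1$phys_len, min_support = 1)
    expect_lt(abs(pr_from_segments(segs) - compute_pr(calls[id, ])), 1)
  }
})

test_that("BED export converts to 0-based half-open coordinates", {
  segs <- data.frame(chrom = "C1", start = c(1, 101), end = c(100, 200),
                     state = c("A", "B"), n_support = c(5, 5))
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(segs, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, c(0, 100))
  expect_equal(bed$V3, c(100, 200))
  expect_equal(bed$V4, c("A", "B"))
})
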