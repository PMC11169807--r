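test_that("parents are reproducible and carry the expected structure", {
  map <- small_map()
  tg <- target_locus(chrom = "C1", pos = 5e6)
  p1 <- make_parents(map, target = tg, seed = 42)
  p2 <- make_parents(map, target = tg, seed = 42)
  expect_identical(p1$variants, p2$variants)
  expect_equal(donor_fraction(p1$recurrent, map), 0)
  expect_equal(donor_fraction(p1$donor, map), 1)
  # het flagging close to its nominal rate
  expect_lt(abs(mean(p1$variants$donor_zygosity == "het") - 0.05), 0.02)
  # the target site is present and homozygous in the donor
  trow <- p1$variants[p1$variants$chrom == "C1" & p1$variants$pos == 5e6, ]
  expect_equal(nrow(trow), 1)
  expect_equal(trow$donor_zygosity, "hom")
  expect_equal(target_genotype(p1$donor, map, tg), "mm")
  expect_equal(target_genotype(p1$recurrent, map, tg), "MM")
})

test_that("parents yield the boundary PR values under any marker set", {
  map <- small_map()
  p <- make_parents(map, target = target_locus("C1", 5e6), seed = 9)
  loci <- utils::head(p$variants[, c("id", "chrom", "pos")], 50)
  calls <- call_genotypes(list(p$recurrent, p$donor), loci, map, seed = 1)
  expect_equal(compute_pr(calls["recurrent", ]), 100)
  expect_equal(compute_pr(calls["donor", ]), 0)
  expect_equal(compute_hgb(calls["recurrent", ]), 100)
  expect_equal(compute_hgb(calls["donor", ]), 100)
})

test_that("gametes from homozygous and F1 parents behave as expected", {
  map <- small_map()
  p <- make_parents(map, target = target_locus("C1", 5e6), seed = 3)
  set.seed(21)
  g <- simulate_gamete(p$recurrent, map)
  expect_true(all(vapply(g, nrow, integer(1)) == 0))
  f1 <- make_f1(p$donor, p$recurrent, map)
  expect_equal(donor_fraction(f1, map), 0.5)
  tot <- sum(vapply(map, `[[`, numeric(1), "gen_len"))
  set.seed(22)
  fr <- replicate(2000, {
    g <- simulate_gamete(f1, map)
    sum(vapply(g, function(m) if (nrow(m)) sum(m[, 2] - m[, 1]) else 0,
               numeric(1))) / tot
  })
  expect_lt(abs(mean(fr) - 0.5), 0.02)
})

test_that("a zero-length genetic map transmits whole chromosomes", {
  map <- genome_map("Z", 1e6, 1e-9)   # effectively no recombination
  dip <- list(Z = list(matrix(c(0, 1e-9), ncol = 2), matrix(numeric(0), ncol = 2)))
  ind <- mabctools:::new_individual("z", "F1", dip)
  set.seed(1)
  for (i in 1:20) {
    g <- simulate_gamete(ind, map)$Z
    expect_true(nrow(g) == 0 || abs(sum(g[, 2] - g[, 1]) - 1e-9) < 1e-15)
  }
})

test_that("backcross donor fractions follow 1/2^(g+1) and Mm segregates 1:1", {
  map <- small_map()
  tg <- target_locus("C1", 5e6)
  p <- make_parents(map, target = tg, seed = 5)
  f1 <- make_f1(p$donor, p$recurrent, map)
  bc1 <- backcross(f1, p$recurrent, 500, map, seed = 31)
  expect_equal(bc1$generation, "BC1")
  fr1 <- vapply(bc1$members, donor_fraction, numeric(1), map = map)
  expect_lt(abs(mean(fr1) - 0.25), 3 * stats::sd(fr1) / sqrt(500))
  # unselected chains to BC3
  fr3 <- vapply(bc1$members[1:300], function(m1) {
    m2 <- backcross(m1, p$recurrent, 1, map,
                    seed = sample.int(1e6, 1))$members[[1]]
    m3 <- backcross(m2, p$recurrent, 1, map,
                    seed = sample.int(1e6, 1))$members[[1]]
    donor_fraction(m3, map)
  }, numeric(1))
  expect_lt(abs(mean(fr3) - 1 / 16), 3 * stats::sd(fr3) / sqrt(300))
  # 1:1 target segregation from an Mm mother
  mm_mother <- bc1$members[[which(vapply(bc1$members, target_genotype,
                                         character(1), map = map,
                                         target = tg) == "Mm")[1]]]
  bc2 <- backcross(mm_mother, p$recurrent, 1000, map, seed = 77)
  n_mm <- sum(vapply(bc2$members, target_genotype, character(1),
                     map = map, target = tg) == "Mm")
  expect_gt(stats::binom.test(n_mm, 1000, 0.5)$p.value, 1e-4)
})

test_that("selfing fixes heterozygosity and segregates 3:1 at the target", {
  map <- small_map()
  tg <- target_locus("C1", 5e6)
  p <- make_parents(map, target = tg, seed = 8)
  f1 <- make_f1(p$donor, p$recurrent, map)
  s1 <- self_pollinate(f1, 2000, map, seed = 41)
  expect_equal(s1$generation, "F1S1")
  gt <- vapply(s1$members, target_genotype, character(1), map = map,
               target = tg)
  expect_gt(stats::binom.test(sum(gt == "mm"), 2000, 0.25)$p.value, 1e-4)
  # homozygous parent selfs to clones of itself
  s2 <- self_pollinate(p$donor, 5, map, seed = 42)
  for (ch in s2$members) expect_equal(donor_fraction(ch, map), 1)
  # selfing raises homozygosity: F1 children average ~50% HGB vs parent 0%
  loci <- p$variants[p$variants$donor_zygosity == "hom", c("id", "chrom", "pos")]
  calls_p <- call_genotypes(list(f1), loci, map, seed = 2)
  calls_c <- call_genotypes(utils::head(s1$members, 200), loci, map, seed = 3)
  hgb_c <- vapply(rownames(calls_c), function(i) compute_hgb(calls_c[i, ]),
                  numeric(1))
  expect_equal(compute_hgb(calls_p[1, ]), 0)
  expect_gt(mean(hgb_c), 40)
})

test_that("meiosis preserves segment-list validity under fuzzing", {
  map <- small_map()
  p <- make_parents(map, target = target_locus("C1", 5e6), seed = 13)
  f1 <- make_f1(p$donor, p$recurrent, map)
  ind <- f1
  set.seed(99)
  ok <- TRUE
  for (i in seq_len(2000)) {
    g <- simulate_gamete(ind, map)
    for (chrom in names(map)) {
      m <- g[[chrom]]
      if (nrow(m)) {
        b <- as.vector(t(m))
        ok <- ok && all(diff(b) >= 0) && b[1] >= 0 &&
          b[length(b)] <= map[[chrom]]$gen_len + 1e-9 &&
          all(m[, 2] > m[, 1])
      }
    }
    # occasionally breed a new individual from two gametes to deepen descent
    if (i %% 200 == 0) {
      g2 <- simulate_gamete(ind, map)
      dip <- lapply(names(map), function(ch) list(g[[ch]], g2[[ch]]))
      names(dip) <- names(map)
      ind <- mabctools:::new_individual("fuzz", "BC1", dip)
    }
  }
  expect_true(ok)
})

test_that("genotype calling reproduces truth and injects noise at rate", {
  map <- small_map()
  p <- make_parents(map, target = target_locus("C1", 5e6), seed = 17)
  f1 <- make_f1(p$donor, p$recurrent, map)
  bc1 <- backcross(f1, p$recurrent, 20, map, seed = 55)
  loci <- p$variants[p$variants$donor_zygosity == "hom", c("id", "chrom", "pos")]
  clean <- call_genotypes(bc1, loci, map, 0, 0, seed = 1)
  clean2 <- call_genotypes(bc1, loci, map, 0, 0, seed = 2)
  expect_identical(clean, clean2)  # truth does not depend on the noise seed
  # truth agrees with the diplotype state
  i <- bc1$members[[3]]
  dos <- donor_dosage(i, map, "C1", loci$pos[loci$chrom == "C1"])
  expect_equal(unname(clean[i$id, loci$chrom == "C1"]),
               c("A", "H", "B")[dos + 1])
  noisy <- call_genotypes(bc1, loci, map, missing_rate = 0.1, seed = 7)
  expect_lt(abs(mean(noisy == "-") - 0.1), 0.02)
  err <- call_genotypes(bc1, loci, map, error_rate = 0.2, seed = 8)
  expect_lt(abs(mean(err != clean) - 0.2), 0.03)
  expect_identical(call_genotypes(bc1, loci, map, 0.1, 0.05, seed = 10),
                   call_genotypes(bc1, loci, map, 0.1, 0.05, seed = 10))
})

test_that("the CI model responds to target genotype and modifiers", {
  map <- small_map()
  tg <- target_locus("C1", 5e6)
  p <- make_parents(map, target = tg, seed = 23)
  mod0 <- modifier_model(loci = data.frame(chrom = character(),
                                           pos = numeric(),
                                           effect = numeric()),
                         noise_sd = 0)
  # no noise, no modifiers: CI is the baseline exactly
  rec_ci <- simulate_ci(p$recurrent, map, mod0, tg)
  expect_equal(rec_ci$ci, 0.1)
  expect_equal(rec_ci$ci_class, "SI")
  don_ci <- simulate_ci(p$donor, map, mod0, tg)
  expect_equal(don_ci$ci, 1.0)
  # default model: MM plants are almost always self-incompatible
  set.seed(61)
  mod <- modifier_model(loci = data.frame(chrom = "C1", pos = 2e6,
                                          effect = 3))
  ci_mm <- replicate(1000, simulate_ci(p$recurrent, map, mod, tg)$ci)
  expect_gt(mean(ci_mm < 1), 0.95)
  # recessive homozygote with all donor modifier alleles reaches SC
  ci_don <- replicate(200, simulate_ci(p$donor, map, mod, tg)$ci)
  expect_gt(mean(ci_don), 4)
  expect_error(modifier_model(base_ci = c(MM = 2, Mm = 0.1, mm = 1)))
})

test_that("variant VCF and genotype matrices round-trip", {
  skip_if_not_installed("vcfR")
  map <- small_map()
  p <- make_parents(map, target = target_locus("C1", 5e6), seed = 29)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(p$variants, path)
  v2 <- read_variants_vcf(path)
  expect_equal(v2$pos, p$variants$pos)
  expect_equal(v2$kind, p$variants$kind)
  expect_equal(v2$donor_zygosity, p$variants$donor_zygosity)
  f1 <- make_f1(p$donor, p$recurrent, map)
  loci <- utils::head(p$variants[, c("id", "chrom", "pos")], 30)
  m <- call_genotypes(list(f1), loci, map, seed = 1)
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(m, gpath)
  expect_identical(read_genotype_matrix(gpath), m)
})
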