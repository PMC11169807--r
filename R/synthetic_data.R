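#' Define the target locus
#'
#' The biallelic locus under introgression.  The default models the
#' MLPK self-compatibility site: a G-to-C substitution at offset 1277 of
#' the coding sequence on chromosome A03, causing the G194R amino-acid
#' change; `C/C` homozygotes carry the recessive `mm` genotype.
#'
#' @param chrom chromosome label.
#' @param pos physical position in bp.  The default is a synthetic
#'   placement inside the donor-linked region of A03.
#' @param dominant_allele,recessive_allele single bases; the recurrent
#'   parent carries the dominant allele, the donor the recessive one.
#' @param cds_offset,aa_change annotation carried along in reports.
#' @return A list of class `target_locus`.
#' @export
target_locus <- function(chrom = "A03", pos = 14652371,
                         dominant_allele = "G", recessive_allele = "C",
                         cds_offset = 1277, aa_change = "G194R") {
  stopifnot(nchar(dominant_allele) == 1, nchar(recessive_allele) == 1,
            dominant_allele != recessive_allele)
  structure(list(chrom = chrom, pos = pos,
                 dominant_allele = dominant_allele,
                 recessive_allele = recessive_allele,
                 cds_offset = cds_offset, aa_change = aa_change),
            class = "target_locus")
}

new_individual <- function(id, generation, diplotype) {
  structure(list(id = id, generation = generation, diplotype = diplotype),
            class = "mabc_individual")
}

#' @export
print.mabc_individual <- function(x, ...) {
  cat("individual", x$id, "(", x$generation, "),",
      length(x$diplotype), "chromosomes\n")
  invisible(x)
}

new_population <- function(generation, members, seed = NA_integer_) {
  structure(list(generation = generation, members = members, seed = seed),
            class = "mabc_population")
}

#' @export
print.mabc_population <- function(x, ...) {
  cat("population", x$generation, "with", length(x$members), "individuals\n")
  invisible(x)
}

#' @export
length.mabc_population <- function(x) length(x$members)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the two homozygous parents and their variant set
#'
#' Emulates the discovery of parental differences by whole-genome
#' resequencing: SNPs and INDELs are placed uniformly along each
#' chromosome, a configurable fraction of donor calls is flagged
#' heterozygous (to exercise the homozygosity filter), and the target
#' locus allele is carried only by the donor.  Each INDEL carries a
#' random reference context (`flank` bp each side) used later for
#' amplicon design.
#'
#' @param map a [genome_map()].
#' @param snp_density,indel_density expected variants per Mb (> 0).
#'   Defaults are scaled-down emulations of resequencing variant density
#'   that leave an ample candidate pool after the marker-design filters.
#' @param het_fraction fraction of variants flagged heterozygous in the
#'   donor caller output.
#' @param indel_len_max maximum INDEL length in bp (lengths are drawn
#'   geometrically, minimum 1).
#' @param flank context length either side of each INDEL, bp.
#' @param target a [target_locus()].
#' @param seed integer seed.
#' @return A list with elements `recurrent` and `donor`
#'   ([new_individual()] objects), `variants` (data frame with columns
#'   `id`, `chrom`, `pos`, `ref`, `alt`, `kind`, `indel_len`,
#'   `donor_zygosity`, `context`, `ctx_offset`) and `target`.
#' @export
make_parents <- function(map, snp_density = 20, indel_density = 10,
                         het_fraction = 0.05, indel_len_max = 30,
                         flank = 150, target = target_locus(), seed = 1L) {
  stopifnot(snp_density > 0, indel_density > 0,
            het_fraction >= 0, het_fraction < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  vars <- list()
  for (chrom in names(map)) {
    mb <- map[[chrom]]$phys_len / 1e6
    n_snp <- stats::rpois(1, snp_density * mb)
    n_ind <- stats::rpois(1, indel_density * mb)
    if (n_snp + n_ind == 0) {
      warning("chromosome ", chrom, " received no variants; ",
              "increase density")
      next
    }
    pos <- sort(sample.int(map[[chrom]]$phys_len - 2L * flank, n_snp + n_ind)) +
      flank
    pos <- unique(pos)
    kind <- sample(rep(c("SNP", "INDEL"), c(n_snp, n_ind)))[seq_along(pos)]
    ref <- character(length(pos)); alt <- character(length(pos))
    ilen <- integer(length(pos)); ctx <- character(length(pos))
    for (i in seq_along(pos)) {
      if (kind[i] == "SNP") {
        ref[i] <- sample(bases, 1)
        alt[i] <- sample(setdiff(bases, ref[i]), 1)
        ilen[i] <- 0L
        ctx[i] <- NA_character_
      } else {
        len <- min(1L + stats::rgeom(1, 0.25), indel_len_max)
        anchor <- sample(bases, 1)
        insert <- random_dna(len)
        if (stats::runif(1) < 0.5) {            # deletion in donor
          ref[i] <- paste0(anchor, insert); alt[i] <- anchor
        } else {                                # insertion in donor
          ref[i] <- anchor; alt[i] <- paste0(anchor, insert)
        }
        ilen[i] <- len
        ctx[i] <- paste0(random_dna(flank), ref[i], random_dna(flank))
      }
    }
    vars[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                                alt = alt, kind = kind, indel_len = ilen,
                                donor_zygosity = "hom", context = ctx,
                                ctx_offset = ifelse(kind == "INDEL",
                                                    flank + 1L, NA_integer_),
                                stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, vars)
  n <- nrow(variants)
  het <- sample.int(n, round(het_fraction * n))
  variants$donor_zygosity[het] <- "het"
  # the target site itself, always homozygous in both parents
  variants <- rbind(variants,
                    data.frame(chrom = target$chrom, pos = target$pos,
                               ref = target$dominant_allele,
                               alt = target$recessive_allele,
                               kind = "SNP", indel_len = 0L,
                               donor_zygosity = "hom",
                               context = NA_character_,
                               ctx_offset = NA_integer_))
  variants <- variants[!duplicated(variants[, c("chrom", "pos")]), ]
  variants <- variants[order(match(variants$chrom, names(map)), variants$pos), ]
  variants$id <- sprintf("%s_%09d", variants$chrom, variants$pos)
  rownames(variants) <- NULL
  variants <- variants[, c("id", "chrom", "pos", "ref", "alt", "kind",
                           "indel_len", "donor_zygosity", "context",
                           "ctx_offset")]

  rec_dip <- lapply(map, function(ch) list(empty_segs(), empty_segs()))
  don_dip <- lapply(map, function(ch) list(full_segs(ch$gen_len),
                                           full_segs(ch$gen_len)))
  list(recurrent = new_individual("recurrent", "P", rec_dip),
       donor = new_individual("donor", "P", don_dip),
       variants = variants, target = target)
}

#' Simulate one meiotic gamete
#'
#' Crossovers per chromosome are Poisson with mean `gen_len / 100`
#' (no interference, no obligate chiasma), breakpoints are uniform on the
#' genetic map, and strands alternate from a random starting strand.
#' Uses the ambient RNG stream; seed at the population level.
#'
#' @param parent a [new_individual()].
#' @param map a [genome_map()].
#' @return A named list (one element per chromosome) of donor-segment
#'   matrices.
#' @export
simulate_gamete <- function(parent, map) {
  out <- vector("list", length(map))
  names(out) <- names(map)
  for (chrom in names(map)) {
    L <- map[[chrom]]$gen_len
    h <- parent$diplotype[[chrom]]
    ncross <- stats::rpois(1, L / 100)
    strand <- sample.int(2L, 1L)
    if (ncross == 0) {
      out[[chrom]] <- h[[strand]]
      next
    }
    cuts <- c(0, sort(stats::runif(ncross, 0, L)), L)
    pieces <- vector("list", length(cuts) - 1L)
    for (w in seq_len(length(cuts) - 1L)) {
      pieces[[w]] <- seg_clip(h[[strand]], cuts[w], cuts[w + 1L])
      strand <- 3L - strand
    }
    out[[chrom]] <- seg_normalize(do.call(rbind, pieces))
  }
  out
}

next_generation_label <- function(gen, selfed = FALSE) {
  if (selfed) {
    if (grepl("^BC[0-9]+$", gen)) return(paste0(gen, "S1"))
    return(paste0(gen, "S1"))
  }
  if (gen %in% c("F1", "P")) return("BC1")
  if (grepl("^BC[0-9]+$", gen)) {
    k <- as.integer(sub("BC", "", gen))
    return(paste0("BC", k + 1L))
  }
  paste0(gen, "xBC")
}

#' Cross two parents to produce an F1 individual
#'
#' Both parents are assumed fully homozygous, so the F1 is unique:
#' one haplotype per chromosome from each parent.
#'
#' @param donor,recurrent homozygous [new_individual()] parents.
#' @param map a [genome_map()].
#' @param id identifier for the offspring.
#' @return An F1 [new_individual()].
#' @export
make_f1 <- function(donor, recurrent, map, id = "F1-1") {
  dip <- lapply(names(map), function(chrom) {
    list(donor$diplotype[[chrom]][[1]], recurrent$diplotype[[chrom]][[1]])
  })
  names(dip) <- names(map)
  new_individual(id, "F1", dip)
}

#' Backcross a mother to the recurrent parent
#'
#' Each child combines one simulated gamete from the mother with one from
#' the recurrent parent; the generation label is incremented (F1 mothers
#' give BC1, BCk mothers give BCk+1).
#'
#' @param mother an [new_individual()] carrying the target allele.
#' @param recurrent the recurrent parent.
#' @param n number of offspring (>= 1).
#' @param map a [genome_map()].
#' @param seed integer seed.
#' @return A population object.
#' @export
backcross <- function(mother, recurrent, n, map, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  gen <- next_generation_label(mother$generation)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    g1 <- simulate_gamete(mother, map)
    g2 <- simulate_gamete(recurrent, map)
    dip <- lapply(names(map), function(chrom) list(g1[[chrom]], g2[[chrom]]))
    names(dip) <- names(map)
    members[[i]] <- new_individual(sprintf("%s-%d", gen, i), gen, dip)
  }
  new_population(gen, members, seed)
}

#' Self-pollinate an individual
#'
#' Each child combines two independent gametes from the same parent;
#' the generation label gains an `S1` suffix.
#'
#' @param parent an [new_individual()].
#' @param n number of offspring (>= 1).
#' @param map a [genome_map()].
#' @param seed integer seed.
#' @param family optional family prefix for offspring ids; defaults to
#'   the parent id.
#' @return A population object.
#' @export
self_pollinate <- function(parent, n, map, seed = 1L, family = NULL) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  gen <- next_generation_label(parent$generation, selfed = TRUE)
  if (is.null(family)) family <- parent$id
  members <- vector("list", n)
  for (i in seq_len(n)) {
    g1 <- simulate_gamete(parent, map)
    g2 <- simulate_gamete(parent, map)
    dip <- lapply(names(map), function(chrom) list(g1[[chrom]], g2[[chrom]]))
    names(dip) <- names(map)
    members[[i]] <- new_individual(sprintf("%sS1-%d", family, i), gen, dip)
  }
  new_population(gen, members, seed)
}

#' Donor dosage of an individual at map positions
#'
#' @param ind an [new_individual()].
#' @param map a [genome_map()].
#' @param chrom chromosome label.
#' @param pos_bp physical position(s).
#' @return Integer vector of donor allele counts (0, 1 or 2).
#' @export
donor_dosage <- function(ind, map, chrom, pos_bp) {
  cm <- bp_to_cM(map, chrom, pos_bp)
  h <- ind$diplotype[[chrom]]
  seg_covers(h[[1]], cm) + seg_covers(h[[2]], cm)
}

#' Target-locus genotype of an individual
#'
#' @param ind an [new_individual()].
#' @param map a [genome_map()].
#' @param target a [target_locus()].
#' @return `"MM"`, `"Mm"` or `"mm"` (donor dosage 0, 1, 2).
#' @export
target_genotype <- function(ind, map, target = target_locus()) {
  c("MM", "Mm", "mm")[donor_dosage(ind, map, target$chrom, target$pos) + 1L]
}

#' Genome-wide donor-genome fraction
#'
#' Allele-dosage fraction of donor genome over the genetic map.
#'
#' @param ind an [new_individual()].
#' @param map a [genome_map()].
#' @return Fraction in `[0, 1]`.
#' @export
donor_fraction <- function(ind, map) {
  tot <- sum(vapply(map, `[[`, numeric(1), "gen_len"))
  don <- sum(vapply(names(map), function(chrom) {
    h <- ind$diplotype[[chrom]]
    seg_total_length(h[[1]]) + seg_total_length(h[[2]])
  }, numeric(1)))
  don / (2 * tot)
}

GT_CODES <- c(HOM_REC = "A", HET = "H", HOM_DON = "B", MISSING = "-")

#' Call genotypes for a population at a set of loci
#'
#' Truth is read from each individual's phased diplotype at the locus
#' genetic position; genotyping errors flip a call to one of the two
#' wrong states uniformly, and missingness masks calls, both applied
#' independently per call.
#'
#' @param pop a population from [backcross()] or [self_pollinate()], or a
#'   list of individuals.
#' @param loci data frame with columns `id`, `chrom`, `pos` (bp).
#' @param map a [genome_map()].
#' @param missing_rate,error_rate probabilities in `[0, 1)`.
#' @param seed integer seed.
#' @return Character matrix (rows = individuals, cols = locus ids) with
#'   codes `"A"` (homozygous recurrent), `"H"` (heterozygous), `"B"`
#'   (homozygous donor), `"-"` (missing).
#' @export
call_genotypes <- function(pop, loci, map, missing_rate = 0,
                           error_rate = 0, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            error_rate >= 0, error_rate < 1)
  members <- if (inherits(pop, "mabc_population")) pop$members else pop
  set.seed(seed)
  states <- c("A", "H", "B")
  m <- matrix("-", nrow = length(members), ncol = nrow(loci),
              dimnames = list(vapply(members, `[[`, character(1), "id"),
                              loci$id))
  for (chrom in unique(loci$chrom)) {
    sel <- which(loci$chrom == chrom)
    cm <- bp_to_cM(map, chrom, loci$pos[sel])
    for (i in seq_along(members)) {
      h <- members[[i]]$diplotype[[chrom]]
      dos <- seg_covers(h[[1]], cm) + seg_covers(h[[2]], cm)
      m[i, sel] <- states[dos + 1L]
    }
  }
  n <- length(m)
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate)
    for (j in err) {
      m[j] <- sample(setdiff(states, m[j]), 1)
    }
  }
  if (missing_rate > 0) {
    m[stats::runif(n) < missing_rate] <- "-"
  }
  m
}

#' Default modifier architecture behind residual self-compatibility
#'
#' Beyond the recessive target genotype, self-compatibility in the
#' simulated material is boosted additively by donor alleles at a small
#' number of modifier loci, emulating the observed segregation of
#' self-compatibility among `mm` plants.  The default places four
#' modifiers at the midpoints of the candidate shared donor segments on
#' A03, A06, A07 and A09.
#'
#' @param loci data frame with columns `chrom`, `pos` (bp), `effect`
#'   (CI units added per homozygous donor dose).
#' @param base_ci named numeric, baseline CI for `MM`, `Mm`, `mm`;
#'   must be non-decreasing in that order.
#' @param noise_sd Gaussian noise on the latent CI, CI units.
#' @return A list of class `modifier_model`.
#' @export
modifier_model <- function(loci = data.frame(
                             chrom = c("A03", "A06", "A07", "A09"),
                             pos = c(16848171, 13775542, 14400624, 12626732),
                             effect = c(3, 3, 3, 3)),
                           base_ci = c(MM = 0.1, Mm = 0.1, mm = 1.0),
                           noise_sd = 0.5) {
  stopifnot(all(is.finite(loci$effect)),
            base_ci["MM"] <= base_ci["Mm"], base_ci["Mm"] <= base_ci["mm"],
            noise_sd >= 0)
  structure(list(loci = loci, base_ci = base_ci, noise_sd = noise_sd),
            class = "modifier_model")
}

#' Simulate a compatibility-index phenotype
#'
#' Latent CI = baseline for the target genotype, plus each modifier
#' effect scaled by half the donor dosage at that locus, plus Gaussian
#' noise, clipped at zero.  Seed count is `round(CI * flowers)`.
#' Uses the ambient RNG stream.
#'
#' @param ind an [new_individual()].
#' @param map a [genome_map()].
#' @param model a [modifier_model()].
#' @param target a [target_locus()].
#' @param flowers number of pollinated flowers.
#' @return One-row data frame: `id`, `genotype`, `n_flowers`, `n_seeds`,
#'   `ci`, `ci_class`.
#' @export
simulate_ci <- function(ind, map, model = modifier_model(),
                        target = target_locus(), flowers = 20) {
  geno <- target_genotype(ind, map, target)
  ci <- unname(model$base_ci[geno])
  if (nrow(model$loci)) {
    dos <- vapply(seq_len(nrow(model$loci)), function(i) {
      donor_dosage(ind, map, model$loci$chrom[i], model$loci$pos[i])
    }, integer(1))
    ci <- ci + sum(model$loci$effect * dos / 2)
  }
  if (model$noise_sd > 0) ci <- ci + stats::rnorm(1, 0, model$noise_sd)
  ci <- max(0, ci)
  seeds <- round(ci * flowers)
  data.frame(id = ind$id, genotype = geno, n_flowers = flowers,
             n_seeds = seeds, ci = seeds / flowers,
             ci_class = classify_ci(seeds / flowers),
             stringsAsFactors = FALSE)
}

#' Write a variant table as a minimal VCF
#'
#' @param variants data frame from [make_parents()].
#' @param path output file.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mabctools",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tDONOR"),
             con)
  gt <- ifelse(variants$donor_zygosity == "hom", "1/1", "0/1")
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                     variants$chrom, variants$pos, variants$id,
                     variants$ref, variants$alt, gt),
             con)
  invisible(path)
}

#' Write / read a genotype matrix as TSV
#'
#' Rows are individuals, columns marker ids, cells the codes
#' `A`/`H`/`B`/`-`.
#'
#' @param m character matrix from [call_genotypes()].
#' @param path file path.
#' @return `read_genotype_matrix` returns the matrix.
#' @export
write_genotype_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
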