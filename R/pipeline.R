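#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end MABC run.  Population sizes
#' default to the breeding scheme that motivated the package: 12 BC1,
#' 1120 BC2 and 768 BC3 plants, three selfed BC3 families with ten
#' recessive-homozygous plants retained per family.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param snp_density,indel_density,het_fraction passed to
#'   [make_parents()].
#' @param n_bc1,n_bc2,n_bc3 backcross population sizes.
#' @param n_bc3s1_progeny selfed progeny simulated per BC3 family
#'   before selecting the recessive homozygotes.
#' @param n_families BC3 individuals carried into selfing.
#' @param n_mm_per_family recessive homozygotes retained per family.
#' @param keep_step1 survivors of the first MAS round in BC2.
#' @param per_chrom_counts background marker counts per chromosome.
#' @param min_indel_len,delta_tm_threshold marker design filters.
#' @param marker_missing,marker_error,dense_missing,dense_error
#'   genotype-call noise rates.
#' @param min_support segment smoothing threshold.
#' @param target a [target_locus()].
#' @param modifier a [modifier_model()].
#' @param flowers pollinated flowers per CI assay.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            snp_density = 20, indel_density = 5,
                            het_fraction = 0.05,
                            n_bc1 = 12L, n_bc2 = 1120L, n_bc3 = 768L,
                            n_bc3s1_progeny = 60L, n_families = 3L,
                            n_mm_per_family = 10L, keep_step1 = 96L,
                            per_chrom_counts = brapa_marker_counts(),
                            min_indel_len = 3, delta_tm_threshold = 0.5,
                            marker_missing = 0.01, marker_error = 0.005,
                            dense_missing = 0.02, dense_error = 0.01,
                            min_support = 3,
                            target = target_locus(),
                            modifier = modifier_model(),
                            flowers = 20L) {
  cfg <- as.list(environment())
  counts <- c(n_bc1, n_bc2, n_bc3, n_bc3s1_progeny, n_families,
              n_mm_per_family, keep_step1)
  if (any(counts <= 0)) stop("all population and keep counts must be positive")
  structure(cfg, class = "pipeline_config")
}

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

best_by_pr <- function(report, k = 1L) {
  report <- report[order(-report$pr, report$id), , drop = FALSE]
  report$id[seq_len(min(k, nrow(report)))]
}

#' Run the end-to-end MABC pipeline
#'
#' Simulates the parents and their variant set, designs the background
#' HRM panel and the allele-specific target marker, advances F1 through
#' BC1-BC3 with target-carrier and background selection (two-step MAS in
#' the large BC2), selfs the top BC3 individuals, selects recessive
#' homozygotes, scores PR/HGB from markers and from dense
#' resequencing-like calls, delineates introgression segments,
#' identifies donor segments shared by self-compatible but absent from
#' self-incompatible individuals, classifies CI phenotypes, and writes
#' every artifact plus a machine-readable JSON summary to `out_dir`.
#' Deterministic under the config seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("mabc_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 40L)
  map <- brapa_genome_map()
  summary <- list(seed = config$seed)

  ## parents and variants -------------------------------------------------
  parents <- tryCatch(
    make_parents(map, snp_density = config$snp_density,
                 indel_density = config$indel_density,
                 het_fraction = config$het_fraction,
                 target = config$target, seed = seeds[1]),
    error = function(e) stage_fail("parents", e))
  write_variants_vcf(parents$variants, file.path(out_dir, "variants.vcf"))

  ## marker design ---------------------------------------------------------
  panel <- tryCatch({
    cand <- design_hrm_candidates(parents$variants, map,
                                  min_indel_len = config$min_indel_len,
                                  delta_tm_threshold = config$delta_tm_threshold)
    select_even_panel(cand, map, config$per_chrom_counts)
  }, error = function(e) stage_fail("marker_design", e))
  write_marker_panel(panel, file.path(out_dir, "marker_panel.tsv"))
  dens <- density_report(panel, map)
  utils::write.table(dens, file.path(out_dir, "marker_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  set.seed(seeds[2])
  target_ctx <- paste0(random_dna(150), config$target$dominant_allele,
                       random_dna(150))
  kasp <- design_target_marker(config$target, target_ctx, 151L)
  utils::write.table(
    data.frame(id = kasp$id, chrom = kasp$chrom, pos = kasp$pos,
               primer_dom = kasp$primer_dom, primer_rec = kasp$primer_rec,
               primer_common = kasp$primer_common),
    file.path(out_dir, "target_marker.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  loci <- data.frame(id = panel$id, chrom = panel$chrom, pos = panel$pos)

  genotype_and_rank <- function(pop, seed) {
    calls <- call_genotypes(pop, loci, map,
                            missing_rate = config$marker_missing,
                            error_rate = config$marker_error, seed = seed)
    list(calls = calls, report = background_report(calls, "marker"))
  }
  find_member <- function(pop, id) {
    pop$members[[which(vapply(pop$members, `[[`, character(1), "id") == id)]]
  }

  ## backcrossing with selection -------------------------------------------
  f1 <- make_f1(parents$donor, parents$recurrent, map)
  generations <- list()
  mother <- f1
  sizes <- c(BC1 = config$n_bc1, BC2 = config$n_bc2, BC3 = config$n_bc3)
  max_prm <- c()
  seg_tests <- list()
  bc3_ranked <- NULL
  for (g in seq_along(sizes)) {
    gen <- names(sizes)[g]
    # re-cross (new seeded attempt) until at least one Mm carrier appears,
    # as a breeder would; matters only for tiny population sizes
    carriers <- NULL
    for (attempt in 0:49) {
      pop <- tryCatch(
        backcross(mother, parents$recurrent, sizes[[g]], map,
                  seed = seeds[2 + g] + attempt),
        error = function(e) stage_fail(gen, e))
      carriers <- select_by_target(pop, map, "Mm", config$target)
      if (length(carriers) > 0) break
    }
    if (length(carriers) == 0) {
      stage_fail(gen, simpleError("no Mm carriers recovered"))
    }
    n_mm <- length(carriers)
    seg_tests[[gen]] <- c(n_Mm = n_mm, n_MM = length(pop) - n_mm,
                          p = segregation_test(n_mm, length(pop) - n_mm)$p)
    gr <- genotype_and_rank(carriers, seeds[6 + g])
    if (gen == "BC2") {
      step1 <- vapply(c("A01", "A02", "A09"), function(ch)
        panel$id[panel$chrom == ch][1], character(1))
      mas <- two_step_mas(gr$calls, step1, keep_step1 = config$keep_step1)
      rank_report <- mas$final
    } else {
      rank_report <- gr$report[order(-gr$report$pr, gr$report$id), ]
    }
    write_genotype_matrix(gr$calls,
                          file.path(out_dir, paste0("calls_", gen, ".tsv")))
    utils::write.table(rank_report,
                       file.path(out_dir, paste0("background_", gen, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    max_prm[gen] <- max(rank_report$pr)
    mother <- find_member(pop, rank_report$id[1])
    if (gen == "BC3") bc3_ranked <- rank_report
    generations[[gen]] <- pop
  }

  ## selfing and recessive-homozygote selection ----------------------------
  founders <- bc3_ranked$id[seq_len(min(config$n_families, nrow(bc3_ranked)))]
  bc3s1_members <- list()
  for (i in seq_along(founders)) {
    mm <- NULL
    for (attempt in 0:49) {
      fam <- tryCatch(
        self_pollinate(find_member(generations$BC3, founders[i]),
                       config$n_bc3s1_progeny, map,
                       seed = seeds[10 + i] + attempt),
        error = function(e) stage_fail("BC3S1", e))
      mm <- select_by_target(fam, map, "mm", config$target)
      if (length(mm) > 0) break
    }
    keep <- utils::head(mm$members, config$n_mm_per_family)
    bc3s1_members <- c(bc3s1_members, keep)
  }
  if (!length(bc3s1_members)) stage_fail("BC3S1", simpleError(
    "no recessive homozygotes recovered; increase n_bc3s1_progeny"))
  bc3s1 <- new_population("BC3S1", bc3s1_members)
  calls_s1 <- call_genotypes(bc3s1, loci, map,
                             missing_rate = config$marker_missing,
                             error_rate = config$marker_error,
                             seed = seeds[15])
  rep_s1 <- background_report(calls_s1, "marker")
  write_genotype_matrix(calls_s1, file.path(out_dir, "calls_BC3S1.tsv"))
  utils::write.table(rep_s1, file.path(out_dir, "background_BC3S1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  max_prm["BC3S1"] <- max(rep_s1$pr)
  gg <- graphical_genotypes(calls_s1, panel,
                            path = file.path(out_dir, "graphical_BC3S1.tsv"))

  ## dense background and segment analysis ---------------------------------
  fam_of <- sub("S1-[0-9]+$", "", vapply(bc3s1_members, `[[`, character(1), "id"))
  selected_ids <- vapply(unique(fam_of), function(f) {
    best_by_pr(rep_s1[fam_of == f, , drop = FALSE])
  }, character(1))
  selected <- lapply(selected_ids, find_member, pop = bc3s1)
  dense_loci <- parents$variants[parents$variants$donor_zygosity == "hom" &
                                   parents$variants$kind == "SNP", ]
  dense_loci <- data.frame(id = dense_loci$id, chrom = dense_loci$chrom,
                           pos = dense_loci$pos)
  dense_calls <- call_genotypes(selected, dense_loci, map,
                                missing_rate = config$dense_missing,
                                error_rate = config$dense_error,
                                seed = seeds[16])
  rep_dense <- background_report(dense_calls, "dense")
  utils::write.table(rep_dense, file.path(out_dir, "background_dense.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  segs_by_ind <- list()
  for (id in selected_ids) {
    segs <- do.call(rbind, lapply(names(map), function(chrom) {
      sel <- dense_loci$chrom == chrom
      delineate_segments(
        data.frame(pos = dense_loci$pos[sel], state = dense_calls[id, sel]),
        chrom, map[[chrom]]$phys_len, min_support = config$min_support)
    }))
    segs_by_ind[[id]] <- segs
    write_segments_bed(segs, file.path(out_dir, paste0("segments_", id, ".bed")))
    write_segments_tsv(segs, file.path(out_dir, paste0("segments_", id, ".tsv")))
  }
  drag <- do.call(rbind, lapply(selected_ids, function(id) {
    d <- drag_report(segs_by_ind[[id]], config$target, genotype = "mm")
    cbind(id = id, d)
  }))
  write_segments_tsv(drag, file.path(out_dir, "drag_report.tsv"))

  ## phenotypes and shared segments ----------------------------------------
  set.seed(seeds[17])
  ci <- do.call(rbind, lapply(bc3s1_members, simulate_ci, map = map,
                              model = config$modifier, target = config$target,
                              flowers = config$flowers))
  utils::write.table(ci, file.path(out_dir, "ci_phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sel_ci <- ci[match(selected_ids, ci$id), ]
  sc_ids <- sel_ci$id[sel_ci$ci_class == "SC"]
  si_ids <- setdiff(selected_ids, sc_ids)
  shared <- if (length(sc_ids)) {
    shared_segments(segs_by_ind[sc_ids], segs_by_ind[si_ids])
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               length_mb = numeric())
  }
  write_segments_tsv(shared, file.path(out_dir, "shared_segments.tsv"))

  ## summary ----------------------------------------------------------------
  summary$n_variants <- nrow(parents$variants)
  summary$n_markers <- nrow(panel)
  summary$genome_avg_density_mb <- dens$avg_phys_mb[dens$chrom == "genome"]
  summary$genome_avg_density_cm <- dens$avg_gen_cm[dens$chrom == "genome"]
  summary$segregation <- seg_tests
  summary$max_prm <- as.list(max_prm)
  summary$selected <- lapply(selected_ids, function(id) list(
    id = id,
    prm = rep_s1$pr[rep_s1$id == id], hgbm = rep_s1$hgb[rep_s1$id == id],
    prs = rep_dense$pr[rep_dense$id == id],
    hgbs = rep_dense$hgb[rep_dense$id == id],
    ci = ci$ci[ci$id == id], ci_class = ci$ci_class[ci$id == id]))
  summary$ci_classes <- as.list(ci_summary(ci))
  summary$n_shared_segments <- nrow(shared)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Read a variant table from a (minimal) VCF
#'
#' Uses `vcfR` to parse the file and reconstructs the variant data frame
#' consumed by the design and genotyping functions (contexts are not
#' stored in VCF and come back as `NA`).
#'
#' @param path VCF file with a single donor sample.
#' @return Variant data frame.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variants_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)[, 1]
  data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.numeric(fix$POS),
             ref = fix$REF, alt = fix$ALT,
             kind = ifelse(nchar(fix$REF) == nchar(fix$ALT), "SNP", "INDEL"),
             indel_len = abs(nchar(fix$ALT) - nchar(fix$REF)),
             donor_zygosity = ifelse(gt %in% c("1/1", "1|1"), "hom", "het"),
             context = NA_character_, ctx_offset = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Validate pipeline input files
#'
#' Schema checks on the genome map, variant VCF, genotype matrix and
#' pollination TSVs; problems are reported with file and line numbers.
#'
#' @param paths named list with any of `map`, `vcf`, `genotypes`,
#'   `phenotypes`.
#' @param map optional [genome_map()] used to check chromosome labels
#'   and position ranges in the VCF.
#' @return List with `ok` (logical) and `issues` (data frame `file`,
#'   `line`, `problem`).
#' @export
validate_inputs <- function(paths, map = NULL) {
  issues <- data.frame(file = character(), line = integer(),
                       problem = character(), stringsAsFactors = FALSE)
  note <- function(file, line, problem) {
    issues <<- rbind(issues, data.frame(file = file, line = line,
                                        problem = problem))
  }
  if (!is.null(paths$map)) {
    tab <- tryCatch(utils::read.table(paths$map, header = TRUE, sep = "\t"),
                    error = function(e) NULL)
    if (is.null(tab) ||
        !all(c("chrom", "phys_len", "gen_len") %in% names(tab))) {
      note(paths$map, 1L, "map file must have chrom/phys_len/gen_len columns")
    } else if (any(tab$phys_len <= 0 | tab$gen_len <= 0)) {
      note(paths$map, which(tab$phys_len <= 0 | tab$gen_len <= 0)[1] + 1L,
           "non-positive chromosome length")
    }
  }
  if (!is.null(paths$vcf)) {
    lines <- readLines(paths$vcf)
    hdr <- grep("^#CHROM\t", lines)
    if (!length(hdr)) {
      note(paths$vcf, 1L, "missing #CHROM header line")
    } else {
      body <- lines[(hdr[1] + 1L):length(lines)]
      fields <- strsplit(body, "\t", fixed = TRUE)
      chrom <- vapply(fields, `[`, character(1), 1)
      pos <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
      bad <- which(is.na(pos))
      if (length(bad)) note(paths$vcf, hdr[1] + bad[1], "non-numeric POS")
      for (ch in unique(chrom)) {
        p <- pos[chrom == ch]
        if (anyNA(p)) next
        if (is.unsorted(p)) {
          ln <- hdr[1] + which(chrom == ch)[which(diff(p) < 0)[1] + 1L]
          note(paths$vcf, ln, paste0("unsorted positions on ", ch))
        }
        if (!is.null(map)) {
          if (!ch %in% names(map)) {
            note(paths$vcf, hdr[1] + which(chrom == ch)[1],
                 paste0("unknown contig ", ch))
          } else if (any(p < 1 | p > map[[ch]]$phys_len, na.rm = TRUE)) {
            note(paths$vcf,
                 hdr[1] + which(chrom == ch)[
                   which(p < 1 | p > map[[ch]]$phys_len)[1]],
                 paste0("position out of range on ", ch))
          }
        }
      }
    }
  }
  if (!is.null(paths$genotypes)) {
    m <- tryCatch(read_genotype_matrix(paths$genotypes),
                  error = function(e) NULL)
    if (is.null(m)) {
      note(paths$genotypes, 1L, "unreadable genotype matrix")
    } else {
      bad <- which(!m %in% c("A", "H", "B", "-"))
      if (length(bad)) {
        note(paths$genotypes, (bad[1] - 1L) %% nrow(m) + 2L,
             paste0("invalid genotype code '", m[bad[1]], "'"))
      }
    }
  }
  if (!is.null(paths$phenotypes)) {
    ph <- tryCatch(utils::read.table(paths$phenotypes, header = TRUE,
                                     sep = "\t"), error = function(e) NULL)
    if (is.null(ph) || !all(c("id", "flowers", "seeds") %in% names(ph))) {
      note(paths$phenotypes, 1L,
           "phenotype file must have id/flowers/seeds columns")
    } else if (any(ph$flowers <= 0)) {
      note(paths$phenotypes, which(ph$flowers <= 0)[1] + 1L,
           "non-positive flower count")
    }
  }
  list(ok = nrow(issues) == 0L, issues = issues)
}
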