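test_that("make_genome echoes sizes, is deterministic and validates input", {
  g <- make_genome(seed = 1, n_chroms = 2, chrom_length = 5e6, n_genes = 200)
  expect_equal(nrow(g$genes), 200)
  expect_equal(nrow(g$chroms), 2)
  g2 <- make_genome(seed = 1, n_chroms = 2, chrom_length = 5e6, n_genes = 200)
  expect_identical(g$genes, g2$genes)

  expect_error(make_genome(seed = 1, n_chroms = 1, chrom_length = 5e6,
                           n_genes = 50), "chromosome")
  expect_error(make_genome(seed = 1, n_chroms = 2, chrom_length = 5e5,
                           n_genes = 50), "chrom_length")
  expect_error(make_genome(seed = 1, n_chroms = 2, chrom_length = 5e6,
                           n_genes = 5), "n_genes")
  # overlap-free placement infeasible at extreme density
  expect_error(make_genome(seed = 1, n_chroms = 2, chrom_length = 1e6,
                           n_genes = 500), "density")
})

test_that("gene bodies are in bounds, non-overlapping, with unique TSS", {
  g <- make_genome(seed = 7, n_chroms = 3, chrom_length = 2e6, n_genes = 60)
  genes <- g$genes
  expect_true(all(genes$start >= 1 & genes$end <= 2e6 & genes$start < genes$end))
  expect_true(!any(duplicated(genes[, c("chrom", "tss")])))
  for (ch in unique(genes$chrom)) {
    gg <- genes[genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
})

test_that("architecture type proportions match request within binomial bounds", {
  g <- make_genome(seed = 2, n_chroms = 4, chrom_length = 1e7, n_genes = 400)
  a <- make_architecture(g, seed = 3, n_loops = 1000,
                         frac_promoter_mediated = 0.875,
                         frac_pp_within_promoter_mediated = 0.5)
  tab <- table(a$loops$type_label)
  # expected counts 437.5 / 437.5 / 125; exact binomial 99% interval
  ci <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)
  expect_true(tab[["P-P"]] >= ci(1000, 0.4375)[1] &&
                tab[["P-P"]] <= ci(1000, 0.4375)[2])
  expect_true(tab[["P-nonP"]] >= ci(1000, 0.4375)[1] &&
                tab[["P-nonP"]] <= ci(1000, 0.4375)[2])
  expect_true(tab[["nonP-nonP"]] >= ci(1000, 0.125)[1] &&
                tab[["nonP-nonP"]] <= ci(1000, 0.125)[2])
})

test_that("architecture boundary fractions and invariants hold", {
  g <- make_genome(seed = 4, n_chroms = 2, chrom_length = 1e7, n_genes = 150)
  a0 <- make_architecture(g, seed = 5, n_loops = 40, frac_distal_sox2 = 0)
  expect_true(all(!a0$enhancers$sox2_bound))

  a1 <- make_architecture(g, seed = 5, n_loops = 40,
                          frac_promoter_mediated = 1,
                          frac_pp_within_promoter_mediated = 1)
  expect_true(all(a1$loops$type_label == "P-P"))

  a <- make_architecture(g, seed = 6, n_loops = 60, frac_distal_sox2 = 0.5)
  # SOX2-bound enhancers are >= 95% dual-marked by construction
  sb <- a$enhancers[a$enhancers$sox2_bound, ]
  expect_gte(mean(sb$mark_state == "active"), 0.95)
  # every SOX2 peak lies inside exactly one enhancer or promoter region
  enh_gr <- toy_gr(a$enhancers$chrom, a$enhancers$start, a$enhancers$end)
  proms <- toy_gr(g$genes$chrom, pmax(1, g$genes$tss - 2500), g$genes$tss + 2500)
  n_hit <- GenomicRanges::countOverlaps(a$sox2_peaks, c(enh_gr, proms),
                                        type = "within")
  expect_true(all(n_hit >= 1))
  # planted type labels consistent with anchor positions vs promoter windows
  la <- toy_gr(a$loops$chrom, a$loops$start_a, a$loops$end_a)
  lb <- toy_gr(a$loops$chrom, a$loops$start_b, a$loops$end_b)
  p_a <- IRanges::overlapsAny(la, proms)
  p_b <- IRanges::overlapsAny(lb, proms)
  expect_identical(unname(classify_interaction(ifelse(p_a, "P", "I"),
                                               ifelse(p_b, "P", "I"))),
                   a$loops$type_label)
  expect_error(make_architecture(g, seed = 5, n_loops = 10), "n_loops")
  expect_error(make_architecture(g, seed = 5, n_loops = 40,
                                 frac_distal_sox2 = 1.2), "fraction")
})

test_that("simulated signal PETs land inside planted anchors", {
  g <- make_genome(seed = 8, n_chroms = 2, chrom_length = 5e6, n_genes = 50)
  a <- make_architecture(g, seed = 9, n_loops = 20)
  a$loops <- a$loops[1, , drop = FALSE]   # isolate a single planted loop
  pets <- simulate_pets(a, g, seed = 10, n_signal_pets = 50,
                        n_background_pets = 0, duplicate_rate = 0,
                        chimera_rate = 0)
  expect_equal(nrow(pets), 50)
  expect_true(all(classify_pet(pets) == "intra_chromosomal"))
  expect_true(all(pets$pos_a >= a$loops$start_a & pets$pos_a <= a$loops$end_a))
  expect_true(all(pets$pos_b >= a$loops$start_b & pets$pos_b <= a$loops$end_b))
})

test_that("chimera and background boundaries behave as defined", {
  g <- make_genome(seed = 8, n_chroms = 2, chrom_length = 5e6, n_genes = 50)
  a <- make_architecture(g, seed = 9, n_loops = 20)
  chim <- simulate_pets(a, g, seed = 10, n_background_pets = 100,
                        chimera_rate = 1)
  expect_true(all(classify_linker(chim$linker_a, chim$linker_b) == "chimeric"))

  selfonly <- simulate_pets(a, g, seed = 11, n_signal_pets = 0,
                            n_background_pets = 500,
                            background_mix = c(1, 0, 0))
  expect_true(all(classify_pet(selfonly) == "self_ligation"))
  expect_true(all(abs(selfonly$pos_b - selfonly$pos_a) <= 8000))
  calls <- call_loops(selfonly)
  expect_equal(calls$counts$clusters, 0)

  expect_error(simulate_pets(a, g, seed = 1, background_mix = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(simulate_pets(a, g, seed = 1, duplicate_rate = 1), "duplicate_rate")
})

test_that("expression model reproduces planted means and effects", {
  g <- make_genome(seed = 12, n_chroms = 2, chrom_length = 1e7, n_genes = 120)
  a <- make_architecture(g, seed = 13, n_loops = 60)
  # no noise: replicates equal the planted condition means exactly
  m0 <- effect_model(replicate_noise_cv = 0, per_enhancer_boost = 1.5,
                     mut_downregulation_factor = 1, seed = 20)
  e0 <- simulate_expression(a, g, m0)
  expect_equal(e0$tpm_wt_rep1, e0$wt_mean_true)
  expect_equal(e0$tpm_mut_rep1, e0$tpm_wt_rep1)  # factor 1: identity case

  # per_enhancer_boost: 3 connected enhancers vs 0 gives ratio 1.5^3 = 3.375
  base0 <- e0$wt_mean_true / 1.5^e0$n_enhancers_true
  expect_equal(e0$wt_mean_true / base0, 1.5^e0$n_enhancers_true)
  expect_equal(unique(round(1.5^3, 10)), 3.375)

  m <- effect_model(replicate_noise_cv = 0, mut_downregulation_factor = 0.15,
                    seed = 21)
  e <- simulate_expression(a, g, m)
  down <- e$planted_down
  expect_true(any(down))
  expect_equal(e$wt_mean_true[down] / e$mut_mean_true[down],
               rep(1 / 0.15, sum(down)))
  # planted log2 fold ratio is -log2(0.15) ~ 2.737
  expect_equal(log2(e$wt_mean_true[down] / e$mut_mean_true[down]),
               rep(-log2(0.15), sum(down)), tolerance = 1e-12)
  expect_true(all(e$mut_mean_true[!down] == e$wt_mean_true[!down]))

  # replicate noise is mean-preserving: empirical means approach the truth
  mk <- effect_model(replicate_noise_cv = 0.2, n_replicates = 200, seed = 22)
  ek <- simulate_expression(a, g, mk)
  wt_reps <- as.matrix(ek[, grep("^tpm_wt_rep", names(ek))])
  ratio <- rowMeans(wt_reps) / ek$wt_mean_true
  expect_lt(max(abs(ratio - 1)), 0.08)

  expect_error(effect_model(mut_downregulation_factor = 0), "factor")
  expect_error(effect_model(per_enhancer_boost = -1), "boost")
})

test_that("datasets are deterministic and round-trip through files", {
  ds1 <- simulate_dataset(seed = 30, genome_params = list(n_genes = 40),
                          arch_params = list(n_loops = 25,
                                             n_extra_enhancers = 10),
                          pet_params = list(n_background_pets = 800))
  ds2 <- simulate_dataset(seed = 30, genome_params = list(n_genes = 40),
                          arch_params = list(n_loops = 25,
                                             n_extra_enhancers = 10),
                          pet_params = list(n_background_pets = 800))
  expect_identical(ds1$pets, ds2$pets)
  expect_identical(ds1$expression, ds2$expression)
  expect_identical(ds1$arch$loops, ds2$arch$loops)

  td <- withr::local_tempdir()
  write_dataset(ds1, td)
  back <- read_dataset(td)
  expect_identical(back$pets$pos_a, ds1$pets$pos_a)
  expect_identical(back$pets$pos_b, ds1$pets$pos_b)
  expect_identical(back$expression$tpm_wt_rep2, ds1$expression$tpm_wt_rep2)
  expect_identical(back$genome$genes$tss, ds1$genome$genes$tss)
  expect_equal(length(back$sox2_peaks), length(ds1$arch$sox2_peaks))
  expect_equal(as.integer(back$bins$wt), ds1$bins$wt)
  # provenance: truth JSON records the seeds and planted parameters
  expect_equal(back$truth$master_seed, 30)
  expect_equal(back$truth$frac_promoter_mediated, 0.875)

  # BED format contract on the files as written: 0 <= start < end <= chrom len
  for (f in c("sox2_peaks.bed", "polII_peaks.bed", "k27_regions.bed")) {
    bed <- read.table(file.path(td, f), sep = "\t")
    expect_true(all(bed$V2 >= 0 & bed$V2 < bed$V3))
    expect_true(all(bed$V3 <= ds1$genome$chroms$length[
      match(bed$V1, ds1$genome$chroms$chrom)]))
  }
  # unwritable output path (a regular file in the way) errors out
  blocker <- withr::local_tempfile(lines = "x")
  expect_error(suppressWarnings(write_dataset(ds1, file.path(blocker, "sub"))),
               "cannot create")
})
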