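test_that("linker codes classify as the library chemistry dictates", {
  expect_equal(classify_linker("A", "A"), "non_chimeric")
  expect_equal(classify_linker("B", "B"), "non_chimeric")
  expect_equal(classify_linker("A", "B"), "chimeric")
  expect_equal(classify_linker("B", "A"), "chimeric")
  # single-bridge-linker libraries carry no codes
  expect_equal(classify_linker(NA, NA), "non_chimeric")
  expect_equal(classify_linker(c("A", "B"), c("A", "A")),
               c("non_chimeric", "chimeric"))
  expect_error(classify_linker("X", "A"), "unknown linker")
})

test_that("PET classes split at the 8-kb self-ligation boundary (inclusive)", {
  pets <- data.frame(chrom_a = c("chr1", "chr1", "chr1"),
                     pos_a = c(1000L, 1000L, 1000L),
                     chrom_b = c("chr1", "chr1", "chr2"),
                     pos_b = c(9000L, 9001L, 2000L))
  expect_equal(classify_pet(pets, self_span = 8000),
               c("self_ligation", "intra_chromosomal", "inter_chromosomal"))
})

test_that("deduplication merges within the joint 2-bp tolerance", {
  mk <- function(pa, pb) data.frame(chrom_a = "chr1", pos_a = pa,
                                    chrom_b = "chr1", pos_b = pb)
  expect_equal(nrow(deduplicate_pets(mk(c(100, 100), c(900, 900)))), 1)
  # offsets (2, 2) merge; (3, 0) do not
  expect_equal(nrow(deduplicate_pets(mk(c(100, 102), c(900, 902)))), 1)
  expect_equal(nrow(deduplicate_pets(mk(c(100, 103), c(900, 900)))), 2)
  empty <- data.frame(chrom_a = character(0), pos_a = integer(0),
                      chrom_b = character(0), pos_b = integer(0))
  expect_equal(nrow(deduplicate_pets(empty)), 0)
  # representative is the lexicographically smallest member
  kept <- deduplicate_pets(mk(c(102, 100), c(902, 900)))
  expect_equal(kept$pos_a, 100)
  # conservation: kept + removed = input
  x <- mk(c(100, 100, 100, 500), c(900, 900, 901, 905))
  d <- deduplicate_pets(x)
  expect_equal(nrow(d) + attr(d, "n_removed"), nrow(x))
})

test_that("clustering follows single linkage on both ends with 1-kb extension", {
  mk <- function(l, r) data.frame(chrom_a = "chr1", pos_a = l,
                                  chrom_b = "chr1", pos_b = r)
  # left chain 100-900 joins (<= 1000); 1901 splits from 900 (1001 > 1000)
  cl <- cluster_intra_pets(mk(c(100, 900, 1901), c(50000, 50000, 50000)))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$c, 2L)
  expect_equal(c(cl$start_a, cl$end_a), c(100L, 900L))

  cl5 <- cluster_intra_pets(mk(rep(1000, 5), rep(60000, 5)))
  expect_equal(cl5$c, 5L)
  expect_equal(c(cl5$start_a, cl5$end_a, cl5$start_b, cl5$end_b),
               c(1000L, 1000L, 60000L, 60000L))

  expect_error(cluster_intra_pets(data.frame(chrom_a = "chr1", pos_a = 1,
                                             chrom_b = "chr2", pos_b = 2)),
               "intra-chromosomal")
})

test_that("clustering matches the O(n^2) closure oracle and ignores order", {
  set.seed(41)
  n <- 180
  pets <- data.frame(
    chrom_a = "chr1",
    pos_a = sort(sample.int(40000, n)),
    chrom_b = "chr1", stringsAsFactors = FALSE)
  pets$pos_b <- pets$pos_a + sample(9000:30000, n, replace = TRUE)
  left <- pmin(pets$pos_a, pets$pos_b)
  right <- pmax(pets$pos_a, pets$pos_b)

  cl <- cluster_intra_pets(pets, extension = 1000)
  expect_identical(cluster_signature(pets, cl),
                   oracle_cluster_signature(left, right, 1000))
  # clusters partition the non-singleton PETs
  memb <- attr(cl, "membership")
  expect_equal(sum(cl$c), sum(!is.na(memb)))

  perm <- sample.int(n)
  cl_perm <- cluster_intra_pets(pets[perm, ], extension = 1000)
  expect_identical(cluster_signature(pets[perm, ], cl_perm),
                   cluster_signature(pets, cl))
})

test_that("hypergeometric tail p matches direct summation", {
  expect_equal(hypergeom_pvalue(0, 10, 10, 100), 1)
  expect_equal(hypergeom_pvalue(5, 5, 5, 5), 1)    # degenerate certainty
  expect_equal(hypergeom_pvalue(5, 10, 10, 100),
               oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)
  # symmetric in the two anchor counts
  expect_equal(hypergeom_pvalue(3, 7, 12, 60), hypergeom_pvalue(3, 12, 7, 60))
  expect_error(hypergeom_pvalue(6, 5, 10, 100), "min")
  expect_error(hypergeom_pvalue(2, 5, 120, 100), "T_total")
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calling enforces iPET, FDR and p thresholds jointly", {
  cl <- toy_clusters(rep("chr1", 3), c(1, 1, 1), c(10, 10, 10),
                     c(50000, 50000, 50000), c(50010, 50010, 50010),
                     c = c(3L, 2L, 5L), n_a = 1, n_b = 1,
                     p = c(0.01, 0.01, 0.01), q = c(0.04, 0.01, 0.06))
  out <- call_significant(cl, cluster_params("insitu"))
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  # the sonication dialect admits iPET-2 clusters
  out_tr1 <- call_significant(cl, cluster_params("tr1"))
  expect_equal(out_tr1$significant, c(TRUE, TRUE, FALSE))
})

test_that("pipeline conservation: class counts and dedup counts add up", {
  g <- make_genome(seed = 51, n_chroms = 2, chrom_length = 5e6, n_genes = 60)
  a <- make_architecture(g, seed = 52, n_loops = 30)
  pets <- simulate_pets(a, g, seed = 53, n_background_pets = 3000,
                        duplicate_rate = 0.1, chimera_rate = 0.1)
  calls <- call_loops(pets)
  cc <- calls$counts
  expect_equal(cc$self + cc$intra + cc$inter, cc$unique)
  expect_lte(cc$unique, cc$total - cc$chimeric)
  expect_gte(cc$total, cc$chimeric)
})

test_that("planted loops are recovered over 10x background with few false calls", {
  g <- make_genome(seed = 61, n_chroms = 2, chrom_length = 1e7, n_genes = 200)
  a <- make_architecture(g, seed = 62, n_loops = 50)
  n_signal <- sum(a$loops$intensity)
  expect_true(all(a$loops$intensity >= 8))
  pets <- simulate_pets(a, g, seed = 63, n_background_pets = 10 * n_signal)
  calls <- call_loops(pets)
  sig <- calls$clusters[calls$clusters$significant, ]

  matched_loops <- vapply(seq_len(nrow(a$loops)), function(i) {
    l <- a$loops[i, ]
    any(sig$chrom == l$chrom &
          abs((sig$start_a + sig$end_a) / 2 - (l$start_a + l$end_a) / 2) <= 2000 &
          abs((sig$start_b + sig$end_b) / 2 - (l$start_b + l$end_b) / 2) <= 2000)
  }, logical(1))
  expect_gte(sum(matched_loops), 45)

  call_is_planted <- vapply(seq_len(nrow(sig)), function(j) {
    any(a$loops$chrom == sig$chrom[j] &
          abs((a$loops$start_a + a$loops$end_a) / 2 -
                (sig$start_a[j] + sig$end_a[j]) / 2) <= 2000 &
          abs((a$loops$start_b + a$loops$end_b) / 2 -
                (sig$start_b[j] + sig$end_b[j]) / 2) <= 2000)
  }, logical(1))
  expect_lte(sum(!call_is_planted), 0.05 * nrow(sig))
})

test_that("tag re-pairing noise simulation is self-consistent", {
  pets <- uniform_intra_pets(20000, len = 5e6, seed = 71)
  sn <- shuffle_noise(pets, n_iterations = 10, seed = 72)
  expect_gt(sn$noise_ratio, 0.6)
  expect_lt(sn$noise_ratio, 1.4)
  expect_length(sn$simulated_clusters, 10)
  # deterministic given the seed
  sn2 <- shuffle_noise(pets, n_iterations = 10, seed = 72)
  expect_identical(sn$simulated_clusters, sn2$simulated_clusters)

  none <- data.frame(chrom_a = "chr1", pos_a = c(1000L, 90000L),
                     chrom_b = "chr1", pos_b = c(50000L, 500000L))
  expect_error(shuffle_noise(none, 5, 1), "no PET-2\\+ clusters")
})

test_that("normalized loop rates round half away from zero", {
  expect_equal(loops_per_million(7046, 691000), 10197)
  expect_equal(loops_per_million(96295, 13105813), 7348)
  expect_equal(loops_per_million(0, 1e6), 0)
  # 0.5 rounds up, not to even
  expect_equal(loops_per_million(1, 2e6), 1)
  expect_error(loops_per_million(10, 0), "> 0")
})
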