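test_that("nodes merge overlapping anchors transitively", {
  # [100,200) and [150,300) in half-open terms -> one node spanning both
  anchors <- toy_gr("chr1", c(100, 150), c(199, 299))
  nodes <- build_nodes(anchors)
  expect_length(nodes, 1)
  expect_equal(GenomicRanges::start(nodes), 100)
  expect_equal(GenomicRanges::end(nodes), 299)

  disjoint <- toy_gr("chr1", c(100, 500), c(200, 700))
  expect_length(build_nodes(disjoint), 2)

  # chain a-b, b-c where a and c do not touch: transitivity gives one node
  chain <- toy_gr("chr1", c(100, 180, 260), c(190, 270, 350))
  nodes3 <- build_nodes(chain)
  expect_length(nodes3, 1)
  expect_equal(nodes3$n_anchors, 3)
})

test_that("node merging agrees with a brute-force union-find oracle", {
  set.seed(81)
  n <- 400
  start <- sample.int(100000, n)
  width <- sample(200:3000, n, replace = TRUE)
  anchors <- toy_gr("chr1", start, start + width - 1)
  nodes <- build_nodes(anchors)

  # oracle: pairwise >= 1 bp overlap edges, transitive components
  e1 <- GenomicRanges::end(anchors)
  s1 <- GenomicRanges::start(anchors)
  overlap <- outer(s1, e1, `<=`) & outer(e1, s1, `>=`)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- which(is.na(comp) & apply(overlap[frontier, , drop = FALSE], 2, any))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  spans <- vapply(split(seq_len(n), comp), function(ix) {
    paste(min(s1[ix]), max(e1[ix]))
  }, character(1))
  got <- paste(GenomicRanges::start(nodes), GenomicRanges::end(nodes))
  expect_setequal(got, unname(spans))
  expect_lte(length(nodes), n)
})

test_that("anchor annotation applies the P > G > I priority at 1-bp overlap", {
  g <- toy_genome()
  # overlaps g1's promoter window (TSS 50000 +/- 2500) and g2's body? No --
  # craft an anchor overlapping the g2 body AND the g1 promoter window
  anchors <- toy_gr("chr1",
                    c(52000, 185000, 400000),
                    c(52400, 185400, 400400))
  ann <- annotate_anchor(anchors, g)
  expect_equal(ann$category, c("P", "G", "I"))
  expect_equal(ann$nearest_gene, c("g1", "g2", NA))

  # promoter priority: inside g2's body but within 2.5 kb of its TSS -> P
  near_tss <- toy_gr("chr1", 198000, 198400)
  expect_equal(annotate_anchor(near_tss, g)$category, "P")
  expect_error(annotate_anchor(toy_gr("chrX", 1, 10), g), "unknown chromosome")
})

test_that("interaction typing is symmetric and exhaustive", {
  expect_equal(classify_interaction("P", "P"), "P-P")
  expect_equal(classify_interaction("P", "G"), "P-nonP")
  expect_equal(classify_interaction("G", "P"), "P-nonP")
  expect_equal(classify_interaction("P", "I"), "P-nonP")
  expect_equal(classify_interaction("G", "I"), "nonP-nonP")
  expect_equal(classify_interaction("I", "I"), "nonP-nonP")
  combos <- expand.grid(a = c("P", "G", "I"), b = c("P", "G", "I"),
                        stringsAsFactors = FALSE)
  types <- classify_interaction(combos$a, combos$b)
  expect_true(all(types %in% c("P-P", "P-nonP", "nonP-nonP")))
  expect_identical(types, classify_interaction(combos$b, combos$a))
})

test_that("Pol II support requires a peak on both anchors", {
  cl <- toy_clusters(rep("chr1", 3),
                     c(1000, 1000, 1000), c(2000, 2000, 2000),
                     c(50000, 50000, 50000), c(51000, 51000, 51000))
  peaks_both <- toy_gr("chr1", c(1500, 50500), c(1600, 50600))
  peaks_one <- toy_gr("chr1", 1500, 1600)
  expect_equal(flag_polII_bound(cl, peaks_both), rep(TRUE, 3))
  expect_equal(flag_polII_bound(cl, peaks_one), rep(FALSE, 3))
  expect_equal(flag_polII_bound(cl, GenomicRanges::GRanges()), rep(FALSE, 3))
})

test_that("SOX2 flags distinguish promoter-side from distal-side binding", {
  g <- toy_genome()
  # three P-nonP interactions (promoter anchor at g1 TSS, distal at 400k)
  # and one P-P (g1 promoter to g2 promoter)
  cl <- toy_clusters(rep("chr1", 4),
                     c(49500, 49500, 49500, 49500),
                     c(50500, 50500, 50500, 50500),
                     c(400000, 420000, 440000, 199500),
                     c(400800, 420800, 440800, 200500))
  ann <- annotate_interactions(cl, g)
  expect_equal(ann$itype, c("P-nonP", "P-nonP", "P-nonP", "P-P"))

  # SOX2 on the promoter anchor only -> (any, not distal)
  sox_prom <- toy_gr("chr1", 50000, 50100)
  f <- flag_sox2(ann, sox_prom)
  expect_equal(f$sox2_any, rep(TRUE, 4))
  expect_equal(f$sox2_distal, rep(FALSE, 4))

  # SOX2 on the first distal anchor -> distal flag only there
  sox_dist <- toy_gr("chr1", 400100, 400200)
  f2 <- flag_sox2(ann, sox_dist)
  expect_equal(f2$sox2_any, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(f2$sox2_distal, c(TRUE, FALSE, FALSE, FALSE))
  # distal-positive implies P-nonP
  expect_true(all(ann$itype[f2$sox2_distal] == "P-nonP"))
})

test_that("interaction reproducibility matches midpoint windows", {
  a <- toy_clusters(rep("chr1", 3), c(1000, 30000, 60000), c(2000, 31000, 61000),
                    c(100000, 130000, 160000), c(101000, 131000, 161000))
  expect_equal(interaction_overlap(a, a, window = 0), 1.0)
  b_far <- toy_clusters("chr2", 1000, 2000, 100000, 101000)
  expect_equal(interaction_overlap(a, b_far, window = 10000), 0.0)
  # one interaction of b offset by 4 kb on both midpoints: matches at 5 kb
  b <- toy_clusters("chr1", 5000, 6000, 104000, 105000)
  expect_equal(interaction_overlap(a, b, window = 5000), 1 / 3)
  expect_equal(interaction_overlap(a, b, window = 3000), 0)
})

test_that("per-gene connectivity counts partners by category", {
  g <- toy_genome()
  # g1: two P-nonP (distal partners) and one P-P with g2
  cl <- toy_clusters(rep("chr1", 3),
                     c(49500, 49500, 49500), c(50500, 50500, 50500),
                     c(400000, 420000, 199500), c(400800, 420800, 200500))
  ann <- annotate_interactions(cl, g)
  conn <- summarize_connectivity(ann, g)
  g1 <- conn[conn$gene_id == "g1", ]
  expect_equal(g1$n_enhancer_partners, 2)
  expect_equal(g1$n_promoter_partners, 1)
  expect_equal(g1$category, "has_pe")
  g2 <- conn[conn$gene_id == "g2", ]
  expect_equal(g2$category, "pp_only")
  expect_equal(conn$category[conn$gene_id == "g3"], "not_connected")

  # permutation invariance of the counts
  conn_perm <- summarize_connectivity(ann[c(3, 1, 2), ], g)
  expect_identical(conn, conn_perm)

  # SOX2-bound distal partner sets has_sox2_pe
  conn_s <- summarize_connectivity(ann, g,
                                   sox2_peaks = toy_gr("chr1", 400100, 400200))
  expect_true(conn_s$has_sox2_pe[conn_s$gene_id == "g1"])
  expect_false(conn_s$has_sox2_pe[conn_s$gene_id == "g2"])
})

test_that("called interactions partition into the three types (synthetic run)", {
  g <- make_genome(seed = 91, n_chroms = 2, chrom_length = 1e7, n_genes = 150)
  a <- make_architecture(g, seed = 92, n_loops = 80)
  pets <- simulate_pets(a, g, seed = 93, n_background_pets = 5000)
  calls <- call_loops(pets)
  sig <- calls$clusters[calls$clusters$significant, ]
  ann <- annotate_interactions(sig, g, sox2_peaks = a$sox2_peaks,
                               polII_peaks = a$polII_peaks)
  expect_equal(sum(table(ann$itype)), nrow(ann))
  expect_true(all(ann$itype %in% c("P-P", "P-nonP", "nonP-nonP")))
  # planted loops carry Pol II peaks on both anchors
  expect_gte(mean(ann$polII_both), 0.9)
})
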