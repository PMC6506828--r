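# Independent enumeration oracles and small fixture builders. All oracles are
# deliberately brute-force and share no code with the implementation paths
# they check.

# Upper-tail hypergeometric P(X >= c) by direct summation of pmf terms
# computed from binomial coefficients.
oracle_hyper_tail <- function(cc, n_a, n_b, T_total) {
  ks <- seq(cc, min(n_a, n_b))
  if (cc > min(n_a, n_b)) return(0)
  sum(choose(n_b, ks) * choose(T_total - n_b, n_a - ks)) / choose(T_total, n_a)
}

# Two-sided Fisher p: sum of hypergeometric point probabilities of all tables
# (with the same margins) at most as probable as the observed one.
oracle_fisher_two_sided <- function(k, n, m, N) {
  lo <- max(0, n + m - N)
  hi <- min(n, m)
  ks <- lo:hi
  probs <- choose(m, ks) * choose(N - m, n - ks) / choose(N, n)
  obs <- probs[ks == k]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# O(n^2) transitive closure of the joint both-ends-within-extension relation.
# Returns a canonical signature: sorted per-cluster member coordinate strings,
# singletons dropped.
oracle_cluster_signature <- function(left, right, extension) {
  n <- length(left)
  adj <- outer(left, left, function(a, b) abs(a - b) <= extension) &
    outer(right, right, function(a, b) abs(a - b) <= extension)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- which(is.na(comp) & apply(adj[frontier, , drop = FALSE], 2, any))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  sizes <- table(comp)
  keep <- comp %in% as.integer(names(sizes)[sizes >= 2])
  sig <- tapply(paste(left[keep], right[keep], sep = ":"), comp[keep],
                function(z) paste(sort(z), collapse = ";"))
  sort(unname(sig))
}

# Canonical signature of a cluster table plus its membership attribute.
cluster_signature <- function(pets, clusters) {
  memb <- attr(clusters, "membership")
  keep <- !is.na(memb)
  left <- pmin(pets$pos_a, pets$pos_b)[keep]
  right <- pmax(pets$pos_a, pets$pos_b)[keep]
  sig <- tapply(paste(left, right, sep = ":"), memb[keep],
                function(z) paste(sort(z), collapse = ";"))
  sort(unname(sig))
}

# Exact two-sided signed-rank p by enumerating every sign assignment.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Hand Benjamini-Hochberg step-up: q_i = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Uniform random intra-chromosomal PETs with independent ends (the law the
# tag re-pairing simulation preserves).
uniform_intra_pets <- function(n, chrom = "chr1", len = 5e6, min_dist = 8001,
                               seed = 1) {
  set.seed(seed)
  p1 <- floor(runif(n, 1, len))
  p2 <- floor(runif(n, 1, len))
  df <- data.frame(chrom_a = chrom, pos_a = pmin(p1, p2),
                   chrom_b = chrom, pos_b = pmax(p1, p2),
                   stringsAsFactors = FALSE)
  df[df$pos_b - df$pos_a >= min_dist, ]
}

# Tiny deterministic gene model: one gene per kilobase slot on chr1/chr2.
toy_genome <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2"),
    tss = c(50000L, 200000L, 100000L),
    strand = c("+", "-", "+"),
    start = c(50000L, 180000L, 100000L),
    end = c(60000L, 200000L, 115000L),
    stringsAsFactors = FALSE
  )
  structure(list(chroms = data.frame(chrom = c("chr1", "chr2"),
                                     length = c(1000000L, 1000000L),
                                     stringsAsFactors = FALSE),
                 genes = genes, seed = 0L),
            class = "syn_genome")
}

toy_gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

# Minimal cluster table builder. Formals are dot-prefixed so short extra
# column names passed through `...` (like `c`) never partially match them.
toy_clusters <- function(.chrom, .start_a, .end_a, .start_b, .end_b, ...) {
  data.frame(cluster_id = sprintf("c%02d", seq_along(.chrom)), chrom = .chrom,
             start_a = .start_a, end_a = .end_a, start_b = .start_b,
             end_b = .end_b, ..., stringsAsFactors = FALSE)
}

# Uniform draw from an integer vector without the length-1 sample() trap.
pick1 <- function(v) v[sample.int(length(v), 1)]
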