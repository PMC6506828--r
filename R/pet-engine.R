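#' Clustering and significance parameters for loop calling
#'
#' Two protocol dialects are supported. The sonication/half-linker dialect
#' (`"tr1"`) calls clusters at iPET >= 2; the in-situ/tagmentation dialect
#' (`"insitu"`, default) requires iPET >= 3. Both use an 8-kb self-ligation
#' span, 1-kb end clustering, 2-bp duplicate merging and FDR < 0.05 with
#' p < 0.05.
#'
#' @param dialect `"insitu"` or `"tr1"`.
#' @param self_span Maximum tag span of a self-ligation PET (bp, inclusive).
#' @param extension Maximum per-end distance for clustering (bp).
#' @param dedup_tolerance Joint per-end tolerance for duplicate merging (bp).
#' @param min_ipet Minimum cluster size called significant; defaults by dialect.
#' @param fdr_cutoff,p_cutoff Significance thresholds.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(dialect = c("insitu", "tr1"), self_span = 8000,
                           extension = 1000, dedup_tolerance = 2,
                           min_ipet = NULL, fdr_cutoff = 0.05, p_cutoff = 0.05) {
  dialect <- match.arg(dialect)
  if (is.null(min_ipet)) min_ipet <- if (dialect == "insitu") 3L else 2L
  stopifnot(self_span > 0, extension > 0, dedup_tolerance >= 0, min_ipet >= 2,
            fdr_cutoff > 0, p_cutoff > 0)
  structure(list(dialect = dialect, self_span = self_span, extension = extension,
                 dedup_tolerance = dedup_tolerance, min_ipet = as.integer(min_ipet),
                 fdr_cutoff = fdr_cutoff, p_cutoff = p_cutoff),
            class = "cluster_params")
}

#' Classify PET linker composition
#'
#' Full linkers AA/BB arise from intra-molecular circularization and are
#' non-chimeric; AB/BA arise from inter-molecular ligation and are chimeric
#' noise. Absent codes (NA) correspond to a single-bridge-linker library and
#' are treated as non-chimeric.
#'
#' @param linker_a,linker_b Character vectors of codes in `{"A", "B"}` or NA.
#' @return Character vector, `"chimeric"` or `"non_chimeric"`.
#' @export
classify_linker <- function(linker_a, linker_b) {
  ok <- function(x) is.na(x) | x %in% c("A", "B")
  if (!all(ok(linker_a)) || !all(ok(linker_b))) {
    stop("unknown linker code; expected 'A', 'B' or NA")
  }
  ifelse(is.na(linker_a) | is.na(linker_b) | linker_a == linker_b,
         "non_chimeric", "chimeric")
}

#' Classify a non-chimeric PET by its tag geometry
#'
#' Tags on different chromosomes are inter-chromosomal; same-chromosome tags
#' with span `<= self_span` (inclusive, default 8 kb) are self-ligation; the
#' rest are intra-chromosomal and carry the loop signal.
#'
#' @param pets Tag-pair data.frame.
#' @param self_span Span threshold in bp.
#' @return Character vector with values `inter_chromosomal`, `self_ligation`,
#'   `intra_chromosomal`.
#' @export
classify_pet <- function(pets, self_span = 8000) {
  ifelse(pets$chrom_a != pets$chrom_b, "inter_chromosomal",
         ifelse(abs(pets$pos_b - pets$pos_a) <= self_span,
                "self_ligation", "intra_chromosomal"))
}

#' Merge clonal PCR duplicates
#'
#' PETs whose head and tail tags both lie within `tolerance` bp of another
#' PET's are merged (transitively), keeping the lexicographically smallest
#' (chrom, pos_a, pos_b) member of each duplicate group.
#'
#' @param pets Tag-pair data.frame.
#' @param tolerance Per-end tolerance in bp (both ends must be within it).
#' @return The retained PETs, sorted by (chrom_a, pos_a, chrom_b, pos_b),
#'   with attribute `n_removed`.
#' @export
deduplicate_pets <- function(pets, tolerance = 2) {
  stopifnot(tolerance >= 0)
  if (nrow(pets) == 0) return(pets)
  ord <- order(pets$chrom_a, pets$pos_a, pets$chrom_b, pets$pos_b)
  pets <- pets[ord, , drop = FALSE]
  key <- paste(pets$chrom_a, pets$chrom_b)
  keep <- logical(nrow(pets))
  for (grp in split(seq_len(nrow(pets)), key)) {
    pa <- pets$pos_a[grp]
    pb <- pets$pos_b[grp]
    hits <- IRanges::findOverlaps(IRanges::IRanges(pa, width = 1L),
                                  maxgap = as.integer(tolerance) - 1L,
                                  drop.self = TRUE, drop.redundant = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    sel <- abs(pb[q] - pb[s]) <= tolerance
    comp <- union_find(length(grp), cbind(q[sel], s[sel]))
    # rows are sorted, so the first member of each component is the
    # lexicographically smallest
    keep[grp[!duplicated(comp)]] <- TRUE
  }
  out <- pets[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(pets) - nrow(out)
  out
}

#' Cluster intra-chromosomal PETs into candidate interactions
#'
#' Single-linkage clustering: two PETs join the same cluster iff their left
#' ends are within `extension` bp AND their right ends are within `extension`
#' bp, transitively closed. Cluster anchors span the member tag positions on
#' each side. Singleton PETs are noise and are discarded.
#'
#' @param pets Deduplicated intra-chromosomal tag pairs.
#' @param extension Per-end clustering distance in bp (default 1 kb).
#' @return data.frame of clusters: `cluster_id`, `chrom`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `c` (iPET count), sorted by coordinates. The
#'   attribute `membership` maps each input PET (in input order) to its
#'   cluster id or NA for singletons.
#' @export
cluster_intra_pets <- function(pets, extension = 1000) {
  if (nrow(pets) > 0 && any(pets$chrom_a != pets$chrom_b)) {
    stop("cluster_intra_pets expects intra-chromosomal PETs only")
  }
  n <- nrow(pets)
  membership <- rep(NA_character_, n)
  if (n == 0) {
    out <- empty_clusters()
    attr(out, "membership") <- membership
    return(out)
  }
  left <- pmin(pets$pos_a, pets$pos_b)
  right <- pmax(pets$pos_a, pets$pos_b)
  rows <- split(seq_len(n), pets$chrom_a)

  clusters <- list()
  for (ch in names(rows)) {
    idx <- rows[[ch]]
    hits <- IRanges::findOverlaps(IRanges::IRanges(left[idx], width = 1L),
                                  maxgap = as.integer(extension) - 1L,
                                  drop.self = TRUE, drop.redundant = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    sel <- abs(right[idx][q] - right[idx][s]) <= extension
    comp <- union_find(length(idx), cbind(q[sel], s[sel]))
    size <- tabulate(comp)
    keep <- size[comp] >= 2
    if (!any(keep)) next
    cl <- data.frame(
      chrom = ch,
      start_a = as.integer(tapply(left[idx][keep], comp[keep], min)),
      end_a = as.integer(tapply(left[idx][keep], comp[keep], max)),
      start_b = as.integer(tapply(right[idx][keep], comp[keep], min)),
      end_b = as.integer(tapply(right[idx][keep], comp[keep], max)),
      c = as.integer(tapply(comp[keep], comp[keep], length)),
      comp = as.integer(names(tapply(comp[keep], comp[keep], length))),
      stringsAsFactors = FALSE
    )
    clusters[[ch]] <- list(cl = cl, idx = idx, comp = comp)
  }
  if (length(clusters) == 0) {
    out <- empty_clusters()
    attr(out, "membership") <- membership
    return(out)
  }
  all_cl <- do.call(rbind, lapply(clusters, `[[`, "cl"))
  ord <- order(all_cl$chrom, all_cl$start_a, all_cl$start_b, all_cl$end_a,
               all_cl$end_b)
  all_cl <- all_cl[ord, , drop = FALSE]
  all_cl$cluster_id <- sprintf("cluster_%05d", seq_len(nrow(all_cl)))
  for (ch in names(clusters)) {
    z <- clusters[[ch]]
    sel <- all_cl$chrom == ch
    id_of_comp <- stats::setNames(all_cl$cluster_id[sel], all_cl$comp[sel])
    membership[z$idx] <- id_of_comp[as.character(z$comp)]
  }
  all_cl$comp <- NULL
  rownames(all_cl) <- NULL
  all_cl <- all_cl[, c("cluster_id", "chrom", "start_a", "end_a",
                       "start_b", "end_b", "c")]
  attr(all_cl, "membership") <- membership
  all_cl
}

empty_clusters <- function() {
  data.frame(cluster_id = character(0), chrom = character(0),
             start_a = integer(0), end_a = integer(0),
             start_b = integer(0), end_b = integer(0), c = integer(0),
             stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric p-value for an interaction cluster
#'
#' The significance model for a cluster with `c` member PETs considers the
#' tag counts `n_a`, `n_b` overlapping its two anchors and the sequencing
#' depth `T` (total intra-chromosomal PETs): `p = P(X >= c)` where `X` is
#' hypergeometric with population `T`, `n_a` draws and `n_b` successes
#' (symmetric in `n_a`, `n_b`).
#'
#' @param c Observed iPET count(s).
#' @param n_a,n_b Anchor tag counts.
#' @param T_total Population size (total intra-chromosomal PETs).
#' @return p-value(s) in (0, 1].
#' @export
hypergeom_pvalue <- function(c, n_a, n_b, T_total) {
  if (any(c < 0) || any(c > pmin(n_a, n_b))) {
    stop("require 0 <= c <= min(n_a, n_b)")
  }
  if (any(n_a > T_total) || any(n_b > T_total)) {
    stop("require n_a, n_b <= T_total")
  }
  p <- stats::phyper(c - 1, n_b, T_total - n_b, n_a, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Count tag ends (both PET sides) overlapping each anchor of each cluster.
count_anchor_tags <- function(clusters, pets) {
  tags <- gr(c(pets$chrom_a, pets$chrom_b), c(pets$pos_a, pets$pos_b),
             c(pets$pos_a, pets$pos_b))
  anch_a <- gr(clusters$chrom, clusters$start_a, clusters$end_a)
  anch_b <- gr(clusters$chrom, clusters$start_b, clusters$end_b)
  list(n_a = GenomicRanges::countOverlaps(anch_a, tags),
       n_b = GenomicRanges::countOverlaps(anch_b, tags))
}

#' Score clusters with the hypergeometric model and BH FDR
#'
#' @param clusters Cluster table from [cluster_intra_pets()].
#' @param pets The deduplicated intra-chromosomal PETs the clusters came from
#'   (defines anchor tag counts and the population size).
#' @return Clusters with `n_a`, `n_b`, `p`, `q` columns added.
#' @export
score_clusters <- function(clusters, pets) {
  if (nrow(clusters) == 0) {
    clusters$n_a <- clusters$n_b <- integer(0)
    clusters$p <- clusters$q <- numeric(0)
    return(clusters)
  }
  counts <- count_anchor_tags(clusters, pets)
  clusters$n_a <- counts$n_a
  clusters$n_b <- counts$n_b
  clusters$p <- hypergeom_pvalue(clusters$c, clusters$n_a, clusters$n_b,
                                 nrow(pets))
  clusters$q <- bh_fdr(clusters$p)
  clusters
}

#' Flag significant interaction clusters
#'
#' A cluster is significant iff `c >= min_ipet`, `q < fdr_cutoff` and
#' `p < p_cutoff`. Flags are added; nothing is filtered or mutated otherwise.
#'
#' @param clusters Scored cluster table.
#' @param params A [cluster_params()].
#' @return Clusters with a logical `significant` column.
#' @export
call_significant <- function(clusters, params = cluster_params()) {
  stopifnot(all(c("p", "q") %in% names(clusters)))
  clusters$significant <- clusters$c >= params$min_ipet &
    clusters$q < params$fdr_cutoff & clusters$p < params$p_cutoff
  clusters
}

#' Call loops from raw tag pairs
#'
#' Full PET-processing driver: drop chimeric PETs (by linker code), merge
#' duplicates, classify the remainder into self-ligation, intra- and
#' inter-chromosomal classes, cluster the intra-chromosomal PETs, score with
#' the hypergeometric model, adjust with BH, and flag significant clusters.
#'
#' @param pets Raw tag-pair data.frame (columns as written by
#'   [write_pets_tsv()]).
#' @param params A [cluster_params()].
#' @return A list of class `loop_calls`: `clusters` (scored, flagged),
#'   `pets_intra` (the deduplicated intra-chromosomal PETs) and `counts`
#'   (total, chimeric, unique, self, intra, inter, clusters, significant).
#' @export
call_loops <- function(pets, params = cluster_params()) {
  n_total <- nrow(pets)
  has_linker <- all(c("linker_a", "linker_b") %in% names(pets))
  if (has_linker) {
    chim <- classify_linker(pets$linker_a, pets$linker_b) == "chimeric"
  } else {
    chim <- rep(FALSE, n_total)
  }
  nonchim <- pets[!chim, , drop = FALSE]
  dedup <- deduplicate_pets(nonchim, params$dedup_tolerance)
  cls <- classify_pet(dedup, params$self_span)
  intra <- dedup[cls == "intra_chromosomal", , drop = FALSE]
  clusters <- cluster_intra_pets(intra, params$extension)
  clusters <- score_clusters(clusters, intra)
  clusters <- call_significant(clusters, params)
  structure(list(
    clusters = clusters,
    pets_intra = intra,
    params = params,
    counts = list(
      total = n_total,
      chimeric = sum(chim),
      unique = nrow(dedup),
      self = sum(cls == "self_ligation"),
      intra = sum(cls == "intra_chromosomal"),
      inter = sum(cls == "inter_chromosomal"),
      clusters = nrow(clusters),
      significant = sum(clusters$significant)
    )
  ), class = "loop_calls")
}

#' @export
print.loop_calls <- function(x, ...) {
  with(x$counts, cat(sprintf(
    paste0("loop calls: %d PETs (%d chimeric removed, %d unique) -> ",
           "self %d / intra %d / inter %d; %d clusters, %d significant\n"),
    total, chimeric, unique, self, intra, inter, clusters, significant)))
  invisible(x)
}

#' Noise level by random tag re-pairing
#'
#' Breaks the pairing of the observed intra-chromosomal PETs: left and right
#' tags are pooled per chromosome and re-paired uniformly at random, the
#' simulated PETs are re-clustered, and PET-2+ cluster counts are compared.
#' The noise level is the mean simulated cluster count divided by the real
#' cluster count.
#'
#' @param pets Deduplicated intra-chromosomal tag pairs.
#' @param n_iterations Number of re-pairing iterations.
#' @param seed Integer seed.
#' @param params A [cluster_params()] (only `extension` is used).
#' @return A list: `noise_ratio`, `real_clusters`, `simulated_clusters`
#'   (per-iteration counts).
#' @export
shuffle_noise <- function(pets, n_iterations = 20, seed = 1,
                          params = cluster_params()) {
  real <- cluster_intra_pets(pets, params$extension)
  n_real <- nrow(real)
  if (n_real == 0) stop("no PET-2+ clusters in the input; noise ratio undefined")
  left <- pmin(pets$pos_a, pets$pos_b)
  right <- pmax(pets$pos_a, pets$pos_b)
  rows <- split(seq_len(nrow(pets)), pets$chrom_a)
  sims <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(it) {
      pa <- left
      pb <- right
      for (idx in rows) {
        pb[idx] <- pb[idx][sample.int(length(idx))]
      }
      sim <- data.frame(chrom_a = pets$chrom_a,
                        pos_a = pmin(pa, pb), pos_b = pmax(pa, pb),
                        chrom_b = pets$chrom_a, stringsAsFactors = FALSE)
      nrow(cluster_intra_pets(sim, params$extension))
    }, numeric(1))
  })
  list(noise_ratio = mean(sims) / n_real, real_clusters = n_real,
       simulated_clusters = sims)
}

#' Loops per million intra-chromosomal PETs
#'
#' Normalized interaction count: `round(n_loops / n_intra_pets * 1e6)`,
#' rounding half away from zero.
#'
#' @param n_loops Number of significant loops.
#' @param n_intra_pets Number of intra-chromosomal PETs.
#' @return Integer-valued normalized rate.
#' @export
loops_per_million <- function(n_loops, n_intra_pets) {
  if (any(n_intra_pets <= 0)) stop("n_intra_pets must be > 0")
  round_half_away(n_loops / n_intra_pets * 1e6)
}

#' Published sequencing/interaction summary of the six Pol II ChIA-PET runs
#'
#' Intra-chromosomal PET totals, significant loop counts and Pol II-bound
#' loop counts for the three wild-type (wTR1-3) and three Sox2-mutant
#' (mTR1-3) neural-stem-cell Pol II ChIA-PET libraries, as published.
#' Pol II-bound loop counts are available for the in-situ libraries only.
#' Included so the normalized per-million loop rates can be recomputed with
#' [loops_per_million()].
#'
#' @return data.frame with columns `sample`, `intra_pets`,
#'   `significant_loops`, `polii_loops`.
#' @export
chia_pet_run_metrics <- function() {
  data.frame(
    sample = c("wTR1", "wTR2", "wTR3", "mTR1", "mTR2", "mTR3"),
    intra_pets = c(691000, 13105813, 10207155, 1300000, 9360576, 6119151),
    significant_loops = c(7046, 96295, 63458, 2984, 29713, 15561),
    polii_loops = c(NA, 18022, 7346, NA, 2878, 3202),
    stringsAsFactors = FALSE
  )
}
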