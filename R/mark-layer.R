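#' Standardize histone-mark peak intervals
#'
#' Peaks shorter than `min_len` are extended symmetrically around their
#' midpoint to `min_len` bp (matching peak resolution); overlapping results
#' are merged. Idempotent: standardizing twice equals once.
#'
#' @param peaks GRanges of narrowPeak-like intervals.
#' @param min_len Minimum standardized length in bp (default 2 kb).
#' @return GRanges of standardized, merged regions.
#' @export
standardize_peaks <- function(peaks, min_len = 2000) {
  if (length(peaks) == 0) return(peaks)
  w <- GenomicRanges::width(peaks)
  short <- w < min_len
  if (any(short)) {
    mid <- floor((GenomicRanges::start(peaks)[short] +
                    GenomicRanges::end(peaks)[short]) / 2)
    half <- floor(min_len / 2)
    new_start <- pmax(1L, mid - half + 1L)
    peaks2 <- peaks
    GenomicRanges::ranges(peaks2)[short] <-
      IRanges::IRanges(start = new_start, end = new_start + min_len - 1L)
    peaks <- peaks2
  }
  reduce_sorted(GenomicRanges::granges(peaks))
}

#' Split mark regions into promoter and distal sets
#'
#' A region is a promoter region when it lies within `window` bp of an
#' annotated TSS (minimum distance between the region interval and the TSS
#' point, endpoints inclusive); otherwise it is a putative distal enhancer.
#' The split is an exhaustive partition.
#'
#' @param regions Standardized mark regions (GRanges).
#' @param tss GRanges of TSS points (width 1) or a `syn_genome`.
#' @param window Distance threshold in bp (default 1 kb).
#' @return List with elements `promoter` and `distal`.
#' @export
split_promoter_distal <- function(regions, tss, window = 1000) {
  if (inherits(tss, "syn_genome")) tss <- tss_gr(tss)
  win <- GenomicRanges::resize(tss, width = 2 * window + 1, fix = "center")
  is_prom <- IRanges::overlapsAny(regions, win)
  list(promoter = regions[is_prom], distal = regions[!is_prom])
}

#' Enhancer chromatin state of query intervals
#'
#' Active enhancers carry both H3K27ac and H3K4me1; poised enhancers carry
#' H3K4me1 only; regions with H3K27ac only or neither mark are reported as
#' `k27_only` and `none`.
#'
#' @param query GRanges to classify.
#' @param k27,k4 Standardized H3K27ac and H3K4me1 region sets (GRanges).
#' @return Character vector: `active`, `poised`, `k27_only` or `none`.
#' @export
enhancer_state <- function(query, k27, k4) {
  h27 <- IRanges::overlapsAny(query, k27)
  h4 <- IRanges::overlapsAny(query, k4)
  ifelse(h27 & h4, "active",
         ifelse(h4, "poised", ifelse(h27, "k27_only", "none")))
}

#' Binarize bin counts against a Poisson background
#'
#' A bin is enriched when the upper-tail Poisson probability of its read
#' count under the genome-wide background rate is below `p_threshold`:
#' `P(X >= r | lambda) < p_threshold` with `lambda` the mean reads per bin.
#'
#' @param counts Integer vector of per-bin read counts.
#' @param p_threshold Poisson tail threshold (default 1e-4).
#' @param lambda Background rate; defaults to `mean(counts)`. Pass a rate
#'   estimated over unmasked bins to exclude unmappable regions.
#' @return Logical vector of enriched flags.
#' @export
binarize_bins <- function(counts, p_threshold = 1e-4, lambda = mean(counts)) {
  if (!is.finite(lambda) || lambda <= 0) stop("background rate must be > 0")
  stats::ppois(counts - 1, lambda, lower.tail = FALSE) < p_threshold
}

#' Chi-square test for WT/MUT differential bin enrichment
#'
#' For a region with `r_wt` reads of `R_wt` total in WT and `r_mut` of
#' `R_mut` in MUT, tests the 2x2 table
#' `[[r_wt, R_wt - r_wt], [r_mut, R_mut - r_mut]]` with a 1-df chi-square
#' (no continuity correction by default). Regions with p below `p_threshold`
#' are differentially enriched. Vectorized over bins.
#'
#' @param r_wt,r_mut Per-bin read counts.
#' @param R_wt,R_mut Genome-wide mapped read totals.
#' @param p_threshold Significance threshold (default 1e-4).
#' @param correct Apply the Yates continuity correction.
#' @return data.frame with `chi2`, `p`, `differential`.
#' @export
differential_bins <- function(r_wt, r_mut, R_wt, R_mut, p_threshold = 1e-4,
                              correct = FALSE) {
  stopifnot(all(r_wt >= 0), all(r_mut >= 0), R_wt > 0, R_mut > 0,
            all(r_wt <= R_wt), all(r_mut <= R_mut))
  a <- r_wt; b <- R_wt - r_wt; c_ <- r_mut; d <- R_mut - r_mut
  n <- R_wt + R_mut
  expected_min <- pmin((a + b) * (a + c_), (a + b) * (b + d),
                       (c_ + d) * (a + c_), (c_ + d) * (b + d)) / n
  if (any(expected_min < 1)) {
    warning("chi-square expected cell count < 1 for some bins; p reported as computed")
  }
  num <- abs(a * d - b * c_)
  if (correct) num <- pmax(0, num - n / 2)
  chi2 <- n * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  chi2[!is.finite(chi2)] <- 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(chi2 = chi2, p = p, differential = p < p_threshold)
}

#' Sliding windows tiling a genome
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window Window size in bp.
#' @param step Stride in bp.
#' @return GRanges of windows.
#' @export
sliding_windows <- function(chrom_lengths, window = 3000, step = 500) {
  parts <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1L, max(1L, chrom_lengths[[ch]] - window + 1L), by = step)
    list(chrom = rep(ch, length(starts)), start = starts,
         end = pmin(starts + window - 1L, chrom_lengths[[ch]]))
  })
  gr(unlist(lapply(parts, `[[`, "chrom")),
     unlist(lapply(parts, `[[`, "start")),
     unlist(lapply(parts, `[[`, "end")))
}

#' Build a mappability mask from window coverage
#'
#' Windows with zero reads are unmappable; their union is merged with any
#' assembly-gap and blacklist intervals into a single excluded-region mask.
#'
#' @param windows GRanges of sliding windows (e.g. [sliding_windows()] with
#'   3-kb windows at 500-bp stride).
#' @param counts Per-window read counts.
#' @param gaps,blacklist Optional GRanges of additional excluded intervals.
#' @return GRanges: merged, sorted mask.
#' @export
build_unmappable_mask <- function(windows, counts, gaps = NULL, blacklist = NULL) {
  stopifnot(length(windows) == length(counts))
  mask <- GenomicRanges::granges(windows[counts == 0])
  if (!is.null(gaps)) mask <- c(mask, GenomicRanges::granges(gaps))
  if (!is.null(blacklist)) mask <- c(mask, GenomicRanges::granges(blacklist))
  if (length(mask) == 0) return(mask)
  sort(GenomicRanges::reduce(sort(mask)))
}

#' Random-sampling enrichment of one interval set in another
#'
#' Compares the observed overlap of `query` with `target` against `n_sets`
#' random interval sets, each with the same number of elements and the same
#' element lengths as `query`, placed uniformly in the unmasked genome
#' (sampled across chromosomes proportionally to placeable positions; no
#' sampled interval ever intersects the mask). The empirical p-value uses the
#' add-one estimator `(1 + #{null >= observed}) / (n_sets + 1)`, so an
#' observed overlap above every null value is reported as p < 1/(n_sets+1).
#'
#' @param query,target GRanges.
#' @param chrom_lengths Named chromosome-length vector.
#' @param mask Optional GRanges of excluded regions.
#' @param n_sets Number of random sets (default 1000).
#' @param seed Integer seed.
#' @param statistic `"elements"` (number of query elements overlapping the
#'   target by >= 1 bp) or `"bp"` (total overlapping base pairs).
#' @return List: `observed`, `null` (length `n_sets`), `p`, `null_mean`,
#'   `null_sd`, `statistic`.
#' @export
empirical_enrichment <- function(query, target, chrom_lengths, mask = NULL,
                                 n_sets = 1000, seed = 1,
                                 statistic = c("elements", "bp")) {
  statistic <- match.arg(statistic)
  whole <- gr(names(chrom_lengths), 1L, as.integer(chrom_lengths))
  free <- if (is.null(mask) || length(mask) == 0) whole else
    GenomicRanges::setdiff(whole, mask)
  fw <- GenomicRanges::width(free)
  fs <- GenomicRanges::start(free)
  fchr <- as.character(GenomicRanges::seqnames(free))

  stat_fun <- function(q) {
    if (statistic == "elements") {
      sum(IRanges::overlapsAny(q, target))
    } else {
      hits <- GenomicRanges::findOverlaps(q, target)
      sum(GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(q)[S4Vectors::queryHits(hits)],
        GenomicRanges::ranges(target)[S4Vectors::subjectHits(hits)])))
    }
  }
  observed <- stat_fun(query)
  lens <- GenomicRanges::width(query)
  nq <- length(query)

  null <- with_seed(seed, {
    # place each query element n_sets times: uniform over all valid start
    # positions across free segments
    starts <- matrix(NA_integer_, nrow = nq, ncol = n_sets)
    chrom_store <- matrix(NA_character_, nrow = nq, ncol = n_sets)
    for (i in seq_len(nq)) {
      valid <- pmax(fw - lens[i] + 1L, 0L)
      total <- sum(as.numeric(valid))
      if (total <= 0) {
        stop("mask leaves no room to place an element of length ", lens[i])
      }
      cum <- cumsum(as.numeric(valid))
      r <- floor(stats::runif(n_sets) * total)  # 0-based position index
      seg <- findInterval(r, cum) + 1L          # r < cum[seg]
      offset <- r - c(0, cum)[seg]
      starts[i, ] <- as.integer(fs[seg] + offset)
      chrom_store[i, ] <- fchr[seg]
    }
    # one GRanges across all sets; per-set statistics by aggregation
    set_id <- rep(seq_len(n_sets), each = nq)
    all_gr <- gr(as.vector(chrom_store), as.vector(starts),
                 as.vector(starts) + rep(lens, n_sets) - 1L)
    if (statistic == "elements") {
      hit <- IRanges::overlapsAny(all_gr, target)
      as.numeric(tabulate(set_id[hit], nbins = n_sets))
    } else {
      hits <- GenomicRanges::findOverlaps(all_gr, target)
      qh <- S4Vectors::queryHits(hits)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(all_gr)[qh],
        GenomicRanges::ranges(target)[S4Vectors::subjectHits(hits)]))
      out <- numeric(n_sets)
      agg <- rowsum(w, set_id[qh])
      out[as.integer(rownames(agg))] <- agg
      out
    }
  })
  p <- (1 + sum(null >= observed)) / (n_sets + 1)
  list(observed = observed, null = null, p = p,
       null_mean = mean(null), null_sd = stats::sd(null),
       statistic = statistic)
}
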