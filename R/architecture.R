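#' Plant a regulatory architecture: loops, enhancers and peak sets
#'
#' Lays chromatin loops over a synthetic genome with a controlled mixture of
#' interaction types, places putative enhancers at distal loop anchors, and
#' derives SOX2, Pol II and histone-mark (H3K27ac, H3K4me1) peak sets. The
#' defaults mirror the regulatory landscape observed in wild-type neural stem
#' cells: 85-90% of interactions promoter-mediated (split evenly between
#' promoter-promoter and promoter-enhancer), roughly 40% of distal elements
#' SOX2-bound, and at least 95% of SOX2-bound distal anchors carrying both
#' active enhancer marks.
#'
#' Promoter anchors are centred on a gene's TSS; distal anchors are kept more
#' than `promoter_window + anchor_width` away from every TSS so the planted
#' type label always agrees with downstream anchor annotation.
#'
#' @param genome A `syn_genome` from [make_genome()].
#' @param seed Integer seed.
#' @param n_loops Number of loops to plant (>= 20).
#' @param frac_promoter_mediated Fraction of loops with at least one promoter
#'   anchor.
#' @param frac_pp_within_promoter_mediated Fraction of promoter-mediated loops
#'   that are promoter-promoter.
#' @param frac_distal_sox2 Fraction of enhancers that are SOX2-bound.
#' @param n_extra_enhancers Standalone (non-interacting) enhancers to add.
#' @param anchor_width Width of each planted anchor in bp.
#' @param span_range Min/max genomic span between the two anchors of a loop.
#' @param promoter_sox2_fraction Fraction of gene promoters carrying a SOX2
#'   peak (SOX2 binds promoters only rarely).
#' @param active_fraction_sox2 Minimum fraction of SOX2-bound enhancers in the
#'   dual-marked (active) state; enforced deterministically by count.
#' @param mark_probs_nonsox2 State probabilities (active, poised, k27_only,
#'   none) for enhancers not bound by SOX2.
#' @param intensity_base,intensity_lambda Planted iPET intensity per loop is
#'   `intensity_base + Poisson(intensity_lambda)`.
#' @return An object of class `planted_architecture`: list with `loops`
#'   (data.frame), `enhancers` (data.frame), `sox2_peaks`, `polII_peaks`,
#'   `k27_regions`, `k4me1_regions` (GRanges) and `truth_params`.
#' @export
make_architecture <- function(genome, seed, n_loops,
                              frac_promoter_mediated = 0.875,
                              frac_pp_within_promoter_mediated = 0.5,
                              frac_distal_sox2 = 0.4,
                              n_extra_enhancers = 100,
                              anchor_width = 1000,
                              span_range = c(20000, 2e6),
                              promoter_sox2_fraction = 0.1,
                              active_fraction_sox2 = 0.95,
                              mark_probs_nonsox2 = c(active = 0.70, poised = 0.15,
                                                     k27_only = 0.075, none = 0.075),
                              intensity_base = 8, intensity_lambda = 4) {
  stopifnot(inherits(genome, "syn_genome"))
  if (n_loops < 20) stop("n_loops must be >= 20")
  stop_if_not_fraction(frac_promoter_mediated, "frac_promoter_mediated")
  stop_if_not_fraction(frac_pp_within_promoter_mediated,
                       "frac_pp_within_promoter_mediated")
  stop_if_not_fraction(frac_distal_sox2, "frac_distal_sox2")
  stop_if_not_fraction(active_fraction_sox2, "active_fraction_sox2")
  if (abs(sum(mark_probs_nonsox2) - 1) > 1e-8) {
    stop("mark_probs_nonsox2 is an infeasible proportion combination (must sum to 1)")
  }
  type_probs <- c(
    "P-P" = frac_promoter_mediated * frac_pp_within_promoter_mediated,
    "P-nonP" = frac_promoter_mediated * (1 - frac_pp_within_promoter_mediated),
    "nonP-nonP" = 1 - frac_promoter_mediated
  )
  if (any(type_probs < -1e-12)) stop("infeasible proportion combination")

  half <- floor(anchor_width / 2)
  edge <- 10000
  clen <- chrom_lengths(genome)
  # Distal anchors must stay clear of every promoter window plus anchor extent.
  tss_clear <- 2500 + anchor_width + 100
  tss_by_chrom <- split(genome$genes$tss, genome$genes$chrom)
  genes <- genome$genes

  arch <- with_seed(seed, {
    types <- sample(names(type_probs), n_loops, replace = TRUE, prob = type_probs)
    used_distal <- stats::setNames(vector("list", length(clen)), names(clen))

    valid_distal <- function(chrom, center) {
      L <- clen[[chrom]]
      if (center < edge || center > L - edge) return(FALSE)
      tt <- tss_by_chrom[[chrom]]
      if (!is.null(tt) && length(tt) > 0 && min(abs(tt - center)) <= tss_clear) {
        return(FALSE)
      }
      ud <- used_distal[[chrom]]
      if (!is.null(ud) && length(ud) > 0 &&
          min(abs(ud - center)) < 3 * anchor_width) {
        return(FALSE)
      }
      TRUE
    }
    claim_distal <- function(chrom, center) {
      used_distal[[chrom]] <<- c(used_distal[[chrom]], center)
    }
    # Draw a distal centre at a loop-scale span from `from`; NA on failure.
    draw_distal <- function(chrom, from = NULL, tries = 200) {
      L <- clen[[chrom]]
      for (i in seq_len(tries)) {
        if (is.null(from)) {
          center <- floor(runif(1, edge, L - edge))
        } else {
          d <- floor(runif(1, span_range[1], span_range[2]))
          center <- from + sample(c(-1L, 1L), 1) * d
        }
        if (valid_distal(chrom, center)) return(center)
      }
      NA_real_
    }

    loops <- vector("list", n_loops)
    n_genes <- nrow(genes)
    for (i in seq_len(n_loops)) {
      ty <- types[i]
      rec <- NULL
      for (attempt in seq_len(200)) {
        if (ty == "P-P") {
          ga <- genes[sample.int(n_genes, 1), ]
          cand <- genes[genes$chrom == ga$chrom &
                          genes$gene_id != ga$gene_id &
                          abs(genes$tss - ga$tss) >= span_range[1] &
                          abs(genes$tss - ga$tss) <= span_range[2], ]
          if (nrow(cand) == 0) next
          gb <- cand[sample.int(nrow(cand), 1), ]
          rec <- list(chrom = ga$chrom, ca = ga$tss, cb = gb$tss,
                      gene_a = ga$gene_id, gene_b = gb$gene_id,
                      prom_a = TRUE, prom_b = TRUE)
        } else if (ty == "P-nonP") {
          ga <- genes[sample.int(n_genes, 1), ]
          ce <- draw_distal(ga$chrom, from = ga$tss, tries = 50)
          if (is.na(ce)) next
          claim_distal(ga$chrom, ce)
          rec <- list(chrom = ga$chrom, ca = ga$tss, cb = ce,
                      gene_a = ga$gene_id, gene_b = NA_character_,
                      prom_a = TRUE, prom_b = FALSE)
        } else {
          chrom <- sample(names(clen), 1, prob = clen)
          c1 <- draw_distal(chrom, tries = 50)
          if (is.na(c1)) next
          c2 <- draw_distal(chrom, from = c1, tries = 50)
          if (is.na(c2)) next
          claim_distal(chrom, c1)
          claim_distal(chrom, c2)
          rec <- list(chrom = chrom, ca = c1, cb = c2,
                      gene_a = NA_character_, gene_b = NA_character_,
                      prom_a = FALSE, prom_b = FALSE)
        }
        if (!is.null(rec)) break
      }
      if (is.null(rec)) stop("failed to place loop anchors; genome too crowded")
      # orient so anchor a precedes anchor b
      if (rec$ca > rec$cb) {
        rec <- list(chrom = rec$chrom, ca = rec$cb, cb = rec$ca,
                    gene_a = rec$gene_b, gene_b = rec$gene_a,
                    prom_a = rec$prom_b, prom_b = rec$prom_a)
      }
      loops[[i]] <- data.frame(
        loop_id = sprintf("loop_%04d", i), chrom = rec$chrom,
        start_a = as.integer(rec$ca - half), end_a = as.integer(rec$ca + half - 1L),
        start_b = as.integer(rec$cb - half), end_b = as.integer(rec$cb + half - 1L),
        type_label = ty, gene_a = rec$gene_a, gene_b = rec$gene_b,
        prom_a = rec$prom_a, prom_b = rec$prom_b,
        stringsAsFactors = FALSE
      )
    }
    loops <- do.call(rbind, loops)
    loops$intensity <- intensity_base + rpois(n_loops, intensity_lambda)

    # Enhancers: every distal loop anchor, plus standalone ones.
    enh <- list()
    for (side in c("a", "b")) {
      sel <- !loops[[paste0("prom_", side)]]
      if (any(sel)) {
        enh[[side]] <- data.frame(
          chrom = loops$chrom[sel],
          start = loops[[paste0("start_", side)]][sel],
          end = loops[[paste0("end_", side)]][sel],
          loop_id = loops$loop_id[sel],
          side = side, stringsAsFactors = FALSE
        )
      }
    }
    extra <- NULL
    if (n_extra_enhancers > 0) {
      centers <- chromv <- rep(NA_real_, n_extra_enhancers)
      for (j in seq_len(n_extra_enhancers)) {
        chrom <- sample(names(clen), 1, prob = clen)
        ce <- draw_distal(chrom)
        if (is.na(ce)) stop("failed to place standalone enhancers")
        claim_distal(chrom, ce)
        centers[j] <- ce
        chromv[j] <- chrom
      }
      extra <- data.frame(chrom = chromv,
                          start = as.integer(centers - half),
                          end = as.integer(centers + half - 1L),
                          loop_id = NA_character_, side = NA_character_,
                          stringsAsFactors = FALSE)
    }
    enhancers <- rbind(do.call(rbind, enh), extra)
    rownames(enhancers) <- NULL
    n_enh <- nrow(enhancers)
    enhancers$enh_id <- sprintf("enh_%04d", seq_len(n_enh))
    enhancers$sox2_bound <- runif(n_enh) < frac_distal_sox2

    # Mark states: SOX2-bound enhancers are >= active_fraction_sox2 dual-marked
    # by construction (count, not chance); others follow mark_probs_nonsox2.
    enhancers$mark_state <- NA_character_
    sb <- which(enhancers$sox2_bound)
    if (length(sb) > 0) {
      n_active <- ceiling(active_fraction_sox2 * length(sb))
      act <- sample(sb, n_active)
      enhancers$mark_state[act] <- "active"
      enhancers$mark_state[setdiff(sb, act)] <- "poised"
    }
    ns <- which(!enhancers$sox2_bound)
    if (length(ns) > 0) {
      enhancers$mark_state[ns] <- sample(names(mark_probs_nonsox2), length(ns),
                                         replace = TRUE, prob = mark_probs_nonsox2)
    }

    # SOX2 peaks: one per bound enhancer, inside it; plus rare promoter peaks.
    sox2 <- enhancers[enhancers$sox2_bound, , drop = FALSE]
    sox2_peaks <- if (nrow(sox2) > 0) {
      ctr <- floor((sox2$start + sox2$end) / 2)
      gr(sox2$chrom, ctr - 150L, ctr + 149L, name = paste0("sox2_", sox2$enh_id))
    } else {
      GenomicRanges::GRanges()
    }
    prom_sox2 <- genes[runif(nrow(genes)) < promoter_sox2_fraction, , drop = FALSE]
    if (nrow(prom_sox2) > 0) {
      sox2_peaks <- c(sox2_peaks,
                      gr(prom_sox2$chrom, prom_sox2$tss - 150L, prom_sox2$tss + 149L,
                         name = paste0("sox2_prom_", prom_sox2$gene_id)))
    }

    # Pol II peaks on every loop anchor (these are Pol II-mediated loops).
    ctr_a <- floor((loops$start_a + loops$end_a) / 2)
    ctr_b <- floor((loops$start_b + loops$end_b) / 2)
    polII_peaks <- reduce_sorted(gr(rep(loops$chrom, 2),
                                    c(ctr_a, ctr_b) - 250L,
                                    c(ctr_a, ctr_b) + 249L))

    # Histone-mark peak intervals (narrowPeak-like, standardized downstream).
    mk_width <- function(n) sample(seq(400L, 1000L), n, replace = TRUE)
    enh_ctr <- floor((enhancers$start + enhancers$end) / 2)
    k27_sel <- enhancers$mark_state %in% c("active", "k27_only")
    k4_sel <- enhancers$mark_state %in% c("active", "poised")
    w27 <- mk_width(sum(k27_sel)); w4 <- mk_width(sum(k4_sel))
    k27 <- gr(enhancers$chrom[k27_sel],
              enh_ctr[k27_sel] - floor(w27 / 2),
              enh_ctr[k27_sel] + floor(w27 / 2) - 1L)
    k4 <- gr(enhancers$chrom[k4_sel],
             enh_ctr[k4_sel] - floor(w4 / 2),
             enh_ctr[k4_sel] + floor(w4 / 2) - 1L)
    pk27 <- genes[runif(nrow(genes)) < 0.9, , drop = FALSE]
    pk4 <- genes[runif(nrow(genes)) < 0.5, , drop = FALSE]
    if (nrow(pk27) > 0) {
      k27 <- c(k27, gr(pk27$chrom, pk27$tss - 400L, pk27$tss + 399L))
    }
    if (nrow(pk4) > 0) {
      k4 <- c(k4, gr(pk4$chrom, pk4$tss - 400L, pk4$tss + 399L))
    }

    list(loops = loops, enhancers = enhancers, sox2_peaks = sox2_peaks,
         polII_peaks = polII_peaks, k27_regions = sort(k27),
         k4me1_regions = sort(k4))
  })

  arch$truth_params <- list(
    seed = as.integer(seed), n_loops = n_loops,
    frac_promoter_mediated = frac_promoter_mediated,
    frac_pp_within_promoter_mediated = frac_pp_within_promoter_mediated,
    frac_distal_sox2 = frac_distal_sox2,
    anchor_width = anchor_width, span_range = span_range,
    promoter_sox2_fraction = promoter_sox2_fraction,
    active_fraction_sox2 = active_fraction_sox2,
    intensity_base = intensity_base, intensity_lambda = intensity_lambda
  )
  class(arch) <- "planted_architecture"
  arch
}

reduce_sorted <- function(x) sort(GenomicRanges::reduce(sort(x), min.gapwidth = 0L))

#' @export
print.planted_architecture <- function(x, ...) {
  tab <- table(x$loops$type_label)
  cat(sprintf("planted architecture: %d loops (%s), %d enhancers (%d SOX2-bound)\n",
              nrow(x$loops),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
              nrow(x$enhancers), sum(x$enhancers$sox2_bound)))
  invisible(x)
}
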