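#' Merge overlapping anchors into nodes
#'
#' Anchors that overlap by at least 1 bp are merged transitively into nodes.
#' A node is flagged as a promoter node when it lies within
#' `promoter_window` bp of any TSS (i.e. it overlaps a TSS +/- window
#' interval); promoter status is decided on the merged node interval, not on
#' individual member anchors.
#'
#' @param anchors GRanges of interaction anchors.
#' @param genome A `syn_genome` (or any object accepted by the gene-model
#'   helpers); optional. Without it nodes carry no promoter flag.
#' @param promoter_window TSS window in bp (default 2.5 kb).
#' @return GRanges of nodes with `node_id`, `n_anchors` and (if a genome is
#'   given) `is_promoter`.
#' @export
build_nodes <- function(anchors, genome = NULL, promoter_window = 2500) {
  nodes <- GenomicRanges::reduce(sort(anchors), min.gapwidth = 0L)
  S4Vectors::mcols(nodes)$node_id <- sprintf("node_%05d", seq_along(nodes))
  S4Vectors::mcols(nodes)$n_anchors <-
    GenomicRanges::countOverlaps(nodes, anchors)
  if (!is.null(genome)) {
    S4Vectors::mcols(nodes)$is_promoter <-
      IRanges::overlapsAny(nodes, promoter_gr(genome, promoter_window))
  }
  nodes
}

#' Annotate anchors against the gene model
#'
#' Priority annotation with 1-bp overlap at each tier: promoter (P, anchor
#' overlaps any TSS +/- `promoter_window`), then gene body (G), otherwise
#' intergenic (I). The nearest gene is reported for P and G anchors.
#'
#' @param anchors GRanges of anchors.
#' @param genome A `syn_genome`.
#' @param promoter_window Promoter half-window in bp.
#' @return data.frame with `category` (`"P"`, `"G"`, `"I"`) and
#'   `nearest_gene` (NA for intergenic anchors).
#' @export
annotate_anchor <- function(anchors, genome, promoter_window = 2500) {
  known <- genome$chroms$chrom
  if (!all(as.character(GenomicRanges::seqnames(anchors)) %in% known)) {
    stop("anchor on unknown chromosome")
  }
  proms <- promoter_gr(genome, promoter_window)
  bodies <- gene_body_gr(genome)
  category <- rep("I", length(anchors))
  nearest_gene <- rep(NA_character_, length(anchors))

  hg <- GenomicRanges::findOverlaps(anchors, bodies)
  if (length(hg) > 0) {
    first <- !duplicated(S4Vectors::queryHits(hg))
    category[S4Vectors::queryHits(hg)[first]] <- "G"
    nearest_gene[S4Vectors::queryHits(hg)[first]] <-
      bodies$gene_id[S4Vectors::subjectHits(hg)[first]]
  }
  hp <- GenomicRanges::findOverlaps(anchors, proms)
  if (length(hp) > 0) {
    first <- !duplicated(S4Vectors::queryHits(hp))
    category[S4Vectors::queryHits(hp)[first]] <- "P"
    nearest_gene[S4Vectors::queryHits(hp)[first]] <-
      proms$gene_id[S4Vectors::subjectHits(hp)[first]]
  }
  data.frame(category = category, nearest_gene = nearest_gene,
             stringsAsFactors = FALSE)
}

#' Type an interaction from its two anchor categories
#'
#' Both anchors promoter: P-P; exactly one: P-nonP; neither: nonP-nonP
#' (gene-body and intergenic anchors both count as non-promoter). Symmetric
#' in its arguments.
#'
#' @param cat_a,cat_b Anchor categories (`"P"`, `"G"`, `"I"`).
#' @return Character vector: `"P-P"`, `"P-nonP"` or `"nonP-nonP"`.
#' @export
classify_interaction <- function(cat_a, cat_b) {
  np <- (cat_a == "P") + (cat_b == "P")
  c("nonP-nonP", "P-nonP", "P-P")[np + 1L]
}

# GRanges for one anchor side of a cluster table.
anchor_gr <- function(clusters, side = c("a", "b")) {
  side <- match.arg(side)
  gr(clusters$chrom, clusters[[paste0("start_", side)]],
     clusters[[paste0("end_", side)]])
}

#' Flag clusters with Pol II binding on both anchors
#'
#' @param clusters Cluster table.
#' @param polII_peaks GRanges of Pol II peaks.
#' @return Logical vector: TRUE iff each anchor overlaps a peak by >= 1 bp.
#' @export
flag_polII_bound <- function(clusters, polII_peaks) {
  IRanges::overlapsAny(anchor_gr(clusters, "a"), polII_peaks) &
    IRanges::overlapsAny(anchor_gr(clusters, "b"), polII_peaks)
}

#' Annotate interactions with type, SOX2/Pol II support and mark state
#'
#' Combines anchor annotation, interaction typing, Pol II double-anchor
#' support, SOX2 occupancy and (optionally) the enhancer mark state of the
#' distal anchor of promoter-distal interactions.
#'
#' @param clusters Cluster table (typically significant clusters from
#'   [call_loops()]).
#' @param genome A `syn_genome`.
#' @param sox2_peaks,polII_peaks Optional GRanges peak sets.
#' @param k27,k4 Optional standardized mark region GRanges for the distal
#'   mark state.
#' @param promoter_window Promoter half-window in bp.
#' @return The cluster table with added columns `cat_a`, `cat_b`, `gene_a`,
#'   `gene_b`, `itype`, `polII_both`, `sox2_any`, `sox2_distal`,
#'   `distal_mark_state`.
#' @export
annotate_interactions <- function(clusters, genome, sox2_peaks = NULL,
                                  polII_peaks = NULL, k27 = NULL, k4 = NULL,
                                  promoter_window = 2500) {
  ann_a <- annotate_anchor(anchor_gr(clusters, "a"), genome, promoter_window)
  ann_b <- annotate_anchor(anchor_gr(clusters, "b"), genome, promoter_window)
  clusters$cat_a <- ann_a$category
  clusters$cat_b <- ann_b$category
  clusters$gene_a <- ann_a$nearest_gene
  clusters$gene_b <- ann_b$nearest_gene
  clusters$itype <- classify_interaction(ann_a$category, ann_b$category)
  clusters$polII_both <- if (!is.null(polII_peaks)) {
    flag_polII_bound(clusters, polII_peaks)
  } else {
    NA
  }
  fs <- flag_sox2(clusters, sox2_peaks)
  clusters$sox2_any <- fs$sox2_any
  clusters$sox2_distal <- fs$sox2_distal
  clusters$distal_mark_state <- NA_character_
  if (!is.null(k27) && !is.null(k4)) {
    pn <- which(clusters$itype == "P-nonP")
    if (length(pn) > 0) {
      distal <- distal_anchor_gr(clusters[pn, , drop = FALSE])
      clusters$distal_mark_state[pn] <- enhancer_state(distal, k27, k4)
    }
  }
  clusters
}

# The non-promoter anchor of each P-nonP interaction.
distal_anchor_gr <- function(clusters) {
  stopifnot(all(clusters$itype == "P-nonP"))
  a_is_distal <- clusters$cat_a != "P"
  gr(clusters$chrom,
     ifelse(a_is_distal, clusters$start_a, clusters$start_b),
     ifelse(a_is_distal, clusters$end_a, clusters$end_b))
}

#' SOX2 occupancy flags for annotated interactions
#'
#' `sox2_any` is TRUE when at least one anchor overlaps a SOX2 peak;
#' `sox2_distal` is TRUE when the non-promoter anchor of a P-nonP interaction
#' does (FALSE by definition for P-P and nonP-nonP interactions).
#'
#' @param interactions Annotated cluster table with `cat_a`, `cat_b`, `itype`.
#' @param sox2_peaks GRanges of SOX2 peaks (NULL gives all-FALSE flags).
#' @return data.frame with logical `sox2_any`, `sox2_distal`.
#' @export
flag_sox2 <- function(interactions, sox2_peaks) {
  n <- nrow(interactions)
  if (is.null(sox2_peaks)) {
    return(data.frame(sox2_any = rep(FALSE, n), sox2_distal = rep(FALSE, n)))
  }
  hit_a <- IRanges::overlapsAny(anchor_gr(interactions, "a"), sox2_peaks)
  hit_b <- IRanges::overlapsAny(anchor_gr(interactions, "b"), sox2_peaks)
  sox2_any <- hit_a | hit_b
  sox2_distal <- rep(FALSE, n)
  pn <- interactions$itype == "P-nonP"
  a_is_distal <- interactions$cat_a != "P"
  sox2_distal[pn] <- ifelse(a_is_distal[pn], hit_a[pn], hit_b[pn])
  data.frame(sox2_any = sox2_any, sox2_distal = sox2_distal)
}

#' Fraction of interactions reproduced in another interaction set
#'
#' An interaction of `set_a` is reproduced when some interaction of `set_b`
#' on the same chromosome has both anchor midpoints within `window` bp of the
#' corresponding midpoints of the `set_a` interaction (anchors order-matched
#' after sorting within each interaction).
#'
#' @param set_a,set_b Cluster tables.
#' @param window Matching window in bp.
#' @return Fraction of `set_a` interactions matched in `set_b`.
#' @export
interaction_overlap <- function(set_a, set_b, window) {
  stopifnot(window >= 0)
  if (nrow(set_a) == 0) return(NaN)
  mid <- function(s, side) {
    floor((s[[paste0("start_", side)]] + s[[paste0("end_", side)]]) / 2)
  }
  ma1 <- mid(set_a, "a"); ma2 <- mid(set_a, "b")
  mb1 <- mid(set_b, "a"); mb2 <- mid(set_b, "b")
  q <- gr(set_a$chrom, pmax(1, ma1 - window), ma1 + window)
  s <- gr(set_b$chrom, mb1, mb1)
  # sets may live on disjoint chromosome spaces; that is a valid zero-overlap
  # comparison, not a seqinfo problem
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  ok <- abs(ma2[S4Vectors::queryHits(hits)] -
              mb2[S4Vectors::subjectHits(hits)]) <= window
  matched <- unique(S4Vectors::queryHits(hits)[ok])
  length(matched) / nrow(set_a)
}

#' Per-gene promoter connectivity
#'
#' A gene is connected when its promoter window overlaps an interaction
#' anchor. For each connecting interaction the partner (other) anchor is
#' counted as a promoter partner if its category is P, otherwise as an
#' enhancer (distal) partner. `has_sox2_pe` marks genes with at least one
#' SOX2-bound distal partner.
#'
#' @param interactions Annotated cluster table (from
#'   [annotate_interactions()]).
#' @param genome A `syn_genome`.
#' @param sox2_peaks Optional GRanges; enables `has_sox2_pe` and
#'   `sox2_promoter`.
#' @param promoter_window Promoter half-window in bp.
#' @return data.frame, one row per gene: `gene_id`, `n_enhancer_partners`,
#'   `n_promoter_partners`, `category` (`not_connected`, `pp_only`,
#'   `has_pe`), `has_sox2_pe`, `sox2_promoter`.
#' @export
summarize_connectivity <- function(interactions, genome, sox2_peaks = NULL,
                                   promoter_window = 2500) {
  proms <- promoter_gr(genome, promoter_window)
  genes <- genome$genes
  n_genes <- nrow(genes)
  n_enh <- n_prom <- integer(n_genes)
  sox2_pe <- logical(n_genes)

  sox2_hit <- function(side_gr) {
    if (is.null(sox2_peaks)) rep(FALSE, length(side_gr))
    else IRanges::overlapsAny(side_gr, sox2_peaks)
  }
  gr_a <- anchor_gr(interactions, "a")
  gr_b <- anchor_gr(interactions, "b")
  sox_a <- sox2_hit(gr_a)
  sox_b <- sox2_hit(gr_b)

  tally <- function(anchor_side_gr, partner_cat, partner_sox2) {
    hits <- GenomicRanges::findOverlaps(anchor_side_gr, proms)
    qi <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    is_p <- partner_cat[qi] == "P"
    for (j in seq_along(qi)) {
      g <- gi[j]
      if (is_p[j]) n_prom[g] <<- n_prom[g] + 1L
      else {
        n_enh[g] <<- n_enh[g] + 1L
        if (partner_sox2[qi[j]]) sox2_pe[g] <<- TRUE
      }
    }
  }
  if (nrow(interactions) > 0) {
    tally(gr_a, interactions$cat_b, sox_b)
    tally(gr_b, interactions$cat_a, sox_a)
  }
  category <- ifelse(n_enh + n_prom == 0, "not_connected",
                     ifelse(n_enh > 0, "has_pe", "pp_only"))
  sox2_promoter <- if (is.null(sox2_peaks)) rep(FALSE, n_genes)
  else IRanges::overlapsAny(proms, sox2_peaks)
  data.frame(gene_id = genes$gene_id,
             n_enhancer_partners = n_enh, n_promoter_partners = n_prom,
             category = category, has_sox2_pe = sox2_pe,
             sox2_promoter = sox2_promoter, stringsAsFactors = FALSE)
}
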