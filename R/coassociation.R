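#' Fisher exact p-value for a gene-set overlap
#'
#' Probability of observing `k` genes common to a set of size `n` and a set
#' of size `m` drawn from `N` annotated genes, from the two-sided Fisher
#' exact test on the table `[[k, n-k], [m-k, N-n-m+k]]`. Vectorized.
#'
#' @param k Genes in both sets.
#' @param n Size of the expression-group set.
#' @param m Genes associated with the interaction category.
#' @param N Total annotated eligible genes.
#' @param alternative Passed to [stats::fisher.test()] (default two-sided:
#'   the signed co-association score covers both enrichment and depletion).
#' @return p-value(s) in (0, 1].
#' @export
fisher_p <- function(k, n, m, N, alternative = "two.sided") {
  stopifnot(length(n) == length(k), length(m) == length(k),
            length(N) == 1 || length(N) == length(k))
  N <- rep(N, length.out = length(k))
  bad <- k < 0 | k > pmin(n, m) | n > N | m > N | (N - n - m + k) < 0
  if (any(bad)) stop("invalid overlap counts: implied 2x2 cell is negative")
  vapply(seq_along(k), function(i) {
    tab <- matrix(c(k[i], n[i] - k[i], m[i] - k[i], N[i] - n[i] - m[i] + k[i]),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab, alternative = alternative)$p.value
  }, numeric(1))
}

#' Signed co-association score
#'
#' `-log10(p)` when the observed overlap `k` exceeds its expectation
#' `n*m/N` (positive co-association), `+log10(p)` otherwise (depletion;
#' non-positive). Scores with `|score| > 2` indicate a statistically
#' significant overlap (or significantly low overlap if below -2).
#'
#' @param k,n,m,N Overlap counts as in [fisher_p()].
#' @param p Fisher p-value(s) for the same counts.
#' @return Numeric score(s).
#' @export
coassoc_score <- function(k, n, m, N, p) {
  expected <- n * m / N
  ifelse(p >= 1, 0, ifelse(k > expected, -log10(p), log10(p)))
}

#' Co-association matrix of expression groups and interaction categories
#'
#' For every expression-variation group and every interaction category,
#' counts the overlap among eligible genes (`N` = eligible total, `n` =
#' group size, `m` = category size, `k` = intersection), computes the Fisher
#' p and the signed score. Categories are set-valued: a gene may belong to
#' several, and each category is tested marginally.
#'
#' @param groups Factor (or character) of group labels named by gene id, NA
#'   for ineligible genes.
#' @param categories Named list of logical vectors (same gene order/names) or
#'   a data.frame of logical columns plus `gene_id`.
#' @param eligible Character vector of eligible gene ids.
#' @return data.frame: `group`, `category`, `k`, `n`, `m`, `N`, `expected`,
#'   `p`, `score`, `significant`.
#' @export
coassociation_matrix <- function(groups, categories, eligible) {
  if (length(eligible) == 0) stop("eligible gene set is empty")
  if (is.data.frame(categories)) {
    gid <- categories$gene_id
    categories <- lapply(categories[setdiff(names(categories), "gene_id")],
                         function(x) stats::setNames(as.logical(x), gid))
  }
  if (is.null(names(groups))) stop("`groups` must be named by gene id")
  eligible <- intersect(eligible, names(groups))
  g <- groups[eligible]
  N <- length(eligible)
  lv <- if (is.factor(groups)) levels(groups) else levels(factor(g))
  out <- list()
  for (grp in lv) {
    in_g <- !is.na(g) & g == grp
    n <- sum(in_g)
    for (cat in names(categories)) {
      cvec <- categories[[cat]][eligible]
      cvec[is.na(cvec)] <- FALSE
      m <- sum(cvec)
      k <- sum(in_g & cvec)
      if (n == 0 || m == 0) {
        p <- 1
      } else {
        p <- fisher_p(k, n, m, N)
      }
      score <- coassoc_score(k, n, m, N, p)
      out[[paste(grp, cat)]] <- data.frame(
        group = grp, category = cat, k = k, n = n, m = m, N = N,
        expected = n * m / N, p = p, score = score,
        significant = abs(score) > 2, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interaction categories per gene for co-association testing
#'
#' Derives the standard category set from a connectivity table: promoter
#' connected to any enhancer (P-E), to a SOX2-bound enhancer, to enhancers
#' none of which is SOX2-bound, promoter-promoter connections, and SOX2
#' binding at the gene's own promoter.
#'
#' @param connectivity Table from [summarize_connectivity()].
#' @return data.frame of logical category columns plus `gene_id`.
#' @export
build_categories <- function(connectivity) {
  data.frame(
    gene_id = connectivity$gene_id,
    pe = connectivity$n_enhancer_partners > 0,
    sox2_pe = connectivity$has_sox2_pe,
    nonsox2_pe = connectivity$n_enhancer_partners > 0 & !connectivity$has_sox2_pe,
    pp = connectivity$n_promoter_partners > 0,
    sox2_promoter = connectivity$sox2_promoter,
    stringsAsFactors = FALSE
  )
}
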