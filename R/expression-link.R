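# Three distinct expression floors are used deliberately at different stages:
# >0 TPM for distribution comparisons, >1 TPM for fold-ratio analyses, and
# >5 TPM for differential grouping and co-association.
TPM_FLOOR_DISTRIBUTION <- 0
TPM_FLOOR_FOLD_RATIO <- 1
TPM_FLOOR_GROUPING <- 5

tpm_matrix <- function(records, condition = c("wt", "mut")) {
  condition <- match.arg(condition)
  cols <- grep(paste0("^tpm_", condition, "_rep"), names(records), value = TRUE)
  if (length(cols) == 0) stop("no replicate columns for condition ", condition)
  as.matrix(records[, cols, drop = FALSE])
}

#' Add per-condition mean TPM columns
#'
#' @param records Expression table with `tpm_wt_rep*` / `tpm_mut_rep*`.
#' @return The table with `mean_wt` and `mean_mut` columns.
#' @export
expression_means <- function(records) {
  records$mean_wt <- rowMeans(tpm_matrix(records, "wt"))
  records$mean_mut <- rowMeans(tpm_matrix(records, "mut"))
  records
}

#' Differential-expression q-values
#'
#' Per-gene evidence for expression change between WT and MUT replicates,
#' BH-adjusted. The default engine fits a limma moderated t-statistic on
#' log2(TPM + 1), which shares variance information across genes and remains
#' powered at typical replicate counts (3 vs 3). `method = "permutation"`
#' instead computes an exact per-gene label-permutation p on the difference
#' of condition means of log2(TPM + 1) (all label splits enumerated when
#' their number does not exceed `n_permutations`, otherwise sampled); note
#' that with 3 vs 3 replicates only C(6,3) = 20 splits exist, so the smallest
#' attainable two-sided permutation p is 2/20 = 0.1. Precomputed q-values
#' from any external DE tool can be supplied downstream instead.
#'
#' @param records Expression table with replicate TPM columns.
#' @param method `"limma"` (default) or `"permutation"`.
#' @param seed Integer seed (used when permutations are sampled).
#' @param n_permutations Cap on enumerated/sampled label splits.
#' @return data.frame with `gene_id`, `p`, `q` (input order preserved).
#' @export
differential_qvalues <- function(records, method = c("limma", "permutation"),
                                 seed = 1, n_permutations = 2000) {
  method <- match.arg(method)
  wt <- log2(tpm_matrix(records, "wt") + 1)
  mut <- log2(tpm_matrix(records, "mut") + 1)
  if (ncol(wt) < 2 || ncol(mut) < 2) {
    stop("need >= 2 replicates per condition")
  }
  p <- if (method == "limma") {
    mat <- cbind(wt, mut)
    design <- cbind(Intercept = 1,
                    mut = rep(c(0, 1), c(ncol(wt), ncol(mut))))
    fit <- limma::eBayes(limma::lmFit(mat, design), trend = FALSE)
    as.numeric(fit$p.value[, "mut"])
  } else {
    permutation_pvalues(wt, mut, seed, n_permutations)
  }
  data.frame(gene_id = records$gene_id, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE)
}

# Exact (or sampled) two-sided label-permutation p-values on the difference
# of condition means; the observed labelling is included in the reference
# set, so p >= 1/n_splits always.
permutation_pvalues <- function(wt, mut, seed, n_permutations) {
  x <- cbind(wt, mut)
  nw <- ncol(wt)
  nt <- ncol(x)
  n_splits <- choose(nt, nw)
  splits <- if (n_splits <= n_permutations) {
    utils::combn(nt, nw, simplify = FALSE)
  } else {
    with_seed(seed, lapply(seq_len(n_permutations),
                           function(i) sample.int(nt, nw)))
  }
  obs <- rowMeans(wt) - rowMeans(mut)
  eps <- 1e-12
  ge <- integer(nrow(x))
  for (s in splits) {
    stat <- rowMeans(x[, s, drop = FALSE]) -
      rowMeans(x[, -s, drop = FALSE])
    ge <- ge + (abs(stat) >= abs(obs) - eps)
  }
  ge / length(splits)
}

#' Log2 fold ratio with a low-expression floor
#'
#' `log2(mean_wt / mean_mut)`, defined only when both condition means exceed
#' `tpm_floor` (genes with low transcript levels are excluded from fold-ratio
#' analyses to avoid ratio instability).
#'
#' @param mean_wt,mean_mut Condition mean TPM.
#' @param tpm_floor Exclusion floor (default 1 TPM).
#' @return Numeric vector; NA where undefined.
#' @export
fold_ratio <- function(mean_wt, mean_mut, tpm_floor = TPM_FLOOR_FOLD_RATIO) {
  ifelse(mean_wt > tpm_floor & mean_mut > tpm_floor,
         log2(mean_wt / mean_mut), NA_real_)
}

#' Assign genes to expression-variation groups
#'
#' Eligible genes (mean TPM above `expression_floor_tpm` in WT or MUT) are
#' partitioned into: group1, significant decrease (linear fold ratio
#' `mean_wt/mean_mut > fold_threshold` and `q < q_sig`); group2, moderate
#' change (not group1 but `q < q_mod`); group3, all other eligible genes.
#' Ineligible genes get NA.
#'
#' @param mean_wt,mean_mut Condition mean TPM.
#' @param q Differential q-values.
#' @param expression_floor_tpm Eligibility floor (default 5 TPM).
#' @param fold_threshold Linear WT/MUT fold threshold (default 1.5).
#' @param q_sig,q_mod Group1/group2 FDR thresholds (0.05, 0.2).
#' @return Factor with levels `group1`, `group2`, `group3`; NA if ineligible.
#' @export
assign_groups <- function(mean_wt, mean_mut, q,
                          expression_floor_tpm = TPM_FLOOR_GROUPING,
                          fold_threshold = 1.5, q_sig = 0.05, q_mod = 0.2) {
  eligible <- mean_wt > expression_floor_tpm | mean_mut > expression_floor_tpm
  fold <- ifelse(mean_mut > 0, mean_wt / mean_mut, Inf)
  g1 <- fold > fold_threshold & q < q_sig
  g2 <- !g1 & q < q_mod
  out <- ifelse(!eligible, NA_character_,
                ifelse(g1, "group1", ifelse(g2, "group2", "group3")))
  factor(out, levels = c("group1", "group2", "group3"))
}

#' Wilcoxon paired signed-rank test
#'
#' Two-sided paired test on per-gene differences; zero differences are
#' dropped. The exact distribution is used for up to 25 non-zero untied
#' differences, otherwise the normal approximation with tie correction.
#' The reported statistic is the signed rank sum (positive when `wt` tends
#' to exceed `mut`); it flips sign, with unchanged p, when the vectors are
#' swapped.
#'
#' @param wt,mut Paired numeric vectors.
#' @return List with `statistic`, `p`, `n` (non-zero pairs).
#' @export
paired_signed_rank <- function(wt, mut) {
  stopifnot(length(wt) == length(mut))
  d <- wt - mut
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, n = 0L))
  r <- rank(abs(d))
  statistic <- sum(sign(d) * r)
  if (n <= 25) {
    # exact null distribution of the positive-rank sum by convolution over
    # the (possibly tied, midranked) rank weights; handles ties, and equals
    # the standard signed-rank distribution when ranks are untied
    w <- as.integer(round(2 * r))            # half-ranks scaled to integers
    counts <- 1
    for (wi in w) {
      shifted <- c(numeric(wi), counts)
      counts <- c(counts, numeric(wi)) + shifted
    }
    v_obs <- as.integer(round(2 * sum(r[d > 0])))
    support <- seq_along(counts) - 1L
    total <- sum(counts)
    p_low <- sum(counts[support <= v_obs]) / total
    p_high <- sum(counts[support >= v_obs]) / total
    p <- min(1, 2 * min(p_low, p_high))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, mu = 0, exact = FALSE, correct = FALSE)$p.value
    )
  }
  list(statistic = statistic, p = p, n = n)
}

#' Expression distributions by interaction category
#'
#' Summarizes WT and MUT expression of all transcribed genes and of nested
#' connectivity categories (promoter is a node; promoter connected to an
#' enhancer; SOX2-positive promoter-enhancer), with a paired signed-rank test
#' of the WT vs MUT shift per category.
#'
#' @param records Expression table (means added if absent).
#' @param connectivity Per-gene table from [summarize_connectivity()].
#' @return List: `summary` (per category and condition: n, mean, quartiles)
#'   and `tests` (per category: signed-rank statistic and p).
#' @export
expression_by_category <- function(records, connectivity) {
  if (!all(c("mean_wt", "mean_mut") %in% names(records))) {
    records <- expression_means(records)
  }
  m <- merge(records, connectivity, by = "gene_id", sort = FALSE)
  m <- m[m$mean_wt > TPM_FLOOR_DISTRIBUTION & m$mean_mut > TPM_FLOOR_DISTRIBUTION, ]
  sets <- list(
    all = rep(TRUE, nrow(m)),
    connected = m$category != "not_connected",
    pe = m$category == "has_pe",
    sox2_pe = m$has_sox2_pe
  )
  summarise_one <- function(x) {
    if (length(x) == 0) {
      return(c(n = 0, mean = NA, q25 = NA, median = NA, q75 = NA))
    }
    c(n = length(x), mean = mean(x),
      q25 = unname(stats::quantile(x, 0.25)), median = stats::median(x),
      q75 = unname(stats::quantile(x, 0.75)))
  }
  rows <- list()
  tests <- list()
  for (nm in names(sets)) {
    sel <- sets[[nm]]
    for (cond in c("wt", "mut")) {
      v <- if (cond == "wt") m$mean_wt[sel] else m$mean_mut[sel]
      rows[[paste(nm, cond)]] <- data.frame(
        category = nm, condition = cond, t(summarise_one(v)),
        stringsAsFactors = FALSE)
    }
    tt <- if (sum(sel) > 0) {
      paired_signed_rank(log2(m$mean_wt[sel] + 1), log2(m$mean_mut[sel] + 1))
    } else {
      list(statistic = NA, p = NA, n = 0L)
    }
    tests[[nm]] <- data.frame(category = nm, statistic = tt$statistic,
                              p = tt$p, n = tt$n, stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tests = do.call(rbind, c(tests, list(make.row.names = FALSE))))
}

#' Expression trend over enhancer-partner count
#'
#' Median WT expression per number of connected enhancers, plus the Spearman
#' rank correlation between enhancer count and expression.
#'
#' @param records Expression table.
#' @param connectivity Per-gene connectivity table.
#' @param max_count Counts at or above this value are pooled into one bin.
#' @return List: `medians` (data.frame n_enhancers, n_genes, median_wt),
#'   `spearman_rho`, `spearman_p` (NA when fewer than two bins are populated).
#' @export
expression_vs_enhancer_count <- function(records, connectivity, max_count = 5) {
  if (!all(c("mean_wt", "mean_mut") %in% names(records))) {
    records <- expression_means(records)
  }
  m <- merge(records, connectivity, by = "gene_id", sort = FALSE)
  m <- m[m$mean_wt > TPM_FLOOR_DISTRIBUTION, ]
  k <- pmin(m$n_enhancer_partners, max_count)
  med <- tapply(m$mean_wt, k, stats::median)
  medians <- data.frame(n_enhancers = as.integer(names(med)),
                        n_genes = as.integer(table(k)),
                        median_wt = as.numeric(med))
  if (length(unique(k)) < 2) {
    return(list(medians = medians, spearman_rho = NA_real_,
                spearman_p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(k, m$mean_wt, method = "spearman", exact = FALSE))
  list(medians = medians, spearman_rho = unname(ct$estimate),
       spearman_p = ct$p.value)
}
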