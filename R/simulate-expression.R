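#' Expression effect model for the synthetic generator
#'
#' Parameters of the planted expression model. Wild-type (WT) mean TPM of a
#' gene is a log-normal base draw multiplied by `per_enhancer_boost` for every
#' connected enhancer; in the Sox2-deleted condition (MUT) genes connected to
#' at least one SOX2-bound enhancer are multiplied by
#' `mut_downregulation_factor` (default 0.15, the magnitude seen for strongly
#' SOX2-dependent targets such as Socs3, reduced to 10-15% of WT levels).
#' Replicates are drawn log-normally around the condition mean with the given
#' coefficient of variation.
#'
#' @param base_tpm_meanlog,base_tpm_sdlog Log-normal parameters of base TPM.
#' @param per_enhancer_boost Multiplicative WT gain per connected enhancer.
#' @param mut_downregulation_factor MUT multiplier for genes connected to a
#'   SOX2-bound enhancer; in (0, 1].
#' @param replicate_noise_cv Coefficient of variation of replicate noise.
#' @param n_replicates Replicates per condition.
#' @param seed Integer seed.
#' @export
effect_model <- function(base_tpm_meanlog = log(30), base_tpm_sdlog = 1,
                         per_enhancer_boost = 1.5,
                         mut_downregulation_factor = 0.15,
                         replicate_noise_cv = 0.2, n_replicates = 3, seed = 1) {
  if (per_enhancer_boost <= 0) stop("per_enhancer_boost must be > 0")
  if (mut_downregulation_factor <= 0 || mut_downregulation_factor > 1) {
    stop("mut_downregulation_factor must be in (0, 1]")
  }
  if (replicate_noise_cv < 0) stop("replicate_noise_cv must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(base_tpm_meanlog = base_tpm_meanlog,
                 base_tpm_sdlog = base_tpm_sdlog,
                 per_enhancer_boost = per_enhancer_boost,
                 mut_downregulation_factor = mut_downregulation_factor,
                 replicate_noise_cv = replicate_noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "effect_model")
}

# Per-gene connectivity truth implied by the planted loops: number of
# connected enhancers and whether any of them is SOX2-bound.
planted_gene_truth <- function(arch, genome) {
  loops <- arch$loops
  enh <- arch$enhancers
  truth <- data.frame(gene_id = genome$genes$gene_id,
                      n_enhancers = 0L, n_sox2_enhancers = 0L,
                      stringsAsFactors = FALSE)
  pe <- loops[loops$type_label == "P-nonP", , drop = FALSE]
  if (nrow(pe) > 0) {
    gene <- ifelse(pe$prom_a, pe$gene_a, pe$gene_b)
    # the distal anchor of each P-nonP loop is an enhancer record
    side <- ifelse(pe$prom_a, "b", "a")
    key <- paste(pe$loop_id, side)
    ek <- paste(enh$loop_id, enh$side)
    sox2 <- enh$sox2_bound[match(key, ek)]
    agg_n <- tapply(rep(1L, length(gene)), gene, sum)
    agg_s <- tapply(as.integer(sox2), gene, sum)
    i <- match(names(agg_n), truth$gene_id)
    truth$n_enhancers[i] <- as.integer(agg_n)
    truth$n_sox2_enhancers[i] <- as.integer(agg_s)
  }
  truth
}

#' Simulate WT/MUT expression tables with planted downregulation
#'
#' Draws per-gene TPM replicates for wild-type and Sox2-deleted conditions
#' according to an [effect_model()]. Genes connected (through planted
#' promoter-enhancer loops) to at least one SOX2-bound enhancer are
#' downregulated in MUT by `mut_downregulation_factor`; all other genes keep
#' their WT mean. Truth labels are returned alongside the replicate values.
#'
#' @param arch A `planted_architecture`.
#' @param genome The underlying `syn_genome`.
#' @param model An [effect_model()].
#' @return A data.frame with one row per gene: `gene_id`, replicate columns
#'   `tpm_wt_rep*` and `tpm_mut_rep*`, and truth columns `wt_mean_true`,
#'   `mut_mean_true`, `n_enhancers_true`, `n_sox2_enhancers_true`,
#'   `planted_down`.
#' @export
simulate_expression <- function(arch, genome, model = effect_model()) {
  stopifnot(inherits(arch, "planted_architecture"),
            inherits(genome, "syn_genome"), inherits(model, "effect_model"))
  truth <- planted_gene_truth(arch, genome)
  n <- nrow(truth)
  k <- model$n_replicates

  with_seed(model$seed, {
    base <- rlnorm(n, model$base_tpm_meanlog, model$base_tpm_sdlog)
    wt_mean <- base * model$per_enhancer_boost^truth$n_enhancers
    planted <- truth$n_sox2_enhancers > 0
    mut_mean <- wt_mean * ifelse(planted, model$mut_downregulation_factor, 1)

    draw_reps <- function(means) {
      if (model$replicate_noise_cv == 0) {
        matrix(rep(means, k), ncol = k)
      } else {
        sdl <- sqrt(log(1 + model$replicate_noise_cv^2))
        matrix(means, nrow = n, ncol = k) *
          matrix(rlnorm(n * k, meanlog = -sdl^2 / 2, sdlog = sdl), ncol = k)
      }
    }
    wt <- draw_reps(wt_mean)
    mut <- draw_reps(mut_mean)
    colnames(wt) <- paste0("tpm_wt_rep", seq_len(k))
    colnames(mut) <- paste0("tpm_mut_rep", seq_len(k))

    data.frame(gene_id = truth$gene_id, wt, mut,
               wt_mean_true = wt_mean, mut_mean_true = mut_mean,
               n_enhancers_true = truth$n_enhancers,
               n_sox2_enhancers_true = truth$n_sox2_enhancers,
               planted_down = planted, stringsAsFactors = FALSE)
  })
}
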