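#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one serializable list:
#' protocol dialect and loop-calling thresholds, promoter windows (2.5 kb for
#' anchors, 1 kb for mark regions), mark standardization length, bin size and
#' chi-square threshold, TPM floors (0/1/5), fold and FDR thresholds, random
#' sampling depth, simulation sizes and the master seed.
#'
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param dialect `"insitu"` or `"tr1"`.
#' @param n_genes,n_chroms,chrom_length,n_loops,n_background_pets Synthetic
#'   dataset sizes.
#' @param ... Overrides for any other stored constant.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, dialect = "insitu", n_genes = 400,
                            n_chroms = 2, chrom_length = 1e7, n_loops = 100,
                            n_background_pets = 10000, ...) {
  cfg <- list(
    seed = as.integer(seed), dialect = dialect,
    n_genes = n_genes, n_chroms = n_chroms, chrom_length = chrom_length,
    n_loops = n_loops, n_background_pets = n_background_pets,
    self_span = 8000, extension = 1000, dedup_tolerance = 2,
    fdr_cutoff = 0.05, p_cutoff = 0.05,
    promoter_window_anchor = 2500, promoter_window_mark = 1000,
    mark_min_len = 2000, bin_size = 200, chi2_threshold = 1e-4,
    tpm_floors = c(distribution = 0, fold = 1, grouping = 5),
    fold_threshold = 1.5, q_sig = 0.05, q_mod = 0.2,
    n_random_sets = 1000,
    frac_promoter_mediated = 0.875, frac_pp = 0.5, frac_distal_sox2 = 0.4,
    mut_downregulation_factor = 0.15, replicate_noise_cv = 0.2,
    n_replicates = 3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes every stage in order on a freshly simulated dataset: simulate ->
#' call loops -> annotate anchors and interactions -> per-gene connectivity ->
#' differential expression and grouping -> co-association matrix -> summary.
#' Identical config and seed give an identical summary. When `outdir` is
#' given, the dataset and key result tables are written as plain-text files.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return List of class `chialink_run`: `dataset`, `calls`, `interactions`,
#'   `nodes`, `connectivity`, `expression`, `groups`, `coassoc` and `summary`
#'   (counts shaped like a sequencing-summary row plus type fractions).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  params <- cluster_params(dialect = config$dialect,
                           self_span = config$self_span,
                           extension = config$extension,
                           dedup_tolerance = config$dedup_tolerance,
                           fdr_cutoff = config$fdr_cutoff,
                           p_cutoff = config$p_cutoff)
  ds <- simulate_dataset(
    seed = config$seed,
    genome_params = list(n_chroms = config$n_chroms,
                         chrom_length = config$chrom_length,
                         n_genes = config$n_genes),
    arch_params = list(n_loops = config$n_loops,
                       frac_promoter_mediated = config$frac_promoter_mediated,
                       frac_pp_within_promoter_mediated = config$frac_pp,
                       frac_distal_sox2 = config$frac_distal_sox2),
    pet_params = list(n_background_pets = config$n_background_pets),
    model = effect_model(
      mut_downregulation_factor = config$mut_downregulation_factor,
      replicate_noise_cv = config$replicate_noise_cv,
      n_replicates = config$n_replicates),
    bin_size = config$bin_size
  )
  calls <- call_loops(ds$pets, params)
  sig <- calls$clusters[calls$clusters$significant, , drop = FALSE]
  interactions <- annotate_interactions(
    sig, ds$genome, sox2_peaks = ds$arch$sox2_peaks,
    polII_peaks = ds$arch$polII_peaks,
    k27 = standardize_peaks(ds$arch$k27_regions, config$mark_min_len),
    k4 = standardize_peaks(ds$arch$k4me1_regions, config$mark_min_len),
    promoter_window = config$promoter_window_anchor)
  anchors <- c(anchor_gr(sig, "a"), anchor_gr(sig, "b"))
  nodes <- build_nodes(anchors, ds$genome, config$promoter_window_anchor)
  connectivity <- summarize_connectivity(interactions, ds$genome,
                                         sox2_peaks = ds$arch$sox2_peaks,
                                         promoter_window = config$promoter_window_anchor)
  expr <- expression_means(ds$expression)
  dq <- differential_qvalues(expr, seed = derive_seeds(config$seed)[["analysis"]])
  expr$q <- dq$q[match(expr$gene_id, dq$gene_id)]
  groups <- assign_groups(expr$mean_wt, expr$mean_mut, expr$q,
                          expression_floor_tpm = config$tpm_floors[["grouping"]],
                          fold_threshold = config$fold_threshold,
                          q_sig = config$q_sig, q_mod = config$q_mod)
  names(groups) <- expr$gene_id
  eligible <- expr$gene_id[!is.na(groups)]
  coassoc <- coassociation_matrix(groups, build_categories(connectivity),
                                  eligible)

  itab <- table(factor(interactions$itype,
                       levels = c("P-P", "P-nonP", "nonP-nonP")))
  n_sig <- nrow(sig)
  summary <- list(
    total_pets = calls$counts$total,
    chimeric = calls$counts$chimeric,
    unique_pets = calls$counts$unique,
    self = calls$counts$self, intra = calls$counts$intra,
    inter = calls$counts$inter,
    clusters = calls$counts$clusters,
    significant_loops = n_sig,
    polii_loops = sum(interactions$polII_both, na.rm = TRUE),
    loops_per_million = loops_per_million(n_sig, calls$counts$intra),
    nodes_total = length(nodes),
    nodes_promoter = sum(nodes$is_promoter),
    nodes_nonpromoter = sum(!nodes$is_promoter),
    itype_counts = as.list(itab),
    itype_fractions = as.list(itab / max(1, n_sig)),
    seed = config$seed
  )
  run <- structure(list(dataset = ds, calls = calls, interactions = interactions,
                        nodes = nodes, connectivity = connectivity,
                        expression = expr, groups = groups, coassoc = coassoc,
                        summary = summary, config = config),
                   class = "chialink_run")
  if (!is.null(outdir)) {
    write_dataset(ds, outdir)
    write_tsv(interactions, file.path(outdir, "interactions_annotated.tsv"))
    write_tsv(connectivity, file.path(outdir, "connectivity.tsv"))
    write_tsv(run$coassoc, file.path(outdir, "coassociation.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

#' @export
print.chialink_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "pipeline run (seed %d)\n",
    "  PETs: %d total, %d unique (self %d / intra %d / inter %d)\n",
    "  loops: %d clusters, %d significant (%d per million intra PETs)\n",
    "  nodes: %d (%d promoter); types P-P %d / P-nonP %d / nonP-nonP %d\n"),
    s$seed, s$total_pets, s$unique_pets, s$self, s$intra, s$inter,
    s$clusters, s$significant_loops, s$loops_per_million,
    s$nodes_total, s$nodes_promoter,
    s$itype_counts[["P-P"]], s$itype_counts[["P-nonP"]],
    s$itype_counts[["nonP-nonP"]]))
  invisible(x)
}

#' Validate pipeline input files
#'
#' Schema and coordinate sanity checks for BED, tag-pair TSV and expression
#' TSV inputs: column counts, `0 <= start < end`, and chromosome-name
#' consistency across files. Problems are reported with file and line number;
#' cross-file chromosome mismatches are warnings.
#'
#' @param paths Named list; recognized names: `bed` (character vector of BED
#'   paths), `pets` (tag-pair TSV), `expression` (expression TSV).
#' @return data.frame with `file`, `line`, `severity`, `problem`; zero rows
#'   when everything is clean.
#' @export
validate_inputs <- function(paths) {
  problems <- list()
  note <- function(file, line, severity, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      file = file, line = line, severity = severity, problem = problem,
      stringsAsFactors = FALSE)
  }
  chrom_sets <- list()

  for (bed in paths$bed %||% character(0)) {
    lines <- readLines(bed)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    ln <- which(keep)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      if (length(f) < 3) {
        note(bed, ln[i], "error", "fewer than 3 BED fields")
        next
      }
      s <- suppressWarnings(as.numeric(f[2]))
      e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e)) {
        note(bed, ln[i], "error", "non-numeric coordinates")
      } else if (s < 0 || s >= e) {
        note(bed, ln[i], "error", sprintf("invalid interval [%s, %s)", f[2], f[3]))
      }
    }
    chrom_sets[[bed]] <- unique(vapply(fields, `[`, character(1), 1))
  }

  if (!is.null(paths$pets)) {
    df <- tryCatch(read_pets_tsv(paths$pets), error = function(e) e)
    if (inherits(df, "error")) {
      note(paths$pets, 1L, "error", conditionMessage(df))
    } else {
      bad <- which(df$pos_a < 0 | df$pos_b < 0)
      for (i in head(bad, 20)) {
        note(paths$pets, i + 1L, "error", "negative tag position")
      }
      chrom_sets[[paths$pets]] <- unique(c(df$chrom_a, df$chrom_b))
    }
  }

  if (!is.null(paths$expression)) {
    df <- tryCatch(read_tsv(paths$expression), error = function(e) e)
    if (inherits(df, "error")) {
      note(paths$expression, 1L, "error", conditionMessage(df))
    } else {
      if (!"gene_id" %in% names(df)) {
        note(paths$expression, 1L, "error", "missing gene_id column")
      }
      tpm <- grep("^tpm_", names(df), value = TRUE)
      if (length(tpm) == 0) {
        note(paths$expression, 1L, "error", "no tpm_* replicate columns")
      } else if (any(as.matrix(df[, tpm]) < 0, na.rm = TRUE)) {
        note(paths$expression, 1L, "error", "negative TPM values")
      }
    }
  }

  if (length(chrom_sets) > 1) {
    all_chroms <- Reduce(union, chrom_sets)
    for (f in names(chrom_sets)) {
      missing <- setdiff(all_chroms, chrom_sets[[f]])
      if (length(missing) > 0) {
        note(f, NA_integer_, "warning",
             paste("chromosomes absent from this file:",
                   paste(missing, collapse = ",")))
      }
    }
  }
  if (length(problems) == 0) {
    return(data.frame(file = character(0), line = integer(0),
                      severity = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, problems)
}
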