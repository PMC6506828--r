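#' Simulate a complete synthetic dataset
#'
#' Convenience driver that builds a genome, plants a regulatory architecture,
#' simulates PET tag pairs, per-bin H3K27ac read counts and WT/MUT expression,
#' and bundles everything (plus the planted truth) into one object that
#' [write_dataset()] can serialize.
#'
#' Stage seeds are derived deterministically from `seed` (fixed small offsets)
#' so each component can be regenerated in isolation.
#'
#' @param seed Integer master seed.
#' @param genome_params,arch_params,pet_params Named lists of overrides passed
#'   to [make_genome()], [make_architecture()] and [simulate_pets()].
#' @param model An [effect_model()]; its seed is replaced by a derived seed.
#' @param bin_size Bin width for the simulated mark count track.
#' @return An object of class `chia_dataset`.
#' @export
simulate_dataset <- function(seed = 1,
                             genome_params = list(),
                             arch_params = list(n_loops = 100),
                             pet_params = list(n_background_pets = 5000),
                             model = effect_model(),
                             bin_size = 200) {
  seeds <- derive_seeds(seed)
  genome <- do.call(make_genome, c(list(seed = seeds[["genome"]]), genome_params))
  arch <- do.call(make_architecture,
                  c(list(genome = genome, seed = seeds[["arch"]]), arch_params))
  pets <- do.call(simulate_pets,
                  c(list(arch = arch, genome = genome, seed = seeds[["pets"]]),
                    pet_params))
  model$seed <- seeds[["expression"]]
  expression <- simulate_expression(arch, genome, model)
  bins <- simulate_bin_counts(arch, genome, seed = seeds[["bins"]],
                              bin_size = bin_size)
  structure(list(genome = genome, arch = arch, pets = pets,
                 expression = expression, bins = bins, model = model,
                 seed = as.integer(seed)),
            class = "chia_dataset")
}

# Fixed fan-out of a master seed into per-stage seeds (kept below 2^31).
derive_seeds <- function(seed) {
  stages <- c("genome", "arch", "pets", "expression", "bins", "analysis")
  stats::setNames(as.integer((as.numeric(seed) * 131 + seq_along(stages) * 9973) %%
                               .Machine$integer.max), stages)
}

#' Simulate a 200-bp binned mark read-count track
#'
#' Poisson counts per genome-tiling bin for an H3K27ac-like mark in WT and
#' MUT: background rate everywhere, an elevated rate inside marked regions,
#' and a configurable fraction of marked regions losing enrichment in MUT so
#' differential-bin testing has planted positives.
#'
#' @param arch A `planted_architecture`.
#' @param genome A `syn_genome`.
#' @param seed Integer seed.
#' @param bin_size Bin width in bp.
#' @param background_rate,enriched_rate Poisson means per bin.
#' @param frac_lost_mut Fraction of marked regions dropped to background in MUT.
#' @return List with `bins` (GRanges tiling the genome) and integer count
#'   vectors `wt`, `mut`, plus `lost_regions` (GRanges truth).
#' @export
simulate_bin_counts <- function(arch, genome, seed, bin_size = 200,
                                background_rate = 0.2, enriched_rate = 5,
                                frac_lost_mut = 0.1) {
  clen <- chrom_lengths(genome)
  bins <- genome_bins(clen, bin_size)
  k27 <- arch$k27_regions
  with_seed(seed, {
    lost <- k27[runif(length(k27)) < frac_lost_mut]
    in_k27 <- IRanges::overlapsAny(bins, k27)
    in_lost <- IRanges::overlapsAny(bins, lost)
    lam_wt <- ifelse(in_k27, enriched_rate, background_rate)
    lam_mut <- ifelse(in_k27 & !in_lost, enriched_rate, background_rate)
    list(bins = bins,
         wt = rpois(length(bins), lam_wt),
         mut = rpois(length(bins), lam_mut),
         lost_regions = lost)
  })
}

# Non-overlapping genome-tiling bins.
genome_bins <- function(chrom_lengths, bin_size) {
  parts <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1L, chrom_lengths[[ch]], by = bin_size)
    list(chrom = rep(ch, length(starts)), start = starts,
         end = pmin(starts + bin_size - 1L, chrom_lengths[[ch]]))
  })
  gr(unlist(lapply(parts, `[[`, "chrom")),
     unlist(lapply(parts, `[[`, "start")),
     unlist(lapply(parts, `[[`, "end")))
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits tag pairs (TSV), peak sets (BED6), gene model (BED12 and TSV),
#' chromosome sizes (TSV), expression (TSV), binned mark counts (bedGraph,
#' WT and MUT) and a truth JSON carrying every planted parameter, so that
#' [read_dataset()] reproduces the in-memory objects.
#'
#' @param dataset A `chia_dataset` from [simulate_dataset()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "chia_dataset"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", outdir)
  p <- function(f) file.path(outdir, f)

  write_pets_tsv(dataset$pets, p("pets.tsv"))
  write_tsv(dataset$genome$chroms, p("chroms.tsv"))
  write_tsv(dataset$genome$genes, p("genes.tsv"))
  write_bed12_genes(dataset$genome$genes, p("genes.bed"))
  write_bed(dataset$arch$sox2_peaks, p("sox2_peaks.bed"))
  write_bed(dataset$arch$polII_peaks, p("polII_peaks.bed"))
  write_bed(dataset$arch$k27_regions, p("k27_regions.bed"))
  write_bed(dataset$arch$k4me1_regions, p("k4me1_regions.bed"))
  expr_cols <- c("gene_id", grep("^tpm_", names(dataset$expression), value = TRUE))
  write_tsv(dataset$expression[, expr_cols], p("expression.tsv"))
  write_bedgraph(dataset$bins$bins, dataset$bins$wt, p("k27_bins_wt.bedGraph"))
  write_bedgraph(dataset$bins$bins, dataset$bins$mut, p("k27_bins_mut.bedGraph"))
  write_tsv(dataset$arch$loops, p("loops_truth.tsv"))
  write_tsv(dataset$arch$enhancers, p("enhancers_truth.tsv"))

  truth <- c(dataset$arch$truth_params,
             list(master_seed = dataset$seed,
                  effect_model = unclass(dataset$model),
                  planted_down_genes =
                    dataset$expression$gene_id[dataset$expression$planted_down]))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list.files(outdir, full.names = TRUE))
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Directory previously populated by [write_dataset()].
#' @return A list with `pets`, `genome`, `sox2_peaks`, `polII_peaks`,
#'   `k27_regions`, `k4me1_regions`, `expression`, `bins`, `loops_truth`,
#'   `enhancers_truth` and `truth`.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  chroms <- read_tsv(p("chroms.tsv"))
  genes <- read_tsv(p("genes.tsv"))
  genome <- structure(list(chroms = chroms, genes = genes, seed = NA_integer_),
                      class = "syn_genome")
  bins_wt <- read_bedgraph(p("k27_bins_wt.bedGraph"))
  bins_mut <- read_bedgraph(p("k27_bins_mut.bedGraph"))
  list(
    pets = read_pets_tsv(p("pets.tsv")),
    genome = genome,
    sox2_peaks = read_bed(p("sox2_peaks.bed")),
    polII_peaks = read_bed(p("polII_peaks.bed")),
    k27_regions = read_bed(p("k27_regions.bed")),
    k4me1_regions = read_bed(p("k4me1_regions.bed")),
    expression = read_tsv(p("expression.tsv")),
    bins = list(bins = bins_wt$gr, wt = bins_wt$score, mut = bins_mut$score),
    loops_truth = read_tsv(p("loops_truth.tsv")),
    enhancers_truth = read_tsv(p("enhancers_truth.tsv")),
    truth = jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  )
}

## --- plain-text format helpers -------------------------------------------

write_tsv <- function(df, path) {
  # serialize doubles at full precision so a read-back reproduces them exactly
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write/read the tag-pair table
#'
#' Tab-separated, eight columns: `chrom_a, pos_a, strand_a, chrom_b, pos_b,
#' strand_b, linker_a, linker_b`. The truth `origin` column, if present, is
#' dropped on write.
#' @param pets Tag-pair data.frame.
#' @param path File path.
#' @export
write_pets_tsv <- function(pets, path) {
  cols <- c("chrom_a", "pos_a", "strand_a", "chrom_b", "pos_b", "strand_b",
            "linker_a", "linker_b")
  write_tsv(pets[, cols], path)
}

#' @rdname write_pets_tsv
#' @export
read_pets_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("chrom_a", "pos_a", "chrom_b", "pos_b")
  if (!all(need %in% names(df))) {
    stop("tag-pair file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

# BED6 via rtracklayer (1-based GRanges <-> 0-based BED handled there).
write_bed <- function(x, path) {
  if (length(x) > 0 && is.null(x$name)) x$name <- paste0("r", seq_along(x))
  if (length(x) > 0 && is.null(x$score)) x$score <- 0L
  rtracklayer::export(x, path, format = "BED")
}

read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

write_bedgraph <- function(bins, score, path) {
  x <- bins
  x$score <- score
  rtracklayer::export(x, path, format = "bedGraph")
}

read_bedgraph <- function(path) {
  x <- rtracklayer::import(path, format = "bedGraph")
  list(gr = GenomicRanges::granges(x), score = x$score)
}

# Minimal BED12: one block per gene, thick region = gene body.
write_bed12_genes <- function(genes, path) {
  df <- data.frame(
    chrom = genes$chrom, start = genes$start - 1L, end = genes$end,
    name = genes$gene_id, score = 0L, strand = genes$strand,
    thickStart = genes$start - 1L, thickEnd = genes$end, rgb = "0,0,0",
    blockCount = 1L, blockSizes = genes$end - genes$start + 1L, blockStarts = 0L
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' @export
print.chia_dataset <- function(x, ...) {
  cat(sprintf("synthetic ChIA-PET dataset (seed %d): %d PETs, %d loops, %d genes\n",
              x$seed, nrow(x$pets), nrow(x$arch$loops), nrow(x$genome$genes)))
  invisible(x)
}
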