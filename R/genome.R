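#' Generate a small synthetic genome with non-overlapping genes
#'
#' Builds a multi-chromosome genome and places non-overlapping gene bodies
#' with recorded transcription start sites (TSS). This is the scaffold every
#' other synthetic component (loops, peaks, expression) is planted on; at
#' least two chromosomes are required so inter-chromosomal PETs can exist.
#'
#' Genes are placed by jittered slotting: each chromosome is divided into
#' equal slots and one gene is drawn uniformly inside its slot, leaving a
#' buffer around every body so promoter windows of neighbouring genes never
#' collide. All coordinates are 1-based closed (BED output converts).
#'
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @param n_chroms Number of chromosomes (>= 2).
#' @param chrom_length Length of every chromosome in bp (>= 1e6).
#' @param n_genes Total number of genes (>= 10), split evenly across
#'   chromosomes.
#' @param gene_length_range Min/max gene-body length in bp.
#' @return An object of class `syn_genome`: a list with `chroms`
#'   (data.frame `chrom`, `length`) and `genes` (data.frame `gene_id`,
#'   `chrom`, `tss`, `strand`, `start`, `end`).
#' @examples
#' g <- make_genome(seed = 1, n_chroms = 2, chrom_length = 5e6, n_genes = 50)
#' nrow(g$genes)
#' @export
make_genome <- function(seed, n_chroms = 2, chrom_length = 5e6, n_genes = 200,
                        gene_length_range = c(5000, 20000)) {
  if (n_chroms < 2) stop("need >= 2 chromosomes so inter-chromosomal PETs can exist")
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (chrom_length < 1e6) stop("chrom_length must be >= 1e6")
  stopifnot(length(gene_length_range) == 2, gene_length_range[1] >= 100,
            gene_length_range[2] >= gene_length_range[1])

  edge <- 25000           # clear margin at chromosome ends
  buffer <- 6000          # clearance between neighbouring gene bodies
  chroms <- data.frame(
    chrom = paste0("chr", seq_len(n_chroms)),
    length = as.integer(rep(chrom_length, n_chroms)),
    stringsAsFactors = FALSE
  )
  per_chrom <- apportion(n_genes, rep(1, n_chroms))

  genes <- with_seed(seed, {
    out <- vector("list", n_chroms)
    for (ci in seq_len(n_chroms)) {
      k <- per_chrom[ci]
      if (k == 0) next
      usable <- chrom_length - 2 * edge
      slot <- floor(usable / k)
      if (slot < gene_length_range[2] + buffer) {
        stop("genes cannot be placed without overlap at the requested density")
      }
      len <- sample(seq(gene_length_range[1], gene_length_range[2]), k,
                    replace = TRUE)
      jitter_max <- slot - len - buffer
      offset <- floor(runif(k) * (jitter_max + 1))
      start <- edge + (seq_len(k) - 1L) * slot + offset + 1L
      end <- start + len - 1L
      strand <- sample(c("+", "-"), k, replace = TRUE)
      out[[ci]] <- data.frame(
        chrom = chroms$chrom[ci],
        start = as.integer(start),
        end = as.integer(end),
        strand = strand,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  genes$tss <- as.integer(ifelse(genes$strand == "+", genes$start, genes$end))
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "tss", "strand", "start", "end")]
  rownames(genes) <- NULL

  structure(list(chroms = chroms, genes = genes, seed = as.integer(seed)),
            class = "syn_genome")
}

#' @export
print.syn_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d chromosomes (%s bp each), %d genes\n",
              nrow(x$chroms), format(x$chroms$length[1], big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

# Named chromosome-length vector.
chrom_lengths <- function(genome) {
  stats::setNames(genome$chroms$length, genome$chroms$chrom)
}

# TSS as width-1 GRanges.
tss_gr <- function(genome) {
  gr(genome$genes$chrom, genome$genes$tss, genome$genes$tss,
     gene_id = genome$genes$gene_id)
}

# Gene bodies as GRanges.
gene_body_gr <- function(genome) {
  gr(genome$genes$chrom, genome$genes$start, genome$genes$end,
     gene_id = genome$genes$gene_id)
}

# Promoter windows (TSS +/- window, endpoints inclusive) as GRanges.
promoter_gr <- function(genome, window = 2500) {
  gr(genome$genes$chrom,
     pmax(1L, genome$genes$tss - as.integer(window)),
     genome$genes$tss + as.integer(window),
     gene_id = genome$genes$gene_id)
}
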