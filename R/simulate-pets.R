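#' Simulate ChIA-PET tag pairs from a planted architecture
#'
#' Emits signal PETs whose two tags fall uniformly inside the two anchors of a
#' planted loop, plus background self-ligation, intra-chromosomal and
#' inter-chromosomal PETs, optional PCR-style duplicates and chimeric
#' (mixed-linker) ligation artifacts.
#'
#' Background intra-chromosomal tag spans follow a truncated power law
#' (exponent `bg_exponent`, minimum `bg_min_dist`), a heavy-tailed stand-in
#' for real ligation noise; self-ligation spans are uniform on
#' `[0, self_span]`. Tag strands are generated but carry no signal: nothing
#' downstream conditions on strand.
#'
#' @param arch A `planted_architecture`.
#' @param genome The `syn_genome` the architecture was planted on.
#' @param seed Integer seed.
#' @param n_signal_pets Total signal PETs, apportioned across loops
#'   proportionally to their planted intensity (largest-remainder, so with the
#'   default `sum(intensity)` every loop receives exactly its intensity).
#' @param n_background_pets Total background PETs.
#' @param background_mix Fractions (self, intra, inter); must sum to 1.
#' @param duplicate_rate Fraction of extra near-duplicate PETs appended
#'   (copies jittered by at most 2 bp per end).
#' @param chimera_rate Fraction of PETs given AB/BA linker codes.
#' @param self_span Maximum self-ligation span in bp.
#' @param bg_exponent,bg_min_dist Power-law parameters for background
#'   intra-chromosomal spans.
#' @return A data.frame of tag pairs with columns `chrom_a`, `pos_a`,
#'   `strand_a`, `chrom_b`, `pos_b`, `strand_b`, `linker_a`, `linker_b` and a
#'   truth column `origin` (loop id, `self_bg`, `intra_bg`, `inter_bg`, or
#'   `duplicate`).
#' @export
simulate_pets <- function(arch, genome, seed,
                          n_signal_pets = NULL, n_background_pets = 0,
                          background_mix = c(self = 0.2, intra = 0.6, inter = 0.2),
                          duplicate_rate = 0, chimera_rate = 0,
                          self_span = 8000, bg_exponent = 1.0, bg_min_dist = 8001) {
  stopifnot(inherits(arch, "planted_architecture"), inherits(genome, "syn_genome"))
  if (abs(sum(background_mix) - 1) > 1e-8) stop("background_mix must sum to 1")
  if (duplicate_rate < 0 || duplicate_rate >= 1) stop("duplicate_rate must be in [0, 1)")
  stop_if_not_fraction(chimera_rate, "chimera_rate")
  loops <- arch$loops
  clen <- chrom_lengths(genome)
  if (is.null(n_signal_pets)) n_signal_pets <- sum(loops$intensity)

  with_seed(seed, {
    parts <- list()

    if (n_signal_pets > 0) {
      per_loop <- apportion(n_signal_pets, loops$intensity)
      idx <- rep(seq_len(nrow(loops)), per_loop)
      pos_a <- loops$start_a[idx] +
        floor(runif(length(idx)) * (loops$end_a[idx] - loops$start_a[idx] + 1))
      pos_b <- loops$start_b[idx] +
        floor(runif(length(idx)) * (loops$end_b[idx] - loops$start_b[idx] + 1))
      parts$signal <- data.frame(
        chrom_a = loops$chrom[idx], pos_a = as.integer(pos_a),
        chrom_b = loops$chrom[idx], pos_b = as.integer(pos_b),
        origin = loops$loop_id[idx], stringsAsFactors = FALSE
      )
    }

    if (n_background_pets > 0) {
      nb <- apportion(n_background_pets, background_mix)
      names(nb) <- c("self", "intra", "inter")
      if (nb[["self"]] > 0) {
        n <- nb[["self"]]
        chrom <- sample(names(clen), n, replace = TRUE, prob = clen)
        d <- floor(runif(n) * (self_span + 1))
        pos_a <- 1L + floor(runif(n) * (clen[chrom] - d - 1))
        parts$self <- data.frame(
          chrom_a = chrom, pos_a = as.integer(pos_a),
          chrom_b = chrom, pos_b = as.integer(pos_a + d),
          origin = "self_bg", stringsAsFactors = FALSE
        )
      }
      if (nb[["intra"]] > 0) {
        n <- nb[["intra"]]
        chrom <- sample(names(clen), n, replace = TRUE, prob = clen)
        dmax <- clen[chrom] - 2
        u <- runif(n)
        d <- if (abs(bg_exponent - 1) < 1e-9) {
          bg_min_dist * (dmax / bg_min_dist)^u
        } else {
          a <- 1 - bg_exponent
          (bg_min_dist^a + u * (dmax^a - bg_min_dist^a))^(1 / a)
        }
        d <- pmin(floor(d), dmax)
        pos_a <- 1L + floor(runif(n) * (clen[chrom] - d - 1))
        parts$intra <- data.frame(
          chrom_a = chrom, pos_a = as.integer(pos_a),
          chrom_b = chrom, pos_b = as.integer(pos_a + d),
          origin = "intra_bg", stringsAsFactors = FALSE
        )
      }
      if (nb[["inter"]] > 0) {
        n <- nb[["inter"]]
        ca <- sample(names(clen), n, replace = TRUE, prob = clen)
        shift <- sample.int(length(clen) - 1L, n, replace = TRUE)
        cb <- names(clen)[((match(ca, names(clen)) - 1L + shift) %% length(clen)) + 1L]
        parts$inter <- data.frame(
          chrom_a = ca, pos_a = as.integer(1L + floor(runif(n) * (clen[ca] - 1))),
          chrom_b = cb, pos_b = as.integer(1L + floor(runif(n) * (clen[cb] - 1))),
          origin = "inter_bg", stringsAsFactors = FALSE
        )
      }
    }

    pets <- do.call(rbind, parts)
    if (is.null(pets) || nrow(pets) == 0) {
      stop("no PETs generated; increase n_signal_pets or n_background_pets")
    }
    rownames(pets) <- NULL

    # canonical orientation: (chrom_a, pos_a) <= (chrom_b, pos_b)
    flip <- pets$chrom_a > pets$chrom_b |
      (pets$chrom_a == pets$chrom_b & pets$pos_a > pets$pos_b)
    if (any(flip)) {
      tmp <- pets[flip, ]
      pets$chrom_a[flip] <- tmp$chrom_b; pets$pos_a[flip] <- tmp$pos_b
      pets$chrom_b[flip] <- tmp$chrom_a; pets$pos_b[flip] <- tmp$pos_a
    }

    if (duplicate_rate > 0) {
      n_dup <- round(duplicate_rate * nrow(pets))
      if (n_dup > 0) {
        src <- pets[sample.int(nrow(pets), n_dup, replace = TRUE), ]
        src$pos_a <- as.integer(pmax(1L, src$pos_a + sample(-2:2, n_dup, TRUE)))
        src$pos_b <- as.integer(pmax(1L, src$pos_b + sample(-2:2, n_dup, TRUE)))
        src$origin <- "duplicate"
        pets <- rbind(pets, src)
      }
    }

    n <- nrow(pets)
    pets$strand_a <- sample(c("+", "-"), n, replace = TRUE)
    pets$strand_b <- sample(c("+", "-"), n, replace = TRUE)
    chim <- runif(n) < chimera_rate
    same <- sample(c("A", "B"), n, replace = TRUE)
    pets$linker_a <- ifelse(chim, ifelse(same == "A", "A", "B"), same)
    pets$linker_b <- ifelse(chim, ifelse(same == "A", "B", "A"), same)

    pets[, c("chrom_a", "pos_a", "strand_a", "chrom_b", "pos_b", "strand_b",
             "linker_a", "linker_b", "origin")]
  })
}
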