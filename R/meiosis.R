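# Gamete-level meiosis engine: no interference, Poisson crossover counts,
# uniform crossover positions, Bernoulli(1/2) start haplotype. Shared by the
# F_t single-seed-descent simulator and the genomic-mating progeny simulator.

# Phase of one gamete along a chromosome: which parental haplotype each
# marker is read from, given the start haplotype and crossover positions.
.gamete_phase <- function(start, xo, pos) {
  (start + vapply(pos, function(p) sum(xo < p), numeric(1))) %% 2
}

# One meiosis per row for a single chromosome.
# H1, H2: n x m parental haplotype matrices (rows are parents/meioses),
# pos: marker positions in cM. Crossover count ~ Poisson(L/100) with L the
# chromosome length in cM; positions ~ Uniform over the marker span.
.meiosis_chrom <- function(H1, H2, pos) {
  n <- nrow(H1)
  m <- length(pos)
  L <- max(pos) - min(pos)
  start <- stats::rbinom(n, 1L, 0.5)
  if (L <= 0) {
    phase <- matrix(start, n, m)
  } else {
    k <- stats::rpois(n, L / 100)
    kmax <- max(k, 0L)
    cross <- matrix(0L, n, m)
    if (kmax > 0) {
      xo <- matrix(Inf, n, kmax)
      for (q in seq_len(kmax)) {
        active <- k >= q
        if (any(active))
          xo[active, q] <- stats::runif(sum(active), min(pos), max(pos))
      }
      for (q in seq_len(kmax))
        cross <- cross + outer(xo[, q], pos, FUN = "<")
    }
    phase <- (start + cross) %% 2L
  }
  phase * H1 + (1L - phase) * H2
}

# Whole-genome meiosis: one gamete per row-parent.
# H1, H2: n x m across all markers; map provides chromosome grouping and cM.
.meiosis_genome <- function(H1, H2, map) {
  if (is.null(map$position_cm)) stop("marker map lacks position_cm")
  out <- matrix(0L, nrow(H1), ncol(H1))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    out[, idx] <- .meiosis_chrom(H1[, idx, drop = FALSE], H2[, idx, drop = FALSE],
                                 map$position_cm[idx])
  }
  out
}

#' Simulate gametes from a phased parent
#'
#' For each chromosome the gamete starts on one parental haplotype with
#' probability 1/2, receives a Poisson number of crossovers with mean equal
#' to the chromosome length in Morgans, places them independently uniformly
#' along the chromosome (no interference, no obligate chiasma), and reads the
#' markers off the resulting mosaic.
#'
#' @param h1,h2 the parent's two phased haplotypes: binary vectors, one entry
#'   per marker in map order.
#' @param map a [marker_map()] with `position_cm`.
#' @param n number of independent gametes.
#' @param seed optional RNG seed for reproducibility.
#' @return If `n = 1` a binary vector, otherwise an `n` x markers binary
#'   matrix; one row per gamete.
#' @export
simulate_gamete <- function(h1, h2, map, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(h1) != nrow(map) || length(h2) != nrow(map))
    stop("haplotype length must match the marker map")
  H1 <- matrix(h1, n, length(h1), byrow = TRUE)
  H2 <- matrix(h2, n, length(h2), byrow = TRUE)
  g <- .meiosis_genome(H1, H2, map)
  colnames(g) <- map$id
  if (n == 1L) g[1L, ] else g
}
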