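#' Gamete (haplotype) probabilities with optional segregation distortion
#'
#' Baseline F1 gamete probabilities for two loci at recombination fraction
#' `theta` are `((1-theta)/2, theta/2, theta/2, (1-theta)/2)` for the classes
#' (AB, Ab, aB, ab). Distortion multiplies the favored classes by `weight`
#' and renormalizes: `"allelic"` favors gametes carrying the reference allele
#' at the first locus (AB, Ab); `"nonrecombinant"` favors the parental
#' classes (AB, ab).
#'
#' @param theta recombination fraction in `[0, 0.5]`.
#' @param distortion `NULL` or a [distortion_spec()].
#' @return Named probability vector `c(AB, Ab, aB, ab)` summing to 1.
#' @export
gamete_probabilities <- function(theta, distortion = NULL) {
  if (theta < 0 || theta > 0.5) stop("theta must be in [0, 0.5]")
  p <- c(AB = (1 - theta) / 2, Ab = theta / 2, aB = theta / 2, ab = (1 - theta) / 2)
  if (!is.null(distortion)) {
    w <- switch(distortion$kind,
                allelic = c(distortion$weight, distortion$weight, 1, 1),
                nonrecombinant = c(distortion$weight, 1, 1, distortion$weight))
    p <- p * w
    p <- p / sum(p)
  }
  p
}

#' Segregation-distortion specification
#'
#' @param kind `"allelic"` (favor gametes carrying the first locus' reference
#'   allele) or `"nonrecombinant"` (favor parental gamete classes).
#' @param weight multiplicative weight `> 0` applied to the favored classes
#'   before renormalization; 1 means no distortion.
#' @return A list of class `distortion_spec`.
#' @export
distortion_spec <- function(kind = c("allelic", "nonrecombinant"), weight = 2) {
  kind <- match.arg(kind)
  if (weight <= 0) stop("weight must be > 0")
  structure(list(kind = kind, weight = weight), class = "distortion_spec")
}

#' Joint two-locus genotype probabilities in a selfing generation
#'
#' The 3x3 distribution of the coded genotype pair in generation `t` of
#' selfing, with heterozygosity `H_t = (1/2)^(t-1)` and `theta` read as the
#' generation-t effective recombination fraction. Margins are
#' `((1-H)/2, H, (1-H)/2)`, single-recombinant classes have probability
#' `H * theta * (1 - theta)` each, the double heterozygote keeps its phase
#' mixture `H * ((1-theta)^2 + theta^2)`, and the two corner classes solve
#' the margin and covariance constraints, which preserves the identity
#' `r = 1 - 2 * theta` at every generation and reduces to the classical F2
#' table at `t = 2`.
#'
#' @param theta recombination fraction in `[0, 0.5]`.
#' @param t selfing generation `>= 2`.
#' @return 3x3 probability matrix (rows/cols are codes 0, 1, 2).
#' @export
ft_joint_probs <- function(theta, t = 2L) {
  if (theta < 0 || theta > 0.5) stop("theta must be in [0, 0.5]")
  if (t < 2) stop("generation t must be >= 2")
  H <- 0.5^(t - 1)
  side <- H * theta * (1 - theta)
  center <- H * ((1 - theta)^2 + theta^2)
  corner_coupling <- 0.5 * (1 - theta) * ((1 - H) - H * theta)
  corner_repulsion <- (1 - H) / 2 - side - corner_coupling
  m <- matrix(c(corner_coupling, side, corner_repulsion,
                side, center, side,
                corner_repulsion, side, corner_coupling), 3, 3)
  dimnames(m) <- list(XA = 0:2, XB = 0:2)
  m
}

#' F_t pair simulation configuration
#'
#' @param theta recombination fraction.
#' @param t selfing generation.
#' @param n number of individuals.
#' @param seed optional RNG seed.
#' @param distortion `NULL` or a [distortion_spec()]; when set,
#'   [simulate_ft_pair()] switches to mechanistic gamete draws.
#' @return A list of class `ft_pair_config`.
#' @export
ft_pair_config <- function(theta, t = 2L, n, seed = NULL, distortion = NULL) {
  stopifnot(theta >= 0, theta <= 0.5, t >= 2, n >= 1)
  structure(list(theta = theta, t = as.integer(t), n = as.integer(n),
                 seed = seed, distortion = distortion),
            class = "ft_pair_config")
}

# draw one generation of F2 genotypes from two independent (possibly
# distorted) F1 gametes per individual; returns list(gA, gB) code vectors
.draw_f2_from_gametes <- function(n, theta, distortion) {
  p <- gamete_probabilities(theta, distortion)
  # gamete classes 1..4 = AB, Ab, aB, ab; allele at A: 1,1,0,0; at B: 1,0,1,0
  g1 <- sample.int(4L, n, replace = TRUE, prob = p)
  g2 <- sample.int(4L, n, replace = TRUE, prob = p)
  aA <- c(1L, 1L, 0L, 0L); aB <- c(1L, 0L, 1L, 0L)
  list(gA = aA[g1] + aA[g2], gB = aB[g1] + aB[g2])
}

#' Simulate a two-locus F_t sample
#'
#' Without distortion, draws i.i.d. genotype pairs from the 9-cell selfing
#' distribution of [ft_joint_probs()] (table mode, `theta` read as the
#' generation-t effective parameter). With a distortion spec, genotypes are
#' built mechanistically from two independent distorted F1 gametes per
#' individual (an F2 meiosis model), which is the mode used by the
#' distortion robustness studies.
#'
#' @param cfg an [ft_pair_config()].
#' @return A list with code vectors `gA`, `gB` of length `n`.
#' @export
simulate_ft_pair <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (!is.null(cfg$distortion)) {
    if (cfg$t != 2L)
      stop("mechanistic distorted draws are defined for t = 2")
    return(.draw_f2_from_gametes(cfg$n, cfg$theta, cfg$distortion))
  }
  probs <- as.vector(ft_joint_probs(cfg$theta, cfg$t))
  cell <- sample.int(9L, cfg$n, replace = TRUE, prob = probs)
  list(gA = (cell - 1L) %% 3L, gB = (cell - 1L) %/% 3L)
}

#' Simulate an F_t population genome by single-seed descent
#'
#' Founders are inbred lines fixed for alternative alleles at every marker;
#' the F1 is fully heterozygous with known phase. Each generation advances
#' every line by selfing a single offspring (single-seed descent), with both
#' gametes produced by the meiosis engine (Poisson crossovers, no
#' interference). Unlike table mode, recombination accumulates over the
#' `t - 1` meioses, so estimated map length grows with `t`.
#'
#' @param map a [marker_map()] with `position_cm`.
#' @param t target selfing generation `>= 2`.
#' @param n number of independent lines.
#' @param seed optional RNG seed.
#' @param keep_phase if `TRUE`, attach the phased haplotypes as attributes
#'   `h1` and `h2`.
#' @return A [genotype_matrix()] of the generation-t genotypes.
#' @export
simulate_ft_genome <- function(map, t = 2L, n, seed = NULL, keep_phase = FALSE) {
  if (is.null(map$position_cm)) stop("marker map lacks position_cm")
  if (t < 2) stop("generation t must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  H1 <- matrix(1L, n, m)  # F1: one haplotype from each founder
  H2 <- matrix(0L, n, m)
  for (gen in 2:t) {
    G1 <- .meiosis_genome(H1, H2, map)
    G2 <- .meiosis_genome(H1, H2, map)
    H1 <- G1
    H2 <- G2
  }
  g <- genotype_matrix(H1 + H2, individual_ids = paste0("line", seq_len(n)),
                       marker_ids = map$id, generation_t = t)
  if (keep_phase) {
    attr(g, "h1") <- H1
    attr(g, "h2") <- H2
  }
  g
}

#' Bias and precision study of the pairwise estimators
#'
#' Replicated two-locus F2 simulations over a grid of recombination
#' fractions: each replicate draws `n` individuals, estimates `theta` with
#' each requested method, and the study reports the mean and standard
#' deviation of the estimates per (theta, method) cell.
#'
#' @param theta_grid recombination fractions to simulate.
#' @param n individuals per replicate.
#' @param reps number of replicates (`>= 2` for standard deviations).
#' @param methods subset of `c("pcorr", "em_codominant", "em_dominant")`.
#' @param seed RNG seed; replicate r of theta index i uses an offset stream
#'   so the study is reproducible as a whole.
#' @param distortion `NULL` or a [distortion_spec()] applied to every
#'   meiosis.
#' @param t selfing generation of the simulated populations.
#' @return A data frame of class `sim_study_result` with columns `theta`,
#'   `method`, `mean`, `sd`, `reps`.
#' @export
run_bias_study <- function(theta_grid, n = 200L, reps = 100L,
                           methods = c("pcorr", "em_codominant", "em_dominant"),
                           seed = 1L, distortion = NULL, t = 2L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  res <- list()
  for (th in theta_grid) {
    est <- matrix(NA_real_, reps, length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(reps)) {
      sim <- simulate_ft_pair(ft_pair_config(th, t = t, n = n,
                                             distortion = distortion))
      tab <- build_joint_table(sim$gA, sim$gB)
      for (meth in methods) {
        e <- tryCatch(switch(meth,
                             pcorr = estimate_pcorr(tab),
                             em_codominant = estimate_em_codominant(tab),
                             em_dominant = estimate_em_dominant(collapse_to_phenotypes(tab))),
                      error = function(e) NULL)
        if (!is.null(e)) est[r, meth] <- e$theta
      }
    }
    for (meth in methods) {
      v <- est[, meth]
      res[[length(res) + 1L]] <- data.frame(
        theta = th, method = meth, mean = mean(v, na.rm = TRUE),
        sd = if (reps >= 2) stats::sd(v, na.rm = TRUE) else NA_real_,
        reps = sum(!is.na(v)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("sim_study_result", "data.frame")
  out
}
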