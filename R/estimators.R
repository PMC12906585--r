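#' EM control options
#'
#' @param theta_init starting value in (0, 0.5); the phase-agnostic midpoint
#'   0.25 is the default.
#' @param tol convergence tolerance on the parameter change between
#'   iterations.
#' @param max_iter maximum number of EM iterations.
#' @return A list of class `em_options`.
#' @export
em_options <- function(theta_init = 0.25, tol = 1e-10, max_iter = 1000L) {
  stopifnot(theta_init > 0, theta_init < 0.5, tol > 0, max_iter >= 1)
  structure(list(theta_init = theta_init, tol = tol, max_iter = as.integer(max_iter)),
            class = "em_options")
}

new_recomb_estimate <- function(theta, se, method, n, r = NA_real_, pi = NA_real_,
                                iterations = 0L, converged = TRUE, clamped = FALSE,
                                se_defined = TRUE, loglik = NA_real_) {
  structure(list(theta = theta, se = se, method = method, n = n, r = r, pi = pi,
                 iterations = as.integer(iterations), converged = converged,
                 clamped = clamped, se_defined = se_defined, loglik = loglik),
            class = "recomb_estimate")
}

#' @export
print.recomb_estimate <- function(x, ...) {
  cat(sprintf("theta = %.5f (se = %s), method = %s, n = %g\n", x$theta,
              if (x$se_defined) sprintf("%.5f", x$se) else "undefined",
              x$method, x$n))
  if (!is.na(x$r)) cat(sprintf("  r = %.5f%s\n", x$r,
                               if (x$clamped) " [negative correlation clamped to 0]" else ""))
  if (!is.na(x$pi)) cat(sprintf("  pi = %.5f\n", x$pi))
  if (x$iterations > 0)
    cat(sprintf("  EM iterations = %d (%s)\n", x$iterations,
                if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# moments of the coded pair implied by a count table
.table_moments <- function(m) {
  n <- sum(m)
  w <- as.vector(m)         # rows vary fastest in as.vector(m)
  i <- rep(0:2, times = 3)  # row code (first locus)
  j <- rep(0:2, each = 3)   # column code (second locus)
  sx <- sum(w * i); sy <- sum(w * j)
  list(n = n,
       sxx = sum(w * i^2) - sx^2 / n,
       syy = sum(w * j^2) - sy^2 / n,
       sxy = sum(w * i * j) - sx * sy / n)
}

#' Recombination fraction from the Pearson correlation of genotype codes
#'
#' In a selfing F_t population with inbred founders, no segregation
#' distortion and no crossover interference, the correlation between the two
#' loci's allele-count codes equals `1 - 2 * theta` for every generation, so
#' `theta` is estimated as `(1 - r) / 2`. A negative sample correlation would
#' imply `theta > 0.5`; it is clamped to `r = 0` (`theta = 0.5`) and flagged.
#' The standard error `(1 - r^2) / (2 * sqrt(n - 3))` uses the post-clamp r.
#'
#' @param t a [joint_count_table()] with at least 4 individuals.
#' @return A `recomb_estimate` with fields `theta`, `se`, `r`, `clamped`.
#' @export
estimate_pcorr <- function(t) {
  m <- unclass(t)
  mom <- .table_moments(m)
  if (mom$n < 4) stop("pcorr needs at least 4 individuals (SE requires n > 3)")
  if (mom$sxx <= 0 || mom$syy <= 0)
    stop("degenerate margin: a locus has zero genotype variance")
  r <- mom$sxy / sqrt(mom$sxx * mom$syy)
  clamped <- r < 0
  if (clamped) r <- 0
  theta <- (1 - r) / 2
  se <- (1 - r^2) / (2 * sqrt(mom$n - 3))
  new_recomb_estimate(theta, se, "pcorr", mom$n, r = r, clamped = clamped)
}

# pieces of the observed-data log likelihood for the codominant model:
# L(theta) = m0*log(1-theta) + m2*log(theta) + m22*log(theta^2+(1-theta)^2) + const
.codominant_stats <- function(m) {
  list(n = sum(m),
       m0 = 2 * (m[1, 1] + m[3, 3]) + (m[1, 2] + m[2, 1] + m[2, 3] + m[3, 2]),
       m2 = 2 * (m[1, 3] + m[3, 1]) + (m[1, 2] + m[2, 1] + m[2, 3] + m[3, 2]),
       m22 = m[2, 2])
}

#' Observed-data log likelihood of the codominant two-locus model
#'
#' Up to an additive constant: groups the nine cells into zero-, one- and
#' two-recombinant classes plus the mixture double-heterozygote class.
#'
#' @param theta recombination fraction(s) in (0, 0.5).
#' @param t a [joint_count_table()].
#' @return Log-likelihood value(s).
#' @export
loglik_codominant <- function(theta, t) {
  s <- .codominant_stats(unclass(t))
  s$m0 * log(1 - theta) + s$m2 * log(theta) + s$m22 * log(theta^2 + (1 - theta)^2)
}

#' Codominant EM estimate of the recombination fraction
#'
#' EM treats the split of the `m22` double heterozygotes into non-recombinant
#' and double-recombinant phase classes as missing data; the M step is the
#' recombinant-gamete share `theta = (m2 + 2 * rho * m22) / (2n)` with
#' posterior `rho = theta^2 / (theta^2 + (1 - theta)^2)`. The standard error
#' comes from Louis observed information: expected complete-data information
#' minus the variance of the complete-data score, both under the posterior of
#' the missing phase indicator at convergence.
#'
#' @param t a [joint_count_table()].
#' @param opts an [em_options()] list.
#' @return A `recomb_estimate`; at the `theta = 0` boundary the standard
#'   error is flagged undefined (`se_defined = FALSE`).
#' @export
estimate_em_codominant <- function(t, opts = em_options()) {
  m <- unclass(t)
  s <- .codominant_stats(m)
  if (s$n < 1) stop("empty table")
  theta <- opts$theta_init
  converged <- FALSE
  it <- 0L
  while (it < opts$max_iter) {
    it <- it + 1L
    rho <- theta^2 / (theta^2 + (1 - theta)^2)
    theta_new <- (s$m2 + 2 * rho * s$m22) / (2 * s$n)
    if (abs(theta_new - theta) < opts$tol) {
      theta <- theta_new
      converged <- TRUE
      break
    }
    theta <- theta_new
  }
  boundary <- s$m2 == 0  # the likelihood is maximized exactly at theta = 0
  if (boundary) theta <- 0
  clamped <- FALSE
  if (theta > 0.5) {  # domain is [0, 0.5]; cap repulsion-leaning tables
    theta <- 0.5
    clamped <- TRUE
  }
  if (boundary || theta >= 1 - 1e-12) {
    se <- NA_real_
    se_def <- FALSE
  } else {
    rho <- theta^2 / (theta^2 + (1 - theta)^2)
    info <- (s$m2 + 2 * rho * s$m22) / theta^2 +
      (s$m0 + 2 * (1 - rho) * s$m22) / (1 - theta)^2 -
      4 * s$m22 * rho * (1 - rho) / (theta * (1 - theta))^2
    se <- 1 / sqrt(info)
    se_def <- TRUE
  }
  ll <- if (theta > 0 && theta < 1) loglik_codominant(theta, t) else NA_real_
  new_recomb_estimate(theta, se, "em_codominant", s$n, iterations = it,
                      converged = converged || boundary, clamped = clamped,
                      se_defined = se_def, loglik = ll)
}

#' Observed-data log likelihood of the dominant four-phenotype model
#'
#' Parameterized by `pi = (1 - theta)^2`; up to an additive constant.
#'
#' @param pi value(s) in (0, 1).
#' @param p a `phenotype_counts` object.
#' @return Log-likelihood value(s).
#' @export
loglik_dominant <- function(pi, p) {
  p$n_AB * log(0.5 + 0.25 * pi) + (p$n_Ab + p$n_aB) * log(1 - pi) +
    p$n_ab * log(pi)
}

#' Dominant-marker EM estimate of the recombination fraction
#'
#' The classical four-phenotype formulation: with both loci dominant in
#' coupling phase the double-dominant class mixes a 1/2 component with a
#' `pi / 4` component, `pi = (1 - theta)^2`. EM iterates
#' `pi <- (pi * n_AB + (2 + pi) * n_ab) / (pi * n_AB + (2 + pi) * (n_ab + n_Ab + n_aB))`
#' and maps back through `theta = 1 - sqrt(pi)`. The variance of `pi` comes
#' from Louis observed information and is transferred to `theta` by the delta
#' method, `var(theta) = var(pi) / (4 * pi)`.
#'
#' @param p a `phenotype_counts` object (see [collapse_to_phenotypes()]).
#' @param opts an [em_options()] list; `theta_init` is converted to a `pi`
#'   start.
#' @return A `recomb_estimate` with the converged `pi` attached; boundary
#'   solutions (`pi` at 0 or 1) have the standard error flagged undefined.
#' @export
estimate_em_dominant <- function(p, opts = em_options()) {
  n_tot <- p$n_AB + p$n_Ab + p$n_aB + p$n_ab
  if (n_tot < 1) stop("empty phenotype counts")
  pi <- (1 - opts$theta_init)^2
  converged <- FALSE
  it <- 0L
  while (it < opts$max_iter) {
    it <- it + 1L
    pi_new <- (pi * p$n_AB + (2 + pi) * p$n_ab) /
      (pi * p$n_AB + (2 + pi) * (p$n_ab + p$n_Ab + p$n_aB))
    if (abs(pi_new - pi) < opts$tol) {
      pi <- pi_new
      converged <- TRUE
      break
    }
    pi <- pi_new
  }
  if (p$n_Ab + p$n_aB == 0) pi <- 1  # no repulsion-class observations
  theta <- 1 - sqrt(pi)
  clamped <- FALSE
  if (theta > 0.5) {  # pi < 0.25 implies theta beyond independent assortment
    theta <- 0.5
    clamped <- TRUE
  }
  boundary <- pi <= 1e-12 || pi >= 1 - 1e-12
  if (boundary) {
    se <- NA_real_
    se_def <- FALSE
  } else {
    rho <- pi / (2 + pi)
    info_pi <- (rho * p$n_AB + p$n_ab) / pi^2 + (p$n_Ab + p$n_aB) / (1 - pi)^2 -
      p$n_AB * rho * (1 - rho) / pi^2
    se <- sqrt(1 / info_pi / (4 * pi))
    se_def <- TRUE
  }
  ll <- if (pi > 0 && pi < 1) loglik_dominant(pi, p) else NA_real_
  new_recomb_estimate(theta, se, "em_dominant", n_tot, pi = pi, iterations = it,
                      converged = converged || p$n_Ab + p$n_aB == 0,
                      clamped = clamped, se_defined = se_def, loglik = ll)
}

#' Direct backcross estimate of the recombination fraction
#'
#' In a backcross the F1 gametes are observed directly, so `theta` is the
#' ratio of recombinant gametes to the total, with the binomial standard
#' error `sqrt(theta * (1 - theta) / n)`.
#'
#' @param n_AB,n_Ab,n_aB,n_ab counts of the four backcross two-locus
#'   genotype classes (parental, recombinant, recombinant, parental).
#' @return A `recomb_estimate`.
#' @export
estimate_bc_direct <- function(n_AB, n_Ab, n_aB, n_ab) {
  total <- n_AB + n_Ab + n_aB + n_ab
  if (total < 1) stop("empty backcross counts")
  theta <- (n_Ab + n_aB) / total
  se <- sqrt(theta * (1 - theta) / total)
  new_recomb_estimate(theta, se, "bc_direct", total,
                      se_defined = theta > 0 && theta < 1)
}

#' Chi-square test of single-locus segregation in a selfing generation
#'
#' Tests observed genotype counts against the expected segregation of
#' generation `t`: heterozygosity `H_t = (1/2)^(t - 1)`, each homozygote
#' `(1 - H_t) / 2` (1:2:1 for an F2). Used as a segregation-distortion
#' diagnostic before trusting the correlation-based estimator.
#'
#' @param counts three genotype counts in code order 0, 1, 2 (the middle
#'   count is the heterozygote).
#' @param t selfing generation, `t >= 2`.
#' @return A list of class `chisq_result`: `statistic`, `df` (2), `p_value`,
#'   `expected`.
#' @export
segregation_chisq <- function(counts, t = 2L) {
  if (length(counts) != 3L || any(counts < 0)) stop("need three non-negative counts")
  n <- sum(counts)
  if (n < 1) stop("empty counts")
  if (t < 2) stop("generation t must be >= 2")
  H <- 0.5^(t - 1)
  expected <- n * c((1 - H) / 2, H, (1 - H) / 2)
  stat <- sum((counts - expected)^2 / expected)
  structure(list(statistic = stat, df = 2L,
                 p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
                 expected = expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("segregation chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pooled (within-family) correlation
#'
#' For a random population structured in families, linkage disequilibrium is
#' preserved within families; the pooled correlation sums within-family
#' cross-products of deviations over families and normalizes by the pooled
#' within-family sums of squares.
#'
#' @param groups a list; each element is a list or data frame with components
#'   `x` and `y` (genotype codes of the two loci for one family). Pairs with
#'   a missing value are dropped; each family needs at least 2 complete
#'   pairs.
#' @return The pooled correlation (scalar).
#' @export
pooled_correlation <- function(groups) {
  if (length(groups) < 1) stop("need at least one group")
  sxy <- sxx <- syy <- 0
  for (g in groups) {
    x <- g$x; y <- g$y
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 2) stop("each group needs at least 2 complete pairs")
    sxy <- sxy + sum((x - mean(x)) * (y - mean(y)))
    sxx <- sxx + sum((x - mean(x))^2)
    syy <- syy + sum((y - mean(y))^2)
  }
  if (sxx <= 0 || syy <= 0) stop("zero pooled variance")
  sxy / sqrt(sxx * syy)
}
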