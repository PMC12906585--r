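#' Base population configuration for the genomic-mating workflow
#'
#' Defaults reproduce the illustration scale: an F2 of 500 individuals from
#' two inbred lines, 20 chromosomes of 100 cM covered by 101 evenly spaced
#' markers each (1 marker per cM, 2020 markers total). Marker additive and
#' dominance effects are drawn from centered normals with the given
#' variances; the residual variance gives broad-sense heritability near 0.72
#' at this scale.
#'
#' @param n number of individuals.
#' @param chromosomes,chrom_length_cm,markers_per_chrom genome layout.
#' @param additive_effect_var,dominance_effect_var variances of the marker
#'   effect distributions.
#' @param residual_var environmental variance of the phenotype.
#' @param seed optional RNG seed.
#' @return A list of class `base_pop_config`.
#' @export
base_pop_config <- function(n = 500L, chromosomes = 20L, chrom_length_cm = 100,
                            markers_per_chrom = 101L, additive_effect_var = 0.5,
                            dominance_effect_var = 1.0, residual_var = 1000,
                            seed = NULL) {
  stopifnot(n >= 2, chromosomes >= 1, chrom_length_cm > 0, markers_per_chrom >= 2,
            additive_effect_var >= 0, dominance_effect_var >= 0, residual_var > 0)
  structure(list(n = as.integer(n), chromosomes = as.integer(chromosomes),
                 chrom_length_cm = chrom_length_cm,
                 markers_per_chrom = as.integer(markers_per_chrom),
                 additive_effect_var = additive_effect_var,
                 dominance_effect_var = dominance_effect_var,
                 residual_var = residual_var, seed = seed),
            class = "base_pop_config")
}

# evenly spaced marker map implied by a base_pop_config
.config_map <- function(cfg) {
  per <- cfg$markers_per_chrom
  pos_cm <- seq(0, cfg$chrom_length_cm, length.out = per)
  marker_map(id = paste0("c", rep(seq_len(cfg$chromosomes), each = per), "_m",
                         rep(seq_len(per), cfg$chromosomes)),
             chromosome = paste0("chr", rep(seq_len(cfg$chromosomes), each = per)),
             position_bp = rep(seq_len(per), cfg$chromosomes),
             position_cm = rep(pos_cm, cfg$chromosomes))
}

#' Simulate the base population of the genomic-mating workflow
#'
#' An F2 population generated by the gamete-level meiosis engine, with marker
#' effects and phenotypes under the additive + dominance model
#' `y = mu + Z gamma + W delta + e`: `Z` counts reference alleles (0/1/2),
#' `W` indicates heterozygotes (0/1/0), `gamma_k ~ N(0, additive_effect_var)`,
#' `delta_k ~ N(0, dominance_effect_var)`, `e ~ N(0, residual_var)`.
#'
#' @param cfg a [base_pop_config()].
#' @return A list of class `base_population`: `Z`, `W`, phased haplotypes
#'   `h1`/`h2`, `map`, `effects` (list `gamma`, `delta`), phenotypes `y`,
#'   true genetic values `g_true`, and `cfg`.
#' @export
simulate_base_population <- function(cfg = base_pop_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  map <- .config_map(cfg)
  g <- simulate_ft_genome(map, t = 2L, n = cfg$n, keep_phase = TRUE)
  Z <- matrix(as.integer(g), nrow(g), ncol(g), dimnames = dimnames(g))
  W <- (Z == 1L) * 1L
  m <- nrow(map)
  gamma <- stats::rnorm(m, 0, sqrt(cfg$additive_effect_var))
  delta <- stats::rnorm(m, 0, sqrt(cfg$dominance_effect_var))
  g_true <- as.vector(Z %*% gamma + W %*% delta)
  y <- g_true + stats::rnorm(cfg$n, 0, sqrt(cfg$residual_var))
  structure(list(Z = Z, W = W, h1 = attr(g, "h1"), h2 = attr(g, "h2"),
                 map = map, effects = list(gamma = gamma, delta = delta),
                 y = y, g_true = g_true, cfg = cfg),
            class = "base_population")
}

#' Additive and dominance kinship matrices
#'
#' `K_gamma = Z Z' / C_gamma` and `K_delta = W W' / C_delta`, with the
#' normalizers `C = trace(XX') / n` so that both kinships have mean diagonal
#' 1 (trace n).
#'
#' @param Z additive code matrix (0/1/2), individuals x markers.
#' @param W dominance code matrix (0/1/0), same dimensions.
#' @return A list `K_gamma`, `K_delta`, `C_gamma`, `C_delta`.
#' @export
build_kinships <- function(Z, W) {
  ZZt <- tcrossprod(Z)
  WWt <- tcrossprod(W)
  Cg <- sum(diag(ZZt)) / nrow(Z)
  Cd <- sum(diag(WWt)) / nrow(W)
  if (Cg <= 0 || Cd <= 0) stop("zero trace: degenerate genotype codes")
  list(K_gamma = ZZt / Cg, K_delta = WWt / Cd, C_gamma = Cg, C_delta = Cd)
}

# minus twice the restricted log likelihood of
# V = s2A*Kg + s2D*Kd + s2E*I (up to a constant)
.neg2_reml <- function(log_s2, y, Kg, Kd, X) {
  s2 <- exp(log_s2)
  n <- length(y)
  V <- s2[1] * Kg + s2[2] * Kd
  diag(V) <- diag(V) + s2[3]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  resid_term <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1] + resid_term
}

#' REML variance components for the additive + dominance mixed model
#'
#' Fits `var(y) = K_gamma * sigma2_A + K_delta * sigma2_D + I * sigma2_E` by
#' direct maximization of the restricted log likelihood over the log
#' variances (Nelder-Mead), which enforces non-negativity; components driven
#' to the boundary come back as (numerically) zero.
#'
#' @param y phenotype vector.
#' @param K_gamma,K_delta kinship matrices from [build_kinships()].
#' @param X fixed-effect design matrix; intercept-only by default.
#' @param init optional starting values `c(sigma2_A, sigma2_D, sigma2_E)`.
#' @return A list of class `variance_components`: `sigma2_A`, `sigma2_D`,
#'   `sigma2_E`, `loglik` (restricted, up to a constant), `converged`,
#'   `iterations`.
#' @export
fit_reml <- function(y, K_gamma, K_delta, X = NULL, init = NULL) {
  n <- length(y)
  if (n < 10) stop("need at least 10 observations")
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(init)) init <- rep(stats::var(y) / 3, 3)
  opt <- stats::optim(log(pmax(init, 1e-8)), .neg2_reml, y = y, Kg = K_gamma,
                      Kd = K_delta, X = X, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  s2 <- exp(opt$par)
  structure(list(sigma2_A = s2[1], sigma2_D = s2[2], sigma2_E = s2[3],
                 loglik = -opt$value / 2, converged = opt$convergence == 0,
                 iterations = opt$counts[["function"]]),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components: sigma2_A = %.4f, sigma2_D = %.4f, sigma2_E = %.4f%s\n",
              x$sigma2_A, x$sigma2_D, x$sigma2_E,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' Polygenic predictions (GBLUP) from fitted variance components
#'
#' Generalized-least-squares fixed effects and the conditional expectations
#' of the additive and dominance polygenic values:
#' `xi_gamma = sigma2_A * K_gamma * V^-1 * (y - X beta)` and
#' `xi_delta = sigma2_D * K_delta * V^-1 * (y - X beta)`; the expected
#' breeding value is their sum.
#'
#' @param y phenotype vector.
#' @param K_gamma,K_delta kinship matrices.
#' @param vc a `variance_components` fit from [fit_reml()].
#' @param X fixed-effect design; intercept-only by default.
#' @return A list of class `polygenic_prediction`: `xi_gamma`, `xi_delta`,
#'   `xi`, `beta_hat`.
#' @export
predict_polygenic <- function(y, K_gamma, K_delta, vc, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  V <- vc$sigma2_A * K_gamma + vc$sigma2_D * K_delta
  diag(V) <- diag(V) + vc$sigma2_E
  R <- chol(V)
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
  Vi_res <- Vi_y - Vi_X %*% beta
  xi_g <- as.vector(vc$sigma2_A * (K_gamma %*% Vi_res))
  xi_d <- as.vector(vc$sigma2_D * (K_delta %*% Vi_res))
  structure(list(xi_gamma = xi_g, xi_delta = xi_d, xi = xi_g + xi_d,
                 beta_hat = as.vector(beta)),
            class = "polygenic_prediction")
}

# Moore-Penrose pseudoinverse solve: returns A' (AA')^+ b for row space A
.pinv_solve <- function(A, b, rtol = 1e-10) {
  AAt <- tcrossprod(A)
  eg <- eigen(AAt, symmetric = TRUE)
  keep <- eg$values > rtol * max(eg$values)
  U <- eg$vectors[, keep, drop = FALSE]
  w <- crossprod(U, b) / eg$values[keep]
  as.vector(crossprod(A, U %*% w))
}

#' Back-solve marker effects from polygenic predictions
#'
#' Minimum-norm conversion of the polygenic values to per-marker effects:
#' `gamma = Z'(ZZ')^- xi_gamma`, `delta = W'(WW')^- xi_delta`, using an
#' eigenvalue-thresholded pseudoinverse (relative tolerance 1e-10) since
#' `WW'` is frequently rank deficient. By construction `Z gamma` reproduces
#' the attainable part of `xi_gamma` exactly.
#'
#' @param pred a `polygenic_prediction` from [predict_polygenic()].
#' @param Z,W genotype code matrices used in the fit.
#' @return A list of class `marker_effects`: `gamma`, `delta`.
#' @export
backsolve_marker_effects <- function(pred, Z, W) {
  structure(list(gamma = .pinv_solve(Z, pred$xi_gamma),
                 delta = .pinv_solve(W, pred$xi_delta)),
            class = "marker_effects")
}

#' Mendelian expectations of progeny genotype codes
#'
#' For one biallelic marker with parental additive codes `g_sire`, `g_dam`
#' in 0/1/2, returns the progeny expectations of the additive code `Z` and
#' the heterozygosity indicator `W` under Mendelian transmission:
#' `E(Z) = (g_sire + g_dam) / 2` and
#' `E(W) = p_sire(A) p_dam(a) + p_sire(a) p_dam(A)` with allele transmission
#' probabilities `g/2`.
#'
#' @param g_sire,g_dam parental codes (vectorized over markers).
#' @return A list with vectors `E_Z` and `E_W`.
#' @export
progeny_expectation <- function(g_sire, g_dam) {
  if (any(!(g_sire %in% 0:2)) || any(!(g_dam %in% 0:2)))
    stop("parental codes must be 0, 1 or 2")
  pA_s <- g_sire / 2
  pA_d <- g_dam / 2
  list(E_Z = (g_sire + g_dam) / 2,
       E_W = pA_s * (1 - pA_d) + (1 - pA_s) * pA_d)
}

#' Expected progeny genetic value of a cross
#'
#' Sums the per-marker Mendelian expectations weighted by the estimated
#' marker effects: `sum(E(Z_k) gamma_k) + sum(E(W_k) delta_k)`.
#'
#' @param g_sire,g_dam parental additive code vectors over the same markers.
#' @param eff a `marker_effects` list.
#' @return Scalar expected progeny value.
#' @export
expected_progeny_value <- function(g_sire, g_dam, eff) {
  ex <- progeny_expectation(g_sire, g_dam)
  sum(ex$E_Z * eff$gamma) + sum(ex$E_W * eff$delta)
}

#' Progeny values by simulated meiosis
#'
#' Forms `N` virtual progeny from independent sire and dam gametes (meiosis
#' engine: Poisson crossovers, no interference), scores each with the
#' estimated marker effects, and returns the mean value and the standard
#' deviation of a single progeny's value (the Mendelian-sampling spread,
#' reported as `se`).
#'
#' @param sire,dam phased parents: lists with binary haplotype vectors `h1`,
#'   `h2` over the map's markers.
#' @param eff a `marker_effects` list.
#' @param map a [marker_map()] with `position_cm`.
#' @param N number of simulated progeny.
#' @param seed optional RNG seed.
#' @return A list `mean`, `se` (`NA` when `N = 1`), `N`, plus the per-marker
#'   simulation averages `Z_bar`, `W_bar`.
#' @export
simulate_progeny_values <- function(sire, dam, eff, map, N = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(map) == 0L) return(list(mean = 0, se = 0, N = N,
                                   Z_bar = numeric(0), W_bar = numeric(0)))
  gs <- simulate_gamete(sire$h1, sire$h2, map, n = N)
  gd <- simulate_gamete(dam$h1, dam$h2, map, n = N)
  if (N == 1L) { gs <- matrix(gs, 1); gd <- matrix(gd, 1) }
  Z <- gs + gd
  W <- (Z == 1L) * 1L
  vals <- as.vector(Z %*% eff$gamma + W %*% eff$delta)
  list(mean = mean(vals), se = if (N >= 2) stats::sd(vals) else NA_real_,
       N = N, Z_bar = colMeans(Z), W_bar = colMeans(W))
}
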