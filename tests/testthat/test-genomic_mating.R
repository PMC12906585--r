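# a reduced genome keeps the mixed-model tests fast
small_cfg <- function(seed, n = 200L)
  base_pop_config(n = n, chromosomes = 5L, markers_per_chrom = 21L,
                  residual_var = 200, seed = seed)

test_that("the base population has the configured genome and is reproducible", {
  cfg <- base_pop_config(seed = 1)
  expect_equal(cfg$chromosomes * cfg$markers_per_chrom, 2020L)
  pop <- simulate_base_population(small_cfg(3))
  expect_equal(dim(pop$Z), c(200L, 105L))
  expect_true(all(pop$W[pop$Z == 1] == 1) && all(pop$W[pop$Z != 1] == 0))
  expect_equal(pop$h1 + pop$h2, unname(pop$Z))
  # marker spacing is 1 marker per cM at the default layout
  map <- corrlink:::.config_map(base_pop_config())
  expect_equal(unique(diff(map$position_cm[1:101])), 1)
  pop2 <- simulate_base_population(small_cfg(3))
  expect_identical(pop$Z, pop2$Z)
  expect_identical(pop$y, pop2$y)
})

test_that("kinship normalization gives trace n and matches the definition", {
  pop <- simulate_base_population(small_cfg(11))
  kin <- build_kinships(pop$Z, pop$W)
  n <- nrow(pop$Z)
  expect_equal(sum(diag(kin$K_gamma)), n)
  expect_equal(sum(diag(kin$K_delta)), n)
  expect_equal(kin$K_gamma, tcrossprod(pop$Z) * n / sum(diag(tcrossprod(pop$Z))))
  # single-marker rank-1 case
  Z1 <- matrix(c(0, 2), 2, 1)
  k1 <- build_kinships(Z1, matrix(c(0, 1), 2, 1))
  expect_equal(qr(k1$K_gamma)$rank, 1L)
})

test_that("REML finds near-zero genetic components on pure-noise phenotypes", {
  pop <- simulate_base_population(small_cfg(21))
  kin <- build_kinships(pop$Z, pop$W)
  set.seed(99)
  ests <- replicate(5, {
    y0 <- rnorm(length(pop$y), 50, 10)
    vc <- fit_reml(y0, kin$K_gamma, kin$K_delta)
    c(vc$sigma2_A + vc$sigma2_D, vc$sigma2_E)
  })
  expect_lt(mean(ests[1, ]), 0.15 * mean(ests[2, ]))
})

test_that("polygenic prediction satisfies its algebraic identities", {
  pop <- simulate_base_population(small_cfg(31))
  kin <- build_kinships(pop$Z, pop$W)
  vc <- fit_reml(pop$y, kin$K_gamma, kin$K_delta)
  pred <- predict_polygenic(pop$y, kin$K_gamma, kin$K_delta, vc)
  expect_equal(pred$xi, pred$xi_gamma + pred$xi_delta)
  expect_gt(cor(pred$xi, pop$g_true), 0.5)
  # switching off dominance zeroes its prediction
  vc0 <- vc; vc0$sigma2_D <- 0
  pred0 <- predict_polygenic(pop$y, kin$K_gamma, kin$K_delta, vc0)
  expect_equal(pred0$xi_delta, rep(0, length(pop$y)))
})

test_that("marker-effect back-solving reproduces the polygenic values", {
  pop <- simulate_base_population(small_cfg(41))
  kin <- build_kinships(pop$Z, pop$W)
  vc <- fit_reml(pop$y, kin$K_gamma, kin$K_delta)
  pred <- predict_polygenic(pop$y, kin$K_gamma, kin$K_delta, vc)
  eff <- backsolve_marker_effects(pred, pop$Z, pop$W)
  expect_lt(max(abs(pop$Z %*% eff$gamma - pred$xi_gamma)), 1e-8)
  expect_lt(max(abs(pop$W %*% eff$delta - pred$xi_delta)), 1e-8)
  # zero polygenic values give zero effects
  pred0 <- pred; pred0$xi_gamma <- rep(0, length(pop$y))
  expect_equal(backsolve_marker_effects(pred0, pop$Z, pop$W)$gamma,
               rep(0, ncol(pop$Z)))
  # small-matrix case against an explicit pseudoinverse solution
  Z <- matrix(c(0, 1, 2, 2, 1, 0), 2, 3, byrow = TRUE)
  xi <- c(1.5, -0.5)
  got <- corrlink:::.pinv_solve(Z, xi)
  sv <- svd(Z)
  keep <- sv$d > 1e-10 * max(sv$d)
  expected <- sv$v[, keep] %*% ((1 / sv$d[keep]) * t(sv$u[, keep])) %*% xi
  expect_equal(got, as.vector(expected))
})

test_that("progeny expectations follow Mendelian transmission and symmetry", {
  # all nine parental combinations against the Mendelian table
  combos <- expand.grid(s = 0:2, d = 0:2)
  ex <- progeny_expectation(combos$s, combos$d)
  expect_equal(ex$E_Z, (combos$s + combos$d) / 2)
  # published expectations for the named crosses
  expect_equal(progeny_expectation(1, 1), list(E_Z = 1, E_W = 0.5))
  expect_equal(progeny_expectation(0, 2), list(E_Z = 1, E_W = 1))
  expect_equal(progeny_expectation(2, 2), list(E_Z = 2, E_W = 0))
  expect_equal(progeny_expectation(0, 1), list(E_Z = 0.5, E_W = 0.5))
  # sire/dam symmetry
  swapped <- progeny_expectation(combos$d, combos$s)
  expect_equal(ex, swapped)
  expect_error(progeny_expectation(3, 0), "0, 1 or 2")
})

test_that("expected progeny value is the effect-weighted Mendelian sum", {
  eff <- list(gamma = 1, delta = 2)
  expect_equal(expected_progeny_value(1, 1, eff), 1 * 1 + 0.5 * 2)
  expect_equal(expected_progeny_value(2, 0, list(gamma = 0, delta = 0)), 0)
})

test_that("simulated progeny values agree with the expectation method", {
  map <- single_chrom_map(11, spacing_cm = 10)
  set.seed(17)
  eff <- list(gamma = rnorm(11, 0, 1), delta = rnorm(11, 0, 1.5))
  # heterozygous sire, mixed dam
  sire <- list(h1 = rep(1, 11), h2 = rep(0, 11))
  dam <- list(h1 = c(rep(1, 6), rep(0, 5)), h2 = rep(0, 11))
  sim <- simulate_progeny_values(sire, dam, eff, map, N = 2000, seed = 18)
  expv <- expected_progeny_value(sire$h1 + sire$h2, dam$h1 + dam$h2, eff)
  expect_lt(abs(sim$mean - expv), 3 * sim$se / sqrt(sim$N))
  # determinism and the single-progeny edge case
  sim2 <- simulate_progeny_values(sire, dam, eff, map, N = 2000, seed = 18)
  expect_identical(sim, sim2)
  expect_true(is.na(simulate_progeny_values(sire, dam, eff, map, N = 1, seed = 1)$se))
})

test_that("scheme counting is exact and matches enumeration", {
  expect_equal(as.numeric(count_mating_schemes(6, 2)), 20)
  expect_equal(attr(count_mating_schemes(6, 2), "digits"), "20")
  expect_equal(as.numeric(count_mating_schemes(9, 3)), 1680)
  expect_equal(as.numeric(count_mating_schemes(3, 3)), 6)
  expect_error(count_mating_schemes(7, 2), "divisible")
  for (case in list(c(4, 2), c(6, 2), c(6, 3), c(8, 4), c(9, 3))) {
    schemes <- enumerate_mating_schemes(case[1], case[2])
    expect_equal(nrow(schemes), as.numeric(count_mating_schemes(case[1], case[2])))
    # partition family: every scheme covers all dams exactly once, no dupes
    expect_true(all(apply(schemes, 1, function(r) identical(sort(r), seq_len(case[1])))))
    expect_equal(anyDuplicated(schemes), 0L)
  }
  expect_equal(nrow(enumerate_mating_schemes(2, 2)), 2L)
  expect_error(enumerate_mating_schemes(100, 10), "cap")
})

test_that("the big-integer digit string is exact for factorial ratios", {
  # 12!/(4!)^3 = 34650, small enough to verify directly
  expect_equal(attr(count_mating_schemes(12, 3), "digits"), "34650")
  expect_equal(as.numeric(count_mating_schemes(12, 3)), 34650)
  # 16!/(4!)^4 = 63063000
  expect_equal(attr(count_mating_schemes(16, 4), "digits"), "63063000")
})

test_that("exhaustive search maximizes the scheme mean with canonical ties", {
  set.seed(23)
  tab <- matrix(runif(27, 20, 80), 3, 9)
  res <- search_best_scheme(tab)
  # brute force over the enumerated schemes
  schemes <- enumerate_mating_schemes(9, 3)
  sire_of_slot <- rep(1:3, each = 3)
  vals <- apply(schemes, 1, function(dams) mean(tab[cbind(sire_of_slot, dams)]))
  expect_equal(res$best_index, which.max(vals))
  expect_equal(res$best_value, max(vals))
  expect_equal(res$average_value, mean(vals))
  # the all-scheme average equals the plain table mean by symmetry
  expect_equal(res$average_value, mean(tab))
  # equal table: zero gain, first scheme wins the tie
  flat <- search_best_scheme(matrix(5, 2, 4))
  expect_equal(flat$gain_percent, 0)
  expect_equal(flat$best_index, 1L)
})

test_that("the end-to-end design selects by EBV rank and gains over random mating", {
  pop <- simulate_base_population(small_cfg(51, n = 150L))
  des <- genomic_mating_design(pop, n_dams = 6L, n_sires = 2L)
  expect_equal(dim(des$cross_expectation), c(2L, 6L))
  # dams are the top-6 EBV ranks, sires the next 2
  ord <- order(des$prediction$xi, decreasing = TRUE)
  expect_equal(des$dams, ord[1:6])
  expect_equal(des$sires, ord[7:8])
  # the argmax cannot fall below the all-scheme average (the percent gain is
  # only meaningful on a positive scale, so compare the raw values here)
  expect_gte(des$search$best_value, des$search$average_value)
  expect_equal(des$search$best_value,
               max(des$search$scheme_values))
})
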