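test_that("pcorr estimate is the correlation transform and clamps negative r", {
  # perfect coupling: diagonal table
  diag_tab <- joint_count_table(diag(c(50, 50, 50)))
  e <- estimate_pcorr(diag_tab)
  expect_equal(e$r, 1)
  expect_equal(e$theta, 0)
  expect_false(e$clamped)

  # anti-diagonal: negative correlation triggers the clamp
  anti <- joint_count_table(matrix(c(0, 0, 50, 0, 50, 0, 50, 0, 0), 3, 3))
  e2 <- estimate_pcorr(anti)
  expect_true(e2$clamped)
  expect_equal(e2$theta, 0.5)
  expect_equal(e2$r, 0)
  expect_equal(e2$se, 1 / (2 * sqrt(sum(anti) - 3)))

  # theta = (1 - r)/2 exactly whenever not clamped
  e3 <- estimate_pcorr(rice_pair_chr1())
  expect_identical(e3$theta, (1 - e3$r) / 2)
})

test_that("pcorr rejects degenerate margins and tiny samples", {
  mono <- joint_count_table(matrix(c(0, 0, 0, 2, 3, 1, 0, 0, 0), 3, 3, byrow = TRUE))
  expect_error(estimate_pcorr(mono), "degenerate margin")
  tiny <- joint_count_table(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3))
  expect_error(estimate_pcorr(tiny), "at least 4")
})

test_that("pcorr is invariant to transposition and joint allele relabeling", {
  for (tab in list(rice_pair_chr1(), rice_pair_chr4())) {
    e <- estimate_pcorr(tab)
    et <- estimate_pcorr(joint_count_table(t(unclass(tab))))
    expect_equal(et$theta, e$theta)
    expect_equal(et$se, e$se)
    # relabeling alleles at both loci reverses rows and columns
    both <- joint_count_table(unclass(tab)[3:1, 3:1])
    expect_equal(estimate_pcorr(both)$theta, e$theta)
    # relabeling one locus only flips the correlation sign -> clamp
    one <- joint_count_table(unclass(tab)[3:1, ])
    e1 <- estimate_pcorr(one)
    expect_true(e1$clamped)
    expect_equal(e1$theta, 0.5)
  }
})

test_that("codominant EM equals the numeric maximizer of the observed likelihood", {
  set.seed(101)
  for (rep in 1:30) {
    theta_true <- runif(1, 0.03, 0.45)
    sim <- simulate_ft_pair(ft_pair_config(theta_true, t = 2, n = 200))
    tab <- build_joint_table(sim$gA, sim$gB)
    em <- estimate_em_codominant(tab)
    oracle <- numeric_argmax(function(th) loglik_codominant(th, tab), 1e-6, 0.5)
    if (em$clamped) oracle <- min(oracle, 0.5)
    expect_lt(abs(em$theta - oracle), 1e-6)
  }
})

test_that("codominant EM handles boundary tables and reproduces first-step zeros", {
  # no recombinant classes at all: theta = 0, SE undefined at the boundary
  m <- matrix(0, 3, 3); m[1, 1] <- 40; m[3, 3] <- 60
  e <- estimate_em_codominant(joint_count_table(m))
  expect_equal(e$theta, 0)
  expect_false(e$se_defined)
  expect_true(e$converged)
  # non-convergence is flagged, not silent
  e2 <- estimate_em_codominant(rice_pair_chr1(), em_options(max_iter = 2))
  expect_false(e2$converged)
})

test_that("dominant EM equals the numeric maximizer mapped through pi", {
  set.seed(202)
  for (rep in 1:30) {
    theta_true <- runif(1, 0.03, 0.45)
    sim <- simulate_ft_pair(ft_pair_config(theta_true, t = 2, n = 300))
    p <- collapse_to_phenotypes(build_joint_table(sim$gA, sim$gB))
    em <- estimate_em_dominant(p)
    pi_oracle <- numeric_argmax(function(pi) loglik_dominant(pi, p), 1e-6, 1 - 1e-6)
    th_oracle <- min(max(1 - sqrt(pi_oracle), 0), 0.5)
    expect_lt(abs(em$theta - th_oracle), 1e-6)
  }
})

test_that("dominant EM flags boundary solutions without a standard error", {
  e <- estimate_em_dominant(phenotype_counts(150, 0, 0, 50))
  expect_equal(e$pi, 1)
  expect_equal(e$theta, 0)
  expect_false(e$se_defined)
})

test_that("Louis standard errors match the numerical observed information", {
  set.seed(303)
  for (rep in 1:20) {
    theta_true <- runif(1, 0.05, 0.4)
    sim <- simulate_ft_pair(ft_pair_config(theta_true, t = 2, n = 500))
    tab <- build_joint_table(sim$gA, sim$gB)
    em <- estimate_em_codominant(tab)
    if (!em$se_defined || em$theta <= 0.01 || em$theta >= 0.49) next
    info_num <- -numeric_d2(function(th) loglik_codominant(th, tab), em$theta)
    expect_lt(abs(em$se - 1 / sqrt(info_num)) / em$se, 1e-3)

    p <- collapse_to_phenotypes(tab)
    emd <- estimate_em_dominant(p)
    if (!emd$se_defined || emd$theta <= 0.01 || emd$theta >= 0.49) next
    info_pi <- -numeric_d2(function(pi) loglik_dominant(pi, p), emd$pi)
    se_num <- sqrt(1 / info_pi / (4 * emd$pi))
    expect_lt(abs(emd$se - se_num) / emd$se, 1e-3)
  }
})

test_that("backcross direct estimate is the recombinant ratio", {
  e <- estimate_bc_direct(90, 5, 5, 100)
  expect_equal(e$theta, 0.05)
  expect_equal(e$se, sqrt(0.05 * 0.95 / 200))
  expect_equal(estimate_bc_direct(100, 0, 0, 100)$theta, 0)
  expect_error(estimate_bc_direct(0, 0, 0, 0), "empty")

  # simulation consistency at theta = 0.2
  set.seed(7)
  p <- gamete_probabilities(0.2)
  cls <- sample.int(4, 10000, replace = TRUE, prob = p)
  cnt <- tabulate(cls, 4)
  e2 <- estimate_bc_direct(cnt[1], cnt[2], cnt[3], cnt[4])
  expect_lt(abs(e2$theta - 0.2), 3 * e2$se)
})

test_that("segregation chi-square uses generation-t expected ratios", {
  r <- segregation_chisq(c(50, 100, 50), t = 2)
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 2L)
  expect_equal(r$expected, c(50, 100, 50))
  # in later generations heterozygotes are rarer: H_4 = 1/8
  r4 <- segregation_chisq(c(70, 20, 70), t = 4)
  expect_equal(r4$expected, 160 * c(7 / 16, 1 / 8, 7 / 16))
  expect_error(segregation_chisq(c(1, 2), t = 2), "three")
  expect_error(segregation_chisq(c(1, 2, 1), t = 1), ">= 2")
})

test_that("pooled correlation reduces to Pearson for one group and pools deviations", {
  set.seed(5)
  x <- rnorm(30); y <- x + rnorm(30)
  expect_equal(pooled_correlation(list(list(x = x, y = y))), cor(x, y))
  # duplicating a group cannot change the pooled value
  expect_equal(pooled_correlation(list(list(x = x, y = y), list(x = x, y = y))),
               cor(x, y))
  # groups with opposite phase and shifted means: compare against explicit
  # evaluation of the pooled-deviation formula
  g1 <- list(x = x, y = y)
  g2 <- list(x = -x + 10, y = y + 5)
  got <- pooled_correlation(list(g1, g2))
  num <- sum((g1$x - mean(g1$x)) * (g1$y - mean(g1$y))) +
    sum((g2$x - mean(g2$x)) * (g2$y - mean(g2$y)))
  den <- sqrt((sum((g1$x - mean(g1$x))^2) + sum((g2$x - mean(g2$x))^2)) *
                (sum((g1$y - mean(g1$y))^2) + sum((g2$y - mean(g2$y))^2)))
  expect_equal(got, num / den)
  expect_error(pooled_correlation(list(list(x = 1, y = 2))), "2 complete pairs")
})
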