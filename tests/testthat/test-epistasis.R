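# Two- and three-locus nonindependence, IPF, enumeration and thresholds.

test_that("two-locus test scores zero on exact independence", {
  p <- c(0.25, 0.5, 0.25)
  q <- c(0.25, 0.5, 0.25)
  tab <- 40 * outer(p, q)
  t <- two_locus_test(tab)
  expect_equal(t$statistic, 0, tolerance = 1e-12)
  expect_equal(t$df, 4)
  expect_equal(t$p_value, 1)
})

test_that("two-locus test matches the hand-computed diagonal table", {
  t <- two_locus_test(diag(c(10, 20, 10)))
  expect_equal(t$statistic, 80)
  expect_equal(t$df, 4)
})

test_that("two-locus test equals the textbook contingency chi-squared", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(9, 20) + 1, 3)
    ours <- two_locus_test(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p_value, unname(ref$p.value))
  }
})

test_that("empty marginal classes collapse with reduced df", {
  # backcross-like pair: homozygote class absent at both loci
  m <- rbind(c(30, 20, 0), c(25, 25, 0), c(0, 0, 0))
  t <- two_locus_test(m)
  expect_equal(t$df, 1)
  expect_error(two_locus_test(rbind(c(10, 0, 0), c(20, 0, 0), c(5, 0, 0))),
               "single non-empty")
})

test_that("IPF reproduces all three pairwise margins", {
  set.seed(11)
  o <- array(rpois(27, 15) + 1, c(3, 3, 3))
  fit <- ipf_fit_no_three_way(o, tol = 1e-10)
  expect_equal(sum(fit), sum(o))
  expect_lt(max(abs(apply(fit, c(1, 2), sum) - apply(o, c(1, 2), sum))), 1e-8)
  expect_lt(max(abs(apply(fit, c(1, 3), sum) - apply(o, c(1, 3), sum))), 1e-8)
  expect_lt(max(abs(apply(fit, c(2, 3), sum) - apply(o, c(2, 3), sum))), 1e-8)
})

test_that("IPF is the identity on members of the pairwise model", {
  u <- array(2, c(3, 3, 3))
  expect_equal(ipf_fit_no_three_way(u), u, ignore_attr = TRUE)

  # complete-independence outer product is in the model
  p <- c(0.2, 0.5, 0.3)
  o <- 100 * outer(outer(p, p), p)
  dim(o) <- c(3, 3, 3)
  fit <- ipf_fit_no_three_way(o)
  expect_equal(fit, o, tolerance = 1e-8, ignore_attr = TRUE)

  # general no-three-way member: fit then refit is idempotent
  m <- no_three_way_table(seed = 3)
  fit1 <- ipf_fit_no_three_way(m)
  expect_equal(fit1, m, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("three-locus test is zero on pairwise-model members", {
  m <- no_three_way_table(seed = 5)
  for (pol in c("reported_12", "loglinear_8")) {
    t <- three_locus_test(m, df_policy = pol)
    expect_equal(t$statistic, 0, tolerance = 1e-6)
    expect_equal(t$p_value, 1, tolerance = 1e-6)
    expect_equal(t$df, if (pol == "reported_12") 12 else 8)
  }
})

test_that("three-locus null mean matches the log-linear df, not 12", {
  # independent distorted loci: the statistic's null mean diagnoses the
  # df convention discrepancy (mean ~ 8 = (3-1)^3)
  set.seed(202)
  p1 <- c(0.4, 0.45, 0.15)
  p2 <- c(0.25, 0.5, 0.25)
  p3 <- c(0.15, 0.55, 0.3)
  stats3 <- vapply(1:300, function(i) {
    cell_p <- outer(outer(p1, p2), p3)
    dim(cell_p) <- c(3, 3, 3)
    o <- array(stats::rmultinom(1, 300, as.vector(cell_p)), c(3, 3, 3))
    suppressWarnings(three_locus_test(o)$statistic)
  }, numeric(1))
  expect_gt(mean(stats3), 7)
  expect_lt(mean(stats3), 9.2)
})

test_that("permutation p-values are bounded and match the observed statistic", {
  panel <- tiny_panel(c("1", "2"), marker_id = c("a", "b"))
  sim <- simulate_cross(sim_config(panel, n_offspring = 120, seed = 31))
  obs <- two_locus_test(joint_counts(sim, c("a", "b")))
  pp <- permutation_p(sim, c("a", "b"), n_perm = 99, seed = 4)
  expect_equal(pp$statistic, obs$statistic)
  expect_gte(pp$p_value, 1 / 100)
  expect_lte(pp$p_value, 1)
  # deterministic given seed
  pp2 <- permutation_p(sim, c("a", "b"), n_perm = 99, seed = 4)
  expect_equal(pp$p_value, pp2$p_value)
  expect_error(permutation_p(sim, c("a", "b"), n_perm = 99), "seed")
})

test_that("permutation p is roughly uniform under the null", {
  panel <- tiny_panel(c("1", "2"), marker_id = c("a", "b"))
  ps <- vapply(1:60, function(i) {
    sim <- simulate_cross(sim_config(panel, n_offspring = 100, seed = 900 + i))
    permutation_p(sim, c("a", "b"), n_perm = 60, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("inter-chromosomal enumeration matches the closed-form counts", {
  p <- default_marker_panel()
  e2 <- enumerate_tests(p, 2)
  e3 <- enumerate_tests(p, 3)
  expect_equal(nrow(e2), 276)
  expect_equal(attr(e2, "n_tests"), 276)
  expect_equal(nrow(e3), 1780)

  counts <- c(1, 3, 5, 3, 2, 2, 1, 4, 1, 1, 1, 1)
  expect_equal(nrow(e2), esym2(counts))
  expect_equal(nrow(e3), esym3(counts))

  # every enumerated tuple is on pairwise distinct chromosomes
  chrom_of <- stats::setNames(p$chromosome, p$marker_id)
  expect_true(all(chrom_of[e2$marker1] != chrom_of[e2$marker2]))
  expect_true(all(
    chrom_of[e3$marker1] != chrom_of[e3$marker2] &
      chrom_of[e3$marker1] != chrom_of[e3$marker3] &
      chrom_of[e3$marker2] != chrom_of[e3$marker3]
  ))
})

test_that("enumeration equals the symmetric-polynomial oracle on random panels", {
  set.seed(99)
  for (i in 1:8) {
    n_chrom <- sample(2:6, 1)
    chroms <- sample(n_chrom, sample(4:12, 1), replace = TRUE)
    chroms <- sort(chroms)
    pan <- tiny_panel(chroms, position_cM = stats::ave(
      seq_along(chroms), chroms, FUN = seq_along
    ) * 10)
    cc <- as.numeric(table(chroms))
    expect_equal(nrow(enumerate_tests(pan, 2)), esym2(cc))
    expect_equal(nrow(enumerate_tests(pan, 3)), esym3(cc))
    expect_equal(nrow(enumerate_tests(pan, 2, policy = "all")),
                 choose(length(chroms), 2))
  }
  expect_equal(nrow(enumerate_tests(tiny_panel(c("1", "1"),
                                               position_cM = c(0, 10)), 2)), 0)
})

test_that("Bonferroni arithmetic and chi-squared helpers agree", {
  expect_equal(bonferroni_alpha(0.05, 25), 0.002)
  expect_equal(bonferroni_alpha(0.05, 276), 0.05 / 276)
  expect_error(bonferroni_alpha(0.05, 0), "positive")
  expect_error(bonferroni_alpha(1.2, 5), "family_alpha")

  # quantile and tail are mutual inverses
  for (df in c(1, 2, 4, 12)) {
    for (p in c(0.001, 0.01, 0.05, 0.5)) {
      expect_equal(chi2_upper_tail(chi2_upper_quantile(p, df), df), p,
                   tolerance = 1e-9)
    }
  }
  # tail strictly decreasing in x
  xs <- seq(0, 40, by = 2)
  expect_true(all(diff(chi2_upper_tail(xs, 4)) < 0))
  expect_error(chi2_upper_quantile(0, 4), "in \\(0, 1\\)")
  expect_error(chi2_upper_tail(-1, 4), ">= 0")
})
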