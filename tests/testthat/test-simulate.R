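# Forward cross simulator: gametes, recombination, designs, selection, sex.

test_that("simulation is deterministic given the configuration", {
  panel <- default_marker_panel()
  cfg <- sim_config(panel, n_offspring = 60, seed = 77)
  expect_identical(simulate_cross(cfg), simulate_cross(cfg))
})

test_that("female gametes transmit whole chromosomes intact", {
  panel <- default_marker_panel()
  f1 <- dmiscan:::make_f1(panel, "P2", "F")
  set.seed(1)
  g <- make_gamete(f1, panel, recombination_model(0), n = 300)
  chr3 <- which(panel$chromosome == "3")
  block <- g[, chr3]
  expect_true(all(block == block[, 1])) # never mixed within a chromosome
  expect_true(all(g %in% 1:2))
})

test_that("male recombinant fraction follows the Haldane map function", {
  panel <- tiny_panel(c("1", "1"), position_cM = c(0, 50))
  f1 <- dmiscan:::make_f1(panel, "P2", "M")
  set.seed(2)
  g <- make_gamete(f1, panel, recombination_model(), n = 20000)
  r_obs <- mean(g[, 1] != g[, 2])
  r_exp <- (1 - exp(-2 * 50 / 100)) / 2 # 0.3161
  se <- sqrt(r_exp * (1 - r_exp) / 20000)
  expect_lt(abs(r_obs - r_exp), 3 * se)
})

test_that("homozygous parents yield identical gametes regardless of map", {
  panel <- tiny_panel(c("1", "1"), position_cM = c(0, 80))
  founder <- dmiscan:::make_founder(panel, "P1", "M")
  set.seed(3)
  g <- make_gamete(founder, panel, recombination_model(), n = 500)
  expect_true(all(g == 1))
})

test_that("F2 transmission is Mendelian without selection", {
  panel <- default_marker_panel()
  sim <- simulate_cross(sim_config(panel, n_offspring = 1000, seed = 9))
  for (m in c("1", "3c", "8b", "12")) {
    freq <- mean(sim[[m]]) / 2 # P2 allele frequency
    se <- sqrt(0.5 * 0.5 / (2 * 1000))
    expect_lt(abs(freq - 0.5), 4 * se)
  }
})

test_that("backcross progeny never carry the non-recurrent homozygote", {
  panel <- default_marker_panel()
  bc2 <- simulate_cross(sim_config(
    panel, "BACKCROSS", n_offspring = 150, seed = 10,
    f1_parent_sex = "M", recurrent_population = "P2"
  ))
  geno <- as.matrix(bc2[, panel$marker_id])
  expect_true(all(geno %in% c(1, 2)))
  bc1 <- simulate_cross(sim_config(
    panel, "BACKCROSS", n_offspring = 150, seed = 10,
    f1_parent_sex = "F", recurrent_population = "P1"
  ))
  expect_true(all(as.matrix(bc1[, panel$marker_id]) %in% c(0, 1)))
})

test_that("nonrecombinant backcross progeny cosegregate chromosome-wide", {
  panel <- default_marker_panel()
  bc <- simulate_cross(sim_config(
    panel, "BACKCROSS", n_offspring = 200, seed = 11,
    f1_parent_sex = "F", recurrent_population = "P2"
  ))
  for (ch in c("2", "3", "8")) {
    idx <- panel$marker_id[panel$chromosome == ch]
    block <- as.matrix(bc[, idx])
    expect_true(all(block == block[, 1]))
  }
  # the recombinant (male-F1) backcross does mix within chromosomes
  bcm <- simulate_cross(sim_config(
    panel, "BACKCROSS", n_offspring = 200, seed = 11,
    f1_parent_sex = "M", recurrent_population = "P2"
  ))
  chr3 <- panel$marker_id[panel$chromosome == "3"]
  block <- as.matrix(bcm[, chr3])
  expect_gt(sum(block != block[, 1]), 0)
})

test_that("lethal homozygote selection removes the class and nothing else", {
  panel <- default_marker_panel()
  chr3 <- panel$marker_id[panel$chromosome == "3"]
  vm <- viability_model(
    single_locus = stats::setNames(
      replicate(5, c(1, 1, 0), simplify = FALSE), chr3
    )
  )
  sim <- simulate_cross(sim_config(panel, n_offspring = 400, seed = 12,
                                   viability = vm))
  for (m in chr3) {
    counts <- marginal_counts(sim, m)
    expect_equal(counts$n2, 0)
    v <- relative_viability(counts)
    expect_equal(v$w_p2, 0)
    # with lethality across the whole linked block and nonrecombinant
    # female transmission, survivors carrying a P2 maternal chromosome
    # need an all-P1 paternal chromosome, so P1/P1 is enriched relative
    # to het: w_p1 = 0.5 / (0.25 + 0.5 * P(all-P1 male gamete)) ~ 1.38,
    # not 1 as it would be for selection at a single locus
    expect_gt(v$w_p1, 1.05)
    expect_lt(v$w_p1, 1.8)
  }
  # neutral chromosomes still segregate 1:2:1
  p12 <- gof_test(marginal_counts(sim, "12"), c(1, 2, 1))$p_value
  expect_gt(p12, 0.001)
})

test_that("simulated viability 0.2 is recovered by the estimator", {
  panel <- tiny_panel(c("1", "2"), marker_id = c("a", "b"))
  vm <- viability_model(single_locus = list(a = c(1, 1, 0.2)))
  hits <- vapply(1:20, function(i) {
    sim <- simulate_cross(sim_config(panel, n_offspring = 1000,
                                     seed = 400 + i, viability = vm))
    v <- relative_viability(marginal_counts(sim, "a"))
    abs(v$w_p2 - 0.2) <= 3 * v$se_p2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate viability models error out of rejection sampling", {
  panel <- tiny_panel("1")
  vm <- viability_model(single_locus = list(m1 = c(1, 1, 1e-9)))
  vm$single_locus$m1 <- c(0, 0, 1e-12) # survival ~ 0 for everyone
  cfg <- sim_config(panel, n_offspring = 50, seed = 13, viability = vm,
                    max_tries_per_offspring = 20)
  expect_error(simulate_cross(cfg), "degenerate")
})

test_that("sex models behave as specified", {
  panel <- default_marker_panel()
  sim <- simulate_cross(sim_config(panel, n_offspring = 10000, seed = 14))
  frac_f <- mean(sim$sex == "F")
  expect_lt(abs(frac_f - 0.5), 3 * sqrt(0.25 / 10000))

  # all-zero polygenic effects reduce to the fair coin
  sim0 <- simulate_cross(sim_config(
    panel, n_offspring = 5000, seed = 15,
    sex = sex_model("polygenic", effects = c("2a" = 0))
  ))
  expect_lt(abs(mean(sim0$sex == "F") - 0.5), 3 * sqrt(0.25 / 5000))

  # a strong positive effect makes female fraction increase with dosage
  simq <- simulate_cross(sim_config(
    panel, n_offspring = 10000, seed = 16,
    sex = sex_model("polygenic", effects = c("2a" = 2))
  ))
  by_dosage <- vapply(0:2, function(d) {
    mean(simq$sex[simq[["2a"]] == d] == "F")
  }, numeric(1))
  expect_true(all(diff(by_dosage) > 0))
})

test_that("the backcross panel produces all eight labelled cross types", {
  panel <- default_marker_panel()
  base <- sim_config(panel, n_offspring = 40, seed = 17)
  tabs <- simulate_backcross_panel(base, 40)
  expect_length(tabs, 8)
  key <- t(vapply(tabs, function(tb) {
    c(tb$f1_parent_sex[1], tb$maternal_population[1],
      tb$recurrent_population[1], tb$cross_id[1])
  }, character(4)))
  expect_equal(anyDuplicated(key[, 4]), 0)
  combos <- unique(paste(key[, 1], key[, 3]))
  expect_length(combos, 4) # both F1 sexes x both recurrent pops
  for (tb in tabs) expect_equal(nrow(tb), 40)
})

test_that("neutral backcross panels pass the 1:1 expectation", {
  panel <- default_marker_panel()
  ok <- vapply(1:5, function(s) {
    base <- sim_config(panel, n_offspring = 200, seed = 600 + s)
    tabs <- simulate_backcross_panel(base, 200)
    all(vapply(tabs, function(tb) {
      ratio <- expected_genotype_ratio("BACKCROSS", tb$recurrent_population[1])
      gof_test(marginal_counts(tb, "3c"), ratio)$p_value > 0.00625
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("BC2 intercross lines retain whole-chromosome heterozygotes", {
  panel <- default_marker_panel()
  cfg <- sim_config(panel, n_offspring = 60, seed = 18,
                    recurrent_population = "P1")
  lines <- simulate_bc2_intercross(cfg, n_lines = 3, selection_marker = "3c")
  expect_gt(length(lines), 0)
  chr3 <- panel$marker_id[panel$chromosome == "3"]
  for (l in lines) {
    # both parents heterozygous across the whole focal chromosome: female
    # transmission is nonrecombinant and selection is on one marker only
    expect_true(all(l$parents[1, chr3] == 1))
    expect_equal(unname(unlist(l$parents[, "3c"])), c(1L, 1L))
    expect_equal(nrow(l$progeny), 60)
    # focal marker segregates all three classes (1:2:1 design)
    p <- gof_test(marginal_counts(l$progeny, "3c"), c(1, 2, 1))$p_value
    expect_gt(p, 1e-4)
  }
})

test_that("BC2 lines under focal lethality mirror zero homozygote viability", {
  panel <- default_marker_panel()
  vm <- viability_model(single_locus = list("3c" = c(1, 1, 0)))
  cfg <- sim_config(panel, n_offspring = 60, seed = 19,
                    recurrent_population = "P1", viability = vm)
  lines <- simulate_bc2_intercross(cfg, n_lines = 2, selection_marker = "3c")
  expect_gt(length(lines), 0)
  for (l in lines) {
    v <- relative_viability(marginal_counts(l$progeny, "3c"))
    expect_equal(v$w_p2, 0)
  }
})
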