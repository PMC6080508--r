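test_that("default templates cover every class with oracle-computed truth", {
  tpl <- default_templates(4)
  expect_gte(nrow(tpl), 13)
  # cached truth columns are exactly the oracle output
  recomputed <- truth_label(tpl$mu_Ar, tpl$mu_Co, tpl$mu_An, tpl$mu_Cn)
  expect_identical(tpl$truth_category, recomputed$category)
  expect_identical(tpl$truth_mechanism, recomputed$mechanism)
  expect_identical(tpl$truth_bias_transition, recomputed$bias_transition)
  # joint coverage of all ELD/additivity/transgressive classes
  expect_true(all(c("NoChange", "IV", "IX", "II", "XI", "I", "XII",
                    "V", "VI", "VIII", "III", "VII", "X")
                  %in% tpl$truth_category))
  # at least one variant per explanation mechanism
  mech <- tpl$truth_mechanism
  expect_true(any(mech == "dominant_down"))
  expect_true(any(mech %in% c("nondominant_up", "dominant_down_nondominant_up")))
  expect_true(any(mech == "nondominant_down"))
  expect_true(any(mech == "both_down"))
  expect_error(default_templates(1), "> 1")
  expect_error(default_templates(0.5), "> 1")
})

test_that("swapping the genomes mirrors template truth labels", {
  tpl <- default_templates(4)
  mirror <- c(NoChange = "NoChange", I = "XII", XII = "I", II = "IV",
              IV = "II", IX = "XI", XI = "IX", V = "VIII", VIII = "V",
              III = "X", X = "III", VI = "VI", VII = "VII")
  swapped <- truth_label(tpl$mu_Co, tpl$mu_Ar, tpl$mu_Cn, tpl$mu_An)
  expect_identical(unname(mirror[tpl$truth_category]), swapped$category)
  state_mirror <- c(A_gt = "C_gt", C_gt = "A_gt", EQ = "EQ")
  expect_identical(unname(state_mirror[tpl$truth_bias_progeny]),
                   swapped$bias_progeny)
})

test_that("simulation configs are validated", {
  expect_error(sim_config(template_mix = numeric(0)), "empty")
  expect_error(sim_config(template_mix = c(no_change = 0.5)), "sum to 1")
  expect_error(sim_config(template_mix = c(nonexistent = 1)), "template")
  expect_error(sim_config(cv = -0.1), "cv")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(base_mean_range = c(5, 2)), "interval")
  expect_equal(sum(default_template_mix()), 1)
})

test_that("simulation is reproducible and honours the noise model", {
  cfg <- sim_config(n_pairs = 300, seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr_parentA, b$expr_parentA)
  expect_identical(a$expr_polyploid, b$expr_polyploid)
  expect_identical(a$truth, b$truth)
  other <- simulate_expression(sim_config(n_pairs = 300, seed = 43))
  expect_false(identical(a$expr_parentA, other$expr_parentA))

  # cv = 0: every replicate equals its true mean exactly
  noiseless <- simulate_expression(sim_config(n_pairs = 100, cv = 0, seed = 5))
  m <- as.matrix(noiseless$expr_parentA[-1])
  expect_identical(unname(m[, 1]), noiseless$truth$mu_Ar)
  expect_true(all(m == m[, 1]))
})

test_that("simulated truth labels always match the exact-mean oracle", {
  ds <- simulate_expression(sim_config(n_pairs = 500, seed = 9))
  tl <- truth_label(ds$truth$mu_Ar, ds$truth$mu_Co,
                    ds$truth$mu_An, ds$truth$mu_Cn)
  expect_identical(ds$truth$truth_category, tl$category)
  expect_identical(ds$truth$truth_group, tl$group)
  expect_identical(ds$truth$truth_mechanism, tl$mechanism)
})

test_that("simulated depth tracks are Poisson with the requested mean", {
  d <- simulate_depth(c(chr1 = 50000), mean_depth = 30, seed = 3)
  expect_identical(nrow(d), 50000L)
  w <- window_means(d)
  # window mean of 10^4 Poisson(30) draws: SD = sqrt(30/10000)
  expect_true(all(abs(w$mean_depth - 30) < 5 * sqrt(30 / 10000)))

  zero <- simulate_depth(c(chrX = 1000), mean_depth = 0, seed = 3)
  expect_true(all(zero$depth == 0))

  again <- simulate_depth(c(chr1 = 50000), mean_depth = 30, seed = 3)
  expect_identical(d, again)
  expect_error(simulate_depth(c(chr1 = 100), mean_depth = -2), ">= 0")
  expect_error(simulate_depth(c(100), mean_depth = 2), "named")
})
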