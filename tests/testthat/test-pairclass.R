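# The decision tables are exercised twice: through the exact-mean oracle
# (truth_label) and through the t-test path on noise-free replicate data,
# which must agree with it.

test_that("exact-mean oracle reproduces hand-derived categories", {
  # (A_r, C_o, A_n, C_n) -> category
  cases <- list(
    list(c(6, 6, 3, 3), "NoChange"),
    list(c(4, 1, 3, 1), "IV"),    # S = A_r > C_o, higher parent
    list(c(1, 4, 1, 0), "IX"),    # S = A_r < C_o, lower parent
    list(c(1, 4, 1, 3), "II"),
    list(c(4, 1, 0, 1), "XI"),
    list(c(1, 4, 1, 1.5), "I"),   # A_r < S = 2.5 < C_o
    list(c(4, 1, 1.5, 1), "XII"),
    list(c(1, 4, 4, 4), "V"),     # S above both, A_r < C_o
    list(c(1, 1, 1, 1), "VI"),    # S above both, parents equal
    list(c(4, 1, 4, 4), "VIII"),  # S above both, A_r > C_o
    list(c(1, 4, 0.25, 0.25), "III"),
    list(c(1, 1, 0.25, 0.25), "VII"),
    list(c(4, 1, 0.25, 0.25), "X")
  )
  for (cs in cases) {
    tl <- truth_label(cs[[1]][1], cs[[1]][2], cs[[1]][3], cs[[1]][4])
    expect_identical(tl$category, cs[[2]])
  }
  # all 9 (d1, d2) cells of the decision table are reachable above:
  got <- vapply(cases, function(cs) {
    truth_label(cs[[1]][1], cs[[1]][2], cs[[1]][3], cs[[1]][4])$category
  }, character(1))
  expect_setequal(got, c("NoChange", "IV", "IX", "II", "XI", "I", "XII",
                         "V", "VI", "VIII", "III", "VII", "X"))
})

test_that("oracle assigns groups, directions and mechanisms consistently", {
  tl <- truth_label(4, 1, 3, 1)
  expect_identical(tl$group, "ELD_A")
  expect_identical(tl$eld_direction, "higher_parent")
  expect_identical(tl$change_A, "down")
  expect_identical(tl$change_C, "unchanged")
  expect_identical(tl$mechanism, "dominant_down")
  tl <- truth_label(1, 4, 1, 0)
  expect_identical(tl$group, "ELD_A")
  expect_identical(tl$eld_direction, "lower_parent")
  expect_identical(tl$mechanism, "nondominant_down")
  tl <- truth_label(1, 4, 0.7, 0.3)
  expect_identical(tl$mechanism, "both_down")
  tl <- truth_label(6, 6, 3, 3)
  expect_true(is.na(tl$mechanism))
  expect_error(truth_label(-1, 1, 1, 1), "non-negative")
})

test_that("noise-free bias classification matches the worked transitions", {
  mu <- rbind(
    c(5, 5, 4, 1),   # parents EQ, progeny A_gt  -> novel
    c(4, 1, 4, 1),   # maintained A-bias
    c(4, 1, 1, 1),   # reverted
    c(4, 1, 1, 4)    # switched
  )
  ds <- make_pair_dataset(mu, cv = 0)
  res <- classify_pair_dataset(ds)
  expect_identical(res$bias$parent_state, c("EQ", "A_gt", "A_gt", "A_gt"))
  expect_identical(res$bias$progeny_state, c("A_gt", "A_gt", "EQ", "C_gt"))
  expect_identical(res$bias$transition,
                   c("novel", "maintained", "reverted", "switched"))
})

test_that("noise-free ELD classification matches the decision table", {
  mu <- rbind(
    c(8, 2, 6, 2),   # S = 8 = A_r > C_o -> IV
    c(3, 3, 3, 3),   # S = 6 above equal parents -> VI
    c(2, 8, 2, 3)    # A_r < S = 5 < C_o -> I
  )
  ds <- make_pair_dataset(mu, cv = 0)
  res <- classify_pair_dataset(ds)
  expect_identical(res$eld$category, c("IV", "VI", "I"))
  expect_identical(res$eld$group, c("ELD_A", "TransUp", "Additivity"))
  expect_identical(res$eld$eld_direction, c("higher_parent", "n/a", "n/a"))
  expect_true(all(res$eld$consistent))
})

test_that("inconsistent parent comparison is flagged, not reclassified", {
  # Parents differ sharply, but the noisy pair total is distinguishable from
  # neither: the decision table still says NoChange, with consistent = FALSE.
  pe <- tibble::tibble(
    pair_id = "p1",
    gene_id_A = "gA", gene_id_C = "gC",
    A_r = list(c(10, 10, 10.1)),
    C_o = list(c(20, 20, 20.1)),
    A_n = list(c(2, 20, 10)),
    C_n = list(c(3, 20, 5))
  )
  res <- classify_eld(pe)
  expect_identical(res$category, "NoChange")
  expect_false(res$consistent)
})

test_that("explanation calls label ELD mechanisms from homoeolog changes", {
  mu <- rbind(
    c(8, 2, 6, 2),     # IV, A down, C unchanged -> dominant_down
    c(2, 8, 2, 6),     # II, C down, A unchanged -> dominant_down
    c(2, 8, 2, 0),     # IX, C down, A unchanged -> nondominant_down
    c(8, 2, 1.4, 0.6)  # XI? S = 2 = C_o < A_r; A down, C down -> both_down
  )
  ds <- make_pair_dataset(mu, cv = 0)
  res <- classify_pair_dataset(ds)
  expl <- explain_eld(res$pe, res$eld)
  expect_identical(res$eld$category, c("IV", "II", "IX", "XI"))
  expect_identical(expl$mechanism,
                   c("dominant_down", "dominant_down",
                     "nondominant_down", "both_down"))
  expect_identical(expl$change_A, c("down", "unchanged", "unchanged", "down"))
})

test_that("explanation is refused when no ELD pairs are supplied", {
  ds <- make_pair_dataset(rbind(c(3, 3, 1.5, 1.5)), cv = 0)
  res <- classify_pair_dataset(ds)
  expect_error(explain_eld(res$pe, res$eld), "ELD")
})

test_that("classification needs at least two replicates", {
  ds <- make_pair_dataset(rbind(c(4, 1, 3, 1)), cv = 0, n_rep = 1)
  pe <- pair_expression(ds$pairs, ds$expr_parentA, ds$expr_parentC,
                        ds$expr_polyploid)
  expect_error(classify_bias(pe), "2 replicates")
  expect_error(classify_eld(pe), "2 replicates")
})

test_that("relabelling the two genomes maps every call to its mirror", {
  set.seed(21)
  n <- 200
  mu <- matrix(rlnorm(4 * n, log(20), 1), ncol = 4)
  ds <- make_pair_dataset(mu, cv = 0.3)
  # reuse the same noisy replicate values, swapped between genomes
  pe <- pair_expression(ds$pairs, ds$expr_parentA, ds$expr_parentC,
                        ds$expr_polyploid)
  pe_sw <- pe
  pe_sw$A_r <- pe$C_o
  pe_sw$C_o <- pe$A_r
  pe_sw$A_n <- pe$C_n
  pe_sw$C_n <- pe$A_n

  cat_mirror <- c(NoChange = "NoChange", I = "XII", XII = "I", II = "IV",
                  IV = "II", IX = "XI", XI = "IX", V = "VIII", VIII = "V",
                  III = "X", X = "III", VI = "VI", VII = "VII")
  state_mirror <- c(A_gt = "C_gt", C_gt = "A_gt", EQ = "EQ")

  eld <- classify_eld(pe)
  eld_sw <- classify_eld(pe_sw)
  expect_identical(unname(cat_mirror[eld$category]), eld_sw$category)

  bias <- classify_bias(pe)
  bias_sw <- classify_bias(pe_sw)
  expect_identical(unname(state_mirror[bias$parent_state]),
                   bias_sw$parent_state)
  expect_identical(unname(state_mirror[bias$progeny_state]),
                   bias_sw$progeny_state)
  expect_identical(bias$transition, bias_sw$transition)
})
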