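test_that("proportion tables are true partitions with 1-decimal percents", {
  pt <- proportion_table(c(a = 6170, b = 10745))
  expect_equal(pt$percent, c(36.5, 63.5))
  expect_equal(sum(pt$count), 16915)
  expect_equal(sum(pt$proportion), 1)
  expect_error(proportion_table(c(a = 1, b = 2), denominator = 10),
               "denominator")
  expect_error(proportion_table(numeric(0)), "empty")
  expect_error(proportion_table(c(1, 2)), "named")
})

test_that("bias summaries partition pairs and fold switched into novel", {
  bias <- tibble::tibble(
    pair_id = sprintf("p%d", 1:8),
    parent_state = c("EQ", "A_gt", "A_gt", "A_gt", "EQ", "C_gt", "EQ", "EQ"),
    progeny_state = c("A_gt", "A_gt", "EQ", "C_gt", "EQ", "C_gt", "EQ", "C_gt"),
    transition = c("novel", "maintained", "reverted", "switched",
                   "maintained", "maintained", "maintained", "novel")
  )
  s <- summarize_bias(bias)
  expect_equal(sum(s$progeny$count), 8)
  expect_equal(s$progeny$count[s$progeny$stratum == "A_biased"], 2)
  # switched counted as novel in the three-way table
  expect_equal(s$transition$count[s$transition$stratum == "novel"], 3)
  expect_equal(s$transition_detail$count[
    s$transition_detail$stratum == "switched"], 1)
  expect_equal(sum(s$transition$count), 8)
  expect_error(summarize_bias(bias[0, ]), "empty")
  expect_error(summarize_bias(dplyr::bind_rows(bias, bias[1, ])), "duplicate")
})

test_that("ELD summaries report groups and categories as partitions", {
  eld <- tibble::tibble(
    pair_id = sprintf("p%d", 1:6),
    category = c("NoChange", "IV", "IX", "II", "V", "I"),
    group = c("NoChange", "ELD_A", "ELD_A", "ELD_C", "TransUp", "Additivity")
  )
  s <- summarize_eld(eld)
  expect_equal(sum(s$group$count), 6)
  expect_equal(sum(s$category$count), 6)
  expect_equal(s$group$count[s$group$stratum == "ELD_A"], 2)
  # group totals equal the sum of their member categories
  cat_tbl <- s$category
  expect_equal(
    sum(cat_tbl$count[cat_tbl$stratum %in% c("IV", "IX")]),
    s$group$count[s$group$stratum == "ELD_A"]
  )
  expect_error(summarize_eld(eld[0, ]), "empty")
})

test_that("mechanism totals follow the dominance geometry", {
  cells <- tibble::tibble(
    category = c("IV", "IV", "IV", "IV", "IX", "IX", "IX"),
    change_A = c("down", "down", "down", "unchanged",
                 "unchanged", "down", "unchanged"),
    change_C = c("down", "unchanged", "up", "up",
                 "down", "down", "unchanged"),
    n = c(208, 1220, 232, 293, 116, 103, 500)
  )
  mt <- explain_mechanism_totals(cells)
  get <- function(cat, mech) mt$n_pairs[mt$category == cat & mt$mechanism == mech]
  expect_equal(get("IV", "dominant_down"), 208 + 1220 + 232)
  expect_equal(get("IV", "nondominant_up"), 293 + 232)
  expect_equal(get("IX", "nondominant_down"), 116)
  expect_equal(get("IX", "both_down"), 103)

  marg <- explain_marginals(cells)
  expect_equal(marg$a_modified, 208 + 1220 + 232 + 103)
  expect_equal(marg$none_modified, 500)
  expect_equal(marg$total, sum(cells$n))
})

test_that("explanation summaries cross-tabulate ELD pairs per category", {
  mu <- rbind(
    c(8, 2, 6, 2),     # IV dominant_down
    c(8, 2, 6, 2),     # IV dominant_down
    c(2, 8, 2, 0)      # IX nondominant_down
  )
  ds <- make_pair_dataset(mu, cv = 0)
  res <- classify_pair_dataset(ds)
  expl <- explain_eld(res$pe, res$eld)
  s <- summarize_explain(expl, res$eld)
  expect_equal(sum(s$cells$n), 3)
  expect_equal(s$marginals$total, 3)
  expect_equal(
    s$cells$n[s$cells$category == "IV" & s$cells$change_A == "down" &
                s$cells$change_C == "unchanged"], 2)
  expect_error(summarize_explain(expl[0, ], res$eld), "missing")
})

test_that("enrichment tests each covered term hypergeometrically", {
  background <- sprintf("g%02d", 1:20)
  study <- sprintf("g%02d", 1:5)
  term_map <- tibble::tibble(
    term = c("T1", "T2"),
    description = c("hit set", "uncovered set"),
    genes = list(c("g01", "g02", "g03", "g04", "g10"),
                 c("g15", "g16"))
  )
  res <- enrich(study, background, term_map)
  expect_identical(res$term, "T1") # k = 0 term excluded
  expect_equal(res$k, 4)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$q, res$p)
  expect_false(res$enriched) # default cutoff 0.001
  expect_identical(formals(enrich)$fdr_cutoff, 0.001)

  expect_error(enrich(c("gXX"), background, term_map), "absent")
  expect_error(
    enrich("g19", background,
           tibble::tibble(term = "T2", description = "x",
                          genes = list("g15"))),
    "no term"
  )
})
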