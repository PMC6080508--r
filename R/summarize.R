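# Count/proportion tables over the per-pair classifications, the
# homoeolog-change decomposition of ELD, and hypergeometric term
# enrichment.

#' Count-and-percentage table over strata
#'
#' Turns named counts into a tidy summary with proportions and percentages
#' rounded (half-to-even) to one decimal, the printing convention used for
#' all pair-level summaries in this package.
#'
#' @param counts Named numeric vector of stratum counts, or a tibble with
#'   columns `stratum` and `count`.
#' @param denominator Total the counts must sum to; defaults to
#'   `sum(counts)`. A mismatch is an error, so every summary table is a
#'   true partition of its denominator.
#' @return Tibble: `stratum`, `count`, `proportion`, `percent`.
#' @examples
#' proportion_table(c(A_biased = 3223, C_biased = 2947, no_bias = 10745))
#' @export
proportion_table <- function(counts, denominator = NULL) {
  if (length(counts) == 0) abort("`counts` is empty.")
  if (is.data.frame(counts)) {
    if (!all(c("stratum", "count") %in% names(counts))) {
      abort("a counts data frame needs columns `stratum` and `count`.")
    }
    strata <- counts$stratum
    counts <- counts$count
  } else {
    if (is.null(names(counts)) || any(names(counts) == "")) {
      abort("`counts` must be fully named.")
    }
    strata <- names(counts)
  }
  if (any(counts < 0)) abort("counts must be non-negative.")
  denominator <- denominator %||% sum(counts)
  if (abs(sum(counts) - denominator) > 1e-9) {
    abort("counts do not sum to the declared denominator.")
  }
  counts <- unname(as.numeric(counts))
  tibble(
    stratum = as.character(strata),
    count = counts,
    proportion = counts / denominator,
    percent = round(100 * counts / denominator, 1)
  )
}

count_strata <- function(values, levels) {
  counts <- table(factor(values, levels = levels))
  proportion_table(setNames(as.numeric(counts), levels))
}

#' Summarise homoeolog expression bias
#'
#' Builds the two headline tables from per-pair bias calls: the progeny
#' bias state (A-biased / C-biased / no bias) and the three-way
#' parental-to-progeny transition table (maintained / novel / reverted), in
#' which the rare switched pairs are folded into `novel` so the three
#' classes partition all expressed pairs; the full four-way table is kept
#' alongside.
#'
#' @param bias Result of [classify_bias()], one row per expressed pair.
#' @return A list of class `bias_summary`: `progeny`, `transition`,
#'   `transition_detail` (each a [proportion_table()]), and `denominator`.
#' @export
summarize_bias <- function(bias) {
  if (nrow(bias) == 0) abort("`bias` is empty.")
  if (anyDuplicated(bias$pair_id)) abort("duplicate pair_id in `bias`.")
  progeny <- count_strata(
    dplyr::case_match(bias$progeny_state,
                      "A_gt" ~ "A_biased", "C_gt" ~ "C_biased",
                      "EQ" ~ "no_bias"),
    c("A_biased", "C_biased", "no_bias")
  )
  three_way <- ifelse(bias$transition == "switched", "novel", bias$transition)
  transition <- count_strata(three_way, c("maintained", "novel", "reverted"))
  detail <- count_strata(bias$transition,
                         c("maintained", "novel", "reverted", "switched"))
  structure(
    list(progeny = progeny, transition = transition,
         transition_detail = detail, denominator = nrow(bias)),
    class = "bias_summary"
  )
}

#' Summarise expression level dominance
#'
#' Group-level and per-category count tables over all expressed pairs.
#'
#' @param eld Result of [classify_eld()], one row per expressed pair.
#' @return A list of class `eld_summary`: `group` and `category`
#'   [proportion_table()]s and `denominator`.
#' @export
summarize_eld <- function(eld) {
  if (nrow(eld) == 0) abort("`eld` is empty.")
  if (anyDuplicated(eld$pair_id)) abort("duplicate pair_id in `eld`.")
  structure(
    list(group = count_strata(eld$group, ELD_GROUPS),
         category = count_strata(eld$category, ELD_CATEGORIES),
         denominator = nrow(eld)),
    class = "eld_summary"
  )
}

complete_cells <- function(cells) {
  lv <- c("up", "down", "unchanged")
  tidyr::complete(cells, category, change_A = lv, change_C = lv,
                  fill = list(n = 0L))
}

#' Mechanism totals from homoeolog-change cell counts
#'
#' Given per-category counts of the (A-homoeolog change x C-homoeolog
#' change) cells for ELD pairs, computes the mechanism sums used to explain
#' dominance. For higher-parent categories (IV, II) `dominant_down` counts
#' every pair whose dominant-parent homoeolog is down (whatever the other
#' homoeolog does) and `nondominant_up` every pair whose nondominant
#' homoeolog is up, so a pair with both changes contributes to both sums.
#' For lower-parent categories (IX, XI) `nondominant_down` counts pairs
#' with only the nondominant homoeolog down and `both_down` pairs with both
#' homoeologs down.
#'
#' @param cells Tibble with columns `category` (IV, II, IX or XI),
#'   `change_A`, `change_C` (each `"up"`, `"down"` or `"unchanged"`) and
#'   `n`.
#' @return Tibble: `category`, `mechanism`, `n_pairs`.
#' @export
explain_mechanism_totals <- function(cells) {
  need <- c("category", "change_A", "change_C", "n")
  if (!all(need %in% names(cells))) {
    abort("`cells` needs columns category, change_A, change_C, n.")
  }
  purrr::map_dfr(intersect(c("IV", "II", "IX", "XI"), cells$category),
                 function(cat) {
    cc <- dplyr::filter(cells, .data$category == cat)
    dom <- if (cat %in% c("IV", "IX")) cc$change_A else cc$change_C
    nondom <- if (cat %in% c("IV", "IX")) cc$change_C else cc$change_A
    if (cat %in% c("IV", "II")) {
      tibble(category = cat,
             mechanism = c("dominant_down", "nondominant_up"),
             n_pairs = c(sum(cc$n[dom == "down"]),
                         sum(cc$n[nondom == "up"])))
    } else {
      tibble(category = cat,
             mechanism = c("nondominant_down", "both_down"),
             n_pairs = c(sum(cc$n[nondom == "down" & dom == "unchanged"]),
                         sum(cc$n[nondom == "down" & dom == "down"])))
    }
  })
}

#' Modification marginals from homoeolog-change cell counts
#'
#' @param cells Tibble with columns `change_A`, `change_C`, `n` (category
#'   granularity is ignored).
#' @return One-row tibble: `a_modified`, `c_modified`, `none_modified`,
#'   `total`, `pct_modified` (percent of pairs with at least one homoeolog
#'   changed, to one decimal).
#' @export
explain_marginals <- function(cells) {
  if (!all(c("change_A", "change_C", "n") %in% names(cells))) {
    abort("`cells` needs columns change_A, change_C, n.")
  }
  total <- sum(cells$n)
  none <- sum(cells$n[cells$change_A == "unchanged" &
                        cells$change_C == "unchanged"])
  tibble(
    a_modified = sum(cells$n[cells$change_A != "unchanged"]),
    c_modified = sum(cells$n[cells$change_C != "unchanged"]),
    none_modified = none,
    total = total,
    pct_modified = round(100 * (total - none) / total, 1)
  )
}

#' Summarise the homoeolog-level explanation of ELD
#'
#' Cross-tabulates the per-homoeolog changes of every ELD pair, per
#' category and overall, and derives the mechanism totals and modification
#' marginals.
#'
#' @param explain Result of [explain_eld()].
#' @param eld Result of [classify_eld()] for the same pairs; used to check
#'   that every ELD-group pair is covered.
#' @return A list of class `explain_summary`: `cells` (per-category 3x3
#'   counts), `cells_all` (summed over categories), `mechanism`
#'   ([explain_mechanism_totals()]), `marginals` ([explain_marginals()]).
#' @export
summarize_explain <- function(explain, eld) {
  eld_ids <- eld$pair_id[eld$group %in% c("ELD_A", "ELD_C")]
  missing_ids <- setdiff(eld_ids, explain$pair_id)
  if (length(missing_ids) > 0) {
    abort(paste0("explain results missing for ELD pairs: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  cells <- explain |>
    dplyr::count(.data$category, .data$change_A, .data$change_C) |>
    complete_cells()
  cells_all <- cells |>
    dplyr::count(.data$change_A, .data$change_C, wt = .data$n, name = "n")
  structure(
    list(cells = cells, cells_all = cells_all,
         mechanism = explain_mechanism_totals(cells),
         marginals = explain_marginals(cells_all)),
    class = "explain_summary"
  )
}

#' Hypergeometric term enrichment over a study gene list
#'
#' One-sided (upper-tail) hypergeometric test of each term's annotated
#' genes against the background, with Benjamini-Hochberg adjustment across
#' all tested terms. A term is tested when it annotates at least one study
#' gene; `enriched` flags terms with `q <= fdr_cutoff` (default 0.001, the
#' stringent convention for GO enrichment).
#'
#' @param study Character vector of study gene ids (a subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param term_map Tibble from [read_gmt()]: `term`, `description`,
#'   `genes` list-column.
#' @param fdr_cutoff FDR threshold for the `enriched` flag (default 0.001).
#' @return Tibble sorted by `q` then `p`: `term`, `description`, `k`, `n`,
#'   `K`, `N`, `p`, `q`, `enriched`.
#' @export
enrich <- function(study, background, term_map, fdr_cutoff = 0.001) {
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0) abort("`study` is empty.")
  outside <- setdiff(study, background)
  if (length(outside) > 0) {
    abort(paste0("study genes absent from the background: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  if (!all(c("term", "genes") %in% names(term_map))) {
    abort("`term_map` needs columns `term` and `genes` (see read_gmt()).")
  }
  N <- length(background)
  n <- length(study)
  rows <- purrr::pmap_dfr(
    list(term_map$term,
         term_map$description %||% rep(NA_character_, nrow(term_map)),
         term_map$genes),
    function(term, description, genes) {
      in_bg <- intersect(genes, background)
      k <- length(intersect(genes, study))
      if (k == 0) return(NULL)
      tibble(term = term, description = description,
             k = k, n = n, K = length(in_bg), N = N)
    }
  )
  if (nrow(rows) == 0) {
    abort("no term annotates any study gene.")
  }
  rows$p <- hypergeom_tail(rows$k, rows$n, rows$K, rows$N)
  rows$q <- bh_fdr(rows$p)
  rows$enriched <- rows$q <= fdr_cutoff
  dplyr::arrange(rows, .data$q, .data$p)
}
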