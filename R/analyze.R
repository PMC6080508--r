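# One-call pipeline over the three expression tables and the pair map:
# expression filter -> pair assembly -> bias, ELD and explanation calls,
# with broom-style accessors on the result.

#' Run the full homoeolog-pair analysis
#'
#' Filters the pair map to pairs expressed in at least one species
#' ([expressed_pairs()]), assembles per-pair replicate data
#' ([pair_expression()]) and runs the three classifiers:
#' [classify_bias()], [classify_eld()] and, for ELD pairs,
#' [explain_eld()].
#'
#' @inheritParams pair_expression
#' @param alpha Significance level of all per-pair t-tests (default 0.05).
#' @param expr_cutoff FPKM expression cutoff (default 1).
#' @return An object of class `homoeolog_analysis`: a list with
#'   `pairs_expressed`, `bias`, `eld`, `explain` tibbles, the summaries
#'   `bias_summary` and `eld_summary`, and `params`. Use [tidy()] for the
#'   per-pair table, [glance()] for a one-row overview and [autoplot()]
#'   for a category barplot.
#' @export
analyze_homoeologs <- function(pairs, expr_parentA, expr_parentC,
                               expr_polyploid, alpha = 0.05,
                               expr_cutoff = 1) {
  kept <- expressed_pairs(pairs, expr_parentA, expr_parentC,
                          expr_polyploid, cutoff = expr_cutoff)
  if (nrow(kept) == 0) {
    abort("no pair is expressed above the cutoff in any species.")
  }
  pe <- pair_expression(kept, expr_parentA, expr_parentC, expr_polyploid)
  bias <- classify_bias(pe, alpha)
  eld <- classify_eld(pe, alpha)
  explain <- if (any(eld$group %in% c("ELD_A", "ELD_C"))) {
    explain_eld(pe, eld, alpha)
  } else {
    tibble(pair_id = character(), category = character(),
           eld_direction = character(), change_A = character(),
           change_C = character(), p_A = numeric(), p_C = numeric(),
           mechanism = character())
  }
  structure(
    list(
      pairs_expressed = kept,
      bias = bias,
      eld = eld,
      explain = explain,
      bias_summary = summarize_bias(bias),
      eld_summary = summarize_eld(eld),
      params = list(alpha = alpha, expr_cutoff = expr_cutoff,
                    n_pairs_input = nrow(pairs),
                    n_pairs_expressed = nrow(kept))
    ),
    class = "homoeolog_analysis"
  )
}

#' @export
print.homoeolog_analysis <- function(x, ...) {
  cat("<homoeolog_analysis> ", x$params$n_pairs_expressed, " of ",
      x$params$n_pairs_input, " pairs expressed (FPKM >= ",
      x$params$expr_cutoff, "), alpha = ", x$params$alpha, "\n", sep = "")
  g <- x$eld_summary$group
  cat("  ELD groups: ",
      paste0(g$stratum, " ", g$count, " (", g$percent, "%)",
             collapse = ", "), "\n", sep = "")
  b <- x$bias_summary$progeny
  cat("  progeny bias: ",
      paste0(b$stratum, " ", b$count, " (", b$percent, "%)",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-pair classification table
#'
#' @param x A `homoeolog_analysis` object.
#' @param ... Unused.
#' @return A tibble with one row per expressed pair joining the bias, ELD
#'   and (where applicable) explanation calls.
#' @exportS3Method generics::tidy
tidy.homoeolog_analysis <- function(x, ...) {
  x$bias |>
    dplyr::select("pair_id", "parent_state", "progeny_state", "transition") |>
    dplyr::left_join(
      dplyr::select(x$eld, "pair_id", "category", "group", "eld_direction",
                    "consistent"),
      by = "pair_id"
    ) |>
    dplyr::left_join(
      dplyr::select(x$explain, "pair_id", "change_A", "change_C",
                    "mechanism"),
      by = "pair_id"
    )
}

#' One-row analysis overview
#'
#' @param x A `homoeolog_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: pair counts, percentage of progeny-biased
#'   pairs, and the percentage of expressed pairs in each ELD group.
#' @exportS3Method generics::glance
glance.homoeolog_analysis <- function(x, ...) {
  g <- x$eld_summary$group
  pct <- setNames(g$percent, paste0("pct_", tolower(g$stratum)))
  dplyr::bind_cols(
    tibble(
      n_pairs_input = x$params$n_pairs_input,
      n_pairs_expressed = x$params$n_pairs_expressed,
      pct_progeny_biased = round(
        100 * sum(x$bias$progeny_state != "EQ") / nrow(x$bias), 1)
    ),
    as_tibble(as.list(pct))
  )
}

#' @rdname plot_eld_summary
#' @param object A `homoeolog_analysis` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.homoeolog_analysis <- function(object, ...) {
  plot_eld_summary(object$eld_summary)
}
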