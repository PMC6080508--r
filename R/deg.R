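# Expression filtering and differential-expression calling between each
# allopolyploid subgenome and its corresponding diploid parent.

#' Flag expressed genes
#'
#' A gene counts as expressed when its replicate-mean FPKM reaches the
#' cutoff (default 1, the conventional empirical threshold).
#'
#' @param expr Expression tibble (see [read_expression()]).
#' @param cutoff FPKM threshold, >= 0 (default 1).
#' @return Tibble: `gene_id`, optional `subgenome`, `mean_fpkm`,
#'   `expressed`.
#' @export
filter_expressed <- function(expr, cutoff = 1) {
  if (!is.numeric(cutoff) || cutoff < 0) abort("`cutoff` must be >= 0.")
  m <- expr_matrix(expr)
  out <- tibble(gene_id = expr$gene_id)
  if ("subgenome" %in% names(expr)) out$subgenome <- expr$subgenome
  out$mean_fpkm <- unname(rowMeans(m))
  out$expressed <- out$mean_fpkm >= cutoff
  out
}

#' Restrict a pair map to pairs expressed in at least one species
#'
#' A pair is retained when it is expressed in parent A, in parent C, or in
#' the allopolyploid, where polyploid-level expression is judged on the
#' per-replicate pair total `A_n + C_n` (the same total used for the ELD
#' comparison) and per-parent expression on the replicate mean of the
#' single homoeolog.
#'
#' @param pairs Pair-map tibble (`pair_id`, `gene_id_A`, `gene_id_C`).
#' @param expr_parentA,expr_parentC,expr_polyploid Expression tables; the
#'   polyploid table needs a `subgenome` column.
#' @param cutoff FPKM threshold (default 1).
#' @return The retained subset of `pairs` with mean-expression columns
#'   `mean_Ar`, `mean_Co`, `mean_poly` appended.
#' @export
expressed_pairs <- function(pairs, expr_parentA, expr_parentC,
                            expr_polyploid, cutoff = 1) {
  check_pair_map(pairs)
  if (!is.numeric(cutoff) || cutoff < 0) abort("`cutoff` must be >= 0.")
  poly_A <- dplyr::filter(expr_polyploid, .data$subgenome == "A")
  poly_C <- dplyr::filter(expr_polyploid, .data$subgenome == "C")
  miss <- c(
    setdiff(pairs$gene_id_A, expr_parentA$gene_id),
    setdiff(pairs$gene_id_C, expr_parentC$gene_id),
    setdiff(pairs$gene_id_A, poly_A$gene_id),
    setdiff(pairs$gene_id_C, poly_C$gene_id)
  )
  if (length(miss) > 0) {
    abort(paste0("pair genes missing from expression tables: ",
                 paste(unique(miss), collapse = ", ")))
  }
  mean_of <- function(tbl, ids) {
    m <- expr_matrix(tbl)
    unname(rowMeans(m[match(ids, tbl$gene_id), , drop = FALSE]))
  }
  m_Ar <- mean_of(expr_parentA, pairs$gene_id_A)
  m_Co <- mean_of(expr_parentC, pairs$gene_id_C)
  mA <- expr_matrix(poly_A)[match(pairs$gene_id_A, poly_A$gene_id), , drop = FALSE]
  mC <- expr_matrix(poly_C)[match(pairs$gene_id_C, poly_C$gene_id), , drop = FALSE]
  m_poly <- unname(rowMeans(mA + mC))
  keep <- m_Ar >= cutoff | m_Co >= cutoff | m_poly >= cutoff
  out <- pairs[keep, ]
  out$mean_Ar <- m_Ar[keep]
  out$mean_Co <- m_Co[keep]
  out$mean_poly <- m_poly[keep]
  out
}

#' Call differentially expressed genes between a subgenome and its parent
#'
#' For the genes shared between one subgenome of the allopolyploid and the
#' corresponding parent, tests `log2(FPKM + pseudocount)` replicate values
#' with Student's t-test, adjusts p-values with Benjamini-Hochberg across
#' all tested genes of the comparison, and calls a gene `up` or `down`
#' (polyploid over parent) when `q <= fdr_cutoff` and
#' `|log2 fold change| >= lfc_cutoff`. Only genes expressed (replicate mean
#' >= `expr_cutoff`) in at least one of the two tables are tested.
#'
#' @param expr_polyploid Polyploid expression table with a `subgenome`
#'   column.
#' @param expr_parent Parent expression table for the same subgenome.
#' @param subgenome `"A"` or `"C"`: which subgenome to compare.
#' @param fdr_cutoff BH FDR threshold (default 0.05).
#' @param lfc_cutoff Absolute log2-fold-change threshold in bits
#'   (default 1).
#' @param pseudocount Stabilising constant added before the log (default 1).
#' @param expr_cutoff Expression filter applied before testing (default 1).
#' @return Tibble with one row per tested gene: `gene_id`, `subgenome`,
#'   `mean_polyploid`, `mean_parent`, `log2fc`, `p`, `q`, `status`
#'   (`"up"`, `"down"`, `"not_de"`).
#' @export
call_degs <- function(expr_polyploid, expr_parent, subgenome = c("A", "C"),
                      fdr_cutoff = 0.05, lfc_cutoff = 1, pseudocount = 1,
                      expr_cutoff = 1) {
  subgenome <- match.arg(subgenome)
  poly <- dplyr::filter(expr_polyploid, .data$subgenome == !!subgenome)
  genes <- intersect(poly$gene_id, expr_parent$gene_id)
  if (length(genes) == 0) {
    abort("no genes shared between the subgenome and the parent table.")
  }
  P <- expr_matrix(poly)[match(genes, poly$gene_id), , drop = FALSE]
  Q <- expr_matrix(expr_parent)[match(genes, expr_parent$gene_id), , drop = FALSE]
  if (ncol(P) < 2 || ncol(Q) < 2) abort("each table needs >= 2 replicates.")
  tested <- rowMeans(P) >= expr_cutoff | rowMeans(Q) >= expr_cutoff
  P <- P[tested, , drop = FALSE]
  Q <- Q[tested, , drop = FALSE]
  genes <- genes[tested]
  if (length(genes) == 0) {
    abort("no genes pass the expression filter in this comparison.")
  }
  tt <- row_t_test(log2(P + pseudocount), log2(Q + pseudocount))
  mean_poly <- unname(rowMeans(P))
  mean_parent <- unname(rowMeans(Q))
  lfc <- log2_fold_change(mean_poly, mean_parent, pseudocount)
  q <- bh_fdr(tt$p)
  status <- dplyr::case_when(
    q <= fdr_cutoff & lfc >= lfc_cutoff ~ "up",
    q <= fdr_cutoff & lfc <= -lfc_cutoff ~ "down",
    TRUE ~ "not_de"
  )
  tibble(
    gene_id = genes, subgenome = subgenome,
    mean_polyploid = mean_poly, mean_parent = mean_parent,
    log2fc = lfc, p = tt$p, q = q, status = status
  )
}

#' Summarise DEG calls
#'
#' Counts up/down/not-DE genes per subgenome comparison and, when the
#' number of expressed polyploid genes is supplied, the DEG percentage of
#' expressed genes.
#'
#' @param degs One or more [call_degs()] results row-bound together.
#' @param n_expressed Optional denominator: number of expressed genes in
#'   the allopolyploid.
#' @return A list with `by_subgenome` (counts per subgenome and status) and
#'   `overall` (one-row tibble: `n_tested`, `n_deg`, `pct_down_of_deg`,
#'   and `pct_deg_of_expressed` when `n_expressed` is given).
#' @export
deg_summary <- function(degs, n_expressed = NULL) {
  if (nrow(degs) == 0) abort("`degs` is empty.")
  by_sub <- degs |>
    dplyr::count(.data$subgenome, .data$status) |>
    tidyr::complete(subgenome = unique(degs$subgenome),
                    status = c("up", "down", "not_de"),
                    fill = list(n = 0L))
  n_deg <- sum(degs$status != "not_de")
  overall <- tibble(
    n_tested = nrow(degs),
    n_deg = n_deg,
    pct_down_of_deg = if (n_deg > 0) {
      round(100 * sum(degs$status == "down") / n_deg, 1)
    } else {
      NA_real_
    }
  )
  if (!is.null(n_expressed)) {
    overall$pct_deg_of_expressed <- round(100 * n_deg / n_expressed, 1)
  }
  list(by_subgenome = by_sub, overall = overall)
}
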