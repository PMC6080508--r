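# Per-pair classification core: homoeolog expression bias with
# parental-to-progeny transitions, the 12-category expression-level-dominance
# (ELD) decision table, the homoeolog-level explanation of ELD, and the
# exact-mean truth oracle used by the simulator.
#
# Notation: A_r / C_o are the homoeolog expression levels in the two diploid
# parents (A-genome and C-genome respectively); A_n / C_n are the
# corresponding homoeologs in the allopolyploid; S = A_n + C_n is the
# per-replicate pair total compared against each parent.

ELD_GROUPS <- c("NoChange", "ELD_A", "ELD_C", "Additivity", "TransUp", "TransDown")
ELD_CATEGORIES <- c("NoChange", "I", "II", "III", "IV", "V", "VI",
                    "VII", "VIII", "IX", "X", "XI", "XII")

# Decision table on the ternary outcomes d1 = dir(S vs A_r),
# d2 = dir(S vs C_o), dAC = dir(A_r vs C_o). The parents' comparison dAC only
# orients the transgressive subclasses; ELD and additivity are decided by the
# two S-versus-parent calls alone.
eld_category_from_directions <- function(d1, d2, dAC) {
  category <- rep("NoChange", length(d1))
  category[d1 == "EQ" & d2 == "GT"] <- "IV"
  category[d1 == "EQ" & d2 == "LT"] <- "IX"
  category[d1 == "GT" & d2 == "EQ"] <- "II"
  category[d1 == "LT" & d2 == "EQ"] <- "XI"
  category[d1 == "GT" & d2 == "LT"] <- "I"
  category[d1 == "LT" & d2 == "GT"] <- "XII"
  up <- d1 == "GT" & d2 == "GT"
  category[up] <- c(LT = "V", EQ = "VI", GT = "VIII")[dAC[up]]
  down <- d1 == "LT" & d2 == "LT"
  category[down] <- c(LT = "III", EQ = "VII", GT = "X")[dAC[down]]
  category
}

eld_group_of <- function(category) {
  dplyr::case_match(category,
    "NoChange" ~ "NoChange",
    c("IV", "IX") ~ "ELD_A",
    c("II", "XI") ~ "ELD_C",
    c("I", "XII") ~ "Additivity",
    c("V", "VI", "VIII") ~ "TransUp",
    c("III", "VII", "X") ~ "TransDown"
  )
}

eld_direction_of <- function(category) {
  dplyr::case_match(category,
    c("IV", "II") ~ "higher_parent",
    c("IX", "XI") ~ "lower_parent",
    .default = "n/a"
  )
}

# A category's geometry implies a parent-vs-parent relation (e.g. IV means
# S = A_r > C_o, so A_r must exceed C_o). `consistent` is FALSE only when the
# observed dAC significantly contradicts that relation; a non-significant EQ
# is never treated as a contradiction for directional categories.
eld_consistency <- function(category, dAC) {
  expected <- dplyr::case_match(category,
    c("IV", "XI", "XII") ~ "GT",  # require A_r > C_o
    c("II", "IX", "I") ~ "LT",    # require A_r < C_o
    .default = NA_character_
  )
  ok <- rep(TRUE, length(category))
  dir_cat <- !is.na(expected)
  opposite <- c(GT = "LT", LT = "GT")
  ok[dir_cat] <- dAC[dir_cat] != opposite[expected[dir_cat]]
  ok[category == "NoChange"] <- dAC[category == "NoChange"] == "EQ"
  ok
}

bias_state_of <- function(direction) {
  dplyr::case_match(direction, "GT" ~ "A_gt", "LT" ~ "C_gt", "EQ" ~ "EQ")
}

bias_transition_of <- function(parent_state, progeny_state) {
  dplyr::case_when(
    parent_state == progeny_state ~ "maintained",
    parent_state == "EQ" ~ "novel",
    progeny_state == "EQ" ~ "reverted",
    TRUE ~ "switched"
  )
}

change_of <- function(direction) {
  dplyr::case_match(direction, "GT" ~ "up", "LT" ~ "down", "EQ" ~ "unchanged")
}

# Mechanism label for an ELD pair given the per-homoeolog changes relative to
# the parents. The dominant homoeolog is the one inherited from the parent
# whose level the pair total matches (A for ELD_A, C for ELD_C).
eld_mechanism_of <- function(group, direction, change_A, change_C) {
  dom <- ifelse(group == "ELD_A", change_A, change_C)
  nondom <- ifelse(group == "ELD_A", change_C, change_A)
  dplyr::case_when(
    !group %in% c("ELD_A", "ELD_C") ~ NA_character_,
    dom == "unchanged" & nondom == "unchanged" ~ "none",
    direction == "higher_parent" & dom == "down" & nondom == "unchanged" ~ "dominant_down",
    direction == "higher_parent" & dom == "unchanged" & nondom == "up" ~ "nondominant_up",
    direction == "higher_parent" & dom == "down" & nondom == "up" ~ "dominant_down_nondominant_up",
    direction == "lower_parent" & dom == "unchanged" & nondom == "down" ~ "nondominant_down",
    direction == "lower_parent" & dom == "down" & nondom == "down" ~ "both_down",
    TRUE ~ "other"
  )
}

#' Assemble per-pair replicate data for classification
#'
#' Joins an orthologous pair map with the three expression tables and returns
#' one row per pair carrying the four replicate vectors as list-columns:
#' `A_r` and `C_o` from the diploid parents, `A_n` and `C_n` from the
#' matching subgenome rows of the allopolyploid table.
#'
#' @param pairs Pair map tibble with columns `pair_id`, `gene_id_A`,
#'   `gene_id_C` (see [read_pair_map()]), typically already filtered with
#'   [expressed_pairs()].
#' @param expr_parentA,expr_parentC,expr_polyploid Expression tables (see
#'   [read_expression()]); the polyploid table must carry a `subgenome`
#'   column with values `"A"` and `"C"`.
#' @return A tibble of class `pair_expression`: `pair_id`, `gene_id_A`,
#'   `gene_id_C` and list-columns `A_r`, `C_o`, `A_n`, `C_n`.
#' @export
pair_expression <- function(pairs, expr_parentA, expr_parentC, expr_polyploid) {
  check_pair_map(pairs)
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
  rows <- function(tbl, ids) {
    m <- expr_matrix(tbl)
    m[match(ids, tbl$gene_id), , drop = FALSE]
  }
  out <- tibble(
    pair_id = pairs$pair_id,
    gene_id_A = pairs$gene_id_A,
    gene_id_C = pairs$gene_id_C,
    A_r = asplit(rows(expr_parentA, pairs$gene_id_A), 1),
    C_o = asplit(rows(expr_parentC, pairs$gene_id_C), 1),
    A_n = asplit(rows(poly_A, pairs$gene_id_A), 1),
    C_n = asplit(rows(poly_C, pairs$gene_id_C), 1)
  )
  class(out) <- c("pair_expression", class(out))
  out
}

# list-column -> replicate matrix (pairs x replicates)
pe_matrix <- function(pe, col) {
  do.call(rbind, pe[[col]])
}

check_pair_expression <- function(pe) {
  need <- c("pair_id", "A_r", "C_o", "A_n", "C_n")
  if (!all(need %in% names(pe))) {
    abort("expected a `pair_expression` table with columns pair_id, A_r, C_o, A_n, C_n.")
  }
  if (nrow(pe) == 0) abort("no pairs to classify.")
  invisible(pe)
}

#' Classify homoeolog expression bias and its parental-to-progeny transition
#'
#' For each homoeolog pair, compares the two parental levels (`A_r` vs `C_o`)
#' and the two homoeolog levels in the allopolyploid (`A_n` vs `C_n`) with
#' Student's t-test at `alpha`, and labels the transition between the two
#' states: `maintained` (same state), `novel` (unbiased parents, biased
#' progeny), `reverted` (biased parents, unbiased progeny) or `switched`
#' (bias flipping between subgenomes).
#'
#' @param pe A [pair_expression()] table.
#' @param alpha Significance level of the per-pair t-tests (default 0.05).
#' @return Tibble: `pair_id`, `parent_state`, `progeny_state` (each
#'   `"A_gt"`, `"EQ"` or `"C_gt"`), `p_parent`, `p_progeny`, `transition`.
#' @export
classify_bias <- function(pe, alpha = 0.05) {
  check_pair_expression(pe)
  parent <- row_t_test(pe_matrix(pe, "A_r"), pe_matrix(pe, "C_o"), alpha)
  progeny <- row_t_test(pe_matrix(pe, "A_n"), pe_matrix(pe, "C_n"), alpha)
  parent_state <- bias_state_of(parent$direction)
  progeny_state <- bias_state_of(progeny$direction)
  tibble(
    pair_id = pe$pair_id,
    parent_state = parent_state,
    progeny_state = progeny_state,
    p_parent = parent$p,
    p_progeny = progeny$p,
    transition = bias_transition_of(parent_state, progeny_state)
  )
}

#' Classify expression level dominance (12-category decision table)
#'
#' Compares the pair total in the allopolyploid (`S = A_n + C_n`, summed per
#' replicate) against each parent with Student's t-test at `alpha`, and maps
#' the two ternary outcomes onto the twelve differential-expression classes:
#' equivalence with both parents (`NoChange`), dominance toward the A-genome
#' parent (`ELD_A`: categories IV and IX) or the C-genome parent (`ELD_C`:
#' II and XI), mid-parent additivity (I and XII), and transgressive
#' expression above (V, VI, VIII) or below (III, VII, X) both parents, the
#' transgressive subclasses being oriented by the parents' own comparison.
#'
#' @inheritParams classify_bias
#' @return Tibble: `pair_id`, three p-values (`p_SA`, `p_SC`, `p_AC`) and
#'   directions (`d_SA`, `d_SC`, `d_AC`), `category` (`"NoChange"`,
#'   `"I"`–`"XII"`), `group` (one of `NoChange`, `ELD_A`, `ELD_C`,
#'   `Additivity`, `TransUp`, `TransDown`), `eld_direction`
#'   (`"higher_parent"`, `"lower_parent"` or `"n/a"`), and `consistent`
#'   (FALSE when the parents' comparison significantly contradicts the
#'   category geometry).
#' @export
classify_eld <- function(pe, alpha = 0.05) {
  check_pair_expression(pe)
  An <- pe_matrix(pe, "A_n")
  Cn <- pe_matrix(pe, "C_n")
  if (!identical(dim(An), dim(Cn))) {
    abort("A and C subgenome replicate counts differ; cannot form pair totals.")
  }
  S <- An + Cn
  Ar <- pe_matrix(pe, "A_r")
  Co <- pe_matrix(pe, "C_o")
  t_SA <- row_t_test(S, Ar, alpha)
  t_SC <- row_t_test(S, Co, alpha)
  t_AC <- row_t_test(Ar, Co, alpha)
  category <- eld_category_from_directions(t_SA$direction, t_SC$direction,
                                           t_AC$direction)
  tibble(
    pair_id = pe$pair_id,
    p_SA = t_SA$p, p_SC = t_SC$p, p_AC = t_AC$p,
    d_SA = t_SA$direction, d_SC = t_SC$direction, d_AC = t_AC$direction,
    category = category,
    group = eld_group_of(category),
    eld_direction = eld_direction_of(category),
    consistent = eld_consistency(category, t_AC$direction)
  )
}

#' Explain ELD by individual homoeolog changes relative to the parents
#'
#' For pairs classified as ELD, compares each homoeolog in the allopolyploid
#' with its own parent (`A_n` vs `A_r`, `C_n` vs `C_o`) and assigns a
#' mechanism label. For higher-parent dominance (IV, II) the recognised
#' mechanisms are downregulation of the dominant-parent homoeolog
#' (`dominant_down`), upregulation of the nondominant-parent homoeolog
#' (`nondominant_up`) or both at once; for lower-parent dominance (IX, XI)
#' they are downregulation of the nondominant homoeolog alone
#' (`nondominant_down`) or of both homoeologs (`both_down`). Pairs with
#' neither homoeolog changed get `none`; any other combination gets `other`.
#'
#' @inheritParams classify_bias
#' @param eld Result of [classify_eld()] covering the pairs in `pe`.
#' @return Tibble with one row per ELD-group pair: `pair_id`, `category`,
#'   `eld_direction`, `change_A`, `change_C` (each `"up"`, `"down"` or
#'   `"unchanged"`), `p_A`, `p_C`, `mechanism`.
#' @export
explain_eld <- function(pe, eld, alpha = 0.05) {
  check_pair_expression(pe)
  if (!all(c("pair_id", "group", "category") %in% names(eld))) {
    abort("`eld` must be the result of classify_eld().")
  }
  eld_pairs <- dplyr::filter(eld, .data$group %in% c("ELD_A", "ELD_C"))
  if (nrow(eld_pairs) == 0) {
    abort("no ELD-group pairs to explain; explain_eld() applies only to ELD_A/ELD_C pairs.")
  }
  missing_ids <- setdiff(eld_pairs$pair_id, pe$pair_id)
  if (length(missing_ids) > 0) {
    abort(paste0("ELD pairs absent from the pair-expression table: ",
                 paste(missing_ids, collapse = ", ")))
  }
  pe_sub <- pe[match(eld_pairs$pair_id, pe$pair_id), ]
  t_A <- row_t_test(pe_matrix(pe_sub, "A_n"), pe_matrix(pe_sub, "A_r"), alpha)
  t_C <- row_t_test(pe_matrix(pe_sub, "C_n"), pe_matrix(pe_sub, "C_o"), alpha)
  change_A <- change_of(t_A$direction)
  change_C <- change_of(t_C$direction)
  tibble(
    pair_id = eld_pairs$pair_id,
    category = eld_pairs$category,
    eld_direction = eld_pairs$eld_direction,
    change_A = change_A,
    change_C = change_C,
    p_A = t_A$p,
    p_C = t_C$p,
    mechanism = eld_mechanism_of(eld_pairs$group, eld_pairs$eld_direction,
                                 change_A, change_C)
  )
}

#' Exact-mean truth labels for a homoeolog pair
#'
#' Applies the same decision tables as [classify_bias()], [classify_eld()]
#' and [explain_eld()] to noise-free true means, with `EQ` meaning exact
#' equality (to a relative tolerance of 1e-9) and `GT`/`LT` decided by sign;
#' no p-values are involved. This is the ground-truth oracle attached to
#' every simulated pair.
#'
#' @param mu_Ar,mu_Co,mu_An,mu_Cn Non-negative true mean expression values
#'   (vectorised).
#' @return Tibble: `category`, `group`, `eld_direction`, `bias_parent`,
#'   `bias_progeny`, `bias_transition`, `change_A`, `change_C`, `mechanism`
#'   (`NA` outside ELD groups).
#' @examples
#' truth_label(4, 1, 3, 1) # category IV, ELD_A, dominant_down
#' @export
truth_label <- function(mu_Ar, mu_Co, mu_An, mu_Cn) {
  if (any(c(mu_Ar, mu_Co, mu_An, mu_Cn) < 0)) {
    abort("true means must be non-negative.")
  }
  exact_dir <- function(a, b) {
    ifelse(near_equal(a, b), "EQ", ifelse(a > b, "GT", "LT"))
  }
  S <- mu_An + mu_Cn
  d_SA <- exact_dir(S, mu_Ar)
  d_SC <- exact_dir(S, mu_Co)
  d_AC <- exact_dir(mu_Ar, mu_Co)
  category <- eld_category_from_directions(d_SA, d_SC, d_AC)
  group <- eld_group_of(category)
  direction <- eld_direction_of(category)
  bias_parent <- bias_state_of(d_AC)
  bias_progeny <- bias_state_of(exact_dir(mu_An, mu_Cn))
  change_A <- change_of(exact_dir(mu_An, mu_Ar))
  change_C <- change_of(exact_dir(mu_Cn, mu_Co))
  tibble(
    category = category,
    group = group,
    eld_direction = direction,
    bias_parent = bias_parent,
    bias_progeny = bias_progeny,
    bias_transition = bias_transition_of(bias_parent, bias_progeny),
    change_A = change_A,
    change_C = change_C,
    mechanism = eld_mechanism_of(group, direction, change_A, change_C)
  )
}
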