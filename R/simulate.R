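# Synthetic homoeolog-pair expression data with exact ground truth, plus
# synthetic per-base depth tracks. Each simulated pair follows a template: a
# quadruple of true means (A_r, C_o, A_n, C_n) whose classification under
# the exact-mean oracle is known by construction. Replicate noise is
# multiplicative lognormal, parameterised by the coefficient of variation,
# so simulated FPKM values are always non-negative and cv = 0 reproduces the
# true means exactly.

TEMPLATE_TRUTH_COLS <- c("category", "group", "eld_direction", "bias_parent",
                         "bias_progeny", "bias_transition", "change_A",
                         "change_C", "mechanism")

#' Construct a simulation template
#'
#' A template is a named quadruple of true mean expression levels for one
#' homoeolog pair, together with its ground-truth labels computed by the
#' exact-mean oracle [truth_label()]. Stored truth columns are a cache of
#' the oracle output, never an independent source.
#'
#' @param name Template label.
#' @param mu_Ar,mu_Co,mu_An,mu_Cn Non-negative true means. For scaled
#'   templates these are interpreted as multiples of a per-pair base level
#'   drawn at simulation time; for unscaled templates they are absolute
#'   FPKM.
#' @param scaled Whether the means scale with the per-pair base level
#'   (default `TRUE`).
#' @return One-row tibble: name, the four means, `scaled`, and the truth
#'   columns `truth_*`.
#' @export
sim_template <- function(name, mu_Ar, mu_Co, mu_An, mu_Cn, scaled = TRUE) {
  if (any(c(mu_Ar, mu_Co, mu_An, mu_Cn) < 0)) {
    abort("template means must be non-negative.")
  }
  truth <- truth_label(mu_Ar, mu_Co, mu_An, mu_Cn)
  names(truth) <- paste0("truth_", names(truth))
  dplyr::bind_cols(
    tibble(name = name, mu_Ar = mu_Ar, mu_Co = mu_Co,
           mu_An = mu_An, mu_Cn = mu_Cn, scaled = scaled),
    truth
  )
}

#' Default simulation templates
#'
#' A library of 20 templates jointly covering every classification outcome:
#' no change, ELD toward either parent in both directions (categories IV,
#' IX, II, XI) with one variant per explanation mechanism (dominant
#' homoeolog down, nondominant up, nondominant down, both down), mid-parent
#' additivity (I, XII), transgressive expression up and down under all three
#' parental relations (V/VI/VIII, III/VII/X), novel- and switched-bias
#' variants, and a below-cutoff `low_expression` template that exercises the
#' FPKM >= 1 filter. Truth labels are computed by [truth_label()], never
#' asserted.
#'
#' Template geometry assumes a clear separation between "high" and "low"
#' parental levels; with `fold_change` close to 1 some templates collapse
#' onto neighbouring categories (their cached truth labels remain correct,
#' since they are always recomputed from the means). The default
#' `fold_change = 4` keeps all templates in their nominal classes.
#'
#' @param fold_change Ratio between high- and low-expressing parental means
#'   inside the templates; must be > 1 (default 4).
#' @return Tibble of templates, one row each (see [sim_template()]).
#' @export
default_templates <- function(fold_change = 4) {
  if (!is.numeric(fold_change) || length(fold_change) != 1 || fold_change <= 1) {
    abort("`fold_change` must be a single number > 1.")
  }
  f <- fold_change
  mid <- (f + 1) / 2
  specs <- list(
    # name,                              A_r, C_o, A_n,     C_n
    list("no_change",                    1,   1,   0.5,     0.5),
    list("eld_A_higher_dominant_down",   f,   1,   f - 1,   1),
    list("eld_A_higher_nondominant_up",  f,   1,   f / 2,   f / 2),
    list("eld_A_lower_nondominant_down", 1,   f,   1,       0),
    list("eld_A_lower_both_down",        1,   f,   0.7,     0.3),
    list("eld_C_higher_dominant_down",   1,   f,   1,       f - 1),
    list("eld_C_higher_nondominant_up",  1,   f,   f / 2,   f / 2),
    list("eld_C_lower_nondominant_down", f,   1,   0,       1),
    list("eld_C_lower_both_down",        f,   1,   0.3,     0.7),
    list("additivity_I",                 1,   f,   1,       mid - 1),
    list("additivity_XII",               f,   1,   mid - 1, 1),
    list("trans_up_V",                   1,   f,   f,       f),
    list("trans_up_VI",                  1,   1,   1,       1),
    list("trans_up_VIII",                f,   1,   f,       f),
    list("trans_down_III",               1,   f,   0.25,    0.25),
    list("trans_down_VII",               1,   1,   0.25,    0.25),
    list("trans_down_X",                 f,   1,   0.25,    0.25),
    list("novel_bias",                   1,   1,   1.5,     0.5),
    list("switched_bias",                f,   1,   0.5,     1.5)
  )
  scaled <- dplyr::bind_rows(lapply(specs, function(s) {
    sim_template(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]])
  }))
  dplyr::bind_rows(
    scaled,
    sim_template("low_expression", 0.3, 0.3, 0.2, 0.2, scaled = FALSE)
  )
}

#' Default template mixture
#'
#' Per-template proportions chosen to emulate the category composition
#' observed in a resynthesized Brassica napus allotetraploid: roughly 46%
#' of expressed pairs unchanged, 40% ELD, 5% additive, 9% transgressive
#' (almost all upward), plus small novel/switched-bias and below-cutoff
#' slices.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_template_mix <- function() {
  c(
    no_change = 0.44,
    eld_A_higher_dominant_down = 0.05,
    eld_A_higher_nondominant_up = 0.05,
    eld_A_lower_nondominant_down = 0.05,
    eld_A_lower_both_down = 0.05,
    eld_C_higher_dominant_down = 0.05,
    eld_C_higher_nondominant_up = 0.05,
    eld_C_lower_nondominant_down = 0.05,
    eld_C_lower_both_down = 0.05,
    additivity_I = 0.02,
    additivity_XII = 0.02,
    trans_up_V = 0.02,
    trans_up_VI = 0.02,
    trans_up_VIII = 0.02,
    trans_down_III = 0.002,
    trans_down_VII = 0.002,
    trans_down_X = 0.002,
    novel_bias = 0.01,
    switched_bias = 0.004,
    low_expression = 0.04
  )
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of [simulate_expression()].
#'
#' @param n_pairs Number of homoeolog pairs.
#' @param template_mix Named vector of template proportions (must sum to 1);
#'   defaults to [default_template_mix()].
#' @param fold_change Template fold change, > 1 (default 4).
#' @param base_mean_range Interval (FPKM) from which each pair's base level
#'   is drawn log-uniformly; default `c(2, 500)`, comfortably above the
#'   FPKM >= 1 expression cutoff.
#' @param cv Replicate coefficient of variation of the multiplicative
#'   lognormal noise, >= 0 (default 0.2).
#' @param n_replicates Biological replicates per species, >= 2 (default 3).
#' @param seed Integer RNG seed (default 1).
#' @param templates Optional custom template tibble (see [sim_template()]);
#'   defaults to [default_templates()] at `fold_change`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 10000,
                       template_mix = default_template_mix(),
                       fold_change = 4,
                       base_mean_range = c(2, 500),
                       cv = 0.2,
                       n_replicates = 3,
                       seed = 1,
                       templates = NULL) {
  if (!is.numeric(n_pairs) || n_pairs < 1) abort("`n_pairs` must be >= 1.")
  if (length(template_mix) == 0) abort("`template_mix` must not be empty.")
  if (is.null(names(template_mix)) || any(names(template_mix) == "")) {
    abort("`template_mix` must be a named vector of proportions.")
  }
  if (any(template_mix < 0) || abs(sum(template_mix) - 1) > 1e-9) {
    abort("template proportions must be non-negative and sum to 1.")
  }
  if (!is.numeric(cv) || cv < 0) abort("`cv` must be >= 0.")
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    abort("`n_replicates` must be >= 2.")
  }
  templates <- templates %||% default_templates(fold_change)
  unknown <- setdiff(names(template_mix), templates$name)
  if (length(unknown) > 0) {
    abort(paste0("template_mix names not in the template set: ",
                 paste(unknown, collapse = ", ")))
  }
  if (length(base_mean_range) != 2 || any(base_mean_range <= 0) ||
      base_mean_range[1] > base_mean_range[2]) {
    abort("`base_mean_range` must be a positive increasing interval.")
  }
  structure(
    list(n_pairs = as.integer(n_pairs), template_mix = template_mix,
         fold_change = fold_change, base_mean_range = base_mean_range,
         cv = cv, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed), templates = templates),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_pairs, " pairs, ", x$n_replicates,
      " replicates, cv = ", x$cv, ", fold change = ", x$fold_change,
      ", seed = ", x$seed, "\n", sep = "")
  cat("  templates: ", paste(names(x$template_mix), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

lognormal_noise <- function(n_row, n_col, cv) {
  if (cv == 0) return(matrix(1, n_row, n_col))
  sigma <- sqrt(log(1 + cv^2))
  matrix(exp(rnorm(n_row * n_col, 0, sigma)), n_row, n_col)
}

#' Simulate a homoeolog-pair expression dataset with known truth
#'
#' Draws a template for each pair according to `template_mix`, a base
#' expression level log-uniformly from `base_mean_range` (applied to scaled
#' templates only), and per-replicate values `true mean * exp(N(0, sigma^2))`
#' with `sigma = sqrt(log(1 + cv^2))`. The same seed yields bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `expr_parentA`, `expr_parentC`,
#'   `expr_polyploid` (expression tibbles in the [read_expression()]
#'   layout), `pair_map`, `truth` (per-pair template, true means and
#'   oracle labels), and `config`.
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().")
  }
  set.seed(config$seed)
  n <- config$n_pairs
  n_rep <- config$n_replicates
  tpl <- config$templates
  mix <- config$template_mix

  tpl_name <- sample(names(mix), n, replace = TRUE, prob = mix)
  tpl_row <- match(tpl_name, tpl$name)
  base <- exp(runif(n, log(config$base_mean_range[1]),
                    log(config$base_mean_range[2])))
  base[!tpl$scaled[tpl_row]] <- 1

  mu <- cbind(
    mu_Ar = tpl$mu_Ar[tpl_row] * base,
    mu_Co = tpl$mu_Co[tpl_row] * base,
    mu_An = tpl$mu_An[tpl_row] * base,
    mu_Cn = tpl$mu_Cn[tpl_row] * base
  )
  vals <- lapply(colnames(mu), function(role) {
    mu[, role] * lognormal_noise(n, n_rep, config$cv)
  })
  names(vals) <- colnames(mu)

  gene_A <- sprintf("BraA%05d", seq_len(n))
  gene_C <- sprintf("BolC%05d", seq_len(n))
  pair_id <- sprintf("pair%05d", seq_len(n))
  rep_tbl <- function(m, prefix) {
    colnames(m) <- paste0(prefix, seq_len(n_rep))
    as_tibble(m)
  }

  expr_parentA <- dplyr::bind_cols(tibble(gene_id = gene_A),
                                   rep_tbl(vals$mu_Ar, "A_r"))
  expr_parentC <- dplyr::bind_cols(tibble(gene_id = gene_C),
                                   rep_tbl(vals$mu_Co, "C_r"))
  expr_polyploid <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(gene_id = gene_A, subgenome = "A"),
                     rep_tbl(vals$mu_An, "N_r")),
    dplyr::bind_cols(tibble(gene_id = gene_C, subgenome = "C"),
                     rep_tbl(vals$mu_Cn, "N_r"))
  )
  pair_map <- tibble(pair_id = pair_id, gene_id_A = gene_A,
                     gene_id_C = gene_C)
  truth <- dplyr::bind_cols(
    tibble(pair_id = pair_id, template = tpl_name,
           mu_Ar = mu[, "mu_Ar"], mu_Co = mu[, "mu_Co"],
           mu_An = mu[, "mu_An"], mu_Cn = mu[, "mu_Cn"]),
    setNames(tpl[tpl_row, paste0("truth_", TEMPLATE_TRUTH_COLS)],
             paste0("truth_", TEMPLATE_TRUTH_COLS))
  )
  structure(
    list(expr_parentA = expr_parentA, expr_parentC = expr_parentC,
         expr_polyploid = expr_polyploid, pair_map = pair_map,
         truth = truth, config = config),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$pair_map), " homoeolog pairs, ",
      x$config$n_replicates, " replicates, cv = ", x$config$cv,
      ", seed = ", x$config$seed, "\n", sep = "")
  counts <- sort(table(x$truth$truth_group), decreasing = TRUE)
  cat("  true groups: ",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a per-base depth track
#'
#' Per-base depths are independent Poisson draws with a per-chromosome mean;
#' a chromosome with mean depth 0 is emitted with all-zero depth, emulating
#' a missing chromosome.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp), all > 0.
#' @param mean_depth Mean depth, a single value or a named vector matching
#'   `chrom_lengths`; all values >= 0.
#' @param seed Optional integer RNG seed.
#' @return Tibble in the depth-track layout: `chrom`, `pos` (1-based),
#'   `depth`.
#' @export
simulate_depth <- function(chrom_lengths, mean_depth, seed = NULL) {
  if (length(chrom_lengths) == 0 || is.null(names(chrom_lengths)) ||
      any(chrom_lengths <= 0)) {
    abort("`chrom_lengths` must be a named vector of positive lengths.")
  }
  if (any(mean_depth < 0)) abort("`mean_depth` must be >= 0.")
  if (length(mean_depth) == 1) {
    mean_depth <- setNames(rep(mean_depth, length(chrom_lengths)),
                           names(chrom_lengths))
  }
  if (!all(names(chrom_lengths) %in% names(mean_depth))) {
    abort("`mean_depth` must cover every chromosome in `chrom_lengths`.")
  }
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    d <- rpois(len, mean_depth[[ch]])
    tibble(chrom = ch, pos = seq_len(len), depth = d)
  })
}
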