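# Shared fixture builders. Everything is generated in code; no files.

# Expression tibble from a vector of per-gene true means: each replicate is
# mean * exp(N(0, sigma^2)) with sigma = sqrt(log(1 + cv^2)).
make_expr <- function(means, cv = 0, n_rep = 3, prefix = "r",
                      gene_ids = NULL, subgenome = NULL) {
  n <- length(means)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n))
  noise <- if (cv == 0) {
    matrix(1, n, n_rep)
  } else {
    sigma <- sqrt(log(1 + cv^2))
    matrix(exp(rnorm(n * n_rep, 0, sigma)), n, n_rep)
  }
  m <- means * noise
  colnames(m) <- paste0(prefix, seq_len(n_rep))
  out <- tibble::tibble(gene_id = gene_ids)
  if (!is.null(subgenome)) out$subgenome <- subgenome
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

# Full four-table fixture from a matrix of pair mean quadruples
# (columns A_r, C_o, A_n, C_n), one row per pair.
make_pair_dataset <- function(mu, cv = 0, n_rep = 3) {
  n <- nrow(mu)
  gene_A <- sprintf("gA%03d", seq_len(n))
  gene_C <- sprintf("gC%03d", seq_len(n))
  list(
    pairs = tibble::tibble(pair_id = sprintf("p%03d", seq_len(n)),
                           gene_id_A = gene_A, gene_id_C = gene_C),
    expr_parentA = make_expr(mu[, 1], cv, n_rep, "A_r", gene_A),
    expr_parentC = make_expr(mu[, 2], cv, n_rep, "C_r", gene_C),
    expr_polyploid = dplyr::bind_rows(
      make_expr(mu[, 3], cv, n_rep, "N_r", gene_A, subgenome = "A"),
      make_expr(mu[, 4], cv, n_rep, "N_r", gene_C, subgenome = "C")
    )
  )
}

classify_pair_dataset <- function(ds, alpha = 0.05) {
  pe <- pair_expression(ds$pairs, ds$expr_parentA, ds$expr_parentC,
                        ds$expr_polyploid)
  list(pe = pe,
       bias = classify_bias(pe, alpha),
       eld = classify_eld(pe, alpha))
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# q_i = min over p_(j) >= p_i of p_(j) * n / rank_j, clamped at 1.
bh_brute <- function(p) {
  n <- length(p)
  vapply(seq_len(n), function(i) {
    ord <- order(p)
    ranks <- match(seq_len(n), ord)
    cand <- vapply(seq_len(n), function(j) {
      p[ord[j]] * n / j
    }, numeric(1))
    min(1, min(cand[seq(from = ranks[i], to = n)]))
  }, numeric(1))
}

# Brute-force hypergeometric upper tail as an explicit combinatorial sum.
hyper_brute <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

ref_path <- function(file) {
  system.file("extdata", file, package = "homoeologr", mustWork = TRUE)
}
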