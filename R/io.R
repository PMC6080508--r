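# Readers and writers for the package's tabular dialects. The canonical
# dialect is TSV: tab-separated, UTF-8, '#' comment lines, header required
# (except the headerless samtools-depth track). All tables come back as
# tibbles.

read_tsv_strict <- function(path, col_names = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path,
                  col_names = col_names,
                  col_types = readr::cols(.default = readr::col_character()),
                  comment = "#", na = character(), progress = FALSE)
}

# Replicate-value columns of an expression table: everything numeric except
# the identifier and subgenome tag.
expr_value_cols <- function(tbl) {
  setdiff(names(tbl), c("gene_id", "subgenome"))
}

expr_matrix <- function(tbl) {
  m <- as.matrix(tbl[expr_value_cols(tbl)])
  rownames(m) <- tbl$gene_id
  m
}

#' Read a replicate-by-gene expression table
#'
#' Reads a TSV with a `gene_id` first column and one numeric column per
#' replicate sample, in FPKM units. A `subgenome` column (values `"A"` /
#' `"C"`) is kept as a tag when present, as in homoeolog-resolved
#' allopolyploid tables. All other columns must parse as finite,
#' non-negative numbers; the first offending cell is reported by row and
#' column. When a sample sheet is given, every value column must be declared
#' in it.
#'
#' @param path Path to a TSV file (header required, `#` comments allowed).
#' @param sample_sheet Optional tibble with columns `sample`, `species`,
#'   `replicate` declaring the expected value columns.
#' @return A tibble: `gene_id`, optional `subgenome`, numeric replicate
#'   columns.
#' @export
read_expression <- function(path, sample_sheet = NULL) {
  raw <- read_tsv_strict(path)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(paste0("expression file is empty or has no value columns: ", path))
  }
  names(raw)[1] <- "gene_id"
  if (anyDuplicated(raw$gene_id)) {
    dups <- unique(raw$gene_id[duplicated(raw$gene_id)])
    abort(paste0("duplicate gene_id in ", path, ": ",
                 paste(head(dups, 5), collapse = ", ")))
  }
  value_cols <- expr_value_cols(raw)
  if (length(value_cols) == 0) abort("no replicate value columns found.")
  if (!is.null(sample_sheet)) {
    undeclared <- setdiff(value_cols, sample_sheet$sample)
    if (length(undeclared) > 0) {
      abort(paste0("columns not declared in the sample sheet: ",
                   paste(undeclared, collapse = ", ")))
    }
  }
  for (col in value_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals) | vals < 0)
    if (length(bad) > 0) {
      abort(paste0("non-numeric or negative value in ", path,
                   ", row ", bad[1], ", column '", col, "': '",
                   raw[[col]][bad[1]], "'"))
    }
    raw[[col]] <- vals
  }
  raw
}

#' Write an expression table
#'
#' @param tbl Expression tibble as returned by [read_expression()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

check_pair_map <- function(pairs) {
  need <- c("pair_id", "gene_id_A", "gene_id_C")
  if (!all(need %in% names(pairs))) {
    abort("pair map needs columns pair_id, gene_id_A, gene_id_C.")
  }
  if (anyDuplicated(pairs$gene_id_A) || anyDuplicated(pairs$gene_id_C)) {
    abort("each gene may appear in at most one pair.")
  }
  if (anyDuplicated(pairs$pair_id)) abort("pair_ids must be unique.")
  invisible(pairs)
}

#' Read an orthologous homoeolog pair map
#'
#' Accepts a 2-column TSV (`gene_id_A`, `gene_id_C`; pair ids are generated
#' from the A-gene id) or a 3-column TSV (`pair_id`, `gene_id_A`,
#' `gene_id_C`). Each gene may appear in at most one pair.
#'
#' @param path Path to the TSV file.
#' @return Tibble: `pair_id`, `gene_id_A`, `gene_id_C`.
#' @export
read_pair_map <- function(path) {
  raw <- read_tsv_strict(path)
  if (nrow(raw) == 0) abort(paste0("pair map is empty: ", path))
  if (ncol(raw) == 2) {
    names(raw) <- c("gene_id_A", "gene_id_C")
    raw <- dplyr::mutate(raw, pair_id = paste0("pair_", .data$gene_id_A),
                         .before = 1)
  } else if (ncol(raw) == 3) {
    names(raw) <- c("pair_id", "gene_id_A", "gene_id_C")
  } else {
    abort("pair map must have 2 or 3 columns.")
  }
  check_pair_map(raw)
  raw
}

#' Write a pair map
#' @param pairs Pair-map tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pair_map <- function(pairs, path) {
  check_pair_map(pairs)
  readr::write_tsv(pairs[c("pair_id", "gene_id_A", "gene_id_C")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a per-base depth track (samtools-depth dialect)
#'
#' Three headerless tab-separated columns: chromosome, 1-based position,
#' integer depth.
#'
#' @param path Path to the depth TSV.
#' @return Tibble: `chrom` (character), `pos` (1-based integer), `depth`.
#' @export
read_depth <- function(path) {
  raw <- read_tsv_strict(path, col_names = c("chrom", "pos", "depth"))
  if (nrow(raw) == 0) abort(paste0("depth track is empty: ", path))
  raw$pos <- suppressWarnings(as.integer(raw$pos))
  raw$depth <- suppressWarnings(as.numeric(raw$depth))
  if (anyNA(raw$pos) || anyNA(raw$depth)) {
    abort("depth track has non-numeric position or depth values.")
  }
  if (any(raw$pos < 1) || any(raw$depth < 0)) {
    abort("positions must be >= 1 and depths >= 0.")
  }
  raw
}

#' Write a depth track (headerless, samtools-depth dialect)
#' @param depth Tibble with `chrom`, `pos`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(depth, path) {
  readr::write_tsv(depth[c("chrom", "pos", "depth")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene-set file in GMT format
#'
#' One term per line: term id, description, then one gene id per remaining
#' tab-separated field.
#'
#' @param path Path to the GMT file.
#' @return Tibble: `term`, `description`, `genes` (list-column of character
#'   vectors).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(paste0("GMT file is empty: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    abort(paste0("GMT line ", which(short)[1],
                 " has fewer than 3 fields (term, description, genes...)."))
  }
  tibble(
    term = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Read a sample sheet
#'
#' TSV with columns `sample`, `species`, `replicate`; `species` must be one
#' of `parentA`, `parentC`, `polyploid`, each with at least two replicates.
#'
#' @param path Path to the TSV file.
#' @return Tibble: `sample`, `species`, `replicate` (integer).
#' @export
read_sample_sheet <- function(path) {
  raw <- read_tsv_strict(path)
  need <- c("sample", "species", "replicate")
  if (!all(need %in% names(raw))) {
    abort("sample sheet needs columns sample, species, replicate.")
  }
  ok_species <- c("parentA", "parentC", "polyploid")
  if (!all(raw$species %in% ok_species)) {
    abort(paste0("species must be one of: ", paste(ok_species, collapse = ", ")))
  }
  raw$replicate <- as.integer(raw$replicate)
  n_rep <- table(raw$species)
  if (any(n_rep < 2)) {
    abort("every species needs at least 2 replicate samples.")
  }
  raw
}

#' Write a run manifest
#'
#' Records the parameters of an analysis run (thresholds, seeds, input
#' paths) as pretty-printed JSON so that deterministic stages can be
#' reproduced bit-identically.
#'
#' @param params Named list of parameters.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(params, path) {
  if (is.null(names(params)) || any(names(params) == "")) {
    abort("`params` must be a fully named list.")
  }
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
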